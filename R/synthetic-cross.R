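# Synthetic founder panels, F2 crosses, environments and phenotypes.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: fully inbred founder strains, recombinant F2 individuals with
# Mendelian segregation, repeated phenotyping of each individual across
# temperatures, seasonal water-temperature draws restricted to 21-35 degC,
# and Hardy-Weinberg outbred genotypes for the power simulator.

#' Simulate a panel of fully inbred founder strains
#'
#' Each strain is homozygous at every site; the allele carried by a strain at
#' a site is drawn from the site's population allele frequency, itself drawn
#' from `af_spectrum`.
#'
#' @param n_strains Number of inbred strains.
#' @param n_chromosomes Number of chromosomes.
#' @param sites_per_chromosome Number of biallelic sites per chromosome.
#' @param af_spectrum Either a single numeric allele frequency in `[0, 1]`, a
#'   numeric vector of length `n_chromosomes * sites_per_chromosome`, or a
#'   function `f(n)` returning `n` frequencies in `[0, 1]`.
#' @param chrom_length_bp Chromosome length in base pairs; site positions are
#'   placed uniformly and sorted within each chromosome.
#' @param seed Integer seed.
#' @return An object of class `founder_panel`: list with `alleles` (strain x
#'   site 0/1 matrix; strains are homozygous so one haplotype represents
#'   both), `map` (data.frame with `id`, `chrom`, `pos`), and `af` (the
#'   population allele frequency used per site).
#' @export
simulate_founders <- function(n_strains, n_chromosomes, sites_per_chromosome,
                              af_spectrum = function(n) stats::runif(n, 0.05, 0.5),
                              chrom_length_bp = 3e7, seed = 1) {
  if (n_strains < 1 || n_chromosomes < 1 || sites_per_chromosome < 1) {
    stop_config("n_strains, n_chromosomes and sites_per_chromosome must all be >= 1")
  }
  m <- n_chromosomes * sites_per_chromosome
  with_seed(seed, {
    af <- if (is.function(af_spectrum)) {
      af_spectrum(m)
    } else if (length(af_spectrum) == 1L) {
      rep(af_spectrum, m)
    } else {
      af_spectrum
    }
    if (length(af) != m || anyNA(af) || any(af < 0 | af > 1)) {
      stop_config("af_spectrum must yield ", m, " allele frequencies in [0, 1]")
    }
    pos <- as.integer(replicate(n_chromosomes,
                                sort(sample.int(chrom_length_bp, sites_per_chromosome))))
    map <- data.frame(
      id = paste0("chr", rep(seq_len(n_chromosomes), each = sites_per_chromosome),
                  "_", pos),
      chrom = rep(seq_len(n_chromosomes), each = sites_per_chromosome),
      pos = pos,
      stringsAsFactors = FALSE
    )
    alleles <- matrix(stats::rbinom(n_strains * m, 1L, rep(af, each = n_strains)),
                      nrow = n_strains, ncol = m,
                      dimnames = list(paste0("strain_", seq_len(n_strains)), map$id))
    structure(list(alleles = alleles, map = map, af = af,
                   chrom_length_bp = chrom_length_bp),
              class = "founder_panel")
  })
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("Founder panel:", nrow(x$alleles), "inbred strains,",
      ncol(x$alleles), "sites on", length(unique(x$map$chrom)), "chromosomes\n")
  invisible(x)
}

#' Define a set of F2 crosses
#'
#' @param maternal,paternal Strain names (must exist in the founder panel) or
#'   indices; recycled against each other.
#' @param n_f2 Number of F2 individuals per cross.
#' @param reciprocal Logical flag marking a cross as the reciprocal of another
#'   (bookkeeping only; segregation mechanics are identical).
#' @return data.frame of class `cross_design`.
#' @export
cross_design <- function(maternal, paternal, n_f2, reciprocal = FALSE) {
  d <- data.frame(maternal = maternal, paternal = paternal, n_f2 = n_f2,
                  reciprocal = reciprocal, stringsAsFactors = FALSE)
  if (any(d$n_f2 < 1)) stop_config("n_f2 must be >= 1 for every cross")
  class(d) <- c("cross_design", "data.frame")
  d
}

# draw one gamete haplotype per (individual, chromosome) from an F1 whose two
# haplotypes are the two founder haplotypes; crossovers follow a Haldane model
# (Poisson count per chromosome, uniform positions, alternating phase)
.f1_gametes <- function(hap_a, hap_b, pos, chrom_length_bp, n_gametes,
                        recombination_rate_per_mb) {
  m <- length(hap_a)
  exp_xo <- recombination_rate_per_mb * chrom_length_bp / 1e6
  n_xo <- stats::rpois(n_gametes, exp_xo)
  start_phase <- stats::rbinom(n_gametes, 1L, 0.5)
  out <- matrix(0L, nrow = n_gametes, ncol = m)
  plain <- n_xo == 0L
  if (any(plain)) {
    # no crossover: whole chromosome from one parent haplotype
    from_a <- start_phase[plain] == 0L
    if (any(from_a)) {
      out[which(plain)[from_a], ] <- matrix(hap_a, sum(from_a), m, byrow = TRUE)
    }
    if (any(!from_a)) {
      out[which(plain)[!from_a], ] <- matrix(hap_b, sum(!from_a), m, byrow = TRUE)
    }
  }
  for (i in which(!plain)) {
    xo <- sort(stats::runif(n_xo[i], 0, chrom_length_bp))
    seg <- findInterval(pos, xo)              # segment index per site
    use_a <- (seg + start_phase[i]) %% 2L == 0L
    out[i, ] <- ifelse(use_a, hap_a, hap_b)
  }
  out
}

#' Simulate F2 genotypes from a founder panel and cross design
#'
#' F1 individuals are heterozygous wherever the two founders carry opposite
#' homozygous alleles; each F2 receives two independent F1 gametes with
#' crossovers placed by a per-chromosome Poisson (Haldane) process.
#'
#' @param founders A `founder_panel`.
#' @param design A `cross_design`.
#' @param recombination_rate_per_mb Expected crossovers per megabase per
#'   gamete (default 0.01, i.e. ~1 cM/Mb).
#' @param seed Integer seed.
#' @return An object of class `genotype_matrix` (see [genotype_matrix()]) with
#'   per-sample `cross` labels.
#' @export
simulate_f2 <- function(founders, design, recombination_rate_per_mb = 0.01,
                        seed = 1) {
  stopifnot(inherits(founders, "founder_panel"))
  if (nrow(design) == 0L) stop_config("empty cross design")
  if (recombination_rate_per_mb < 0) stop_config("recombination rate must be >= 0")
  strains <- rownames(founders$alleles)
  idx <- function(s) {
    if (is.numeric(s)) return(as.integer(s))
    i <- match(s, strains)
    if (anyNA(i)) stop_config("cross design names strains absent from the founder panel")
    i
  }
  mom <- idx(design$maternal); dad <- idx(design$paternal)
  map <- founders$map
  chroms <- unique(map$chrom)
  n_tot <- sum(design$n_f2)
  dos <- matrix(0L, nrow = n_tot, ncol = nrow(map))
  cross_lab <- character(n_tot)
  sample_ids <- character(n_tot)
  with_seed(seed, {
    row0 <- 0L
    for (k in seq_len(nrow(design))) {
      n_k <- design$n_f2[k]
      lab <- paste0(strains[mom[k]], "x", strains[dad[k]],
                    if (isTRUE(design$reciprocal[k])) "_recip" else "")
      for (cc in chroms) {
        sites <- which(map$chrom == cc)
        hap_a <- founders$alleles[mom[k], sites]
        hap_b <- founders$alleles[dad[k], sites]
        g1 <- .f1_gametes(hap_a, hap_b, map$pos[sites], founders$chrom_length_bp,
                          n_k, recombination_rate_per_mb)
        g2 <- .f1_gametes(hap_a, hap_b, map$pos[sites], founders$chrom_length_bp,
                          n_k, recombination_rate_per_mb)
        dos[row0 + seq_len(n_k), sites] <- g1 + g2
      }
      cross_lab[row0 + seq_len(n_k)] <- lab
      sample_ids[row0 + seq_len(n_k)] <- paste0(lab, "_", seq_len(n_k))
      row0 <- row0 + n_k
    }
  })
  rownames(dos) <- sample_ids
  colnames(dos) <- map$id
  genotype_matrix(dos, map, cross = cross_lab)
}

#' Construct a genotype matrix object
#'
#' @param dosages Integer matrix, samples x variants, values in `{0, 1, 2}`
#'   (copies of the alternate allele).
#' @param map data.frame with columns `id`, `chrom`, `pos` (one row per
#'   variant, in column order of `dosages`).
#' @param cross Optional per-sample cross label.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map, cross = NULL) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages) || !all(dosages %in% 0:2)) {
    stop_config("dosages must be complete and in {0, 1, 2}")
  }
  if (ncol(dosages) != nrow(map)) stop_config("map/dosage dimension mismatch")
  if (!is.null(cross) && length(cross) != nrow(dosages)) {
    stop_config("cross labels must match the number of samples")
  }
  structure(list(dosages = dosages, map = map, cross = cross),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants on", length(unique(x$map$chrom)), "chromosome(s)\n")
  if (!is.null(x$cross)) {
    cat("Crosses:", paste(names(table(x$cross)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Simulate outbred Hardy-Weinberg genotype dosages
#'
#' Dosages are i.i.d. Binomial(2, `allele_frequency`), the generating model of
#' the misspecification power simulator.
#'
#' @param n Number of individuals.
#' @param allele_frequency Frequency of the alternate allele, in `(0, 1)`.
#' @param seed Integer seed (use `NULL` to draw from the current RNG state).
#' @return Integer dosage vector of length `n`.
#' @export
simulate_outbred_genotypes <- function(n, allele_frequency, seed = NULL) {
  if (n < 1) stop_config("n must be >= 1")
  if (allele_frequency <= 0 || allele_frequency >= 1) {
    stop_config("allele_frequency must be in (0, 1)")
  }
  with_seed(seed, stats::rbinom(n, 2L, allele_frequency))
}

#' Built-in synthetic seasonal water-temperature series
#'
#' Annual sinusoid (mean 22 degC, amplitude 10 degC) with hourly Gaussian
#' jitter (sd 1.5 degC), emulating two years of hourly outdoor pond
#' measurements. The raw series is returned untruncated; [sample_environment()]
#' applies the 21-35 degC range restriction.
#'
#' @param years Number of years of hourly measurements.
#' @param mean_c,amplitude_c,jitter_sd Sinusoid mean, amplitude and hourly
#'   jitter, all in degC.
#' @param seed Integer seed.
#' @return Numeric vector of hourly temperatures in degC.
#' @export
seasonal_temperature_series <- function(years = 2, mean_c = 22, amplitude_c = 10,
                                        jitter_sd = 1.5, seed = 1) {
  with_seed(seed, {
    hours <- seq_len(round(years * 365.25 * 24))
    day <- hours / 24
    mean_c + amplitude_c * sin(2 * pi * day / 365.25) +
      stats::rnorm(length(hours), 0, jitter_sd)
  })
}

#' Sample environment (temperature) values
#'
#' Draws `n` temperatures with replacement from a measurement source,
#' optionally restricted to the 21-35 degC range observed during phenotyping,
#' and attaches the linearizing transform `log(t - 6)`.
#'
#' @param n Number of draws.
#' @param source Numeric vector of temperature measurements (degC), or
#'   `"seasonal"` for the built-in synthetic seasonal series.
#' @param restrict_range Keep only source values within `range_c` before
#'   sampling (default `TRUE`).
#' @param range_c Two-element numeric range, default `c(21, 35)`.
#' @param seed Integer seed.
#' @return data.frame of class `environment_sample` with columns `temperature`
#'   (degC) and `e` (`log(temperature - 6)`).
#' @export
sample_environment <- function(n, source = "seasonal", restrict_range = TRUE,
                               range_c = c(21, 35), seed = 1) {
  src <- if (identical(source, "seasonal")) {
    seasonal_temperature_series(seed = child_seeds(seed %||% 1, 2)[1])
  } else {
    as.numeric(source)
  }
  if (restrict_range) src <- src[src >= range_c[1] & src <= range_c[2]]
  if (length(src) == 0L) stop_config("no temperature measurements remain after range restriction")
  if (any(src <= 6)) stop_config("log(t - 6) transform undefined for temperatures <= 6 degC")
  temp <- with_seed(if (identical(source, "seasonal")) child_seeds(seed %||% 1, 2)[2] else seed,
                    src[sample.int(length(src), n, replace = TRUE)])
  structure(data.frame(temperature = temp, e = log(temp - 6)),
            class = c("environment_sample", "data.frame"))
}

#' Effect-size block for phenotype generation
#'
#' Collects the coefficients of the generating model on the log heart-rate
#' scale: `y = intercept + bG*g + bE*e + bD*d + bGxE*g*e + bDxE*d*e +
#' sum_p(bP*gp + bPxE*gp*e + bGxG*g*gp + bGxGxE*g*gp*e) + N(0, sigma2)`,
#' where `d = 1` iff `g = 1` and `e = log(t - 6)`.
#'
#' @param intercept,beta_g,beta_e,beta_d,beta_gxe,beta_dxe Scalar coefficients.
#' @param partners Optional named list, one element per epistatic partner
#'   locus, each a list with `af` (the partner's fixed allele frequency),
#'   `beta_p` (partner marginal), `beta_pxe` (partner x environment), and
#'   optionally `beta_gxg`, `beta_gxgxe` (absent means 0).
#' @param sigma2 Residual variance (> 0 required at generation time).
#' @return Object of class `effect_sizes`.
#' @export
effect_sizes <- function(intercept = 0, beta_g = 0, beta_e = 0, beta_d = 0,
                         beta_gxe = 0, beta_dxe = 0, partners = list(),
                         sigma2 = 1) {
  if (sigma2 < 0) stop_config("sigma2 must be >= 0")
  structure(list(intercept = intercept, beta_g = beta_g, beta_e = beta_e,
                 beta_d = beta_d, beta_gxe = beta_gxe, beta_dxe = beta_dxe,
                 partners = partners, sigma2 = sigma2),
            class = "effect_sizes")
}

#' @export
print.effect_sizes <- function(x, ...) {
  cat("Effect sizes (log-bpm scale):\n")
  b <- unlist(x[c("intercept", "beta_g", "beta_e", "beta_d", "beta_gxe", "beta_dxe")])
  print(round(b, 4))
  if (length(x$partners)) {
    cat("Epistatic partners:", paste(names(x$partners), collapse = ", "), "\n")
  }
  cat("Residual variance:", signif(x$sigma2, 4), "\n")
  invisible(x)
}

#' Dominance encoding of a dosage vector
#'
#' Heterozygotes are encoded as 1, any homozygote as 0.
#'
#' @param g Dosage vector in `{0, 1, 2}`.
#' @return Integer vector.
#' @export
dominance_code <- function(g) as.integer(g == 1)

#' Simulate phenotypes from genotypes, environment and effect sizes
#'
#' Sums the products of each generating-model term with its effect size and
#' adds Gaussian noise with variance `effects$sigma2`. Phenotypes are on the
#' log scale throughout.
#'
#' @param g Dosage vector (one per sample) at the focal locus.
#' @param env An `environment_sample`. If it has one row per sample, each
#'   sample is measured once; if it has `k` rows and `repeat_measures = TRUE`,
#'   every sample is measured at each of the `k` environment levels.
#' @param effects An `effect_sizes` object.
#' @param partner_genotypes Named list of dosage vectors for the epistatic
#'   partner loci (required when `effects$partners` carry nonzero epistatic
#'   or marginal terms).
#' @param repeat_measures Logical; see `env`.
#' @param plate Optional per-record plate labels; default assigns plates of
#'   `plate_size` samples.
#' @param plate_size Number of samples per phenotyping plate.
#' @param cross Optional per-sample cross labels.
#' @param seed Integer seed.
#' @return data.frame of class `phenotype_table` with columns `sample`, `env`
#'   (temperature, degC), `e` (`log(t - 6)`), `value` (log-scale phenotype),
#'   `plate`, `cross`.
#' @export
simulate_phenotype <- function(g, env, effects, partner_genotypes = list(),
                               repeat_measures = NULL, plate = NULL,
                               plate_size = 96, cross = NULL, seed = 1) {
  stopifnot(inherits(effects, "effect_sizes"))
  n <- length(g)
  if (is.null(repeat_measures)) repeat_measures <- nrow(env) != n
  if (length(effects$partners) && !setequal(names(effects$partners),
                                            names(partner_genotypes))) {
    stop_config("partner_genotypes must be supplied for every partner locus in effects")
  }
  if (repeat_measures) {
    k <- nrow(env)
    idx <- rep(seq_len(n), each = k)
    e <- rep(env$e, times = n)
    temp <- rep(env$temperature, times = n)
  } else {
    if (nrow(env) != n) stop_config("env must have one row per sample")
    idx <- seq_len(n)
    e <- env$e
    temp <- env$temperature
  }
  gg <- g[idx]
  dd <- dominance_code(gg)
  mu <- effects$intercept + effects$beta_g * gg + effects$beta_e * e +
    effects$beta_d * dd + effects$beta_gxe * gg * e + effects$beta_dxe * dd * e
  for (p in names(effects$partners)) {
    pp <- effects$partners[[p]]
    gp <- partner_genotypes[[p]][idx]
    mu <- mu + (pp$beta_p %||% 0) * gp + (pp$beta_pxe %||% 0) * gp * e +
      (pp$beta_gxg %||% 0) * gg * gp + (pp$beta_gxgxe %||% 0) * gg * gp * e
  }
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sqrt(effects$sigma2)))
  sample_id <- if (!is.null(names(g))) names(g)[idx] else paste0("s", idx)
  plate <- plate %||% paste0("plate_", (idx - 1) %/% plate_size + 1)
  cross_rec <- if (!is.null(cross)) cross[idx] else "cross_1"
  structure(data.frame(sample = sample_id, env = temp, e = e, value = y,
                       plate = plate, cross = cross_rec,
                       stringsAsFactors = FALSE),
            class = c("phenotype_table", "data.frame"))
}

#' Construct a tagging SNP in known linkage with a causal variant
#'
#' Works at the haplotype level: each tag allele equals the corresponding
#' causal allele with probability `sqrt(target_r2)` and is otherwise redrawn
#' Bernoulli(`af`), so the expected genotype-level squared correlation is
#' `target_r2` and the tag's marginal allele frequency matches the causal
#' variant's.
#'
#' @param haplotypes Two-column 0/1 matrix of causal-variant haplotype alleles
#'   (one row per individual), e.g. from [split_haplotypes()].
#' @param target_r2 Target squared correlation in `(0, 1]`.
#' @param af Causal allele frequency used for redraws (default: empirical).
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return List with `dosage` (tag genotype vector) and `haplotypes`.
#' @export
make_tag_snp <- function(haplotypes, target_r2, af = NULL, seed = NULL) {
  if (target_r2 <= 0 || target_r2 > 1) stop_config("target_r2 must be in (0, 1]")
  haplotypes <- as.matrix(haplotypes)
  stopifnot(ncol(haplotypes) == 2L)
  af <- af %||% mean(haplotypes)
  r <- sqrt(target_r2)
  with_seed(seed, {
    keep <- matrix(stats::runif(length(haplotypes)) < r, nrow(haplotypes))
    redraw <- matrix(stats::rbinom(length(haplotypes), 1L, af), nrow(haplotypes))
    tag <- ifelse(keep, haplotypes, redraw)
  })
  list(dosage = as.integer(rowSums(tag)), haplotypes = tag)
}

#' Split Hardy-Weinberg genotypes into haplotypes
#'
#' Decomposes Binomial(2, af) dosages into two exchangeable Bernoulli
#' haplotypes (heterozygotes are phased at random), as needed by
#' [make_tag_snp()].
#'
#' @param g Dosage vector in `{0, 1, 2}`.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return Two-column 0/1 matrix.
#' @export
split_haplotypes <- function(g, seed = NULL) {
  with_seed(seed, {
    h1 <- ifelse(g == 2L, 1L, ifelse(g == 0L, 0L, stats::rbinom(length(g), 1L, 0.5)))
  })
  cbind(h1 = h1, h2 = as.integer(g) - h1)
}

#' Simulate strain-structured phenotypes with known broad-sense heritability
#'
#' One-way random-effects generator used to exercise the ANOVA heritability
#' estimator: strain effects N(0, h2), residuals N(0, 1 - h2).
#'
#' @param n_strains,n_per_strain Design.
#' @param h2 True broad-sense heritability in `[0, 1)`.
#' @param seed Integer seed.
#' @return data.frame with `strain` and `value`.
#' @export
simulate_strain_phenotypes <- function(n_strains, n_per_strain, h2, seed = 1) {
  stopifnot(h2 >= 0, h2 < 1)
  with_seed(seed, {
    u <- stats::rnorm(n_strains, 0, sqrt(h2))
    data.frame(
      strain = factor(rep(paste0("strain_", seq_len(n_strains)), each = n_per_strain)),
      value = rep(u, each = n_per_strain) +
        stats::rnorm(n_strains * n_per_strain, 0, sqrt(1 - h2))
    )
  })
}

#' Simulate a polygenic phenotype with known narrow-sense heritability
#'
#' Draws `y = u + eps` with `u ~ N(0, h2 * K)` and independent residuals, used
#' to exercise the GRM-based heritability estimator.
#'
#' @param grm A `grm` object or PSD matrix `K`.
#' @param h2 True heritability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Numeric phenotype vector.
#' @export
simulate_polygenic_phenotype <- function(grm, h2, seed = 1) {
  K <- if (inherits(grm, "grm")) grm$K else grm
  stopifnot(h2 >= 0, h2 < 1)
  n <- nrow(K)
  ed <- eigen(K, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  with_seed(seed, {
    u <- ed$vectors %*% (sqrt(lam * h2) * stats::rnorm(n))
    as.numeric(u) + stats::rnorm(n, 0, sqrt(1 - h2))
  })
}
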
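# Misspecification power simulator: estimate effect sizes from F2 data,
# generate outbred GWAS datasets under a known generating model, fit discovery
# models of varying misspecification, and locate minimum discoverable sample
# sizes.

#' Estimate generating-model effect sizes from F2 data
#'
#' Fits the joint continuous-environment model on (optionally whitened) F2
#' data: `log(y) ~ g + e + d + g:e + d:e` plus, for every epistatic partner
#' locus, its marginal effect and environment interaction as covariates and
#' (with `include_epistasis = TRUE`) the `g:gp` and `g:gp:e` terms. The
#' environment enters as `e = log(t - 6)`.
#'
#' @param locus Per-sample dosage vector at the focal locus.
#' @param pheno A `phenotype_table` (bpm values; log-transformed internally
#'   unless `log_transform = FALSE`) with the continuous transform in column
#'   `e`.
#' @param partner_genotypes Named list of per-sample dosage vectors for the
#'   partner loci; required (the partner covariates are structural).
#' @param covariance Optional `multienv_cov` for whitening; `NULL` fits by
#'   ordinary least squares.
#' @param include_epistasis Include `g:gp` and `g:gp:e` terms.
#' @param partner_af Named numeric vector of fixed partner allele frequencies
#'   used later in simulation (default: empirical frequency).
#' @param log_transform Log-transform the phenotype.
#' @return An [effect_sizes()] object; `sigma2` is the REML residual variance
#'   when whitening, otherwise the OLS residual variance.
#' @export
estimate_effect_sizes <- function(locus, pheno, partner_genotypes,
                                  covariance = NULL, include_epistasis = FALSE,
                                  partner_af = NULL, log_transform = TRUE) {
  if (missing(partner_genotypes) || is.null(partner_genotypes) ||
      length(partner_genotypes) == 0L) {
    stop_config("partner_genotypes are structural covariates and must be supplied")
  }
  samples <- unique(pheno$sample)
  n <- length(samples)
  if (length(locus) != n) stop_config("locus dosage must have one entry per sample")
  rec <- match(pheno$sample, samples)
  y <- if (log_transform) log(pheno$value) else pheno$value
  e <- pheno$e
  if (anyNA(e)) stop_config("pheno$e (the log(t - 6) transform) must be complete")
  g <- locus[rec]
  d <- dominance_code(g)
  X <- cbind(intercept = 1, g = g, e = e, d = d, gxe = g * e, dxe = d * e)
  pnames <- names(partner_genotypes)
  for (p in pnames) {
    gp <- partner_genotypes[[p]][rec]
    X <- cbind(X, gp, gp * e)
    colnames(X)[ncol(X) - 1:0] <- paste0(p, c("", "_xe"))
    if (include_epistasis) {
      X <- cbind(X, g * gp, g * gp * e)
      colnames(X)[ncol(X) - 1:0] <- paste0(p, c("_gxg", "_gxgxe"))
    }
  }
  if (qr(X)$rank < ncol(X)) stop_config("collinear design in effect-size estimation")
  if (!is.null(covariance)) {
    vc <- suppressWarnings(estimate_variance_components(
      y, X[, c("intercept", "g", "e"), drop = FALSE], covariance))
    w <- whiten(y, X, vc, covariance)
    cf <- qr.coef(qr(w$X), w$y)
    names(cf) <- colnames(X)
    sigma2 <- vc$sigma2_resid
  } else {
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    sigma2 <- sum(fit$residuals^2) / (length(y) - ncol(X))
  }
  partners <- list()
  for (p in pnames) {
    partners[[p]] <- list(
      af = unname((partner_af %||% vapply(partner_genotypes, function(v) mean(v) / 2, 1))[p]),
      beta_p = unname(cf[p]),
      beta_pxe = unname(cf[paste0(p, "_xe")]),
      beta_gxg = if (include_epistasis) unname(cf[paste0(p, "_gxg")]) else 0,
      beta_gxgxe = if (include_epistasis) unname(cf[paste0(p, "_gxgxe")]) else 0
    )
  }
  effect_sizes(intercept = unname(cf["intercept"]), beta_g = unname(cf["g"]),
               beta_e = unname(cf["e"]), beta_d = unname(cf["d"]),
               beta_gxe = unname(cf["gxe"]), beta_dxe = unname(cf["dxe"]),
               partners = partners, sigma2 = sigma2)
}

#' Define a simulation condition for the power simulator
#'
#' @param af Allele frequency of the focal (most recessive) allele, in
#'   `(0, 0.5]`.
#' @param discovery_model One of `"G"`, `"G+E"`, `"G+E+GxE"`, `"full"`.
#' @param noise_fraction Fraction of the *observed* temperature variance
#'   contributed by measurement noise: one of the study levels 0, 0.01, 0.10,
#'   0.50 or any value in `[0, 1)`.
#' @param tagging_r2 Squared correlation between the tested and causal
#'   variant; 1 means the causal variant is genotyped directly.
#' @param generating_epistasis Include the GxG and GxGxE terms of the
#'   partner loci in the generating model (and in the `"full"` discovery
#'   model).
#' @param noise_convention `"of_total"` (default: noise variance
#'   `f/(1-f) * Var(E)` so noise is fraction `f` of the total observed
#'   variance) or `"of_signal"` (noise variance `f * Var(E)`).
#' @param threshold Genome-wide significance threshold (default 5e-8).
#' @return List of class `sim_condition`.
#' @export
sim_condition <- function(af, discovery_model = "G+E", noise_fraction = 0,
                          tagging_r2 = 1, generating_epistasis = FALSE,
                          noise_convention = c("of_total", "of_signal"),
                          threshold = 5e-8) {
  if (af <= 0 || af > 0.5) stop_config("af must be in (0, 0.5]")
  if (noise_fraction < 0 || noise_fraction >= 1) {
    stop_config("noise_fraction must be in [0, 1)")
  }
  if (!discovery_model %in% c("G", "G+E", "G+E+GxE", "full")) {
    stop_config("unknown discovery model: ", discovery_model)
  }
  structure(list(af = af, discovery_model = discovery_model,
                 noise_fraction = noise_fraction, tagging_r2 = tagging_r2,
                 generating_epistasis = generating_epistasis,
                 noise_convention = match.arg(noise_convention),
                 threshold = threshold),
            class = "sim_condition")
}

# generate `n` fresh samples under a condition; child seeds per stage
.generate_block <- function(effects, n, condition, env_source, seed) {
  seeds <- child_seeds(seed, 5)
  hap <- with_seed(seeds[1], matrix(stats::rbinom(2 * n, 1L, condition$af), n, 2))
  g <- as.integer(rowSums(hap))
  gp <- matrix(0L, n, length(effects$partners),
               dimnames = list(NULL, names(effects$partners)))
  with_seed(seeds[2], {
    for (j in seq_along(effects$partners)) {
      gp[, j] <- stats::rbinom(n, 2L, effects$partners[[j]]$af)
    }
  })
  env <- sample_environment(n, source = env_source, seed = seeds[3])
  t_true <- env$temperature
  e_true <- env$e
  f <- condition$noise_fraction
  if (f > 0) {
    v_true <- stats::var(t_true)
    sd_n <- sqrt(if (condition$noise_convention == "of_total") {
      f / (1 - f) * v_true
    } else {
      f * v_true
    })
    t_obs <- with_seed(seeds[4], {
      t_obs <- t_true + stats::rnorm(n, 0, sd_n)
      while (any(bad <- t_obs <= 6.5)) {
        t_obs[bad] <- t_true[bad] + stats::rnorm(sum(bad), 0, sd_n)
      }
      t_obs
    })
  } else {
    t_obs <- t_true
  }
  e_obs <- log(t_obs - 6)
  d <- dominance_code(g)
  mu <- effects$intercept + effects$beta_g * g + effects$beta_e * e_true +
    effects$beta_d * d + effects$beta_gxe * g * e_true +
    effects$beta_dxe * d * e_true
  for (j in seq_along(effects$partners)) {
    p <- effects$partners[[j]]
    mu <- mu + (p$beta_p %||% 0) * gp[, j] + (p$beta_pxe %||% 0) * gp[, j] * e_true
    if (condition$generating_epistasis) {
      mu <- mu + (p$beta_gxg %||% 0) * g * gp[, j] +
        (p$beta_gxgxe %||% 0) * g * gp[, j] * e_true
    }
  }
  y <- with_seed(seeds[5], mu + stats::rnorm(n, 0, sqrt(effects$sigma2)))
  g_tested <- if (condition$tagging_r2 < 1) {
    make_tag_snp(hap, condition$tagging_r2, af = condition$af,
                 seed = child_seeds(seeds[1], 2)[2])$dosage
  } else {
    g
  }
  list(g_causal = g, g_tested = g_tested, gp = gp,
       e_true = e_true, e_obs = e_obs, y = y)
}

#' Generate an outbred GWAS dataset under a simulation condition
#'
#' Genotypes are Binomial(2, af) (Hardy-Weinberg); the *true* environment
#' drives the phenotype while the *observed* environment carries Gaussian
#' measurement noise added on the Celsius scale before the `log(t - 6)`
#' transform; under tagging, the tested genotype is a tag SNP in `r2`
#' linkage with the causal variant, and every focal-locus term in the
#' discovery design (dominance, interactions) is recomputed from the tag.
#'
#' @param effects An `effect_sizes` object (the generating model).
#' @param n Sample size.
#' @param condition A [sim_condition()].
#' @param env_source Temperature source passed to [sample_environment()].
#' @param seed Integer seed.
#' @return List of class `sim_dataset` with `g_causal`, `g_tested`, `gp`
#'   (partner dosage matrix), `e_true`, `e_obs`, `y`, `condition`.
#' @export
generate_condition_dataset <- function(effects, n, condition,
                                       env_source = "seasonal", seed = 1) {
  stopifnot(inherits(effects, "effect_sizes"), inherits(condition, "sim_condition"))
  block <- .generate_block(effects, n, condition, env_source, seed)
  structure(c(block, list(condition = condition, effects = effects,
                          env_source = env_source)),
            class = "sim_dataset")
}

# RSS by QR for moderate n, chunked normal equations for very large n
.ols_rss <- function(X, y) {
  n <- length(y)
  if (n <= 2e5) {
    return(sum(qr.resid(qr(X), y)^2))
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  b <- tryCatch(solve(XtX, Xty), error = function(e) {
    solve(XtX + diag(1e-10 * max(diag(XtX)), ncol(X)), Xty)
  })
  max(sum(y^2) - sum(b * Xty), 0)
}

#' Fit a (possibly misspecified) discovery model
#'
#' Ordinary-least-squares likelihood-ratio test of the focal-locus block.
#' Every discovery design uses the *tested* genotype and the *observed*
#' environment. The null model contains the intercept, the environment, the
#' partner loci, and the partner x environment interactions; for the
#' environment-blind `"G"` model the null is intercept + partners only. The
#' alternative adds the focal-locus terms: `g` (models `"G"`, `"G+E"`);
#' `g, g:e` (`"G+E+GxE"`); `g, d, g:e, d:e` plus (under an epistatic
#' generating model) `g:gp, g:gp:e` (`"full"`).
#'
#' @param dataset A `sim_dataset`.
#' @param discovery_model Override of the condition's discovery model.
#' @return An `lrt_result`.
#' @export
fit_discovery_model <- function(dataset, discovery_model = NULL) {
  stopifnot(inherits(dataset, "sim_dataset"))
  model <- discovery_model %||% dataset$condition$discovery_model
  g <- dataset$g_tested
  d <- dominance_code(g)
  e <- dataset$e_obs
  gp <- dataset$gp
  n <- length(dataset$y)
  if (model == "G") {
    X0 <- cbind(1, gp)
    focal <- cbind(g = g)
  } else {
    X0 <- cbind(1, e, gp, gp * e)
    focal <- switch(model,
      "G+E" = cbind(g = g),
      "G+E+GxE" = cbind(g = g, gxe = g * e),
      "full" = {
        fx <- cbind(g = g, d = d, gxe = g * e, dxe = d * e)
        if (dataset$condition$generating_epistasis && ncol(gp) > 0) {
          fx <- cbind(fx, g * gp, g * gp * e)
        }
        fx
      })
  }
  if (n <= ncol(X0) + ncol(focal) + 1) {
    stop_config("sample size too small for the discovery design")
  }
  rss0 <- .ols_rss(X0, dataset$y)
  rss1 <- .ols_rss(cbind(X0, focal), dataset$y)
  df <- ncol(focal)
  chi2 <- max(n * log(rss0 / max(rss1, .Machine$double.xmin)), 0)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 rss_null = rss0, rss_alt = rss1, n = n),
            class = "lrt_result")
}

#' Default sample-size ladder
#'
#' A `{1, 2, 5}` per-decade grid from `10^2` to `10^7`.
#'
#' @param from,to Decade bounds.
#' @return Increasing integer vector.
#' @export
sample_size_ladder <- function(from = 1e2, to = 1e7) {
  lad <- sort(as.vector(outer(c(1, 2, 5), 10^(floor(log10(from)):ceiling(log10(to))))))
  lad[lad >= from & lad <= to]
}

# shared rung-climbing machinery: `alt_test` computes the p-value on the
# accumulated dataset
.climb_ladder <- function(effects, condition, ladder, n_reps, env_source,
                          seed, p_fun) {
  if (length(ladder) == 0L) stop_config("empty sample-size ladder")
  if (any(diff(ladder) <= 0)) stop_config("ladder must be strictly increasing")
  rep_seeds <- child_seeds(seed, n_reps)
  min_n <- numeric(n_reps)
  censored <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    block_seeds <- child_seeds(rep_seeds[r], length(ladder))
    acc <- NULL
    hit <- FALSE
    for (i in seq_along(ladder)) {
      add <- ladder[i] - (if (i == 1) 0 else ladder[i - 1])
      nb <- .generate_block(effects, add, condition, env_source, block_seeds[i])
      acc <- if (is.null(acc)) nb else Map(function(a, b) {
        if (is.matrix(a)) rbind(a, b) else c(a, b)
      }, acc, nb)
      ds <- structure(c(acc, list(condition = condition)), class = "sim_dataset")
      p <- p_fun(ds)
      if (is.finite(p) && p < condition$threshold) {
        min_n[r] <- ladder[i]; hit <- TRUE
        break
      }
    }
    if (!hit) {
      min_n[r] <- ladder[length(ladder)]
      censored[r] <- TRUE
    }
  }
  med <- stats::median(ifelse(censored, Inf, min_n))
  structure(list(min_n = min_n, censored = censored,
                 median_min_n = med, median_censored = !is.finite(med),
                 ladder = ladder, condition = condition),
            class = "power_cell")
}

#' Minimum discoverable sample size under a simulation condition
#'
#' For each replicate, climbs the sample-size ladder (accumulating samples so
#' successive rungs share their prefix) and records the smallest rung at
#' which the discovery-model likelihood-ratio test clears the genome-wide
#' threshold; replicates that never clear it are right-censored at the ladder
#' maximum.
#'
#' @param effects An `effect_sizes` object.
#' @param condition A [sim_condition()].
#' @param ladder Strictly increasing sample sizes, default
#'   [sample_size_ladder()].
#' @param n_reps Replicates (default 100).
#' @param env_source Temperature source.
#' @param seed Integer seed.
#' @return Object of class `power_cell`: `min_n` (per replicate), `censored`,
#'   `median_min_n` (`Inf` when the median replicate is censored), `ladder`,
#'   `condition`.
#' @export
min_sample_size <- function(effects, condition, ladder = sample_size_ladder(),
                            n_reps = 100, env_source = "seasonal", seed = 1) {
  .climb_ladder(effects, condition, ladder, n_reps, env_source, seed,
                function(ds) fit_discovery_model(ds)$p)
}

#' @export
print.power_cell <- function(x, ...) {
  cat(sprintf("Power cell: af = %g, model = %s, noise = %g%%, tagging r2 = %g\n",
              x$condition$af, x$condition$discovery_model,
              100 * x$condition$noise_fraction, x$condition$tagging_r2))
  cat(sprintf("  median minimum n = %s (%d/%d replicates censored at %g)\n",
              if (x$median_censored) "not reached" else format(x$median_min_n),
              sum(x$censored), length(x$censored), max(x$ladder)))
  invisible(x)
}

#' Minimum sample size to detect a non-additive term
#'
#' Same ladder machinery as [min_sample_size()], but the likelihood-ratio
#' test targets the dominance (`mode = "D"`) or gene-by-environment
#' (`mode = "GxE"`) block against a null model containing the intercept, the
#' additive focal effect, the environment, and the partner loci.
#'
#' @inheritParams min_sample_size
#' @param mode `"D"` or `"GxE"`.
#' @return A `power_cell`.
#' @export
nonadditive_detection_power <- function(effects, condition, mode = c("D", "GxE"),
                                        ladder = sample_size_ladder(),
                                        n_reps = 100, env_source = "seasonal",
                                        seed = 1) {
  mode <- match.arg(mode)
  p_fun <- function(ds) {
    g <- ds$g_tested
    e <- ds$e_obs
    X0 <- cbind(1, g, e, ds$gp)
    extra <- if (mode == "D") cbind(d = dominance_code(g)) else cbind(gxe = g * e)
    n <- length(ds$y)
    rss0 <- .ols_rss(X0, ds$y)
    rss1 <- .ols_rss(cbind(X0, extra), ds$y)
    chi2 <- max(n * log(rss0 / max(rss1, .Machine$double.xmin)), 0)
    stats::pchisq(chi2, ncol(extra), lower.tail = FALSE)
  }
  .climb_ladder(effects, condition, ladder, n_reps, env_source, seed, p_fun)
}

#' Is a locus discoverable?
#'
#' A locus counts as discoverable under a model if its median minimum sample
#' size is strictly smaller than `n_max` at some allele frequency strictly
#' below `maf_max`.
#'
#' @param curve data.frame with columns `af` and `median_min_n` (one row per
#'   allele frequency; `Inf`/`NA` = censored), or a list of `power_cell`s.
#' @param n_max Sample-size bound (default 500,000).
#' @param maf_max Allele-frequency bound (default 0.01).
#' @return Logical flag.
#' @export
discoverability <- function(curve, n_max = 5e5, maf_max = 0.01) {
  if (is.list(curve) && all(vapply(curve, inherits, TRUE, "power_cell"))) {
    curve <- data.frame(
      af = vapply(curve, function(x) x$condition$af, 1),
      median_min_n = vapply(curve, `[[`, 1, "median_min_n"))
  }
  rare <- curve[curve$af < maf_max, , drop = FALSE]
  any(is.finite(rare$median_min_n) & rare$median_min_n < n_max)
}

#' Dominance ratio and dominance/recessive classification
#'
#' Environment-averaged dominance-to-additive effect ratio
#' `d/g = (bD + bDxE * mean_e) / (bG + bGxE * mean_e)`. Its absolute value
#' measures the degree of non-additivity; a positive ratio is classified as
#' dominant, a negative one as recessive. The allele-swapped variant (with
#' reference and alternate alleles exchanged, which negates the additive
#' terms) is reported alongside. A vanishing denominator (additive and GxE
#' effects cancelling at the mean environment) is flagged as a candidate for
#' overdominance and the ratio is undefined.
#'
#' @param effects An `effect_sizes` object.
#' @param mean_env Mean environmental value on the transformed `log(t - 6)`
#'   scale.
#' @param tol Denominator tolerance.
#' @return List with `ratio`, `class` (`"dominant"`, `"recessive"`,
#'   `"additive"`, or `"undefined"`), `ratio_swapped`, `degree` (absolute
#'   ratio), `denominator`.
#' @export
dominance_ratio <- function(effects, mean_env, tol = 1e-12) {
  num <- effects$beta_d + effects$beta_dxe * mean_env
  den <- effects$beta_g + effects$beta_gxe * mean_env
  if (abs(den) < tol) {
    return(list(ratio = NA_real_, class = "undefined", ratio_swapped = NA_real_,
                degree = Inf, denominator = den,
                flag = "vanishing additive effect at the mean environment (candidate overdominance)"))
  }
  ratio <- num / den
  list(ratio = ratio,
       class = if (ratio > 0) "dominant" else if (ratio < 0) "recessive" else "additive",
       ratio_swapped = -ratio, degree = abs(ratio), denominator = den)
}
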
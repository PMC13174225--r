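# Stratified-by-environment genome scan: transforms, outlier filter,
# difference phenotypes, whitened LRT scan, permutation thresholds, and
# automated locus clumping.

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles via `qnorm((rank - 0.5) / n)`,
#' ties receiving average ranks. The output is invariant to any monotone
#' transformation of the input.
#'
#' @param values Numeric vector (NAs preserved; at least 3 distinct finite
#'   values required).
#' @return Numeric vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3) stop_config("at least 3 finite values required")
  if (length(unique(values[ok])) < 2) {
    stop_config("all values identical; ranks carry no information")
  }
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / sum(ok))
  out
}

#' Tukey fence outlier filter
#'
#' Keeps values inside `[Q1 - k IQR, Q3 + k IQR]`. The default `k = 4` is far
#' outside the conventional 1.5 ("outliers") and 3 ("far out") fences and
#' marks only exceptionally strong outliers.
#'
#' @param values Numeric vector (>= 4 values).
#' @param k Fence multiplier (> 0), default 4.
#' @return Logical inclusion mask (`TRUE` = keep). A degenerate IQR of 0
#'   keeps all equal values.
#' @export
tukey_filter <- function(values, k = 4) {
  if (k <= 0) stop_config("k must be > 0")
  if (sum(is.finite(values)) < 4) stop_config("at least 4 finite values required")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2] - q[1]
  values >= q[1] - k * iqr & values <= q[2] + k * iqr
}

#' Construct a temperature-response (difference) phenotype
#'
#' For each sample measured at both environments, computes
#' `trait(env_b) - trait(env_a)`; samples missing either measurement are
#' dropped (count reported via `message()`).
#'
#' @param pheno A `phenotype_table`.
#' @param env_a,env_b Environment levels (values of the `env` column).
#' @return A `phenotype_table` with one record per retained sample; the `env`
#'   column is labelled `"diff_<env_b>-<env_a>"`.
#' @export
make_difference_phenotype <- function(pheno, env_a, env_b) {
  a <- pheno[pheno$env == env_a, ]
  b <- pheno[pheno$env == env_b, ]
  common <- intersect(a$sample, b$sample)
  if (length(common) == 0L) stop_config("no sample measured at both environments")
  dropped <- length(union(a$sample, b$sample)) - length(common)
  if (dropped > 0) message("make_difference_phenotype: dropped ", dropped,
                           " sample(s) missing one measurement")
  a <- a[match(common, a$sample), ]
  b <- b[match(common, b$sample), ]
  out <- data.frame(sample = common,
                    env = paste0("diff_", env_b, "-", env_a),
                    e = NA_real_,
                    value = b$value - a$value,
                    plate = b$plate, cross = b$cross,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

# Per-chromosome whitened scan state: covariate-only fit plus whitened
# genotype columns. LOCO GRMs are computed here unless supplied.
.scan_prep <- function(genotypes, phenotype, covariates, grm_loco, dominance) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosages)
  if (length(phenotype) != n) stop_config("phenotype/sample mismatch")
  X <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  } else {
    as.matrix(covariates)
  }
  chroms <- unique(genotypes$map$chrom)
  prep <- list()
  for (cc in as.character(chroms)) {
    K <- if (is.list(grm_loco) && !inherits(grm_loco, "grm")) {
      grm_loco[[cc]]
    } else if (inherits(grm_loco, "grm")) {
      grm_loco
    } else if (length(chroms) > 1L) {
      compute_grm(genotypes, exclude_chromosomes = cc)
    } else {
      compute_grm(genotypes)   # single chromosome: LOCO impossible
    }
    vc <- suppressWarnings(
      estimate_variance_components(phenotype, X, covariances = K)
    )
    w <- whiten(phenotype, X, vc, K)
    sites <- which(genotypes$map$chrom == cc)
    G <- genotypes$dosages[, sites, drop = FALSE]
    Gw <- backsolve(w$chol, G, transpose = TRUE)
    Dw <- if (dominance) {
      backsolve(w$chol, matrix(as.numeric(G == 1L), n), transpose = TRUE)
    }
    q0 <- qr(w$X)
    prep[[cc]] <- list(sites = sites, yw = w$y, Xw = w$X, Gw = Gw, Dw = Dw,
                       G_raw = G, q0 = q0,
                       fitted0 = qr.fitted(q0, w$y),
                       resid0 = qr.resid(q0, w$y), vc = vc)
  }
  prep
}

.scan_eval <- function(prep, map, dominance, yw_override = NULL) {
  rows <- vector("list", length(prep))
  for (j in seq_along(prep)) {
    pc <- prep[[j]]
    yw <- yw_override[[j]] %||% pc$yw
    n <- length(yw)
    rss0 <- sum(qr.resid(pc$q0, yw)^2)
    m <- ncol(pc$Gw)
    p <- chi2 <- beta_g <- beta_d <- rep(NA_real_, m)
    flag <- rep("", m)
    for (v in seq_len(m)) {
      graw <- pc$G_raw[, v]
      if (stats::sd(graw) == 0) {
        p[v] <- 1; chi2[v] <- 0; flag[v] <- "monomorphic"
        next
      }
      Xa <- cbind(pc$Xw, g = pc$Gw[, v],
                  if (dominance && stats::sd(graw == 1L) > 0) pc$Dw[, v])
      qa <- qr(Xa)
      df <- qa$rank - pc$q0$rank
      if (df < 1) {
        p[v] <- 1; chi2[v] <- 0; flag[v] <- "collinear"
        next
      }
      rss1 <- sum(qr.resid(qa, yw)^2)
      chi2[v] <- max(n * log(rss0 / rss1), 0)
      p[v] <- stats::pchisq(chi2[v], df, lower.tail = FALSE)
      cf <- qr.coef(qa, yw)
      beta_g[v] <- cf["g"]
      beta_d[v] <- if (dominance && ncol(Xa) > ncol(pc$Xw) + 1) cf[ncol(Xa)] else NA_real_
    }
    rows[[j]] <- data.frame(map[pc$sites, c("id", "chrom", "pos")],
                            chi2 = chi2, p = p, beta_g = beta_g,
                            beta_d = beta_d, flag = flag,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Genome-wide mixed-model association scan
#'
#' Per variant, a likelihood-ratio test of covariates-only versus covariates
#' plus an additive dosage term and (by default) a dominance term, on data
#' whitened under a single-GRM mixed model. GRMs are leave-one-chromosome-out:
#' variance components are re-estimated per chromosome under the covariate-only
#' fixed-effect structure. Monomorphic variants are reported with `p = 1` and
#' flagged rather than dropped.
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotype Numeric vector, one value per sample, already transformed
#'   (e.g. with [inverse_normal_transform()]).
#' @param covariates Optional design matrix of fixed covariates (intercept,
#'   plate, cross, optional lead-SNP block); default intercept only.
#' @param grm_loco Optional pre-computed GRM(s): a single `grm` used for all
#'   chromosomes, or a named list (by chromosome) of `grm` objects. Default
#'   recomputes LOCO GRMs internally.
#' @param dominance Include the dominance term (df = 2 test); `FALSE` gives
#'   the additive-only df = 1 scan.
#' @return A `scan_result` data.frame: `id`, `chrom`, `pos`, `chi2`, `p`,
#'   `beta_g`, `beta_d`, `flag`.
#' @export
scan_genome <- function(genotypes, phenotype, covariates = NULL,
                        grm_loco = NULL, dominance = TRUE) {
  prep <- .scan_prep(genotypes, phenotype, covariates, grm_loco, dominance)
  .scan_eval(prep, genotypes$map, dominance)
}

#' Permutation-based genome-wide significance threshold
#'
#' Permutes the whitened residuals of the covariate-only model (preserving the
#' covariate structure), re-runs the scan for each permutation, and records
#' the genome-wide minimum p-value. The default threshold is the minimum of
#' these minima; the conventional alternative (a low quantile of the
#' permutation minima) is available via `quantile_rule`.
#'
#' @inheritParams scan_genome
#' @param n_perm Number of permutations (>= 1), default 100.
#' @param quantile_rule `NULL` (default) for the minimum-of-minima rule, or a
#'   probability (e.g. 0.05) for the corresponding quantile of the minima.
#' @param seed Integer seed.
#' @return List with `threshold`, `min_p` (per-permutation genome-wide
#'   minima), and `rule`.
#' @export
permutation_threshold <- function(genotypes, phenotype, covariates = NULL,
                                  grm_loco = NULL, dominance = TRUE,
                                  n_perm = 100, quantile_rule = NULL, seed = 1) {
  if (n_perm < 1) stop_config("n_perm must be >= 1")
  prep <- .scan_prep(genotypes, phenotype, covariates, grm_loco, dominance)
  n <- length(phenotype)
  min_p <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      yws <- lapply(prep, function(pc) pc$fitted0 + pc$resid0[perm])
      min(.scan_eval(prep, genotypes$map, dominance, yw_override = yws)$p)
    }, numeric(1))
  })
  threshold <- if (is.null(quantile_rule)) {
    min(min_p)
  } else {
    stats::quantile(min_p, quantile_rule, names = FALSE)
  }
  list(threshold = threshold, min_p = min_p,
       rule = if (is.null(quantile_rule)) "min" else paste0("quantile_", quantile_rule))
}

#' Clump significant variants into loci
#'
#' Merges significant variants within `merge_window_bp` of each other (same
#' chromosome) into loci and picks each locus's lead SNP: the smallest
#' p-value among variants carrying both homozygous genotype classes (variants
#' missing a homozygous state entirely are ineligible as leads when genotype
#' data are supplied).
#'
#' @param scan A `scan_result`.
#' @param threshold Genome-wide significance threshold in `(0, 1)`.
#' @param merge_window_bp Maximum gap between significant variants within a
#'   locus (default 1 Mb).
#' @param genotypes Optional `genotype_matrix` for lead-SNP eligibility.
#' @return data.frame of class `qtl_set`: `locus`, `chrom`, `start`, `end`,
#'   `lead_id`, `lead_pos`, `lead_p`, `n_variants`. Empty when nothing is
#'   significant.
#' @export
define_loci <- function(scan, threshold, merge_window_bp = 1e6,
                        genotypes = NULL) {
  if (threshold <= 0 || threshold >= 1) stop_config("threshold must be in (0, 1)")
  sig <- scan[scan$p < threshold & scan$flag == "", , drop = FALSE]
  out <- data.frame(locus = character(), chrom = character(), start = integer(),
                    end = integer(), lead_id = character(), lead_pos = integer(),
                    lead_p = numeric(), n_variants = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) {
    class(out) <- c("qtl_set", "data.frame")
    return(out)
  }
  sig <- sig[order(sig$chrom, sig$pos), ]
  new_locus <- c(TRUE, diff(sig$pos) > merge_window_bp |
                   sig$chrom[-1] != sig$chrom[-nrow(sig)])
  grp <- cumsum(new_locus)
  for (g in unique(grp)) {
    block <- sig[grp == g, ]
    eligible <- rep(TRUE, nrow(block))
    if (!is.null(genotypes)) {
      eligible <- vapply(block$id, function(vid) {
        dos <- genotypes$dosages[, match(vid, genotypes$map$id)]
        all(c(0L, 2L) %in% dos)
      }, logical(1))
      if (!any(eligible)) eligible <- rep(TRUE, nrow(block))
    }
    lead <- block[eligible, ][which.min(block$p[eligible]), ]
    out <- rbind(out, data.frame(
      locus = paste0("chr", lead$chrom, "_", lead$pos),
      chrom = as.character(block$chrom[1]),
      start = min(block$pos), end = max(block$pos),
      lead_id = lead$id, lead_pos = lead$pos, lead_p = lead$p,
      n_variants = nrow(block), stringsAsFactors = FALSE))
  }
  class(out) <- c("qtl_set", "data.frame")
  out
}
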
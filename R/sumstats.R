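# Summary-statistics validation: reconstruct per-marker residual variance
# from GWAS summary statistics, simulate marker + phenotype, and compare the
# recovered significance with the reported one.

#' Variance of a Hardy-Weinberg marker
#'
#' `sigma_x^2 = 2 p (1 - p)` for a Binomial(2, p) dosage. Exact only under
#' Hardy-Weinberg equilibrium.
#'
#' @param p Allele frequency in `(0, 1)`.
#' @return Numeric marker variance.
#' @export
marker_variance <- function(p) {
  if (any(p <= 0 | p >= 1)) stop_config("allele frequency must be in (0, 1)")
  2 * p * (1 - p)
}

#' Residual variance implied by GWAS summary statistics
#'
#' Under the single-marker OLS model, `sigma_eps^2 = SE_beta^2 * n *
#' sigma_x^2` reconstructs the phenotype's residual variance from the
#' reported standard error, sample size and allele frequency.
#'
#' @param records data.frame with columns `maf`, `se`, `n` (a `beta` column
#'   is carried along when present), or individual numeric arguments.
#' @param maf,se,n Alternative scalar/vector inputs.
#' @return Numeric vector of residual variances.
#' @export
residual_variance_from_sumstats <- function(records = NULL, maf = NULL,
                                            se = NULL, n = NULL) {
  if (!is.null(records)) {
    maf <- records$maf; se <- records$se; n <- records$n
  }
  if (any(se <= 0) || any(n < 2)) stop_config("se must be > 0 and n >= 2")
  se^2 * n * marker_variance(maf)
}

#' Simulate a marker and phenotype from a summary-statistics record and refit
#'
#' Draws a Binomial(2, maf) genotype vector of length `n`, builds
#' `y = beta * x + eps` with `eps ~ N(0, sigma_eps^2)` where the residual
#' variance is reconstructed via [residual_variance_from_sumstats()], fits
#' ordinary least squares, and returns the Wald p-value for the slope.
#'
#' @param record One-row data.frame (or list) with `maf`, `beta`, `se`, `n`.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return List with `p`, `beta_hat`, `se_hat`, `sigma2_eps`.
#' @export
simulate_and_refit <- function(record, seed = NULL) {
  maf <- record$maf; beta <- record$beta; n <- as.integer(record$n)
  if (n < 3) stop_config("n must be >= 3")
  s2e <- residual_variance_from_sumstats(maf = maf, se = record$se, n = n)
  with_seed(seed, {
    x <- stats::rbinom(n, 2L, maf)
    y <- beta * x + stats::rnorm(n, 0, sqrt(s2e))
  })
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(list(p = 1, beta_hat = NA_real_, se_hat = NA_real_,
                            sigma2_eps = s2e))
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se_hat <- sqrt(rss / (n - 2) / sxx)
  tval <- b / se_hat
  list(p = 2 * stats::pt(-abs(tval), n - 2), beta_hat = b, se_hat = se_hat,
       sigma2_eps = s2e)
}

#' Round-trip a table of summary statistics through simulation
#'
#' Applies [simulate_and_refit()] to every record; the output pairs each
#' reported p-value with the simulated one for calibration assessment.
#'
#' @param records data.frame with columns `maf`, `beta`, `se`, `n` and
#'   optionally `pval` (the reported p-value) and `marker`.
#' @param seed Integer seed (fanned out per record).
#' @return data.frame with `marker`, `p_reported`, `p_simulated`.
#' @export
sumstats_roundtrip <- function(records, seed = 1) {
  seeds <- child_seeds(seed, nrow(records))
  p_sim <- vapply(seq_len(nrow(records)), function(i) {
    simulate_and_refit(records[i, ], seed = seeds[i])$p
  }, numeric(1))
  data.frame(marker = records$marker %||% paste0("m", seq_len(nrow(records))),
             p_reported = records$pval %||% NA_real_,
             p_simulated = p_sim)
}

#' Generate a synthetic grid of GWAS summary-statistics records
#'
#' Builds internally consistent records spanning a wide significance range:
#' allele frequencies uniform in `[0.05, 0.5]`, per-marker standard errors
#' implied by a unit residual variance, effects `beta = z * SE` for Wald
#' z-scores spread over `z_range`, and reported p-values from the normal
#' approximation. Used to exercise the round-trip validation without any
#' external download.
#'
#' @param n_records Number of markers.
#' @param n Per-marker GWAS sample size.
#' @param z_range Range of absolute Wald z-scores (reported p-values use the
#'   matching t reference distribution, so the grid is self-consistent at any
#'   sample size).
#' @param seed Integer seed.
#' @return data.frame with `marker`, `maf`, `beta`, `se`, `n`, `pval`.
#' @export
synthesize_sumstats_records <- function(n_records = 500, n = 2000,
                                        z_range = c(2, 35), seed = 1) {
  with_seed(seed, {
    maf <- stats::runif(n_records, 0.05, 0.5)
    z <- stats::runif(n_records, z_range[1], z_range[2]) *
      sample(c(-1, 1), n_records, replace = TRUE)
    se <- sqrt(1 / (n * marker_variance(maf)))   # unit residual variance
    beta <- z * se
    data.frame(marker = paste0("m", seq_len(n_records)), maf = maf,
               beta = beta, se = se, n = n,
               pval = 2 * stats::pt(-abs(z), n - 2))
  })
}

#' Read GWAS summary statistics from a delimited file
#'
#' Generic TSV/CSV reader with a column-mapping so arbitrary summary-stats
#' exports can be adapted; no download is performed.
#'
#' @param path File path.
#' @param colmap Named character vector mapping the required names `maf`,
#'   `beta`, `se`, `n`, `pval` to the file's column names.
#' @param sep Field separator (default tab).
#' @return data.frame with standardized columns.
#' @export
read_sumstats <- function(path, colmap = c(maf = "maf", beta = "beta",
                                           se = "se", n = "n", pval = "pval"),
                          sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(colmap), names(raw))
  if (length(missing_cols)) {
    stop_config("columns absent from file: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(lapply(colmap, function(cn) raw[[cn]]))
  names(out) <- names(colmap)
  out
}
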
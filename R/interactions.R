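# Joint-across-temperature per-locus testing of dominance, GxE and DxE,
# pairwise epistasis (GxG, GxGxE), variance decomposition, reciprocal-cross
# and per-cross post-hoc checks, and the Bonferroni bookkeeping.

# Align a long phenotype table and per-sample vectors with the record order of
# a multienv_cov (sample-major, environment fastest). Environments are the
# sorted unique values of pheno$env, mapped onto 1..n_env.
.align_records <- function(pheno, covariance) {
  samples <- unique(covariance$layout$sample)
  envs <- sort(unique(pheno$env))
  if (length(envs) != covariance$n_env) {
    stop_config("phenotype has ", length(envs), " environment levels but the ",
                "covariance structure expects ", covariance$n_env)
  }
  key <- paste(pheno$sample, pheno$env)
  want <- paste(rep(samples, each = length(envs)), rep(envs, length(samples)))
  idx <- match(want, key)
  if (anyNA(idx)) stop_config("phenotype records do not cover every sample x environment combination")
  list(pheno = pheno[idx, ], samples = samples, envs = envs)
}

# Build the whitened per-locus design blocks shared by all interaction tests.
.locus_blocks <- function(locus, pheno, covariance, covariates,
                          lead_covariate, log_transform) {
  al <- .align_records(pheno, covariance)
  ph <- al$pheno
  n <- length(al$samples); k <- length(al$envs)
  rec_sample <- rep(seq_len(n), each = k)
  if (length(locus) != n) stop_config("locus dosage must have one entry per sample")
  if (stats::sd(locus) == 0) stop_config("locus is monomorphic")
  y <- if (log_transform) log(ph$value) else ph$value
  env_f <- factor(ph$env)
  Xcov <- stats::model.matrix(~env_f)
  colnames(Xcov) <- c("intercept", paste0("env_", levels(env_f)[-1]))
  for (col in c("plate", "cross")) {
    f <- factor(ph[[col]])
    if (nlevels(f) > 1) {
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(col, "_", levels(f)[-1])
      Xcov <- cbind(Xcov, mm)
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    Xcov <- cbind(Xcov, covariates[rec_sample, , drop = FALSE])
  }
  env_dum <- stats::model.matrix(~env_f)[, -1, drop = FALSE]
  if (!is.null(lead_covariate)) {
    lead <- lead_covariate[rec_sample]
    Xcov <- cbind(Xcov, lead = lead, lead_x_env = env_dum * lead)
  }
  g <- locus[rec_sample]
  d <- dominance_code(g)
  blocks <- list(
    G = matrix(g, ncol = 1, dimnames = list(NULL, "G")),
    D = matrix(d, ncol = 1, dimnames = list(NULL, "D")),
    GxE = {m <- env_dum * g; colnames(m) <- paste0("GxE_", seq_len(ncol(m))); m},
    DxE = {m <- env_dum * d; colnames(m) <- paste0("DxE_", seq_len(ncol(m))); m}
  )
  list(y = y, Xcov = Xcov, blocks = blocks, env_dum = env_dum,
       rec_sample = rec_sample, n = n, k = k, g = g)
}

#' Fit the nested per-locus models across temperatures
#'
#' Jointly models the phenotype measured at all environments under the
#' three-matrix mixed model. Variance components are estimated once, under a
#' fixed-effect structure containing the covariates plus the additive locus
#' encoding only, and reused for every nested comparison of the locus. The
#' five model forms `G+E`, `G+E+GxE`, `G+E+D`, `G+E+D+GxE` and
#' `G+E+D+GxE+DxE` are then fitted on the whitened data and each compared to
#' the covariate-only model by likelihood-ratio test; the best model is the
#' one with the smallest p-value.
#'
#' @param locus Dosage vector (0/1/2), one entry per sample, ordered as the
#'   covariance structure's samples.
#' @param pheno A `phenotype_table` with every sample measured at every
#'   environment level; values on the bpm scale unless
#'   `log_transform = FALSE`.
#' @param covariance A `multienv_cov` built from the LOCO GRM for the locus's
#'   chromosome.
#' @param covariates Optional per-sample covariate matrix (expanded across
#'   environments internally). Plate and cross columns of `pheno` are always
#'   included as fixed covariates when they vary.
#' @param lead_covariate Optional per-sample dosage of a lead SNP whose main
#'   effect and environment interactions are added to the covariates (used to
#'   condition on a large-effect locus).
#' @param log_transform Log-transform the phenotype (variance stabilization);
#'   default `TRUE`.
#' @return Object of class `locus_fit`: list with `models` (named list of
#'   `lrt_result` vs covariate-only), `best` (model label), `w` (whitened
#'   response and design blocks), `vc` (the `vc_fit`).
#' @export
fit_locus_models <- function(locus, pheno, covariance, covariates = NULL,
                             lead_covariate = NULL, log_transform = TRUE) {
  lb <- .locus_blocks(locus, pheno, covariance, covariates, lead_covariate,
                      log_transform)
  vc <- suppressWarnings(estimate_variance_components(
    lb$y, cbind(lb$Xcov, lb$blocks$G), covariance))
  all_cols <- cbind(lb$Xcov, do.call(cbind, lb$blocks))
  w <- whiten(lb$y, all_cols, vc, covariance)
  nc <- ncol(lb$Xcov)
  wb <- list(Xcov = w$X[, seq_len(nc), drop = FALSE])
  off <- nc
  for (b in names(lb$blocks)) {
    wb[[b]] <- w$X[, off + seq_len(ncol(lb$blocks[[b]])), drop = FALSE]
    off <- off + ncol(lb$blocks[[b]])
  }
  designs <- list(
    "G+E" = c("G"),
    "G+E+GxE" = c("G", "GxE"),
    "G+E+D" = c("G", "D"),
    "G+E+D+GxE" = c("G", "D", "GxE"),
    "G+E+D+GxE+DxE" = c("G", "D", "GxE", "DxE")
  )
  models <- lapply(designs, function(terms) {
    lrt(w$y, wb$Xcov, do.call(cbind, c(list(wb$Xcov), wb[terms])))
  })
  # log-scale comparison stays informative when p-values underflow
  best <- names(models)[which.min(vapply(models, `[[`, 1, "log_p"))]
  structure(list(models = models, best = best,
                 w = c(list(y = w$y), wb), vc = vc),
            class = "locus_fit")
}

#' @export
print.locus_fit <- function(x, ...) {
  tab <- data.frame(model = names(x$models),
                    chi2 = vapply(x$models, `[[`, 1, "chi2"),
                    df = vapply(x$models, `[[`, 1, "df"),
                    p = vapply(x$models, `[[`, 1, "p"))
  print(tab, row.names = FALSE, digits = 4)
  cat("Best model:", x$best, "\n")
  invisible(x)
}

#' Bonferroni family sizes for the per-locus and pairwise test batteries
#'
#' The per-locus battery tests `n_modes` interaction modes (dominance, GxE,
#' DxE) at each locus; the pairwise battery tests 2 modes (GxG, GxGxE) for
#' every unordered locus pair. The two families are corrected independently.
#'
#' @param n_loci Number of mapped loci.
#' @param n_modes Number of interaction modes per unit (3 for the per-locus
#'   battery, 2 for the pairwise battery).
#' @return Integer family size.
#' @export
interaction_test_family <- function(n_loci, n_modes = 3) {
  as.integer(n_loci * n_modes)
}

#' @rdname interaction_test_family
#' @export
epistasis_test_family <- function(n_loci, n_modes = 2) {
  as.integer(choose(n_loci, 2) * n_modes)
}

#' Expected minority-class share for two unlinked F2 loci
#'
#' For two unlinked loci each segregating 1:2:1 in an F2 cross, each
#' double-homozygote class is the product of the two homozygote shares
#' (0.25 x 0.25 = 0.0625 at 50% allele frequency). Used to reason about
#' epistasis detection power.
#'
#' @param hom_freq_a,hom_freq_b Homozygote class frequencies at the two loci
#'   (0.25 each under Mendelian F2 segregation).
#' @param n Optional cross size; when given, the expected count in the class
#'   is returned alongside the fraction.
#' @return List with `fraction` and (if `n` given) `expected_count`.
#' @export
double_homozygote_expectation <- function(hom_freq_a = 0.25, hom_freq_b = 0.25,
                                          n = NULL) {
  fr <- hom_freq_a * hom_freq_b
  out <- list(fraction = fr)
  if (!is.null(n)) out$expected_count <- fr * n
  out
}

#' Test the dominance, GxE and DxE modes at a fitted locus
#'
#' One likelihood-ratio test per mode, each comparing nested whitened models
#' that differ only by the term of interest: GxE is `G+E+GxE` vs `G+E`; D is
#' `G+E+D` vs `G+E`; DxE is the full model vs `G+E+D+GxE`. Bonferroni
#' correction uses the family of all loci times all modes.
#'
#' @param fit A `locus_fit`.
#' @param n_loci Number of loci in the testing family (family size =
#'   `3 * n_loci`).
#' @param alpha Family-wise significance level.
#' @return data.frame: `mode`, `chi2`, `df`, `p`, `p_bonf`, `significant`,
#'   `family`.
#' @export
test_interaction_modes <- function(fit, n_loci = 1, alpha = 0.05) {
  w <- fit$w
  base_GE <- cbind(w$Xcov, w$G)
  tests <- list(
    D = lrt(w$y, base_GE, cbind(base_GE, w$D)),
    GxE = lrt(w$y, base_GE, cbind(base_GE, w$GxE)),
    DxE = lrt(w$y, cbind(base_GE, w$D, w$GxE),
              cbind(base_GE, w$D, w$GxE, w$DxE))
  )
  family <- interaction_test_family(n_loci)
  p <- vapply(tests, `[[`, 1, "p")
  data.frame(mode = names(tests),
             chi2 = vapply(tests, `[[`, 1, "chi2"),
             df = vapply(tests, `[[`, 1, "df"),
             p = p,
             p_bonf = pmin(p * family, 1),
             significant = p * family < alpha,
             family = family, row.names = NULL)
}

# sequential sums of squares over ordered column blocks (QR-based ANOVA)
.sequential_ss <- function(y, block_list) {
  rss_prev <- sum(y^2)
  X <- NULL
  ss <- numeric(length(block_list))
  for (i in seq_along(block_list)) {
    X <- cbind(X, block_list[[i]])
    rss <- sum(qr.resid(qr(X), y)^2)
    ss[i] <- rss_prev - rss
    rss_prev <- rss
  }
  list(ss = stats::setNames(ss, names(block_list)), rss = rss_prev)
}

#' Variance explained by the genetic terms of a locus
#'
#' Sequential ANOVA on the whitened full-model fit: each term's sum of
#' squares divided by the model's total sum of squares gives the absolute
#' fraction; divided by the summed G, D, GxE and DxE sums of squares it gives
#' the fraction relative to the locus's genetic variance. The decomposition
#' is exact: covariate, genetic and residual fractions sum to 1.
#'
#' @param fit A `locus_fit`.
#' @return Object of class `variance_decomposition`: data.frame with `term`,
#'   `ss`, `abs_fraction`, `rel_fraction` (NA for covariates/residual;
#'   flagged all-NA when no genetic term has positive sum of squares).
#' @export
variance_explained <- function(fit) {
  w <- fit$w
  dec <- .sequential_ss(w$y, list(covariates = w$Xcov, G = w$G, D = w$D,
                                  GxE = w$GxE, DxE = w$DxE))
  genetic <- c("G", "D", "GxE", "DxE")
  total <- sum(dec$ss) + dec$rss
  gen_total <- sum(dec$ss[genetic])
  out <- data.frame(
    term = c(names(dec$ss), "residual"),
    ss = c(dec$ss, dec$rss),
    abs_fraction = c(dec$ss, dec$rss) / total,
    rel_fraction = NA_real_, row.names = NULL
  )
  if (gen_total > 0) {
    out$rel_fraction[match(genetic, out$term)] <- dec$ss[genetic] / gen_total
  } else {
    attr(out, "degenerate") <- "no genetic term has positive sum of squares"
  }
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' Pairwise epistasis tests (GxG and GxGxE) between two loci
#'
#' The null design always contains the marginal additive effects of both loci
#' and their marginal environment interactions (the epistasis covariate
#' guard), on top of the usual covariates. The GxG test adds the dosage
#' product `gA * gB`; the GxGxE test adds its environment interactions on top
#' of the GxG model. Variance components are estimated once under the
#' additive structure, with a GRM excluding both loci's chromosomes expected
#' in `covariance`. The test is skipped (with reason) when the smallest
#' two-locus genotype class falls below `min_class_count`.
#'
#' @param locus_a,locus_b Dosage vectors, one entry per sample.
#' @param pheno,covariance,covariates,lead_covariate,log_transform As in
#'   [fit_locus_models()].
#' @param n_loci Number of loci in the family (family size =
#'   `choose(n_loci, 2) * 2`).
#' @param min_class_count Minimum count required in the smallest of the nine
#'   two-locus genotype classes (default 10).
#' @param alpha Family-wise significance level.
#' @return data.frame: `mode`, `chi2`, `df`, `p`, `p_bonf`, `significant`,
#'   `family`, `skipped`, `reason`.
#' @export
test_pairwise_epistasis <- function(locus_a, locus_b, pheno, covariance,
                                    covariates = NULL, lead_covariate = NULL,
                                    n_loci = 2, min_class_count = 10,
                                    alpha = 0.05, log_transform = TRUE) {
  family <- epistasis_test_family(n_loci)
  counts <- table(factor(locus_a, 0:2), factor(locus_b, 0:2))
  if (min(counts) < min_class_count) {
    return(data.frame(mode = c("GxG", "GxGxE"), chi2 = NA, df = NA, p = NA,
                      p_bonf = NA, significant = NA, family = family,
                      skipped = TRUE,
                      reason = paste0("smallest two-locus genotype class has ",
                                      min(counts), " < ", min_class_count,
                                      " samples")))
  }
  lb <- .locus_blocks(locus_a, pheno, covariance, covariates, lead_covariate,
                      log_transform)
  if (length(locus_b) != lb$n) stop_config("locus_b dosage must have one entry per sample")
  gB <- locus_b[lb$rec_sample]
  gA <- lb$g
  gAxE <- lb$env_dum * gA
  colnames(gAxE) <- paste0("gAxE_", seq_len(ncol(gAxE)))
  gBxE <- lb$env_dum * gB
  colnames(gBxE) <- paste0("gBxE_", seq_len(ncol(gBxE)))
  guard <- cbind(gA = gA, gB = gB, gAxE, gBxE)
  X0 <- cbind(lb$Xcov, guard)
  gg <- matrix(gA * gB, ncol = 1, dimnames = list(NULL, "GxG"))
  gge <- lb$env_dum * as.numeric(gg)
  colnames(gge) <- paste0("GxGxE_", seq_len(ncol(gge)))
  vc <- suppressWarnings(estimate_variance_components(lb$y, X0, covariance))
  w <- whiten(lb$y, cbind(X0, gg, gge), vc, covariance)
  n0 <- ncol(X0)
  X0w <- w$X[, seq_len(n0), drop = FALSE]
  ggw <- w$X[, n0 + 1, drop = FALSE]
  ggew <- w$X[, n0 + 1 + seq_len(ncol(gge)), drop = FALSE]
  t_gg <- lrt(w$y, X0w, cbind(X0w, ggw))
  t_gge <- lrt(w$y, cbind(X0w, ggw), cbind(X0w, ggw, ggew))
  p <- c(t_gg$p, t_gge$p)
  out <- data.frame(mode = c("GxG", "GxGxE"),
                    chi2 = c(t_gg$chi2, t_gge$chi2),
                    df = c(t_gg$df, t_gge$df), p = p,
                    p_bonf = pmin(p * family, 1),
                    significant = p * family < alpha,
                    family = family, skipped = FALSE, reason = "")
  attr(out, "null_design_columns") <- colnames(X0)
  out
}

#' Reciprocal-cross (parent-of-origin) tests at a locus
#'
#' Stratified by temperature: within each environment the phenotype is
#' inverse-normal transformed and two plain linear-model LRTs are run. The
#' interaction test compares plate + genotype + reciprocal-cross against the
#' same model plus the genotype x reciprocal-cross interaction; the marginal
#' test compares plate-only against plate + reciprocal-cross (no genetic
#' terms). A stratum is skipped unless each reciprocal cross has at least
#' `min_class_count` samples in its least frequent genotype class.
#'
#' @param pheno A `phenotype_table` restricted to the reciprocal cross pair.
#' @param locus Per-sample dosage vector (aligned to the samples appearing in
#'   `pheno`, by sample id via `names(locus)` or in order of first
#'   appearance).
#' @param reciprocal Per-sample factor with the two reciprocal cross labels.
#' @param min_class_count Inclusion rule threshold (default 10).
#' @return data.frame: `env`, `test` ("interaction"/"marginal"), `chi2`,
#'   `df`, `p`, plus FDR (`p_fdr`) and Bonferroni (`p_bonf`) adjusted values
#'   computed within each test type across strata.
#' @export
test_reciprocal_cross <- function(pheno, locus, reciprocal,
                                  min_class_count = 10) {
  samples <- unique(pheno$sample)
  if (is.null(names(locus))) names(locus) <- samples
  if (is.null(names(reciprocal))) names(reciprocal) <- samples
  reciprocal <- factor(reciprocal)
  if (nlevels(reciprocal) != 2) stop_config("exactly two reciprocal cross labels required")
  rows <- list()
  for (ev in sort(unique(pheno$env))) {
    ph <- pheno[pheno$env == ev, ]
    g <- locus[ph$sample]
    rc <- droplevels(reciprocal[ph$sample])
    ok <- all(vapply(levels(rc), function(l) {
      tb <- table(factor(g[rc == l], 0:2))
      min(tb) >= min_class_count
    }, logical(1)))
    if (!ok) {
      rows[[length(rows) + 1]] <- data.frame(
        env = ev, test = c("interaction", "marginal"), chi2 = NA, df = NA,
        p = NA, skipped = TRUE)
      next
    }
    y <- inverse_normal_transform(ph$value)
    plate <- factor(ph$plate)
    Xp <- stats::model.matrix(~plate)
    gf <- factor(g)
    Xnull <- cbind(Xp, stats::model.matrix(~gf + rc)[, -1, drop = FALSE])
    Xalt <- cbind(Xp, stats::model.matrix(~gf * rc)[, -1, drop = FALSE])
    t_int <- lrt(y, Xnull, Xalt)
    t_marg <- lrt(y, Xp, cbind(Xp, stats::model.matrix(~rc)[, -1, drop = FALSE]))
    rows[[length(rows) + 1]] <- data.frame(
      env = ev, test = c("interaction", "marginal"),
      chi2 = c(t_int$chi2, t_marg$chi2), df = c(t_int$df, t_marg$df),
      p = c(t_int$p, t_marg$p), skipped = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_; out$p_bonf <- NA_real_
  for (tt in c("interaction", "marginal")) {
    i <- out$test == tt & !out$skipped
    out$p_fdr[i] <- stats::p.adjust(out$p[i], "BH")
    out$p_bonf[i] <- stats::p.adjust(out$p[i], "bonferroni")
  }
  rownames(out) <- NULL
  out
}

#' Per-cross post-hoc QTL detectability check
#'
#' Fits cross-specific linear models of the (inverse-normal transformed)
#' phenotype on each lead SNP's additive dosage and evaluates the p-values at
#' a 5% false discovery rate (Benjamini-Hochberg) across the full cross-by-
#' locus matrix. Cells where the lead SNP is monomorphic within the cross are
#' marked untestable.
#'
#' @param values Per-sample phenotype vector.
#' @param lead_dosages Sample x locus dosage matrix of the lead SNPs.
#' @param cross Per-sample cross labels.
#' @param fdr False-discovery-rate threshold (default 0.05).
#' @return List with matrices `p`, `q`, `flag` (logical significance;
#'   NA = untestable) and `n` (samples per cross).
#' @export
per_cross_qtl_check <- function(values, lead_dosages, cross, fdr = 0.05) {
  lead_dosages <- as.matrix(lead_dosages)
  cross <- factor(cross)
  L <- ncol(lead_dosages)
  p <- matrix(NA_real_, nlevels(cross), L,
              dimnames = list(levels(cross), colnames(lead_dosages)))
  for (cr in levels(cross)) {
    i <- cross == cr
    if (sum(i) < 4) next
    y <- tryCatch(inverse_normal_transform(values[i]), error = function(e) NULL)
    if (is.null(y)) next
    for (l in seq_len(L)) {
      g <- lead_dosages[i, l]
      if (stats::sd(g) == 0) next
      X0 <- matrix(1, sum(i), 1)
      p[cr, l] <- lrt(y, X0, cbind(X0, g))$p
    }
  }
  q <- p
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], "BH")
  list(p = p, q = q, flag = q < fdr, n = table(cross))
}
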
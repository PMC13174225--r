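# REML variance-component estimation, whitening, and likelihood-ratio tests.
#
# The model is y = X b + sum_i u_i + eps with u_i ~ N(0, s2_i K_i) and
# eps ~ N(0, s2_e I), so V = sum_i s2_i K_i + s2_e I. Estimation maximizes the
# restricted likelihood over log-variances (non-negativity by construction).
#
# When all K_i share an eigenbasis -- which holds exactly for the Kronecker
# multi-environment structure (I(x)J, K(x)J, K(x)I all commute) -- the model
# is rotated into that basis once and every likelihood evaluation costs O(n)
# instead of O(n^3). A dense Cholesky fallback covers arbitrary PSD matrices.

.as_cov_list <- function(covariances) {
  if (inherits(covariances, "multienv_cov")) return(covariances$K)
  if (inherits(covariances, "grm")) return(list(genetic = covariances$K))
  if (is.matrix(covariances)) return(list(K1 = covariances))
  stopifnot(is.list(covariances), all(vapply(covariances, is.matrix, TRUE)))
  if (is.null(names(covariances)) || any(names(covariances) == "")) {
    names(covariances) <- paste0("K", seq_along(covariances))
  }
  covariances
}

.check_psd <- function(K_list, tol = 1e-8) {
  for (nm in names(K_list)) {
    K <- K_list[[nm]]
    if (!isSymmetric(unname(K), tol = 1e-8)) {
      stop_numeric("covariance matrix '", nm, "' is not symmetric")
    }
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * max(abs(ev), 1)) {
      stop_numeric("covariance matrix '", nm, "' is not positive semidefinite")
    }
  }
}

# joint eigenbasis of all K_i if one exists; NULL otherwise
.joint_eigen <- function(K_list) {
  n <- nrow(K_list[[1]])
  w <- sqrt(c(2, 3, 5, 7, 11, 13, 17, 19))[seq_along(K_list)]
  Kw <- Reduce(`+`, Map(`*`, K_list, w))
  U <- eigen(Kw, symmetric = TRUE)$vectors
  d <- matrix(0, n, length(K_list), dimnames = list(NULL, names(K_list)))
  for (i in seq_along(K_list)) {
    M <- crossprod(U, K_list[[i]] %*% U)
    dg <- diag(M)
    off <- max(abs(M - diag(dg, n)))
    if (off > 1e-7 * max(abs(dg), 1)) return(NULL)
    d[, i] <- pmax(dg, 0)
  }
  list(U = U, d = d)
}

# -2 restricted log-likelihood on the rotated (diagonal) model
.neg2_reml_spectral <- function(log_s2, d, yt, Xt) {
  s2 <- exp(log_s2)
  k <- ncol(d)
  v <- as.numeric(d %*% s2[seq_len(k)]) + s2[k + 1L]
  if (any(v <= 0) || any(!is.finite(v))) return(1e10)
  Xv <- Xt / v
  XtVX <- crossprod(Xt, Xv)
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, yt / v)))
  r <- yt - Xt %*% beta
  quad <- sum(r^2 / v)
  sum(log(v)) + 2 * sum(log(diag(ch))) + quad +
    (length(yt) - ncol(Xt)) * log(2 * pi)
}

.neg2_reml_dense <- function(log_s2, K_list, y, X) {
  s2 <- exp(log_s2)
  k <- length(K_list)
  n <- length(y)
  V <- diag(s2[k + 1L], n)
  for (i in seq_len(k)) V <- V + s2[i] * K_list[[i]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  XtVX <- crossprod(Xt)
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, yt)))
  r <- yt - Xt %*% beta
  2 * sum(log(diag(R))) + 2 * sum(log(diag(ch))) + sum(r^2) +
    (n - ncol(X)) * log(2 * pi)
}

#' Estimate variance components by REML
#'
#' Fits `y = X b + sum_i u_i + eps`, `u_i ~ N(0, s2_i K_i)`, by restricted
#' maximum likelihood over log-parameterized variances with multiple starting
#' points. Returns a model object of class `vc_fit` with `print`, `summary`,
#' `coef` and `logLik` methods.
#'
#' @param y Numeric response vector (one entry per record).
#' @param X Fixed-effect design matrix (full column rank; include the
#'   intercept explicitly). Defaults to an intercept-only design.
#' @param covariances A `multienv_cov`, a `grm`, a single matrix, or a named
#'   list of PSD matrices.
#' @param n_starts Number of optimizer starting points (default 3).
#' @param reltol Relative convergence tolerance on -2 log-likelihood.
#' @return `vc_fit` object with elements `sigma2` (named vector, one per
#'   covariance matrix), `sigma2_resid`, `loglik` (restricted log-likelihood),
#'   `converged`, `n`, `method` (`"spectral"` or `"dense"`), plus internals
#'   reused by [whiten()].
#' @export
estimate_variance_components <- function(y, X = NULL, covariances,
                                         n_starts = 3, reltol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  X <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "intercept")) else as.matrix(X)
  if (nrow(X) != n) stop_config("y and X must have the same number of rows")
  if (qr(X)$rank < ncol(X)) stop_config("X is rank deficient")
  K_list <- .as_cov_list(covariances)
  if (any(vapply(K_list, nrow, 1L) != n)) {
    stop_config("covariance dimension does not match length(y)")
  }
  k <- length(K_list)

  # reuse the analytic Kronecker eigenbasis when available
  je <- if (inherits(covariances, "multienv_cov") &&
            !is.null(covariances$spectral)) {
    covariances$spectral
  } else {
    .check_psd(K_list)
    .joint_eigen(K_list)
  }

  # warn when components are aliased (e.g. a K_i proportional to the
  # identity): in the joint eigenbasis this is linear dependence among the
  # eigenvalue profiles and the constant residual profile
  aliased <- if (!is.null(je)) {
    qr(cbind(je$d, 1))$rank < k + 1L
  } else if (n <= 300) {
    dmat_alias <- vapply(K_list, function(K) as.numeric(K), numeric(n * n))
    qr(cbind(dmat_alias, as.numeric(diag(n))))$rank < k + 1L
  } else {
    FALSE
  }
  if (aliased) {
    warning("variance components are aliased (a covariance matrix is linearly ",
            "dependent on the others / the residual identity); the split ",
            "between aliased components is not identifiable", call. = FALSE)
  }
  if (!is.null(je)) {
    yt <- crossprod(je$U, y)
    Xt <- crossprod(je$U, X)
    obj <- function(th) .neg2_reml_spectral(th, je$d, yt, Xt)
    method <- "spectral"
  } else {
    obj <- function(th) .neg2_reml_dense(th, K_list, y, X)
    method <- "dense"
  }

  vy <- stats::var(y)
  starts <- list(rep(log(vy / (k + 1)), k + 1L),
                 c(rep(log(vy / (10 * k)), k), log(vy * 0.9)),
                 c(rep(log(vy * 0.9 / k), k), log(vy / 10)))
  starts <- starts[seq_len(min(n_starts, 3L))]
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = reltol))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 200, reltol = reltol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  s2 <- exp(best$par)
  structure(list(
    sigma2 = stats::setNames(s2[seq_len(k)], names(K_list)),
    sigma2_resid = s2[k + 1L],
    loglik = -best$value / 2,
    converged = best$convergence == 0,
    n = n, p = ncol(X), method = method,
    K_names = names(K_list)
  ), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("REML variance components (", x$method, " path, n = ", x$n, "):\n", sep = "")
  print(round(c(x$sigma2, residual = x$sigma2_resid), 6))
  cat("Restricted log-likelihood:", round(x$loglik, 3),
      if (!x$converged) "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.vc_fit <- function(object, ...) {
  s2 <- c(object$sigma2, residual = object$sigma2_resid)
  out <- data.frame(component = names(s2), sigma2 = as.numeric(s2),
                    proportion = as.numeric(s2) / sum(s2))
  structure(list(table = out, loglik = object$loglik,
                 converged = object$converged), class = "summary.vc_fit")
}

#' @export
print.summary.vc_fit <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat("Restricted log-likelihood:", round(x$loglik, 3), "\n")
  invisible(x)
}

#' @export
coef.vc_fit <- function(object, ...) {
  c(object$sigma2, residual = object$sigma2_resid)
}

#' @export
logLik.vc_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2) + 1, class = "logLik")
}

#' Whiten (decorrelate) a model under fitted variance components
#'
#' Computes `V = sum_i s2_i K_i + s2_resid I`, its Cholesky factor `V = L L'`,
#' and returns `y* = L^-1 y`, `X* = L^-1 X`, so that ordinary least squares on
#' the starred quantities equals generalized least squares on the originals.
#' A small diagonal jitter (1e-8) is applied, with a message, if `V` is not
#' numerically positive definite.
#'
#' @param y,X Response and design as in [estimate_variance_components()].
#' @param vc A `vc_fit`.
#' @param covariances The same covariance structure used for fitting.
#' @return List with `y`, `X` (whitened), and `chol` (the upper-triangular
#'   factor `R`, `V = R'R`; whiten further columns with
#'   `backsolve(chol, M, transpose = TRUE)`).
#' @export
whiten <- function(y, X, vc, covariances) {
  K_list <- .as_cov_list(covariances)
  stopifnot(inherits(vc, "vc_fit"), identical(names(K_list), vc$K_names))
  n <- length(y)
  V <- diag(vc$sigma2_resid, n)
  for (i in seq_along(K_list)) V <- V + vc$sigma2[i] * K_list[[i]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    message("whiten: V not positive definite; applying 1e-8 diagonal jitter")
    R <- tryCatch(chol(V + diag(1e-8, n)), error = function(e) NULL)
    if (is.null(R)) stop_numeric("V is not positive definite even after jitter")
  }
  list(y = backsolve(R, as.numeric(y), transpose = TRUE),
       X = backsolve(R, as.matrix(X), transpose = TRUE),
       chol = R)
}

#' Likelihood-ratio test between nested whitened linear models
#'
#' On whitened data the Gaussian profile-likelihood ratio reduces to
#' `chi2 = n log(RSS_null / RSS_alt)` with degrees of freedom equal to the
#' number of independent columns added by the alternative design.
#'
#' @param y Whitened response.
#' @param X_null,X_alt Whitened design matrices; the null design's column
#'   span must be contained in the alternative's.
#' @return Object of class `lrt_result`: list with `chi2`, `df`, `p`,
#'   `log_p` (natural-log p-value, informative even when `p` underflows),
#'   `rss_null`, `rss_alt`, `n`.
#' @export
lrt <- function(y, X_null, X_alt) {
  X_null <- as.matrix(X_null); X_alt <- as.matrix(X_alt)
  n <- length(y)
  qa <- qr(X_alt)
  # nesting check: every null column must lie in the alternative column span
  proj <- qr.resid(qa, X_null)
  if (max(abs(proj)) > 1e-6 * max(abs(X_null), 1)) {
    stop_config("designs are not nested: X_null is not contained in X_alt")
  }
  q0 <- qr(X_null)
  df <- qa$rank - q0$rank
  if (df == 0L) {
    # identical column spans: nothing to test
    return(structure(list(chi2 = 0, df = 0L, p = 1, log_p = 0,
                          rss_null = sum(qr.resid(q0, y)^2),
                          rss_alt = sum(qr.resid(qa, y)^2), n = n),
                     class = "lrt_result"))
  }
  rss0 <- sum(qr.resid(q0, y)^2)
  rss1 <- sum(qr.resid(qa, y)^2)
  chi2 <- max(n * log(rss0 / rss1), 0)
  log_p <- stats::pchisq(chi2, df, lower.tail = FALSE, log.p = TRUE)
  structure(list(chi2 = chi2, df = df, p = exp(log_p), log_p = log_p,
                 rss_null = rss0, rss_alt = rss1, n = n),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.3f, df = %d, p = %.3g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Estimate heritability
#'
#' Two modes matching the two study designs:
#'
#' * `"anova_strain"`: broad-sense heritability of inbred-panel data from a
#'   one-way random-effects decomposition (between-strain variance over total,
#'   method-of-moments with the unbalanced-design correction).
#' * `"mixed_grm"`: narrow-sense heritability from a single-GRM mixed model,
#'   `h2 = s2_g / (s2_g + s2_e)`, REML-estimated.
#'
#' Confidence intervals are nonparametric bootstrap percentiles (resampling
#' strains, or samples, with replacement).
#'
#' @param values Phenotype vector.
#' @param mode `"anova_strain"` or `"mixed_grm"`.
#' @param strain Factor of strain labels (anova mode).
#' @param grm A `grm` or relatedness matrix (mixed mode).
#' @param n_boot Bootstrap replicates (default 100; 0 skips the CI).
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `heritability`: list with `h2`, `ci`, `mode`,
#'   `boot` (bootstrap draws).
#' @export
estimate_heritability <- function(values, mode = c("anova_strain", "mixed_grm"),
                                  strain = NULL, grm = NULL, n_boot = 100,
                                  conf = 0.95, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "anova_strain") {
    strain <- droplevels(as.factor(strain))
    if (nlevels(strain) < 2) stop_config("at least 2 strains required")
    point <- .h2_anova(values, strain)
    boot <- if (n_boot > 0) with_seed(seed, {
      levs <- levels(strain)
      vapply(seq_len(n_boot), function(b) {
        pick <- sample(levs, replace = TRUE)
        idx <- unlist(lapply(seq_along(pick), function(i) which(strain == pick[i])))
        newstrain <- factor(rep(seq_along(pick),
                                times = vapply(pick, function(l) sum(strain == l), 1L)))
        .h2_anova(values[idx], newstrain)
      }, numeric(1))
    })
  } else {
    K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
    if (is.null(K) || nrow(K) < 3) stop_config("a valid GRM is required for mixed_grm mode")
    if (max(abs(K - diag(diag(K)))) < 1e-10) stop_config("degenerate (diagonal) GRM")
    point <- .h2_mixed(values, K)
    boot <- if (n_boot > 0) with_seed(seed, {
      n <- length(values)
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, replace = TRUE)
        tryCatch(.h2_mixed(values[idx], K[idx, idx]), error = function(e) NA_real_)
      }, numeric(1))
    })
  }
  ci <- if (n_boot > 0) {
    stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  }
  structure(list(h2 = point, ci = ci, mode = mode, boot = boot),
            class = "heritability")
}

.h2_anova <- function(values, strain) {
  ni <- tabulate(strain)
  N <- sum(ni); a <- nlevels(strain)
  means <- tapply(values, strain, mean)
  ssb <- sum(ni * (means - mean(values))^2)
  ssw <- sum((values - means[strain])^2)
  msb <- ssb / (a - 1); msw <- ssw / (N - a)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  s2b <- max((msb - msw) / n0, 0)
  s2b / (s2b + msw)
}

.h2_mixed <- function(values, K) {
  fit <- suppressWarnings(
    estimate_variance_components(values, covariances = list(genetic = K))
  )
  as.numeric(fit$sigma2[1] / (fit$sigma2[1] + fit$sigma2_resid))
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("Heritability (%s): %.3f", x$mode, x$h2))
  if (!is.null(x$ci)) cat(sprintf(" [%.3f, %.3f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}
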
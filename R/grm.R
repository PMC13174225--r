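# Genomic relatedness matrices and the multi-environment covariance structure.

#' Compute a genomic relatedness matrix (GRM)
#'
#' VanRaden-type GRM from column-standardized dosages: `K = W W' / m` over the
#' `m` retained polymorphic variants. Supports leave-one-chromosome-out (LOCO)
#' construction by excluding the chromosome(s) carrying the tested locus, so
#' the tested variant never contributes to the relatedness correction.
#'
#' @param genotypes A `genotype_matrix`.
#' @param exclude_chromosomes Chromosome identifiers to drop (LOCO); default
#'   none.
#' @return Object of class `grm`: list with `K` (n x n symmetric matrix),
#'   `m` (number of variants used), `excluded` (chromosomes left out).
#' @export
compute_grm <- function(genotypes, exclude_chromosomes = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  keep <- !(genotypes$map$chrom %in% exclude_chromosomes)
  W <- genotypes$dosages[, keep, drop = FALSE]
  sds <- apply(W, 2, stats::sd)
  poly <- !is.na(sds) & sds > 0
  if (sum(poly) < 2L) stop_config("fewer than 2 polymorphic variants retained for the GRM")
  W <- scale(W[, poly, drop = FALSE])
  K <- tcrossprod(W) / ncol(W)
  dimnames(K) <- list(rownames(genotypes$dosages), rownames(genotypes$dosages))
  structure(list(K = K, m = ncol(W), excluded = exclude_chromosomes),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM:", nrow(x$K), "samples,", x$m, "variants",
      if (length(x$excluded)) paste0("(excluding chromosome(s) ",
                                     paste(x$excluded, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Build the three-matrix multi-environment covariance structure
#'
#' For `n` samples each measured in `n_env` environments (records ordered
#' sample-major, environment fastest), constructs the three PSD random-effect
#' covariance matrices of the compound-symmetry environment model:
#'
#' * `id`: 1 for pairs of records from the same sample, 0 otherwise
#'   (`I_n (x) J`), absorbing repeated-measurement correlation;
#' * `shared`: the GRM expanded across environments (`K (x) J`, `J` the all-ones
#'   matrix), the environment-independent genetic covariance;
#' * `env`: the GRM within environments only (`K (x) I`), genetic covariance
#'   that does not transfer between environments.
#'
#' Together `shared` and `env` define a compound-symmetry model in which the
#' genetic variance and the between-environment genetic covariance are each
#' constant but possibly different.
#'
#' @param grm A `grm` object or a bare relatedness matrix.
#' @param n_env Number of environments (>= 2).
#' @return Object of class `multienv_cov`: list with `K` (named list of the
#'   three matrices), `layout` (data.frame `sample`, `env` per record), `n`,
#'   `n_env`, and the original GRM for fast-path REML.
#' @export
build_multienv_covariances <- function(grm, n_env) {
  K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop_config("GRM must be symmetric")
  if (n_env < 2) stop_config("n_env must be >= 2")
  n <- nrow(K)
  J <- matrix(1, n_env, n_env)
  I_e <- diag(n_env)
  mats <- list(
    id = kronecker(diag(n), J),
    shared = kronecker(K, J),
    env = kronecker(K, I_e)
  )
  layout <- data.frame(
    sample = rep(rownames(K) %||% paste0("s", seq_len(n)), each = n_env),
    env = rep(seq_len(n_env), times = n)
  )
  # the three matrices commute and share the Kronecker eigenbasis
  # U_grm (x) U_J; precompute it so REML evaluations stay O(n)
  edK <- eigen(K, symmetric = TRUE)
  edJ <- eigen(J, symmetric = TRUE)
  spectral <- list(
    U = kronecker(edK$vectors, edJ$vectors),
    d = cbind(id = rep(pmax(edJ$values, 0), times = n),
              shared = kronecker(pmax(edK$values, 0), pmax(edJ$values, 0)),
              env = rep(pmax(edK$values, 0), each = n_env))
  )
  structure(list(K = mats, layout = layout, n = n, n_env = n_env, grm = K,
                 spectral = spectral),
            class = "multienv_cov")
}

#' @export
print.multienv_cov <- function(x, ...) {
  cat("Multi-environment covariance structure:", x$n, "samples x", x$n_env,
      "environments =", x$n * x$n_env, "records; matrices:",
      paste(names(x$K), collapse = ", "), "\n")
  invisible(x)
}
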
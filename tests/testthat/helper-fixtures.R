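# Shared fixture builders: everything is generated in code at test time.

env3 <- function() {
  structure(data.frame(temperature = c(21, 28, 35),
                       e = log(c(21, 28, 35) - 6)),
            class = c("environment_sample", "data.frame"))
}

# small two-cross F2 population
tiny_f2 <- function(n_f2 = 60, n_chrom = 2, sites = 15, seed = 7) {
  fp <- simulate_founders(4, n_chrom, sites, seed = seed)
  cd <- cross_design(c("strain_1", "strain_3"), c("strain_2", "strain_4"),
                     n_f2 = n_f2)
  list(founders = fp, f2 = simulate_f2(fp, cd, seed = seed + 1))
}

# multi-cross F2 population with a richer relatedness structure
rich_f2 <- function(n_crosses = 10, n_f2 = 30, seed = 51) {
  fp <- simulate_founders(8, 3, 60, seed = seed)
  pairs <- with_seed_local(seed + 1, {
    p <- cbind(sample(8, n_crosses, TRUE), sample(8, n_crosses, TRUE))
    same <- p[, 1] == p[, 2]
    p[same, 2] <- (p[same, 2] %% 8) + 1
    p
  })
  cd <- cross_design(paste0("strain_", pairs[, 1]),
                     paste0("strain_", pairs[, 2]), n_f2 = n_f2)
  simulate_f2(fp, cd, seed = seed + 2)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# a mid-frequency variant segregating in every cross of a genotype matrix
pick_segregating <- function(f2, chrom = NULL) {
  afs <- colMeans(f2$dosages) / 2
  ok <- afs > 0.35 & afs < 0.65
  if (!is.null(chrom)) ok <- ok & f2$map$chrom == chrom
  seg_everywhere <- vapply(seq_len(ncol(f2$dosages)), function(j) {
    all(tapply(f2$dosages[, j], f2$cross, function(v) stats::sd(v) > 0))
  }, logical(1))
  idx <- which(ok & seg_everywhere)
  if (length(idx) == 0L) idx <- which(ok)
  unname(idx[which.min(abs(afs[idx] - 0.5))])
}

# phenotype with multi-environment random-effect structure: y = shared
# polygenic + env-specific polygenic + per-sample + iid noise, plus an
# optional fixed genetic signal; record order matches build_multienv_covariances
gen_multienv_pheno <- function(K, s2 = c(id = 0.2, shared = 0.3, env = 0.2,
                                         resid = 0.3),
                               n_env = 3, fixed = 0, seed = 1) {
  n <- nrow(K)
  ed <- eigen(K, symmetric = TRUE)
  rtK <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)))
  with_seed_local(seed, {
    a_sh <- as.numeric(rtK %*% stats::rnorm(n)) * sqrt(s2["shared"])
    a_env <- vapply(seq_len(n_env),
                    function(e) as.numeric(rtK %*% stats::rnorm(n)) * sqrt(s2["env"]),
                    numeric(n))
    idf <- stats::rnorm(n, 0, sqrt(s2["id"]))
    y <- numeric(n * n_env)
    for (e in seq_len(n_env)) {
      y[seq(e, n * n_env, by = n_env)] <-
        a_sh + a_env[, e] + idf + stats::rnorm(n, 0, sqrt(s2["resid"]))
    }
    y + fixed
  })
}

# wrap a numeric record vector as a phenotype_table on the bpm scale,
# sample-major env-fastest to match a multienv_cov built on the same samples
as_pheno_table <- function(y_log, samples, envs = c(21, 28, 35),
                           cross = "cross_1") {
  n <- length(samples)
  structure(data.frame(
    sample = rep(samples, each = length(envs)),
    env = rep(envs, times = n),
    e = rep(log(envs - 6), times = n),
    value = exp(y_log),
    plate = "plate_1",
    cross = if (length(cross) == n) rep(cross, each = length(envs)) else cross,
    stringsAsFactors = FALSE), class = c("phenotype_table", "data.frame"))
}
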
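# Mixed-model engine: GRM construction, Kronecker covariance structure,
# REML estimation, whitening/GLS equivalence, LRT behaviour, heritability.

test_that("GRM reflects duplication, LOCO exclusion and cross structure", {
  tf <- tiny_f2(n_f2 = 40, n_chrom = 3, sites = 20)
  f2 <- tf$f2

  # duplicated sample: off-diagonal entry matches the diagonal
  dup <- genotype_matrix(rbind(f2$dosages, f2$dosages[1, , drop = FALSE]),
                         f2$map)
  Kd <- compute_grm(dup)$K
  n <- nrow(Kd)
  expect_lt(abs(Kd[1, n] - Kd[1, 1]), 1e-8)

  # LOCO bookkeeping: excluding chromosomes removes exactly their variants
  g_all <- compute_grm(f2)
  g_loco <- compute_grm(f2, exclude_chromosomes = c(1, 2))
  kept_poly <- sum(apply(f2$dosages[, f2$map$chrom == 3, drop = FALSE], 2, sd) > 0)
  expect_equal(g_loco$m, kept_poly)
  expect_error(compute_grm(f2, exclude_chromosomes = 1:3),
               class = "interax_config_error")

  # siblings from the same cross are more related than cross-strangers
  K <- g_all$K
  same <- outer(f2$cross, f2$cross, "==")
  off <- row(K) != col(K)
  expect_gt(mean(K[same & off]), mean(K[!same]))
})

test_that("multi-environment covariances equal brute-force construction", {
  tf <- tiny_f2(n_f2 = 5, n_chrom = 2, sites = 12)
  K <- compute_grm(tf$f2)$K
  n <- nrow(K); n_env <- 3
  mc <- build_multienv_covariances(K, n_env)
  expect_true(all(vapply(mc$K, function(M) all(dim(M) == n * n_env), TRUE)))

  # elementwise oracle straight from the definitions
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (e in seq_len(n_env)) for (f in seq_len(n_env)) {
      r <- (i - 1) * n_env + e; c <- (j - 1) * n_env + f
      expect_identical(mc$K$id[r, c], as.numeric(i == j))
      expect_identical(mc$K$shared[r, c], K[i, j])
      expect_identical(mc$K$env[r, c], if (e == f) K[i, j] else 0)
    }
  }
  expect_error(build_multienv_covariances(K, 1), class = "interax_config_error")
})

test_that("REML recovers variance components and scales correctly", {
  f2 <- rich_f2(n_crosses = 6, n_f2 = 20)
  K <- compute_grm(f2)$K
  mc <- build_multienv_covariances(K, 3)
  y <- gen_multienv_pheno(K, seed = 21)
  fit <- estimate_variance_components(y, covariances = mc)
  expect_true(fit$converged)
  expect_true(all(coef(fit) >= 0))

  # multiplying y by 2 multiplies every variance component by 4
  fit2 <- estimate_variance_components(2 * y, covariances = mc)
  expect_equal(unname(coef(fit2)), unname(4 * coef(fit)), tolerance = 1e-3)

  # estimates invariant to sample reordering
  perm <- with_seed_local(3, sample(nrow(K)))
  recs <- as.vector(vapply(perm, function(i) (i - 1) * 3 + 1:3, numeric(3)))
  mc_p <- build_multienv_covariances(K[perm, perm], 3)
  fit_p <- estimate_variance_components(y[recs], covariances = mc_p)
  expect_equal(unname(coef(fit_p)), unname(coef(fit)), tolerance = 1e-3)

  # aliased design: identity covariance against the identity residual
  expect_warning(
    estimate_variance_components(rnorm(40), covariances = list(g = diag(40))),
    "aliased")
})

test_that("spectral and dense REML objectives agree", {
  tf <- tiny_f2(n_f2 = 8, n_chrom = 2, sites = 12)
  K <- compute_grm(tf$f2)$K
  mc <- build_multienv_covariances(K, 3)
  y <- gen_multienv_pheno(K, seed = 5)
  X <- matrix(1, length(y), 1)
  th <- log(c(0.15, 0.25, 0.3, 0.35))
  dense <- interax:::.neg2_reml_dense(th, mc$K, y, X)
  spec <- interax:::.neg2_reml_spectral(th, mc$spectral$d,
                                        crossprod(mc$spectral$U, y),
                                        crossprod(mc$spectral$U, X))
  expect_equal(dense, spec, tolerance = 1e-9)
})

test_that("whitened OLS equals closed-form GLS", {
  with_seed_local(31, {
    for (rep in 1:5) {
      n <- sample(10:30, 1)
      A <- matrix(rnorm(n * n), n)
      K1 <- crossprod(A) / n
      B <- matrix(rnorm(n * n), n)
      K2 <- crossprod(B) / n
      y <- rnorm(n)
      X <- cbind(1, rnorm(n), rnorm(n))
      s2 <- c(0.7, 0.4); s2e <- 0.6
      vc <- structure(list(sigma2 = c(K1 = s2[1], K2 = s2[2]),
                           sigma2_resid = s2e, K_names = c("K1", "K2")),
                      class = "vc_fit")
      w <- whiten(y, X, vc, list(K1 = K1, K2 = K2))
      b_ols <- qr.coef(qr(w$X), w$y)
      V <- s2[1] * K1 + s2[2] * K2 + s2e * diag(n)
      b_gls <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, y)))
      expect_lt(max(abs(b_ols - b_gls)) / max(abs(b_gls)), 1e-8)
    }
  })
  # pure-residual model: whitening is a rescaling by 1/sigma only
  vc0 <- structure(list(sigma2 = c(K1 = 0), sigma2_resid = 1, K_names = "K1"),
                   class = "vc_fit")
  y <- rnorm(12); X <- cbind(1, rnorm(12))
  w0 <- whiten(y, X, vc0, list(K1 = diag(0, 12)))
  expect_equal(w0$y, y)
  expect_equal(w0$X, X, ignore_attr = TRUE)
})

test_that("likelihood-ratio test is sane and calibrated", {
  with_seed_local(41, {
    y <- rnorm(60); X0 <- cbind(1, rnorm(60)); X1 <- cbind(X0, rnorm(60))
    same <- lrt(y, X0, X0)
    expect_equal(same$chi2, 0)
    expect_equal(same$p, 1)
    r <- lrt(y, X0, X1)
    expect_equal(r$df, 1)
    expect_gte(r$chi2, 0)
    expect_equal(r$p, pchisq(r$chi2, 1, lower.tail = FALSE))
    # non-nested designs rejected
    expect_error(lrt(y, cbind(rnorm(60)), X1), class = "interax_config_error")
  })
  # null-true simulation: p approximately uniform
  pvals <- with_seed_local(42, vapply(1:400, function(b) {
    y <- rnorm(300); X0 <- matrix(1, 300, 1)
    lrt(y, X0, cbind(X0, rnorm(300)))$p
  }, numeric(1)))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("heritability estimators behave at the boundaries and recover truth", {
  # no strain differences: h2 ~ 0
  sp0 <- data.frame(strain = factor(rep(1:10, each = 8)), value = rnorm(80))
  h0 <- estimate_heritability(sp0$value, "anova_strain", strain = sp0$strain,
                              n_boot = 0)
  expect_lt(h0$h2, 0.25)

  # no residual noise: h2 ~ 1
  sp1 <- data.frame(strain = factor(rep(1:10, each = 8)),
                    value = rep(rnorm(10), each = 8) + rnorm(80, 0, 1e-4))
  h1 <- estimate_heritability(sp1$value, "anova_strain", strain = sp1$strain,
                              n_boot = 0)
  expect_gt(h1$h2, 0.99)

  # recovery at the study's h2 regime
  sp <- simulate_strain_phenotypes(80, 20, h2 = 0.45, seed = 61)
  h <- estimate_heritability(sp$value, "anova_strain", strain = sp$strain,
                             n_boot = 100, seed = 62)
  expect_lt(abs(h$h2 - 0.45), 0.08)
  expect_true(h$ci[1] < 0.45 && h$ci[2] > 0.45)

  # mixed-model mode on a GRM
  f2 <- rich_f2(n_crosses = 6, n_f2 = 25)
  Kg <- compute_grm(f2)
  yg <- simulate_polygenic_phenotype(Kg, h2 = 0.45, seed = 63)
  hg <- estimate_heritability(yg, "mixed_grm", grm = Kg, n_boot = 0)
  expect_lt(abs(hg$h2 - 0.45), 0.2)

  expect_error(estimate_heritability(rnorm(10), "anova_strain",
                                     strain = factor(rep(1, 10))),
               class = "interax_config_error")
})
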
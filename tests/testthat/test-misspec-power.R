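# Power simulator: effect-size recovery, noise conventions, tagging
# semantics, discovery-model behaviour, the sample-size ladder, dominance
# ratios and discoverability rules.

test_that("effect sizes are recovered from generated data", {
  n <- 3000
  g <- simulate_outbred_genotypes(n, 0.4, seed = 91)
  names(g) <- paste0("s", seq_len(n))
  gp <- simulate_outbred_genotypes(n, 0.3, seed = 92)
  ev <- sample_environment(n, source = "seasonal", seed = 93)
  truth <- effect_sizes(intercept = 1.95, beta_g = 0.05, beta_e = 1.05,
                        beta_d = 0.03, beta_gxe = 0.04, beta_dxe = 0.02,
                        partners = list(pA = list(af = 0.3, beta_p = 0.04,
                                                  beta_pxe = 0.01)),
                        sigma2 = 0.01)
  ph <- simulate_phenotype(g, ev, truth, partner_genotypes = list(pA = gp),
                           seed = 94)
  ph$value <- exp(ph$value)
  est <- estimate_effect_sizes(g, ph, partner_genotypes = list(pA = gp))
  # the well-identified quantities: effective effects at the mean environment
  e_bar <- mean(ev$e)
  expect_lt(abs((est$beta_g + est$beta_gxe * e_bar) -
                (truth$beta_g + truth$beta_gxe * e_bar)), 0.01)
  expect_lt(abs((est$beta_d + est$beta_dxe * e_bar) -
                (truth$beta_d + truth$beta_dxe * e_bar)), 0.015)
  expect_lt(abs(est$beta_e - truth$beta_e), 0.1)
  expect_lt(abs(est$sigma2 / truth$sigma2 - 1), 0.1)

  # epistasis-free data: nested fit leaves the shared terms stable
  est_epi <- estimate_effect_sizes(g, ph, partner_genotypes = list(pA = gp),
                                   include_epistasis = TRUE)
  expect_lt(abs(est_epi$partners$pA$beta_gxg), 0.05)
  expect_lt(abs(est_epi$beta_e - est$beta_e), 0.05)

  # partner covariates are structural
  expect_error(estimate_effect_sizes(g, ph, partner_genotypes = list()),
               class = "interax_config_error")
})

test_that("environment noise follows the chosen variance convention", {
  eff <- bundled_effect_sizes("qtl_additive")
  cond5 <- sim_condition(af = 0.3, noise_fraction = 0.5)
  ds <- generate_condition_dataset(eff, 20000, cond5, seed = 95)
  t_true <- exp(ds$e_true) + 6
  t_obs <- exp(ds$e_obs) + 6
  noise <- t_obs - t_true
  # noise is half of the total observed variance
  expect_lt(abs(var(noise) / var(t_obs) - 0.5), 0.05)
  expect_lt(abs(var(noise) / var(t_true) - 1), 0.1)

  # zero noise: observed environment is the true one
  cond0 <- sim_condition(af = 0.3, noise_fraction = 0)
  ds0 <- generate_condition_dataset(eff, 500, cond0, seed = 96)
  expect_identical(ds0$e_obs, ds0$e_true)

  # alternative convention: sigma_n^2 = f * Var(E)
  condS <- sim_condition(af = 0.3, noise_fraction = 0.5,
                         noise_convention = "of_signal")
  dsS <- generate_condition_dataset(eff, 20000, condS, seed = 95)
  noiseS <- (exp(dsS$e_obs) + 6) - (exp(dsS$e_true) + 6)
  expect_lt(abs(var(noiseS) / var(exp(dsS$e_true) + 6) - 0.5), 0.05)

  expect_error(sim_condition(af = 0.3, noise_fraction = 1),
               class = "interax_config_error")
})

test_that("tagging at r2 = 1 reproduces causal genotyping exactly", {
  eff <- bundled_effect_sizes("qtl_additive")
  c_tag <- sim_condition(af = 0.3, tagging_r2 = 1)
  c_causal <- sim_condition(af = 0.3)
  d1 <- generate_condition_dataset(eff, 2000, c_tag, seed = 97)
  d2 <- generate_condition_dataset(eff, 2000, c_causal, seed = 97)
  expect_identical(d1$g_tested, d2$g_causal)
  expect_equal(fit_discovery_model(d1)$p, fit_discovery_model(d2)$p)

  # at r2 = 0.9 the tested genotype is correlated but not identical
  c_09 <- sim_condition(af = 0.3, tagging_r2 = 0.9)
  d3 <- generate_condition_dataset(eff, 20000, c_09, seed = 97)
  expect_false(identical(d3$g_tested, d3$g_causal))
  expect_lt(abs(cor(d3$g_tested, d3$g_causal)^2 - 0.9), 0.03)
})

test_that("discovery-model p-values are calibrated under the null", {
  null_eff <- effect_sizes(intercept = 1.95, beta_e = 1.05,
                           partners = list(pA = list(af = 0.3, beta_p = 0.03,
                                                     beta_pxe = 0.01)),
                           sigma2 = 0.005)
  cond <- sim_condition(af = 0.3, discovery_model = "G+E")
  pvals <- vapply(1:100, function(s) {
    ds <- generate_condition_dataset(null_eff, 400, cond, seed = 1000 + s)
    fit_discovery_model(ds)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("the sample-size ladder saturates and censors correctly", {
  lad <- sample_size_ladder(100, 1e4)
  expect_true(all(diff(lad) > 0))
  expect_identical(lad[1], 100)

  big <- effect_sizes(intercept = 1.95, beta_g = 2, beta_e = 1.05,
                      partners = list(pA = list(af = 0.3, beta_p = 0.02)),
                      sigma2 = 0.005)
  cond <- sim_condition(af = 0.3, discovery_model = "G+E")
  pc_big <- min_sample_size(big, cond, ladder = c(100, 200, 500),
                            n_reps = 5, seed = 11)
  expect_true(all(pc_big$min_n == 100))
  expect_false(any(pc_big$censored))

  null_eff <- effect_sizes(intercept = 1.95, beta_e = 1.05,
                           partners = list(pA = list(af = 0.3, beta_p = 0)),
                           sigma2 = 0.005)
  pc_null <- min_sample_size(null_eff, cond, ladder = c(100, 200, 500),
                             n_reps = 5, seed = 12)
  expect_true(all(pc_null$censored))
  expect_true(pc_null$median_censored)

  expect_error(min_sample_size(big, cond, ladder = numeric(0)),
               class = "interax_config_error")
})

test_that("GxE detection degrades with environmental measurement noise", {
  eff <- effect_sizes(intercept = 1.95, beta_g = 0.02, beta_e = 1.05,
                      beta_gxe = 0.1,
                      partners = list(pA = list(af = 0.3, beta_p = 0.02)),
                      sigma2 = 0.005)
  lad <- sample_size_ladder(500, 5e4)
  pc0 <- nonadditive_detection_power(eff, sim_condition(af = 0.3),
                                     mode = "GxE", ladder = lad,
                                     n_reps = 7, seed = 13)
  pc5 <- nonadditive_detection_power(eff,
                                     sim_condition(af = 0.3, noise_fraction = 0.5),
                                     mode = "GxE", ladder = lad,
                                     n_reps = 7, seed = 13)
  expect_gte(pc5$median_min_n, pc0$median_min_n)

  # no dominance effect: dominance detection is censored
  pcD <- nonadditive_detection_power(eff, sim_condition(af = 0.3), mode = "D",
                                     ladder = c(200, 1000), n_reps = 4,
                                     seed = 14)
  expect_true(all(pcD$censored))
})

test_that("discoverability applies the strict bounds", {
  expect_false(discoverability(data.frame(af = c(0.001, 0.005),
                                          median_min_n = c(Inf, Inf))))
  expect_true(discoverability(data.frame(af = 0.005, median_min_n = 1e4)))
  # boundary: exactly 500,000 is not discoverable; af at 1% is out of range
  expect_false(discoverability(data.frame(af = 0.005, median_min_n = 5e5)))
  expect_false(discoverability(data.frame(af = 0.01, median_min_n = 1e3)))
})

test_that("dominance ratio classifies architectures", {
  # pure additivity: ratio 0
  eA <- effect_sizes(beta_g = 0.1, sigma2 = 1)
  expect_equal(dominance_ratio(eA, mean_env = 3)$ratio, 0)
  # complete dominance: beta_d = beta_g, no environment terms
  eD <- effect_sizes(beta_g = 0.1, beta_d = 0.1, sigma2 = 1)
  rD <- dominance_ratio(eD, mean_env = 3)
  expect_equal(rD$ratio, 1)
  expect_identical(rD$class, "dominant")
  expect_equal(rD$ratio_swapped, -1)
  # cancelling additive terms: undefined, flagged
  eU <- effect_sizes(beta_g = 0.1, beta_gxe = -0.05, beta_d = 0.2, sigma2 = 1)
  rU <- dominance_ratio(eU, mean_env = 2)
  expect_identical(rU$class, "undefined")
  expect_true(is.na(rU$ratio))
  # recessive: negative ratio
  eR <- effect_sizes(beta_g = 0.1, beta_d = -0.08, sigma2 = 1)
  expect_identical(dominance_ratio(eR, mean_env = 3)$class, "recessive")
})

test_that("bundled effect-size blocks load and are internally consistent", {
  blocks <- bundled_effect_sizes()
  expect_true(all(c("qtl_temperature_sensitive", "qtl_additive",
                    "qtl_overdominant") %in% names(blocks)))
  for (b in blocks) {
    expect_s3_class(b, "effect_sizes")
    expect_gt(b$sigma2, 0)
    expect_true(all(c("p15", "p21") %in% names(b$partners)))
  }
  # the overdominant block really is dominance-heavy at the study's
  # mean environment
  e_bar <- mean(log(c(21, 28, 35) - 6))
  r <- dominance_ratio(blocks$qtl_overdominant, e_bar)
  expect_gt(r$degree, dominance_ratio(blocks$qtl_additive, e_bar)$degree)
})
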
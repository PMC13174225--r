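# Interaction battery: model selection, mode tests, variance decomposition,
# epistasis with its covariate guard, reciprocal-cross and per-cross checks,
# and the multiple-testing bookkeeping.

make_locus_setup <- function(seed = 71, n_f2 = 80) {
  tf <- tiny_f2(n_f2 = n_f2, n_chrom = 2, sites = 15, seed = seed)
  f2 <- tf$f2
  loc <- pick_segregating(f2, chrom = 1)
  g <- f2$dosages[, loc]
  names(g) <- rownames(f2$dosages)
  mc <- build_multienv_covariances(compute_grm(f2, exclude_chromosomes = 1), 3)
  list(f2 = f2, g = g, mc = mc, loc = loc)
}

test_that("multiple-testing families match the study bookkeeping", {
  expect_identical(interaction_test_family(16), 48L)
  expect_identical(epistasis_test_family(16), 240L)
  expect_identical(as.integer(choose(16, 2)), 120L)
  # the two families are computed independently of each other
  expect_identical(interaction_test_family(10), 30L)
  expect_identical(epistasis_test_family(10), 90L)
})

test_that("double-homozygote expectation follows the product rule", {
  e <- double_homozygote_expectation(n = 220)
  expect_identical(e$fraction, 0.0625)
  expect_identical(e$expected_count, 13.75)
  expect_identical(double_homozygote_expectation(0.3, 0.2)$fraction, 0.06)
})

test_that("model selection follows the simulated architecture", {
  ms <- make_locus_setup()
  # additive-only data: best model is G+E in the majority of replicates
  best_add <- vapply(1:7, function(s) {
    eff <- effect_sizes(intercept = 1.95, beta_g = 0.08, beta_e = 1.05,
                        sigma2 = 0.004)
    ph <- simulate_phenotype(ms$g, env3(), eff, cross = ms$f2$cross,
                             seed = 100 + s)
    ph$value <- exp(ph$value)
    fit_locus_models(ms$g, ph, ms$mc)$best
  }, character(1))
  expect_gt(mean(best_add == "G+E"), 0.5)

  # strong GxE + dominance: the full model wins and beats the additive fit
  eff2 <- effect_sizes(intercept = 1.95, beta_g = 0.02, beta_e = 1.05,
                       beta_d = 0.1, beta_gxe = 0.15, beta_dxe = 0.08,
                       sigma2 = 0.004)
  ph2 <- simulate_phenotype(ms$g, env3(), eff2, cross = ms$f2$cross, seed = 301)
  ph2$value <- exp(ph2$value)
  fit2 <- fit_locus_models(ms$g, ph2, ms$mc)
  expect_lt(fit2$models[["G+E+D+GxE+DxE"]]$p, fit2$models[["G+E"]]$p)
  expect_true(fit2$best %in% c("G+E+D+GxE", "G+E+D+GxE+DxE"))

  # monomorphic locus is rejected outright
  expect_error(fit_locus_models(rep(1L, length(ms$g)), ph2, ms$mc),
               class = "interax_config_error")
})

test_that("interaction-mode tests isolate the simulated mode", {
  ms <- make_locus_setup(seed = 73)
  # DxE-only signal: DxE mode more significant than GxE at matched power
  eff <- effect_sizes(intercept = 1.95, beta_g = 0.05, beta_e = 1.05,
                      beta_d = 0.02, beta_dxe = 0.25, sigma2 = 0.004)
  ph <- simulate_phenotype(ms$g, env3(), eff, cross = ms$f2$cross, seed = 401)
  ph$value <- exp(ph$value)
  fit <- fit_locus_models(ms$g, ph, ms$mc)
  tm <- test_interaction_modes(fit, n_loci = 16)
  expect_setequal(tm$mode, c("D", "GxE", "DxE"))
  expect_identical(unique(tm$family), 48L)
  expect_lt(tm$p[tm$mode == "DxE"], tm$p[tm$mode == "GxE"])
  expect_true(tm$significant[tm$mode == "DxE"])
})

test_that("variance decomposition is exact and tracks the architecture", {
  ms <- make_locus_setup(seed = 75)
  effA <- effect_sizes(intercept = 1.95, beta_g = 0.12, beta_e = 1.05,
                       sigma2 = 0.004)
  phA <- simulate_phenotype(ms$g, env3(), effA, cross = ms$f2$cross, seed = 501)
  phA$value <- exp(phA$value)
  fitA <- fit_locus_models(ms$g, phA, ms$mc)
  veA <- variance_explained(fitA)
  # ANOVA identity: absolute fractions sum to exactly 1
  expect_equal(sum(veA$abs_fraction), 1, tolerance = 1e-12)
  # relative fractions over the genetic terms sum to 1
  expect_equal(sum(veA$rel_fraction, na.rm = TRUE), 1, tolerance = 1e-12)
  # purely additive locus: nearly all genetic variance is additive
  expect_gt(veA$rel_fraction[veA$term == "G"], 0.85)

  # GxE-dominated locus with no effect at the reference temperature
  # (the genetic effect exists only at the warmer conditions): the
  # additive share collapses
  effB <- effect_sizes(intercept = 1.95, beta_g = -0.25 * log(21 - 6),
                       beta_e = 1.05, beta_gxe = 0.25, sigma2 = 0.004)
  phB <- simulate_phenotype(ms$g, env3(), effB, cross = ms$f2$cross, seed = 502)
  phB$value <- exp(phB$value)
  fitB <- fit_locus_models(ms$g, phB, ms$mc)
  veB <- variance_explained(fitB)
  expect_lt(veB$rel_fraction[veB$term == "G"],
            veA$rel_fraction[veA$term == "G"])
})

test_that("pairwise epistasis keeps its covariate guard and class rule", {
  ms <- make_locus_setup(seed = 77, n_f2 = 120)
  locB <- pick_segregating(ms$f2, chrom = 2)
  gB <- ms$f2$dosages[, locB]
  # generating model with a sign-flipping environment-dependent interaction
  eff <- effect_sizes(intercept = 1.95, beta_g = 0.03, beta_e = 1.05,
                      partners = list(pB = list(af = 0.5, beta_p = 0.02,
                                                beta_pxe = 0, beta_gxg = -0.3,
                                                beta_gxgxe = 0.12)),
                      sigma2 = 0.004)
  ph <- simulate_phenotype(ms$g, env3(), eff,
                           partner_genotypes = list(pB = gB),
                           cross = ms$f2$cross, seed = 601)
  ph$value <- exp(ph$value)
  mc2 <- build_multienv_covariances(compute_grm(ms$f2), 3)
  ep <- test_pairwise_epistasis(ms$g, gB, ph, mc2, n_loci = 16,
                                min_class_count = 1)
  expect_identical(unique(ep$family), 240L)
  # covariate guard: both marginals and both marginal GxE blocks present
  guard <- attr(ep, "null_design_columns")
  expect_true(all(c("gA", "gB") %in% guard))
  expect_true(any(grepl("gAxE", guard)) && any(grepl("gBxE", guard)))
  expect_true(ep$significant[ep$mode == "GxGxE"])

  # class rule: sparse minority class skips the pair with a reason
  ep_skip <- test_pairwise_epistasis(ms$g, gB, ph, mc2, n_loci = 16,
                                     min_class_count = 1e5)
  expect_true(all(ep_skip$skipped))
  expect_match(ep_skip$reason[1], "genotype class")
})

test_that("reciprocal-cross tests separate marginal from interaction effects", {
  fp <- simulate_founders(2, 2, 12, seed = 81)
  cd <- cross_design(c("strain_1", "strain_2"), c("strain_2", "strain_1"),
                     n_f2 = c(150, 150), reciprocal = c(FALSE, TRUE))
  f2 <- simulate_f2(fp, cd, seed = 82)
  loc <- pick_segregating(f2)
  g <- f2$dosages[, loc]; names(g) <- rownames(f2$dosages)
  recip <- stats::setNames(f2$cross, rownames(f2$dosages))
  eff <- effect_sizes(intercept = 1.95, beta_g = 0.05, beta_e = 1.05,
                      sigma2 = 0.004)
  ph <- simulate_phenotype(g, env3(), eff, cross = f2$cross, seed = 83)
  # plates randomized across crosses (a plate blocked on cross would absorb
  # the group shift)
  ph$plate <- with_seed_local(84, {
    rep(sample(rep(c("p1", "p2"), length.out = length(g))), each = 3)
  })
  # constant multiplicative shift for one reciprocal group
  shift <- ifelse(recip[ph$sample] == f2$cross[1], 0.05, 0)
  ph$value <- exp(ph$value + shift)

  rc <- test_reciprocal_cross(ph, g, recip)
  marg <- rc[rc$test == "marginal", ]
  intr <- rc[rc$test == "interaction", ]
  expect_true(all(marg$p_bonf < 0.05))
  expect_true(all(intr$p_bonf > 0.05))

  # inclusion rule: a 9-sample minority class excludes the stratum
  rc_skip <- test_reciprocal_cross(ph, g, recip, min_class_count = 1e4)
  expect_true(all(rc_skip$skipped))
})

test_that("per-cross checks flag only crosses where the locus segregates", {
  # crafted lead SNP segregating in cross A only
  cross <- rep(c("A", "B"), each = 150)
  g1 <- with_seed_local(86, c(rbinom(150, 2, 0.5), rep(0L, 150)))
  vals <- with_seed_local(87, 0.8 * g1 + rnorm(300))
  res <- per_cross_qtl_check(vals, cbind(lead = g1), cross)
  expect_true(is.na(res$p["B", "lead"]))
  expect_true(res$flag["A", "lead"])

  # strong locus segregating everywhere is flagged everywhere
  g2 <- with_seed_local(88, rbinom(300, 2, 0.5))
  vals2 <- with_seed_local(89, 0.8 * g2 + rnorm(300))
  res2 <- per_cross_qtl_check(vals2, cbind(lead = g2), cross)
  expect_true(all(res2$flag[, "lead"]))

  # global-null calibration: false-flag proportion controlled by the FDR
  with_seed_local(90, {
    leads <- matrix(rbinom(300 * 8, 2, 0.4), 300, 8,
                    dimnames = list(NULL, paste0("l", 1:8)))
    flags <- per_cross_qtl_check(rnorm(300), leads, cross)$flag
    expect_lt(mean(flags, na.rm = TRUE), 0.20)
  })
})
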
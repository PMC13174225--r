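#!/usr/bin/env Rscript
# Regenerates inst/extdata/synthetic_effect_sizes.json.
#
# Synthetic stand-in for the unpublished F2 effect-size estimates: an F2
# cross is simulated under fixed generating coefficients chosen to be
# realistic for embryonic heart rate on the log-bpm scale (rates roughly
# double between 21 and 35 degC => beta_E ~ 1.05 on log(t - 6); per-allele
# QTL effects of a few percent; residual CV ~ 7%), phenotypes are generated
# at 21/28/35 degC, and effect sizes are re-estimated with the whitened
# joint fit. The re-estimated blocks are what ships.
#
# Run from the package root: Rscript tools/make_fixtures.R

devtools::load_all(".", quiet = TRUE)

env3 <- structure(data.frame(temperature = c(21, 28, 35),
                             e = log(c(21, 28, 35) - 6)),
                  class = c("environment_sample", "data.frame"))

fp <- simulate_founders(8, 6, 25, seed = 101)
cd <- cross_design(paste0("strain_", c(1, 3, 5, 7)),
                   paste0("strain_", c(2, 4, 6, 8)), n_f2 = 100)
f2 <- simulate_f2(fp, cd, seed = 102)
afs <- colMeans(f2$dosages) / 2
pick <- function(chrom) {
  i <- which(f2$map$chrom == chrom & afs > 0.35 & afs < 0.65)
  unname(i[which.min(abs(afs[i] - 0.5))])
}
focal_site <- pick(1)
partner_sites <- c(p15 = pick(3), p21 = pick(4))
wild_af <- c(p15 = 0.03, p21 = 0.005)   # rare in the wild, common in-cross
partner_geno <- lapply(partner_sites, function(i) f2$dosages[, i])

generating <- list(
  qtl_temperature_sensitive = effect_sizes(
    intercept = 1.95, beta_g = 0.03, beta_e = 1.05, beta_d = 0.015,
    beta_gxe = 0.008, beta_dxe = 0.003,
    partners = list(
      p15 = list(af = 0.5, beta_p = 0.06, beta_pxe = 0.01,
                 beta_gxg = 0.01, beta_gxgxe = 0.004),
      p21 = list(af = 0.5, beta_p = 0.04, beta_pxe = 0.008)
    ),
    sigma2 = 0.005),
  qtl_additive = effect_sizes(
    intercept = 1.95, beta_g = 0.05, beta_e = 1.05,
    partners = list(
      p15 = list(af = 0.5, beta_p = 0.06, beta_pxe = 0.01),
      p21 = list(af = 0.5, beta_p = 0.04, beta_pxe = 0.008)
    ),
    sigma2 = 0.005),
  qtl_overdominant = effect_sizes(
    intercept = 1.95, beta_g = 0.005, beta_e = 1.05, beta_d = 0.04,
    beta_gxe = 0.002, beta_dxe = 0.001,
    partners = list(
      p15 = list(af = 0.5, beta_p = 0.06, beta_pxe = 0.01),
      p21 = list(af = 0.5, beta_p = 0.04, beta_pxe = 0.008)
    ),
    sigma2 = 0.005)
)

g <- f2$dosages[, focal_site]
names(g) <- rownames(f2$dosages)
mc <- build_multienv_covariances(
  compute_grm(f2, exclude_chromosomes = f2$map$chrom[focal_site]), 3)

blocks <- list()
for (nm in names(generating)) {
  ph <- simulate_phenotype(g, env3, generating[[nm]],
                           partner_genotypes = partner_geno,
                           cross = f2$cross, seed = 103 + match(nm, names(generating)))
  ph$value <- exp(ph$value)
  est <- estimate_effect_sizes(g, ph, partner_genotypes = partner_geno,
                               covariance = mc,
                               include_epistasis = nm == "qtl_temperature_sensitive",
                               partner_af = wild_af)
  blocks[[nm]] <- est
}
write_effect_sizes(blocks, "inst/extdata/synthetic_effect_sizes.json")
cat("wrote", length(blocks), "blocks\n")
for (nm in names(blocks)) { cat("--", nm, "\n"); print(blocks[[nm]]) }
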
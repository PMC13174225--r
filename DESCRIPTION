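Package: interax
Title: Gene-by-Environment and Epistatic QTL Analysis for Multi-Parental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component mixed-model machinery for mapping quantitative
    trait loci (QTLs) in multi-parental F2 crosses phenotyped repeatedly across
    environments, with a focus on temperature-dependent heart rate in fish
    embryos. Provides leave-one-chromosome-out genomic relatedness matrices, a
    Kronecker-structured compound-symmetry covariance model for repeated
    measurements across environments, restricted maximum likelihood (REML)
    variance-component estimation, decorrelation ("whitening") so that ordinary
    least squares reproduces generalized least squares, likelihood-ratio scans
    with permutation-based genome-wide thresholds, joint tests for dominance,
    gene-by-environment (GxE), dominance-by-environment (DxE) and pairwise
    epistatic (GxG, GxGxE) effects with variance decomposition, a power
    simulator quantifying how statistical-model misspecification affects
    genome-wide association study (GWAS) discovery power in outbred
    populations, and a summary-statistics-based validation of the simulator.
    A synthetic-data generator produces founder panels, recombinant F2 crosses,
    seasonal temperature draws and phenotypes with the full interaction
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
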
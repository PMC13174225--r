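---
title: "Models and methods: temperature-dependent QTL mapping with interaction effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: temperature-dependent QTL mapping with interaction effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`interax` implements the statistical core of a multi-parental F2
quantitative-trait-locus (QTL) study of a repeatedly measured physiological
trait — embryonic heart rate assayed in the same individuals at 21, 28 and
35 °C. The package covers five connected pieces:

1. a **synthetic-data generator** (founder strains, recombinant F2 crosses,
   seasonal temperatures, phenotypes with dominance, G×E, and epistatic
   structure);
2. a **variance-component mixed-model engine** (genomic relatedness
   matrices, a Kronecker-structured multi-environment covariance model,
   REML, whitening, likelihood-ratio tests, heritability);
3. a **genome scan** with permutation-based genome-wide thresholds;
4. a **per-locus interaction battery** (dominance, G×E, D×E, pairwise G×G
   and G×G×E, variance decomposition, reciprocal-cross and per-cross
   checks);
5. a **power simulator** quantifying how model misspecification,
   environmental measurement noise and tag-SNP genotyping affect GWAS
   discovery in outbred populations, validated by a summary-statistics
   round trip.

This vignette explains the models, the defaults and the numerical choices.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The mixed model

For each locus, the trait measured on $n$ individuals in $k$ environments
(records ordered sample-major, environment fastest) is modelled as

$$ y = X\beta + u_{id} + u_{shared} + u_{env} + \varepsilon $$

with three independent random effects whose covariances encode the
repeated-measures and genetic structure:

* $\mathrm{Cov}(u_{id}) = \sigma^2_{id}\, (I_n \otimes J_k)$ — a block of
  ones for the $k$ records of the same individual, absorbing
  individual-level correlation across environments;
* $\mathrm{Cov}(u_{shared}) = \sigma^2_{shared}\, (K \otimes J_k)$ — the
  genomic relatedness matrix (GRM) $K$ expanded across all environment
  pairs: genetic covariance that transfers between environments;
* $\mathrm{Cov}(u_{env}) = \sigma^2_{env}\, (K \otimes I_k)$ — genetic
  covariance confined within an environment.

Together the last two define a compound-symmetry environment model: the
genetic variance and the between-environment genetic covariance are each
constant but may differ, so a genome-wide genotype-by-environment component
is estimable without per-locus terms. `build_multienv_covariances()`
constructs all three matrices and is tested against an elementwise
brute-force oracle.

**GRM.** `compute_grm()` uses the column-standardized (VanRaden-type) form
$K = WW^\top/m$ over polymorphic variants, with leave-one-chromosome-out
(LOCO) exclusion of the tested chromosome — and of both chromosomes for
pairwise epistasis tests — so a tested variant never contributes to its own
relatedness correction. No formula was dictated by the data-generating
study; this is the common LOCO-GWAS choice.

**REML.** `estimate_variance_components()` maximizes the restricted
likelihood over log-parameterized variances (non-negativity holds by
construction) with three starting points, Nelder–Mead refined by BFGS, and
a relative tolerance of `1e-8` on $-2\ell_R$. The three Kronecker matrices
commute, so they share the eigenbasis $U_K \otimes U_J$; the model is
rotated into that basis once (computed analytically when the covariance
object is built) and every likelihood evaluation is then $O(n k)$. A dense
Cholesky fallback covers arbitrary covariance lists. Aliased components
(e.g. a covariance proportional to the identity next to the residual) are
reported with a warning because their split is not identifiable. Variance
components are estimated **once per locus**, under a fixed-effect structure
containing the covariates and the additive locus encoding only, and reused
for every nested comparison at that locus; they are not re-estimated per
alternative model.

**Whitening.** `whiten()` forms $V = \sum_i \sigma^2_i K_i +
\sigma^2_\varepsilon I$, its Cholesky factor $V = LL^\top$, and returns
$L^{-1}y$ and $L^{-1}X$, after which ordinary least squares equals
generalized least squares (verified against the closed form on random
instances to relative error $<10^{-8}$). If $V$ is numerically singular a
`1e-8` diagonal jitter is applied once, with a message.

**Likelihood-ratio tests.** On whitened data the Gaussian profile
likelihood gives $\chi^2 = n \log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ with
degrees of freedom equal to the rank added by the alternative design.
Identical designs return $p = 1$; non-nested designs are an error. Null
calibration (type-I error within $[0.03, 0.07]$ at $\alpha = 0.05$) is
exercised in the acceptance suite for the dominance, G×E and G×G tests.

# Genome scan and thresholds

`scan_genome()` inverse-normal-transforms are left to the caller
(`inverse_normal_transform()` uses ranks mapped through
$\Phi^{-1}((r - 0.5)/n)$, average ranks on ties). The discovery test is a
df-2 LRT of covariates-only versus covariates + additive dosage + dominance
indicator (heterozygote = 1), the additive-only df-1 scan being available
by flag. Monomorphic or collinear variants are reported with $p = 1$ and a
flag rather than dropped, so every tested variant yields a record.

`permutation_threshold()` permutes the whitened residuals of the
covariate-only model — preserving the covariate structure — re-runs the
scan, and records each permutation's genome-wide minimum p-value. The
default threshold is the **minimum of these minima**, the literal rule of
the source study; because that rule is stricter than common practice, the
conventional low-quantile alternative (e.g. the 5% quantile of the minima)
is exposed via `quantile_rule`. Locus definition
(`define_loci()`) is automated clumping with a 1 Mb merge window — the
original study drew locus boundaries by manual inspection, so the clumping
is a reproducible stand-in, and results remain traceable to the raw scan
table. Lead SNPs skip variants missing a homozygous class entirely.

Outlier handling uses Tukey fences with $k = 4$ (`tukey_filter()`), far
beyond the conventional 1.5 and 3, so only exceptionally strong outliers
are removed. Temperature-response phenotypes are within-individual
differences between two environments (`make_difference_phenotype()`), with
incompletely measured individuals dropped and counted.

# Interaction battery

`fit_locus_models()` fits the five nested forms `G+E`, `G+E+G×E`, `G+E+D`,
`G+E+D+G×E`, `G+E+D+G×E+D×E` on whitened multi-environment data (log-bpm
phenotype; environment categorical; plate and cross as fixed covariates; an
optional lead-SNP block with its environment interactions to condition on a
large-effect locus). The best model is the smallest LRT p-value against the
covariate-only fit. Mode tests compare the minimally differing nested pair
(e.g. D×E: full vs `G+E+D+G×E`). Bonferroni families follow the study's
bookkeeping — loci × 3 modes for {D, G×E, D×E} and
$\binom{\text{loci}}{2} \times 2$ for {G×G, G×G×E}, corrected
independently of each other.

Variance decomposition is sequential ANOVA on the whitened full fit in the
fixed order covariates → G → D → G×E → D×E; each term's sum of squares over
the total gives the absolute fraction (the decomposition is exact by the
ANOVA identity), and over the summed genetic sums of squares gives the
relative fraction. Because the environment enters untransformed (treatment
coding with the coldest condition as reference), the `G` term measures the
additive effect *at the reference temperature* — a locus acting only at
warm temperatures therefore shows a small additive share, which is the
intended reading.

Pairwise epistasis tests always include both loci's marginal effects and
marginal environment interactions in the null (the "covariate guard",
verified structurally in the tests), use a GRM excluding both chromosomes,
and skip pairs whose smallest two-locus genotype class falls below
`min_class_count` (default 10, mirroring the reciprocal-cross inclusion
rule; the study states the expectation calculus — 6.25% of samples per
minority class for two unlinked 50%-frequency loci, about 14 of 220 — but
no hard cutoff). Reciprocal-cross tests are stratified by temperature on
inverse-normal data and separate the genotype × parent-of-origin
interaction from the marginal group effect; per-cross detectability uses
Benjamini–Hochberg at 5% FDR across the full cross × locus matrix
(`p.adjust`).

# Power simulator

`estimate_effect_sizes()` fits the continuous-environment generating model
on (optionally whitened) F2 data: `log(bpm) ~ g + e + d + g:e + d:e` with
`e = log(t − 6)` — the transform that linearizes the temperature /
log-heart-rate relationship over 21–35 °C — plus each epistatic partner's
marginal and partner×e terms (structural covariates; omitting them is an
error) and, optionally, `g:gp` and `g:gp:e`. With only three distinct
temperatures the split between a main effect and its environment
interaction is poorly identified (the design is nearly collinear), while
the effective effects at the mean environment, e.g.
$\beta_G + \beta_{G\times E}\bar e$, are well identified; tests therefore
check those combinations, and the dominance ratio
$d/g = (\beta_D + \beta_{D\times E}\bar e)/(\beta_G + \beta_{G\times E}\bar e)$
(`dominance_ratio()`) is built from them. A vanishing denominator is
flagged as candidate overdominance; the allele-swapped variant negates the
ratio.

`generate_condition_dataset()` draws Binomial(2, af) genotypes
(Hardy–Weinberg), seasonal temperatures (annual sinusoid, mean 22 °C,
amplitude 10 °C, hourly jitter sd 1.5 °C, truncated to 21–35 °C — a
synthetic stand-in for undeposited outdoor pond measurements), and
phenotypes from the estimated effects; partner loci are always simulated at
their fixed wild allele frequencies and always included as covariates in
discovery. Environmental measurement noise is added **on the Celsius scale
before the log transform** (draws that would fall at or below the
transform's 6 °C pole are redrawn), with variance $f/(1-f)\,\mathrm{Var}(t)$
so that noise makes up fraction $f$ of the *total observed* variance; the
alternative reading $f\,\mathrm{Var}(t)$ is available as
`noise_convention = "of_signal"` (the two differ at most twofold at
$f = 0.5$). Under tagging, a haplotype-level copy-with-flip construction
(`make_tag_snp()`; copy probability $\sqrt{r^2}$, redraw at the causal
allele frequency otherwise) yields a tag with the target genotype $r^2$ and
the causal variant's marginal frequency, and **every** focal term of the
discovery design — dominance and interactions included — is recomputed from
the tag.

Discovery models (`fit_discovery_model()`) are plain OLS LRTs (no random
effects or covariates beyond the partner block, matching the outbred
setting): `G` (environment-blind; null = intercept + partners), `G+E`,
`G+E+G×E`, and `full`. `min_sample_size()` climbs a strictly increasing
sample-size ladder — default $\{1,2,5\}\times10^k$ from $10^2$ to $10^7$;
the source study names no ladder — accumulating samples so successive rungs
share their prefix, and records the first rung whose p-value clears
$5\times10^{-8}$; first crossing defines the minimum, accepting stochastic
non-monotonicity. Replicates never reaching significance are right-censored
at the ladder top and propagate as `Inf` into medians.
`nonadditive_detection_power()` applies the same machinery to the dominance
or G×E block against a null of intercept + additive effect + environment +
partners. `discoverability()` applies the strict bounds: median minimum
$n < 500{,}000$ at some allele frequency $< 1\%$.

Since the original study's per-locus effect sizes are not published, the
package ships three **synthetic** effect-size blocks
(`bundled_effect_sizes()`; `inst/extdata/synthetic_effect_sizes.json`),
produced by `tools/make_fixtures.R`: fixed generating coefficients chosen
once on domain grounds (heart rate roughly doubling from 21 to 35 °C gives
$\beta_E \approx 1.05$ on the `log(t − 6)` scale; per-allele QTL effects of
a few percent of the log-bpm scale; residual variance 0.005, i.e. ~7%
coefficient of variation) are pushed through a simulated 400-sample F2
cross and re-estimated with the whitened joint fit — the shipped numbers
are the estimates. The partner loci carry wild allele frequencies of 0.03
and 0.005, rare in the wild though common in-cross, as the power analysis
requires.

# Summary-statistics validation

From a GWAS summary record (maf $p$, $\beta$, SE, $n$) the residual
variance is reconstructed under Hardy–Weinberg as
$\sigma^2_\varepsilon = \mathrm{SE}^2 \cdot n \cdot \sigma^2_x$ with
$\sigma^2_x = 2p(1-p)$ (exact only under HWE — stated, not silently
assumed); `simulate_and_refit()` regenerates marker and phenotype and
returns the OLS Wald p-value. `synthesize_sumstats_records()` builds an
internally consistent synthetic grid (reported p-values use the same $t$
reference distribution the refit uses, so the round trip is honest at any
sample size); the acceptance suite requires rank correlation $> 0.99$ and a
log-p regression slope within $[0.9, 1.1]$ over 500 records. No external
download is performed; arbitrary summary-stats exports are adapted through
a column map (`read_sumstats()`).

# Heritability

`estimate_heritability()` offers the two estimators the study designs call
for: a one-way random-effects ANOVA decomposition for inbred-panel data
(method of moments with the unbalanced-design correction on the group
size), and $\sigma^2_g/(\sigma^2_g + \sigma^2_\varepsilon)$ from a
single-GRM REML fit for F2 data. Confidence intervals are nonparametric
bootstrap percentiles — resampling strains (ANOVA mode) or individuals
(mixed mode) — because the interval method behind the study's reported CIs
is not stated; this is the package's own choice and is flagged as such.

# Synthetic data: what it does and does not emulate

The generator reproduces the features the statistics rely on: fully
homozygous founders; F1 heterozygosity at founder-contrasted sites; F2
Mendelian segregation with Haldane crossovers (Poisson count per
chromosome, uniform positions — the cross mechanics are a modelling choice,
only the genotype law matters downstream); per-cross relatedness exceeding
between-cross relatedness; bounded seasonal temperatures; and the full
interaction structure of the phenotype model. It does **not** emulate
sequence-level error (reads, imputation), mutation or drift, sex
chromosomes, or F1 family nesting within crosses (mating-group structure is
off by default and left configurable). Passing tests therefore demonstrate
correctness of the statistical machinery under the stated generating law,
not robustness to imputation artefacts or pedigree misspecification in
real data.

# Problem sizes and numerical choices

The test and acceptance workloads use deliberately desk-scale instances
chosen as the smallest sizes at which each property is
identifiable: 10 crosses × 30 F2 for the three-component REML recovery
(n = 300 individuals, 900 records), 1000 replicates of a 50-individual
cross for null calibration, $10^5$ haplotypes for the tag-SNP contract,
$10^6$ F2 individuals for the minority-class frequency, and ladders capped
at $10^4$–$10^5$ for the power properties. Degenerate inputs are handled
explicitly: monomorphic loci are errors in per-locus fits but flagged
records in scans; IQR = 0 keeps all equal values in the outlier filter;
empty two-locus genotype classes skip the epistasis test with a recorded
reason; censored power medians stay censored rather than being imputed.
Ties in the inverse-normal transform receive average ranks. All randomness
flows from explicit integer seeds fanned out per stage (`child_seeds()`),
and identical seeds reproduce results bit for bit.

# Known limitations

* The REML engine is dense beyond the Kronecker fast path; no sparse or
  low-rank GRM approximations are provided, so it targets crosses of
  hundreds to a few thousand individuals, not biobank cohorts.
* Standard errors for variance components are not computed beyond the
  bootstrap.
* The $\chi^2 = n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ statistic is
  asymptotic; at very small record counts its finite-sample inflation is
  visible, which is why calibration is checked at the sizes the package
  targets.
* The power simulator inherits the source framework's simplifications: a
  single environmental exposure, no population structure, no
  genotype–environment correlation, no interactions between linked loci.
  Its outputs are best-case discovery estimates, not architecture models.
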
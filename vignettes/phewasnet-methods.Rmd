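---
title: "Methods: deep-phenotype PheWAS and its post-PheWAS analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-phenotype PheWAS and its post-PheWAS analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phewasnet)
```

# The problem and the model

A phenome-wide association study (PheWAS) is the transpose of a GWAS: every
variant in an additive dosage coding is tested against every phenotype of a
deeply phenotyped cohort — continuous clinical measurements by linear
regression, case/control outcomes by logistic regression — adjusting each
fit for age, sex and the top genotype principal components:

    outcome ~ dosage + age + sex + PC1 + PC2 + PC3

The per-test output is the dosage effect (beta or log-odds), its standard
error and a Wald p-value.  Linear fits use the exact t reference with the
model's residual degrees of freedom; logistic fits use the normal reference
on the maximum-likelihood estimate.  Both are computed per (variant,
phenotype) pair on complete cases.  For fully observed variants the linear
scan runs through the Frisch–Waugh–Lovell fast path (residualize the
outcome and all dosage columns on the covariates once, then fit each
variant by simple regression on residuals), which is algebraically
identical to the full multiple regression; the test suite checks it
against `lm()` to 1e-10.  The non-convergence policy for logistic fits is:
a fit whose iterations do not converge or whose fitted probabilities pin
at 0/1 is flagged `"separation"` and its p-value set missing — never
fabricated.  Binary phenotypes left without cases (or controls) after
complete-case filtering are skipped with a message and counted.

## Significance calibration

The family-wise threshold uses an LD-aware Bonferroni correction: the
denominator is the number of *independent* SNPs (greedy LD pruning at
r² ≤ 0.3, scanning in position order with a 500-variant lookback window)
times the number of phenotypes:

    threshold = alpha / (n_independent x n_phenotypes)

As a consistency check, 0.05 / (747,874 × 136) = 4.916e-10, matching the
threshold this kind of scan reports at biobank scale.  The count pairing is
an inference (the independent-SNP count behind the printed threshold is
never published); it is asserted as arithmetic, not as a reproduction.
Downstream systematic analyses use the conventional exploratory filter
p < 1e-4.  False-discovery control, where used, is Benjamini–Hochberg
(`fdr_adjust()`), tested against hand-computed step-up values.

# The synthetic cohort generator

Every downstream stage is validated against a generator with known
architecture (`sim_config()`, `simulate_cohort()`).  What it emulates:

* **Genotypes.**  Two haplotypes per individual are drawn from a latent
  first-order autoregressive Gaussian chain per LD block and thresholded at
  the allele-frequency quantile, which yields Hardy–Weinberg genotypes
  exactly.  Thresholding attenuates correlation, so the latent
  autocorrelation of each adjacent pair is *calibrated* (vectorized
  bisection on the bivariate-normal orthant probability, evaluated with
  40-node Gauss–Legendre quadrature) so the realized adjacent *genotype*
  correlation equals the requested `rho`.  Two binary variables with very
  different frequencies cannot reach arbitrary correlation (the Fréchet
  bound); for such pairs the generator delivers the attainable maximum.
  `rho` may be a vector recycled across blocks: a genome with heterogeneous
  LD strength, which also produces the spread of LD scores that LD-score
  regression needs for a stable slope.  Blocks are mutually independent;
  within a block correlation decays approximately as `rho^distance`.
* **Continuous traits.**  `y = sum(beta_i * standardized dosage_i) +
  sum(gamma_p * parent_p) + beta_age*(age-mean) + beta_sex*sex + e`, with
  the Gaussian noise scaled so the *direct genetic* variance fraction
  (genetic over genetic-plus-noise) equals the `h2` target.  Covariate and
  parent-phenotype contributions sit on top of that definition; with the
  default small covariate effects the distinction is negligible at the
  simulated effect sizes.
* **Binary traits.**  The same liability thresholded at its empirical
  `1 - prevalence` quantile (probit/liability model), so the realized case
  fraction is exact by construction and logistic scans can detect the
  liability effects.
* **Pleiotropy and causal pairs.**  Causal-variant sets may overlap across
  phenotypes (cross-phenotype ground truth) and phenotypes may have causal
  parents (`gamma` coefficients, acyclic by validation); children act on
  the parent's *observed* value, which for binary parents is the 0/1 state.
* **Covariates.**  Age is discrete-uniform on 35–65 and sex Bernoulli(0.585),
  matching a middle-aged health-check-up cohort with a modest male excess;
  defaults `beta_age = 0.02` per year and `beta_sex = 0.2` exercise the
  adjustment without dominating the trait.
* **Population structure.**  None by default; the PCA test plants a
  two-subpopulation allele-frequency shift directly to verify PC1 recovers
  the labels.

What it does **not** emulate: imputation uncertainty, genotyping error,
realistic site-frequency spectra, long-range LD, assortative mating, or
ascertainment — so a green test establishes correctness of the estimators
on their own model assumptions, not robustness to real-data pathologies.

# Annotation

Variants map to every gene whose body extended by 5,000 bp on both sides
contains their position (strand-symmetric).  Because the consequence
predictor itself is out of scope, its impact taxonomy is collapsed to a
two-level surrogate — `moderate-high` iff the position falls in a coding
subinterval, else `modifier-low` — and `impact_override` accepts externally
computed labels when real consequence annotations exist.  Where a variant
sits within the flank of several genes the default keeps *all* of them;
`mode = "nearest"` keeps one, ties broken by distance then lexicographic
symbol (determinism).

# Networks

A cross-phenotype association is a variant with two or more phenotypes
below the exploratory threshold.  "Locus" is operationalized as a single
variant id; callers wanting clump-collapsed loci can pass clumped ids.
The bipartite phenotype network joins phenotypes sharing at least one such
locus (edges carry deduplicated shared-locus/gene lists, weight = shared
locus count); the gene network joins genes sharing at least one associated
phenotype, each node carrying its phenotype degree and gene degree.
Handshake-lemma and input-order-invariance properties are asserted over
100 random fixtures.  Venn-style focus partitions refuse more than six
focus phenotypes (2^k blowup).

# Mendelian randomization

The split-sample hybrid: instruments are discovered on the full-sample
scan (exposure p < 1e-4), screened against direct outcome association on
the full-sample scan (outcome p < 0.01 removes the IV — read here as a
marginal screen; the alternative split-B reading is not used), then
LD-clumped at r² = 0.001 within 10,000 kb ranked by exposure p.  Effect
estimates come from disjoint random halves: exposure betas from split A,
outcome betas from split B.  Estimators:

* **IVW** (primary): fixed-effect inverse-variance weighting of per-IV Wald
  ratios, identical to zero-intercept WLS of outcome on exposure effects
  with weights 1/se_out² (checked to 1e-10 against an independent WLS
  oracle); with one IV it is exactly the Wald ratio.
* **MR-Egger**: weighted free-intercept regression after orienting every
  exposure effect positive; the intercept measures directional pleiotropy.
  Fewer than 3 IVs returns "not estimable", not an error.
* **Weighted median**: inverse-variance weighted median of Wald ratios,
  standard error by a seeded 1,000-resample bootstrap over IVs.

The causal map tests both orderings of every phenotype-network edge,
adjusts all IVW p-values by a single global Benjamini–Hochberg family
(chosen over per-exposure families, consistent with the package's other
FDR use), and calls forward / reverse / bidirectional / none at q < 0.05.
Pairs with no surviving instruments are recorded as untestable.  A note on
design tension: under a strong causal chain, the very loci that create the
phenotype-network edge are strongly associated with the outcome and are
therefore removed by the outcome screen; direction recovery relies on the
realistic presence of moderate-effect instruments alongside the
edge-forming large effects, and the test worlds are built that way.

# Heritability

LD scores are computed in-sample: `l_j = 1 + sum of r^2` over neighbors
within a kilobase window (raw r², so under independence the mean carries a
small (m_window − 1)/n inflation that vanishes with sample size; a reader
for external reference tables is provided).  The simplified single-
component LD-score regression fits `chi2_j ~ 1 + (N h2 / M) l_j` by
weighted least squares with heteroskedasticity weights
`1/(1 + N h2 l_j / M)^2` iterated twice from an unweighted start; `h2 =
slope * M / N`, the intercept is reported, and the standard error is a
delete-one block jackknife over 20 contiguous variant blocks (reduced with
a warning when variants are fewer).  Estimates outside [0, 1] are reported
and flagged rather than truncated; binary traits are reported on the
observed scale (no liability conversion).  The jackknife se shrinks with N
only while sampling noise dominates (N h2 l/M small); at scale it plateaus
at an M-limited floor — the consistency test runs at N = 400 vs 1,600
where shrinkage holds.  The impact–heritability analysis computes, per
phenotype, the fraction of its sub-threshold loci in the `moderate-high`
group and Pearson-correlates that fraction with h² across phenotypes
(Fisher-z CI); constant fractions yield an explicit degenerate result.
This per-phenotype-fraction reading of "correlation between impact group
and heritability" is one of several possible operationalizations; it is
the package's fixed choice.

# Comparative analyses

Trans-cohort locus overlap partitions each matched phenotype's union of
significant loci into cohort-1-only / shared / cohort-2-only with
percentages summing to 100.  Variant harmonization matches on (chromosome,
position, allele set) with automatic ref/alt flips (sign-flipping the
effect) and drops strand-ambiguous A/T and C/G sites by default.
Meta-analysis is fixed-effect inverse-variance (`w = 1/se²`), so k equal
cohorts shrink the standard error by exactly sqrt(k); novelty flags
compare meta and per-cohort significance at the genome-wide threshold.
The EHR concordance scan tests every phenotype pair — Pearson for
continuous-continuous, chi-squared on the 2×2 table for binary-binary,
point-biserial (Pearson on 0/1) for mixed — and takes pairs surviving
global BH at 0.05 as the EHR-driven set; "multi-test corrected" is read as
BH-FDR, consistent with the rest of the package.  Per-phenotype overlap is
undefined (NA, not 0) for phenotypes with no genotype-driven pairs.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally; BED input is converted on
  read.  Positions are integers; the default synthetic spacing is 1 kb.
* Orthant probabilities: 40-node Gauss–Legendre on [t1, 8.5], 40 bisection
  iterations; adequate to ~1e-6 in the calibrated correlation.
* PCA signs are fixed by forcing the largest-magnitude loading positive;
  missing dosages are mean-imputed per variant before standardizing;
  zero-variance variants are excluded with a warning.
* Greedy pruning/clumping treat undefined correlations (monomorphic
  columns) as 0 and are deterministic given input order / p-value ranking.
* The weighted median interpolates standardized cumulative weights at 1/2
  and returns boundary ratios when weight concentrates there.
* p = 0 is rejected on input records (p must lie in (0, 1]); summary
  statistics round-trip through plain TSV with a fixed header.

# Limitations

No mixed models, dominance codings or gene–environment interactions; no
genotype QC or imputation; no multivariable MR or outlier-removal variants
(MR-PRESSO); no partitioned heritability or genetic correlation; no
transcript-level consequences.  Network construction at the exploratory
threshold deliberately tolerates false positives, as the downstream
analyses (MR screening, concordance) are designed to absorb them.
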
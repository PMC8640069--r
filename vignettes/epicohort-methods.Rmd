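---
title: "Models, calibration and design choices in epicohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design choices in epicohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicohort)
```

epicohort implements the integrative analysis used in whole-blood molecular
epidemiology of autoimmune disease: covariate-adjusted scans for
differential methylation level and variability, region-level enrichment,
differential expression, cis genetic regulation, genotype-by-disease
interaction, mediation-direction reasoning and an HLA association suite —
all validated against a synthetic cohort generator with planted ground
truth. This vignette explains the statistical models, the generator's
assumptions, the numerical choices, and what the validation does and does
not establish.

## The association models

**Differential methylation (DMP).** For each CpG, methylation beta (the
fraction of methylated molecules, in [0, 1]) is regressed by ordinary least
squares on disease status plus covariates: sex, age, the first genetic
principal component, measured blood cell proportions and batch factors. The
disease coefficient is tested with a two-sided t test; family-wise control
uses Bonferroni `α/m` over the CpGs tested, with Benjamini–Hochberg FDR
reported alongside. We model betas directly rather than M-values, because
the effect-size metric of interest (Δβ, the case-control difference in mean
beta) lives on that scale; an M-value mode is not offered since the OLS
engine is agnostic to the transform a caller applies first. Cell
proportions enter as k−1 columns (the last is dropped) to avoid the
sum-to-one collinearity; batch enters as fixed-effect dummies, the simplest
defensible reading when the alternative (pre-correction) is not specified
by the upstream data.

**Differential variability (VMP).** Betas are first residualized on all
covariates *except* disease, so that disease-related mean structure is not
absorbed; the Brown–Forsythe test (one-way F across the two groups on
absolute deviations from the *group medians*) then compares residual
spread. Median centring is the standard robust reading of a "Levene test
accounting for mean differences", and makes the statistic exactly invariant
to adding a constant to either group's residuals; classic mean-centred
Levene is available via `center = "mean"`. Zero within-group deviation
yields F = 0 and p = 1 with a degeneracy flag.

**Region detection (DMR).** CpGs are ranked by the signed disease t
statistic (ties broken lexicographically by id so the ranking is a pure
function of its inputs). Each predefined region — promoter, gene body or
CpG island set with at least 5 ranked members — is scored with the weighted
Kolmogorov–Smirnov running sum of GSEA (weight exponent 1): hits increment
by `|t|^p / Σ|t|^p`, misses decrement by `1/(N − n)`, and the enrichment
score is the extremum of the walk, with ties in magnitude resolved in walk
order. Significance comes from a permutation null of random member sets of
equal size drawn from the ranked CpGs. The null is **pooled across regions
with the same member count** — the gene-permutation scheme of the fgsea
family — because per-region nulls cap the attainable p at `1/(n_perm + 1)`,
which can never survive BH adjustment across hundreds of regions;
sample-label permutation was considered and rejected as it answers a
different (and far slower) question. The leading edge is the member set at
or before the score extremum (at or after, for depletion), and its
per-sample mean beta is the region's methylation profile.

**eQTM.** A region's leading-edge profile is Pearson-correlated with
log-scale expression of every gene whose strand-aware TSS lies within 1500
bp of the region span (min to max member position, boundary inclusive),
with optional case/control-stratified correlations. Zero-variance profiles
are flagged rather than dropped silently.

**Differential expression.** A deliberately simple negative-binomial Wald
test: median-of-ratios size factors (geometric-mean reference over genes
positive in every sample, factors rescaled to geometric mean 1), gene-wise
method-of-moments dispersion `α = max((s² − μ)/μ², 1e-8)` on normalized
counts, then an NB log-link regression with `offset = log(size factor)` and
fixed `α`, fitted by iteratively reweighted least squares; the disease
coefficient is tested against a two-sided normal reference and reported as
log2FC = β/ln 2. There is no dispersion shrinkage, no outlier refitting and
no independent filtering: validity is demonstrated by parameter recovery
and null calibration on synthetic NB data, not by matching a particular
production DE tool. The marginal method-of-moments estimator absorbs
covariate-driven variation into `α`, which makes the test mildly
conservative for strongly covariate-loaded genes — an accepted cost of the
simplification. All-zero genes are dropped before testing and excluded from
the Bonferroni denominator.

**cis-QTL and interaction scans.** cis pairs are same-chromosome SNP ×
feature combinations with `|pos_SNP − anchor| ≤ 1 Mb` (inclusive; anchor =
CpG position or strand-aware TSS). The full-cohort scan regresses the
molecular level on allele dosage plus covariates *including disease
status*, with BH FDR per layer and a cohort-wide MAF ≥ 0.05 filter; missing
dosages drop samples per SNP only (complete-case). For complete dosage
matrices the scan residualizes both the feature and the dosage on the
shared covariate design and fits the simple regression of residuals with
the degrees of freedom of the full model — the Frisch–Waugh identity makes
this *exactly* the full OLS fit, and the tests assert that equality. The
interaction scan adds a dosage × disease term (covariate × disease terms
are not included — nothing in the design motivates them) and reports
case-only and control-only stratified fits. The disease-dependent filter
keeps pairs with P_INT < 0.005 in discovery, P_INT < 0.05 in replication
with the same interaction sign (signs only; magnitudes are not compared),
a case-group QTL at P < 0.05 with control-group P > 0.05, and case MAF >
0.10. Nominal case-group P is the default evidence rule, with a
`ss_evidence = "fdr"` switch, since the two published descriptions of this
condition disagree; the MAF floor is computed in cases only while the cis
filter uses the full cohort.

**Mediation direction.** For a SNP with a case-control association (additive
logistic model; dosage effects per supplied allele, never re-oriented), the
verdict is `consistent` iff `sign(β_QTL) × sign(log OR) =
sign(β_disease)`; an odds ratio of exactly 1 carries no direction and is
flagged. The verdict is invariant to flipping the coded allele, which the
tests assert exactly. The association significance level `alpha_snp` is a
required argument because its denominator depends on the SNP set a caller
brings.

**HLA suite.** Six models per allele dosage: logistic disease ~ allele +
sex + age; logistic SSA ~ allele + sex + age among cases (controls are
negative by definition, so including them would duplicate the first model);
linear IFN-proxy beta ~ allele + sex + age + cells + batch among cases,
with and without SSA adjustment; and the disease model restricted to
IFN-signature-positive or -negative cases against *all* controls. The
signature is proxy beta < 0.8 (a beta of exactly 0.8 is negative, matching
the "≥ 0.8 is negative" convention). SNP case-control models default to
PC1 + sex + age as covariates — the intersection of the two published
covariate descriptions — with the full covariate set available through
`run_assoc_scan(covariates = ...)`.

## The synthetic cohort generator

`simulate_cohort()` emulates a two-arm whole-blood cohort; defaults are 189
cases and 220 controls (the discovery-cohort scale of the motivating study
design) with 2000 CpGs in 10-CpG promoter blocks, 1000 genes and 500 SNPs
on one synthetic chromosome laid out so each feature sees a handful of cis
SNPs.

* **Methylation** is generated on the logit scale — baseline (bimodal, as
  on arrays), array batch/sex/age/PC1 loadings, disease shifts, cis allele
  effects, case-only interaction effects, SSA-driven IFN-block
  hypomethylation, Gaussian noise — and inverse-logit transformed.
  **Cell-composition effects are added on the beta scale**, because bulk
  methylation is a proportion-weighted mixture of cell-type methylomes:
  this is the physically correct model and it keeps covariate-adjusted
  scans exactly calibrated under the null. Cell proportions are Dirichlet
  with case/control-specific concentrations (mild neutrophilia/lymphopenia
  in cases), creating genuine confounding that the covariates must remove.
* **Calibration.** A planted beta-scale effect (Δβ, per-allele β, IFN-block
  depth) is converted to a logit shift by numerically inverting
  `E[plogis(l + d + σZ)] − E[plogis(l + σZ)] = target` (Gaussian
  quadrature + root finding), so the *expected realized* beta-scale effect
  equals the configured target despite the nonlinearity; case-only effects
  are calibrated at the case baseline (including any disease shift at the
  same CpG). Empirically, planted Δβ is recovered to well within ±0.03 at
  n ≥ 400.
* **Variance inflation** at VMP sites multiplies the case noise *standard
  deviation* by √factor so the case/control residual-variance ratio equals
  the configured factor (recovered within ±20 % at n ≥ 400; the inverse
  logit compresses it slightly, which is why VMP baselines sit mid-range).
* **QTLs** are planted preferentially at disease-associated features
  (DMPs/DEGs), mirroring a design that maps genetic control *of the disease
  signature*; planted QTL SNPs are common (MAF ≥ 0.2), as the reported
  disease-dependent QTLs are, and are placed within ±100 kb of their
  partner feature. Genotypes are LD-free Binomial(2, MAF) — the statistics
  need no LD, and LD simulation is out of scope. Default per-allele effect
  magnitudes span 0.02–0.3 (beta scale; a separate log-scale range is
  available for expression), covering the published effect-size band.
* **The HLA chain.** SSA status is drawn for cases (55 % positive; controls
  negative; SSB positivity nested within SSA-positive cases), and the risk
  allele is enriched among SSA-positive cases by a retrospective logistic
  tilt `P(d) ∝ Binom(d; 2, f) · exp(b·d)` with per-allele log-odds `b`
  (default 1.1). This encodes the substantive claim that HLA risk acts
  through the autoantibody-positive subtype: the allele then associates
  with SSA, with the IFN signature (which is attenuated to null when SSA is
  conditioned on), and with disease only in the signature-positive stratum —
  while SSA-negative cases carry the population frequency. IFN-block CpGs
  (baseline 0.75–0.9, as at interferon-regulated promoters in health) are
  hypomethylated by the configured depth in SSA-positive cases only; the
  first block CpG serves as the signature proxy.
* **Coherent blocks** for region detection place all CpGs of a promoter at
  intermediate methylation (baseline 0.5, σ = 0.35) with a small common
  shift, so the region signal is strong while each member is individually
  unremarkable.

What the generator does **not** emulate: LD and relatedness, probe-level
artifacts (cross-reactivity, detection failure), count outliers and
library-composition biases, ancestry admixture, longitudinal or treatment
dynamics, X-chromosome dosage. Passing recovery tests therefore show the
pipeline's statistics are correct and calibrated under the stated
generative assumptions — not that real-data preprocessing (normalization,
QC, imputation), which is explicitly upstream of this package, is solved.

## Validation scenarios and problem sizes

The test suite and `scripts/acceptance.R` use: a null cohort of 200 + 200
samples × 2000 CpGs / 1000 genes / 500 SNPs for calibration (KS uniformity
and type-I error of all five scans); a recovery cohort of 800 + 800 split
into discovery/replication halves with Δβ = 0.30 DMPs, variance-ratio-4
VMPs, log2FC = 2 DEGs, 0.05/allele cis-meQTLs and case-only interaction
QTLs (0.05 beta-scale; 0.4 log-scale) pushed through the three-condition
filter; a 65 + 65 cohort of 3000 CpGs with one 8-CpG block at per-CpG
Δβ = 0.05 for region detection (19,999 pooled permutations); and the
default-size cohort for the HLA chain. These sizes make every Monte-Carlo
power estimate sharp while keeping a full run in minutes on one CPU. The
region scenario's "individually insignificant" bar is the genome-wide
EWAS cutoff 6.4 × 10⁻⁸ — the regime the region scan complements — since a
desk-scale Bonferroni denominator would not reproduce that regime.

## Numerical choices

* OLS uses a QR/Cholesky solve with explicit rank checking; rank-deficient
  designs abort naming the collinear columns; constant responses return a
  zero estimate with p = 1 and a degeneracy flag.
* Logistic fits use IRLS (deviance tolerance 1e-12, ≤ 100 iterations);
  complete separation (detected via the fitted-probability warning or
  |β| > 15) and non-convergence yield flagged records with NA p-values
  rather than errors.
* The enrichment-score walk is evaluated only at member positions (O(m)
  per set), with the extremum tie rule of a literal element-by-element
  scan (earliest position wins at equal magnitude, within 1e-9).
* Permutation p-values are `(1 + exceedances) / (n_perm + 1)`; NES is
  `es / mean(|es_null|)` over the pooled null of the region's size class.
* Missing dosages: per-pair complete-case analysis; monomorphic SNPs (or
  strata) are skipped or flagged, never silently zero.
* Truth registries and stage sidecars are JSON at full double precision;
  matrices round-trip TSV at 12 significant digits.

## Known limitations

The DE model's marginal dispersion estimate is conservative for
covariate-dominated genes; the VMP F-approximation, while calibrated at the
tested sizes, inherits Brown–Forsythe's small-sample approximation; the
eQTM pairing uses a single fixed window rather than annotation-aware
promoter assignment; and the disease-dependent filter's control-group
condition (P_CTRL > 0.05) bounds per-pair recovery at 95 % by construction
— a property of the published rule itself, visible in the interaction
recovery power.
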
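---
title: "Selecting prognostic serum protein markers with random survival forests"
author: "SeroSurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting prognostic serum protein markers with random survival forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeroSurv)
```

## The problem

Multiplex proximity extension assays (PEA) measure ~92 serum proteins per
sample and report relative abundance as NPX, an arbitrary unit on a log2
scale: a one-unit NPX increase corresponds to a doubling of protein content.
In survival cohorts — the motivating setting is newly diagnosed metastatic
breast cancer with overall survival (OS) and progression-free survival (PFS)
endpoints — the analyst's task is to find the few proteins, out of a panel
that is wide relative to the cohort, whose serum levels carry prognostic
information *independently* of established clinical factors (age, ECOG
performance status, metastasis-free interval, number and site of metastases,
tumor subtype, histological grade, circulating tumor cell count).

SeroSurv implements that workflow end to end: NPX preprocessing, covariate
residualization, a cascaded random-survival-forest (RSF) feature selection
with recursive feature elimination (RFE) against Harrell's concordance
index, validation with classical and elastic-net penalized Cox regression
reporting per-doubling hazard ratios with Benjamini–Hochberg (BH) q-values,
and median-dichotomized association testing against clinicopathological
features. Because patient-level cohorts of this kind are typically not
publicly deposited, the package carries a synthetic-cohort generator whose
draws have the statistical structure the analysis assumes, so every stage
is testable.

## NPX preprocessing

Four fixed stages, in order; each returns a `PreprocessReport` whose counts
must reconcile:

1. **Sample exclusions.** An availability manifest (reason codes
   `available`, `no_sample`, `qc_fail`, `insufficient_material`) determines
   the analyzable set; exclusions are itemized per reason.
2. **LOD filtering.** Proteins whose below-LOD fraction strictly exceeds
   15% of samples are removed, then samples with strictly more than 15% of
   retained proteins below LOD. Proteins are filtered before samples and
   the boundary is strict (exactly 15% is kept). The order is a
   convention; with moderate below-LOD rates the two orders give the same
   result on realistic panels.
3. **Rescaling and censoring.** Each retained value v becomes
   v − LOD(protein); values already below LOD − 2·SD(LOD) are set to `NA`
   instead. SD(LOD) is a per-protein input; when a panel provides no LOD
   uncertainty the default SD(LOD) = 0 is the conservative reading — every
   below-LOD value becomes `NA` rather than a rescaled negative value.
   Rescaling is a per-protein affine shift, so between-sample contrasts of
   observed values are untouched.
4. **kNN imputation** (k = 5 by default). Each `NA` becomes the unweighted
   mean of the k nearest samples' observed values for that protein. The
   distance between two samples is the Euclidean distance over proteins
   observed in both, normalized by the shared-protein count so sparsely
   observed samples remain comparable; neighbor ties are broken by sample
   order for determinism. Observed values are never altered.

## Survival machinery

All survival code treats right-censored (time, event) pairs; times are in
months from baseline sampling.

**Harrell's C** is computed over comparable pairs (i, j) with
t_i < t_j and event_i = 1: credit 1 if risk_i > risk_j, 0.5 on risk ties,
0 otherwise. Pairs tied on time are not comparable (Harrell's original
convention). C is invariant under strictly monotone transforms of the risk
score, and the implementation is checked exactly against an O(n²) pair
enumeration.

**The random survival forest** is built from scratch (C++ core):

- trees are grown on bootstrap resamples; out-of-bag (OOB) membership is
  recorded;
- at each node, `maxFeatures` candidate proteins are drawn without
  replacement; candidate thresholds are the midpoints between sorted
  distinct values; the best split maximizes the two-group log-rank
  statistic (O − E)²/V with the hypergeometric variance — the canonical RSF
  split rule (ties broken toward the lowest protein index, then the lowest
  threshold, so a fit is a deterministic function of the seed);
- node growth stops at `minSamplesSplit` / `minSamplesLeaf`;
- each leaf stores the Nelson–Aalen cumulative hazard of its bootstrap
  samples, evaluated on the shared grid of training event times;
- the risk score of a sample is the *ensemble mortality*: the mean over
  trees of the leaf cumulative hazard summed over the event-time grid.

**Permutation importance** of protein p is the mean drop in Harrell's C
when column p is permuted, evaluated OOB by default (an evaluation-set
variant is exposed, since protocols differ on this point). A protein never
used in any split has importance exactly 0 — permuting it cannot change
routing.

## The selection cascade

1. **Residualization.** Each protein is regressed (OLS) on the shared
   eight-covariate design (age continuous; the categorical factors
   dummy-coded against their first level). Residuals are orthogonal to the
   design by construction. The same design builder is reused by the
   adjusted Cox models so the two cannot drift.
2. **Prescreen.** Repeated untuned forests (500 trees, √p features by
   default) rank proteins by median permutation importance; the
   ceiling(25%) lowest-median proteins are eliminated and the top 20 of the
   remainder go forward. The screen's only role is coarse elimination, so
   it reuses the survival-forest machinery rather than a separate
   censoring-blind regression forest whose response would have to be
   invented.
3. **Tuning.** A randomized grid over number of trees (100–1000),
   candidate features per split (2–10), minimum leaf size (3–15) and
   minimum split size (6–30), 25 sampled configurations, each scored by
   5-fold cross-validated test C repeated 100 times in the full protocol.
4. **Evaluation.** 10-fold cross-validation repeated 100 times with the
   tuned parameters yields train and test C distributions and their
   medians.
5. **RFE.** Proteins are ordered by descending median cross-validated
   permutation importance; for every k the top-k set is re-evaluated by
   cross-validation, and the selected size maximizes the median test C,
   with ties broken toward smaller k (parsimony). Whether hyperparameters
   should be re-tuned at each k is ambiguous in protocols of this kind;
   the default reuses the tuned parameters, which is cheaper and avoids
   selection noise from re-tuning on nested subsets.
6. **Rank concordance.** Per-protein ranks from the screen, the RSF, the
   univariable Cox P values and the elastic nets (on regressed and
   un-regressed data) are tabulated with pairwise Spearman correlations and
   top-k set overlaps.

Repeat counts are configuration values: the full protocol uses the 100s
quoted above, while the shipped `desk` profile (5-fold × 5 tuning CV,
10-fold × 5 evaluation CV, reduced RFE repeats) runs the identical code at
desk scale. The package's own tests exercise the cascade at n = 300 with
3 screen repeats, 3-fold RFE evaluation and 150–200 trees, sizes chosen so
the planted-signal recovery properties are sharp while a full test run
stays comfortably interactive.

## Cox validation

`fitCox` wraps the Efron-ties Newton–Raphson partial-likelihood maximizer
(`survival::coxph`, convergence 1e−9, 100 iterations); because the
predictor is log2 NPX, exp(β) is the hazard ratio per doubling of protein
content. Efron's tie correction is the default because month-resolution
follow-up produces heavily tied times. Monotone-likelihood (separation) and
non-convergence are *flagged*, never silently reported; flagged fits enter
the FDR computation with p = 1. The adjusted model adds the shared
covariate design, dropping incomplete cases per model with the dropped
count logged.

`fitElasticNetCox` wraps coordinate-descent penalized Cox regression
(glmnet) with mixing penalty λ·[α·L1 + (1−α)/2·L2], α = 0.5 by default (a
balanced elastic net; the mixing value is exposed), λ chosen by
cross-validated partial-likelihood deviance, and variable weights defined
as |standardized coefficient| at the selected λ. At λ = 0 the coefficients
agree with the unpenalized multi-protein fit to 1e−4, which is tested.

BH q-values are computed per analysis (UV/MV × OS/PFS) over the *full*
panel size m (92 by default) even when fewer fits converge, matching the
convention of adjusting over all assayed proteins. Two evidence thresholds
are used throughout: P < 0.005 "significant", 0.005 ≤ P < 0.05
"suggestive", otherwise weak.

## Clinicopathological associations

Each selected marker is dichotomized at its median (ties to "low", for
determinism). Two-level features are tested with Fisher's exact test
(two-sided by the probability-mass method; the reported OR is the
cross-product ad/bc, flagged NA on a zero margin); features with three or
more levels use logistic regression of marker-high on the dummy-coded
feature, reporting per-level ORs against the first-listed reference level.
Marker-high is the outcome because that orientation yields one OR per
feature level against a reference of 1; for 2×2 tables the direction is
immaterial. Per-feature missing samples are dropped and counted.

## The synthetic-cohort generator

The generator is the package's study-conditions mirror, not a fixture:

- **NPX.** Latent proteins × samples draws from a Gaussian with mean 5,
  SD 1 (log2 units) and compound-symmetric correlation inside configurable
  blocks (defaults: blocks of 10/10/8 at ρ = 0.6/0.4/0.3, echoing the
  correlated cytokine clusters of immuno-oncology panels). Per-protein LODs
  are the empirical `lodQuantile` (default 5%) of each protein's values;
  below-LOD values are flagged but still recorded, since truncation is a
  preprocessing decision.
- **Clinical covariates** are multinomial draws matching the category
  frequencies of a newly diagnosed MBC cohort (ECOG 0 ≈ 57%, visceral
  involvement ≈ 59%, ER+HER2− ≈ 71%, CTC ≥ 5 ≈ 51%, age ≈ N(64.5, 11)
  truncated to ≥ 18).
- **Outcomes.** OS and PFS times are Weibull proportional-hazards draws
  (shape 1.2; scales put the baseline median OS at 36 months and median
  PFS at 9 months, typical of first-line metastatic breast cancer). The
  linear predictor is Σ (planted per-doubling log-HR × centered NPX) +
  Σ (covariate log-HRs) + a shared Gaussian frailty (SD 0.5) that couples
  OS and PFS so their marker sets overlap, as they do in real cohorts.
  Censoring is independent exponential with the rate solved numerically so
  the realized censored fraction hits the target (±5 points at n ≥ 500);
  administrative censoring patterns are not modeled.
- **Manifest.** A configurable fraction of samples is flagged unavailable,
  with reasons in proportions 14:5:1 (no sample : QC failure :
  insufficient material), the loss pattern of baseline serum sampling.

What the generator does *not* emulate: plate structure and vendor
normalization, assay-specific LOD heterogeneity, non-Gaussian NPX tails,
informative censoring, and covariate-outcome interactions. Passing tests
on synthetic cohorts therefore demonstrate that the machinery recovers the
structure it assumes — not that any particular real cohort satisfies those
assumptions.

Two calibration points are worth stating. First, with several effects
planted, the *univariable* Cox estimate of one protein marginalizes over
the others; hazard ratios are non-collapsible, so the marginal estimate is
mildly attenuated relative to the planted conditional value even in a
correctly specified generator (at the tested conditions the mean log-HR
bias stays below 0.05, which is what the recovery tests assert). The same
applies more strongly when the shared frailty is active, which is why the
estimator-calibration experiments use a generator configuration with no
frailty and no covariate effects: marginal bias is only a meaningful
quantity when no unobserved heterogeneity is planted. Second, under the
global null the fraction of univariable P < 0.05 is checked against a
3-standard-error Monte-Carlo band around 5% with *independent* proteins;
correlated blocks would inflate the variance of that fraction without
changing its mean.

## Numerical choices and degenerate inputs

- All RNG flows through explicit seeds; the C++ forest uses a Mersenne
  twister with explicit Fisher–Yates shuffles so fits are bit-reproducible
  for a given seed.
- Split and RFE ties break deterministically (lowest protein index /
  threshold; smallest k).
- `harrellC` errors when no comparable pair exists; the log-rank statistic
  returns 0 when the variance term degenerates; single-leaf forests yield
  constant risk and test C exactly 0.5.
- Cohort writing uses full-precision (%.17g) text so a write/read round
  trip is exact.
- Below-LOD masks use strict inequality (value < LOD), matching the strict
  15% filter boundary.

## Known limitations

- The RSF supports neither competing risks nor time-varying covariates,
  and trees are not pruned.
- Separation in Cox or logistic fits is flagged, not repaired (no Firth
  correction).
- The association grid applies no multiplicity correction, mirroring
  protocols that reserve FDR for the Cox panel.
- Proportional-hazards diagnostics are out of scope; the generator is PH
  by construction, real data need not be.

## A minimal run

```{r example, eval = FALSE}
cfg <- cohortConfig(
  nSamples = 156, plantedEffectsOS = c(P001 = log(2), P002 = -log(2)),
  plantedEffectsPFS = c(P001 = log(2)), missingSampleFraction = 0.13,
  seed = 1)
rc <- runConfig(simulate = cfg, outDir = "serosurv_out", profile = "desk",
                seed = 1)
res <- runPipeline(rc)
res$endpoints$os$selected     # RFE-selected OS markers
res$endpoints$os$coxTable     # per-doubling HRs, CIs, P, q, evidence
res$overlap                   # OS/PFS marker-set intersection and union
```
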
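# SeroSurv

Feature selection and validation for serum protein prognostication in
right-censored survival cohorts.

## What it is for

Multiplex proximity extension assays (Olink-style panels) measure ~92 serum
proteins per patient and report relative abundance as **NPX**, a log2-scale
unit: +1 NPX = a doubling of protein content. In metastatic breast cancer
cohorts — and survival cohorts generally — the question is which of those
proteins carry prognostic information for overall survival (OS) and
progression-free survival (PFS) *independently* of established clinical
factors (age, ECOG, metastasis-free interval, number/site of metastases,
subtype, grade, CTC count).

SeroSurv implements the full analysis a biostatistician would run:

1. **NPX preprocessing** — sample-exclusion accounting, removal of proteins
   with > 15% of values below the limit of detection (LOD) and of samples
   with > 15% of proteins below LOD, rescaling by `NPX − LOD` with values
   below `LOD − 2·SD(LOD)` set to NA, and kNN imputation (k = 5).
2. **Covariate residualization** — per-protein OLS on the shared
   eight-covariate clinical design.
3. **Cascaded selection** — a survival-forest prescreen (drop the
   lowest-importance 25%, keep the top 20), randomized-grid hyperparameter
   tuning with repeated 5-fold CV, repeated 10-fold CV evaluation, and
   recursive feature elimination (RFE) choosing the marker-set size that
   maximizes the median cross-validated **Harrell's C**,

   `C = P(risk_i > risk_j | t_i < t_j, event_i = 1)`,

   computed over comparable pairs with 0.5 credit for risk ties. The random
   survival forest is built from scratch: log-rank split rule
   `(O − E)² / V` with hypergeometric variance, Nelson–Aalen cumulative
   hazard leaves on a shared event-time grid, ensemble-mortality risk
   scores, and out-of-bag permutation importance.
4. **Validation** — univariable and covariate-adjusted Cox models per
   protein (Efron ties) reporting the hazard ratio **per doubling**
   (`HR = exp(β)` because the predictor is log2 NPX) with Wald 95% CIs,
   Benjamini–Hochberg q-values over the full 92-protein panel, the
   two-threshold evidence convention (P < 0.005 significant,
   0.005 ≤ P < 0.05 suggestive), elastic-net penalized Cox on regressed and
   un-regressed data, and cross-model rank-concordance tables.
5. **Clinicopathological associations** — markers dichotomized at their
   medians, tested against clinical features by Fisher's exact test
   (two-level) or logistic-regression odds ratios (multi-level).

Because patient-level cohorts of this kind are rarely deposited, the
package ships a **synthetic-cohort generator** (block-correlated log2 NPX,
LOD flagging, realistic clinical covariate frequencies, Weibull
proportional-hazards OS/PFS with planted per-doubling log hazard ratios and
calibrated censoring) so the whole pipeline is testable end to end.

## Worked example

Simulate a 156-patient cohort with two planted OS markers (HR 2.0 and 0.5
per doubling) and two planted PFS markers, 13% of samples unavailable, then
run the desk-scale profile of the full pipeline:

```r
library(SeroSurv)
cfg <- cohortConfig(
  nSamples = 156,
  plantedEffectsOS  = c(P030 = log(2), P040 = -log(2)),
  plantedEffectsPFS = c(P030 = log(2), P050 = log(2)),
  missingSampleFraction = 0.13, seed = 1)
rc  <- runConfig(simulate = cfg, profile = "desk", seed = 1)
res <- runPipeline(rc)
```

This prints (reformatted):

```
enrolled: 156 | analyzable: 136 | after preprocessing: 135 samples x 92 proteins
OS selected: P040, P030, P053, P079, P014, P019, P046, P028, P015, P067, ...
OS median train/test C: 0.914 / 0.731
PFS selected: P030, P050
PFS median train/test C: 0.916 / 0.696
overlap: 1 | union: 18
```

20 of 156 samples were excluded by the manifest (no serum / QC failure /
insufficient material), one more sample fell to the below-LOD filter. Both
planted OS markers head the OS selection and both planted PFS markers are
exactly the PFS selection; the OS/PFS sets overlap in the shared marker
P030. The Cox validation table for the selected OS markers begins:

```
protein uv_hr     uv_p    uv_q mv_hr     mv_p    mv_q mv_evidence
P040    0.575 1.22e-05 0.00112 0.554 1.27e-05 0.00117 significant
P030    1.504 2.88e-04 0.01326 1.692 3.80e-05 0.00175 significant
P053    1.308 3.73e-02 0.34272 1.360 4.02e-02 0.38772 suggestive
...
```

i.e. a doubling of P040 halves the hazard (HR 0.58, q ≈ 0.001 after BH
adjustment over all 92 proteins) and both planted markers remain
significant after covariate adjustment, while the trailing noise proteins
show weak or suggestive evidence at best. `res$endpoints$os$associations`
holds the Table-style marker × clinical-feature odds-ratio grid, and
`res$endpoints$os$rankConcordance` the cross-model rank table (screen, RSF,
Cox, elastic nets).

A YAML-driven command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

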
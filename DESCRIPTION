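Package: SeroSurv
Title: Serum Protein Marker Selection for Survival Prognostication
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for serum proteomic prognostication in
    metastatic cancer cohorts profiled on multiplex proximity extension
    assay (PEA) panels reported as NPX (log2) values. Implements NPX
    preprocessing (limit-of-detection filtering, LOD rescaling with NA
    censoring, kNN imputation), covariate residualization, a from-scratch
    random survival forest with log-rank splitting and Nelson-Aalen leaf
    estimators, permutation importance, randomized-grid hyperparameter
    tuning, repeated cross-validation against Harrell's concordance index,
    recursive feature elimination, classical and elastic-net penalized Cox
    validation with per-doubling hazard ratios and Benjamini-Hochberg
    q-values, and median-dichotomized clinicopathological association
    testing. Includes a synthetic-cohort generator with planted
    proportional-hazards effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    glmnet,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Survival, Proteomics, FeatureExtraction, Classification
RoxygenNote: 7.3.3
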
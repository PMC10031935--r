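#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData assay<- assays<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' NPXExperiment: NPX proteomics container with survival annotation
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are proteins, columns are
#' samples (the Bioconductor orientation). The \code{"npx"} assay holds log2
#' NPX values (may contain \code{NA}); the \code{"belowLOD"} assay is a
#' logical mask marking values below the per-protein limit of detection.
#' \code{rowData} must carry a numeric \code{lod} column (NPX units) and may
#' carry \code{lod_sd}, the standard deviation of the LOD estimate.
#' \code{colData} carries clinical covariates, survival endpoints
#' (\code{os_months}, \code{os_event}, \code{pfs_months}, \code{pfs_event})
#' and, when present, a \code{sample_status} manifest column with levels
#' \code{available}, \code{no_sample}, \code{qc_fail},
#' \code{insufficient_material}.
#'
#' @export
setClass("NPXExperiment", contains = "SummarizedExperiment")

setValidity("NPXExperiment", function(object) {
  msg <- character()
  if (!"npx" %in% assayNames(object))
    msg <- c(msg, "assay 'npx' is required")
  if (!"lod" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'lod' is required")
  if ("npx" %in% assayNames(object) && !is.numeric(assay(object, "npx")))
    msg <- c(msg, "assay 'npx' must be numeric")
  if ("belowLOD" %in% assayNames(object)) {
    m <- assay(object, "belowLOD")
    if (!is.logical(m))
      msg <- c(msg, "assay 'belowLOD' must be logical")
  }
  if (length(msg)) msg else TRUE
})

#' Random survival forest fit
#'
#' Ensemble of log-rank-split survival trees with Nelson-Aalen cumulative
#' hazard estimators in the leaves, all sharing one event-time grid.
#'
#' @slot trees list of per-tree flat node tables (split variable, threshold,
#'   children) plus leaf cumulative-hazard matrices over the grid.
#' @slot grid numeric, the distinct training event times.
#' @slot inbag integer matrix (samples x trees) of bootstrap counts.
#' @slot proteinIds character, column order the forest was trained on.
#' @slot params list, the \code{rsfParams} used.
#' @slot seed integer seed the fit used.
#' @export
setClass("RandomSurvivalForest",
  representation(trees = "list", grid = "numeric", inbag = "matrix",
                 proteinIds = "character", params = "list", seed = "integer"))

setValidity("RandomSurvivalForest", function(object) {
  if (length(object@trees) < 1) return("forest has no trees")
  if (nrow(object@inbag) < 1) return("empty inbag record")
  TRUE
})

#' Preprocessing report
#'
#' Per-stage accounting of the NPX preprocessing pipeline: how many samples
#' and proteins entered and left, which were removed and why, and how many
#' values were rescaled, set to NA, or imputed.
#'
#' @slot nSamplesIn,nSamplesOut,nProteinsIn,nProteinsOut integer counts.
#' @slot removedSamples data.frame with columns \code{sample_id},
#'   \code{reason} (and \code{below_lod_fraction} where relevant).
#' @slot removedProteins data.frame with columns \code{protein_id},
#'   \code{below_lod_fraction}.
#' @slot nValuesRescaled,nValuesSetNA,nValuesImputed integer counts.
#' @export
setClass("PreprocessReport",
  representation(nSamplesIn = "integer", nSamplesOut = "integer",
                 nProteinsIn = "integer", nProteinsOut = "integer",
                 removedSamples = "data.frame",
                 removedProteins = "data.frame",
                 nValuesRescaled = "integer", nValuesSetNA = "integer",
                 nValuesImputed = "integer"),
  prototype(nSamplesIn = 0L, nSamplesOut = 0L, nProteinsIn = 0L,
            nProteinsOut = 0L,
            removedSamples = data.frame(sample_id = character(),
                                        reason = character()),
            removedProteins = data.frame(protein_id = character(),
                                         below_lod_fraction = numeric()),
            nValuesRescaled = 0L, nValuesSetNA = 0L, nValuesImputed = 0L))

setValidity("PreprocessReport", function(object) {
  msg <- character()
  if (object@nSamplesIn - nrow(object@removedSamples) != object@nSamplesOut)
    msg <- c(msg, "sample counts do not reconcile")
  if (object@nProteinsIn - nrow(object@removedProteins) != object@nProteinsOut)
    msg <- c(msg, "protein counts do not reconcile")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' Defines the generative model of \code{\link{simulateCohort}}: correlated
#' log2 NPX blocks, covariate-linked shifts, Weibull proportional-hazards
#' OS/PFS with planted per-doubling log hazard ratios, independent
#' exponential censoring calibrated to a target rate, per-protein LOD
#' quantiles and a sample-availability manifest.
#'
#' @slot nSamples,nProteins integers.
#' @slot correlationBlocks list of \code{c(size, rho)} pairs.
#' @slot plantedEffectsOS,plantedEffectsPFS named numeric: log-HR per
#'   doubling keyed by protein id.
#' @slot covariateEffects named numeric of log-HRs on design columns.
#' @slot confounding data.frame (protein, covariate_column, shift) of NPX
#'   shifts linked to covariates.
#' @slot lodQuantile,lodSD,censoringRate numerics.
#' @slot baselineShape,baselineScaleOS,baselineScalePFS Weibull baseline.
#' @slot frailtySD numeric, SD of the shared OS/PFS Gaussian frailty.
#' @slot missingSampleFraction numeric.
#' @slot seed integer.
#' @export
setClass("CohortConfig",
  representation(nSamples = "integer", nProteins = "integer",
                 correlationBlocks = "list",
                 plantedEffectsOS = "numeric", plantedEffectsPFS = "numeric",
                 covariateEffects = "numeric", confounding = "data.frame",
                 lodQuantile = "numeric", lodSD = "numeric",
                 censoringRate = "numeric", baselineShape = "numeric",
                 baselineScaleOS = "numeric", baselineScalePFS = "numeric",
                 frailtySD = "numeric", missingSampleFraction = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nSamples < 10L)
    msg <- c(msg, "nSamples must be at least 10")
  if (object@nProteins < 1L)
    msg <- c(msg, "nProteins must be positive")
  frac <- c(lodQuantile = object@lodQuantile,
            censoringRate = object@censoringRate,
            missingSampleFraction = object@missingSampleFraction)
  bad <- names(frac)[frac < 0 | frac >= 1]
  if (length(bad))
    msg <- c(msg, paste0("fractions must lie in [0,1): ",
                         paste(bad, collapse = ", ")))
  sizes <- vapply(object@correlationBlocks, function(b) b[[1]], numeric(1))
  if (sum(sizes) > object@nProteins)
    msg <- c(msg, "correlation block sizes exceed nProteins")
  rhos <- vapply(object@correlationBlocks, function(b) b[[2]], numeric(1))
  if (any(rhos < 0 | rhos >= 1))
    msg <- c(msg, "within-block correlations must lie in [0,1)")
  ids <- proteinIdsFor(object@nProteins)
  planted <- c(names(object@plantedEffectsOS), names(object@plantedEffectsPFS))
  unknown <- setdiff(planted, ids)
  if (length(unknown))
    msg <- c(msg, paste0("planted effects refer to unknown proteins: ",
                         paste(unknown, collapse = ", ")))
  lp <- sum(abs(c(object@plantedEffectsOS, object@plantedEffectsPFS))) * 20 +
    sum(abs(object@covariateEffects))
  if (!is.finite(lp) || lp > 500)
    msg <- c(msg, "planted effects would overflow the linear predictor")
  if (length(msg)) msg else TRUE
})

#' RSF hyperparameter tuning result
#'
#' @slot candidates data.frame of sampled configurations with median CV
#'   concordance.
#' @slot cvC list of per-configuration test-C distributions.
#' @slot bestParams list (an \code{rsfParams}).
#' @export
setClass("TuningResult",
  representation(candidates = "data.frame", cvC = "list",
                 bestParams = "list"))

#' Recursive feature elimination result
#'
#' @slot curve data.frame with columns \code{n_features}, \code{median_test_c}.
#' @slot ranking character, proteins by descending median importance.
#' @slot selectedSet character, the selected marker set.
#' @slot selectedSize integer.
#' @slot settings list of CV repeat settings used.
#' @export
setClass("RFEResult",
  representation(curve = "data.frame", ranking = "character",
                 selectedSet = "character", selectedSize = "integer",
                 settings = "list"))

setValidity("RFEResult", function(object) {
  msg <- character()
  if (length(object@selectedSet) != object@selectedSize)
    msg <- c(msg, "selectedSize does not match selectedSet")
  best <- max(object@curve$median_test_c)
  sel <- object@curve$median_test_c[
    object@curve$n_features == object@selectedSize]
  if (length(sel) != 1L || sel < best - 1e-12)
    msg <- c(msg, "selectedSize does not maximize the concordance curve")
  if (length(msg)) msg else TRUE
})
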
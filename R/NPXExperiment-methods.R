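#' Construct an NPXExperiment
#'
#' @param npx numeric matrix of log2 NPX values, proteins x samples.
#' @param lod numeric vector, per-protein limit of detection (NPX units).
#' @param lodSD optional numeric vector, per-protein SD of the LOD estimate;
#'   defaults to 0 (every below-LOD value is censored by
#'   \code{\link{rescaleAndCensor}}).
#' @param colData data.frame / DataFrame of per-sample annotation (clinical
#'   covariates, outcomes, manifest).
#' @param belowLOD optional logical mask of the same shape as \code{npx};
#'   computed as \code{npx < lod} when absent.
#'
#' @return an \linkS4class{NPXExperiment}.
#' @export
NPXExperiment <- function(npx, lod, lodSD = NULL, colData = NULL,
                          belowLOD = NULL) {
  npx <- as.matrix(npx)
  if (is.null(rownames(npx)))
    rownames(npx) <- proteinIdsFor(nrow(npx))
  if (is.null(colnames(npx)))
    colnames(npx) <- sprintf("S%04d", seq_len(ncol(npx)))
  if (length(lod) != nrow(npx))
    stop("lod must have one entry per protein")
  if (is.null(lodSD)) lodSD <- rep(0, nrow(npx))
  if (is.null(belowLOD))
    belowLOD <- sweep(npx, 1, lod, "<") & !is.na(npx)
  belowLOD[is.na(belowLOD)] <- FALSE
  rd <- DataFrame(lod = as.numeric(lod), lod_sd = as.numeric(lodSD),
                  row.names = rownames(npx))
  if (is.null(colData)) {
    cd <- DataFrame(row.names = colnames(npx))
  } else {
    cd <- DataFrame(colData, row.names = colnames(npx))
  }
  se <- SummarizedExperiment(
    assays = list(npx = npx, belowLOD = belowLOD),
    rowData = rd, colData = cd)
  methods::new("NPXExperiment", se)
}

#' Accessors for NPXExperiment
#'
#' \code{npxValues} returns the proteins x samples NPX matrix;
#' \code{sampleMatrix} its transpose (samples x proteins), the orientation
#' the statistical machinery consumes. \code{lodValues} and \code{lodSD}
#' return per-protein LOD metadata, \code{belowLOD} the logical mask, and
#' \code{survivalOutcome} a \code{survival::Surv} object for one endpoint.
#'
#' @param x an \linkS4class{NPXExperiment}.
#' @name npx-accessors
NULL

#' @rdname npx-accessors
#' @export
npxValues <- function(x) assay(x, "npx")

#' @rdname npx-accessors
#' @export
sampleMatrix <- function(x) t(assay(x, "npx"))

#' @rdname npx-accessors
#' @export
lodValues <- function(x) setNames(rowData(x)$lod, rownames(x))

#' @rdname npx-accessors
#' @export
lodSD <- function(x) {
  if (!"lod_sd" %in% colnames(rowData(x)))
    return(setNames(rep(0, nrow(x)), rownames(x)))
  setNames(rowData(x)$lod_sd, rownames(x))
}

#' @rdname npx-accessors
#' @export
belowLOD <- function(x) assay(x, "belowLOD")

#' @rdname npx-accessors
#' @param endpoint \code{"os"} or \code{"pfs"}.
#' @export
survivalOutcome <- function(x, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  cd <- colData(x)
  tcol <- paste0(endpoint, "_months")
  ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% colnames(cd)))
    stop("no ", toupper(endpoint), " outcome columns in colData")
  survival::Surv(as.numeric(cd[[tcol]]), as.integer(cd[[ecol]]))
}

#' @rdname npx-accessors
#' @export
clinicalCovariates <- function(x) {
  cd <- as.data.frame(colData(x))
  keep <- intersect(clinicalFactorNames(), colnames(cd))
  cd[, keep, drop = FALSE]
}

#' @rdname npx-accessors
#' @export
sampleManifest <- function(x) {
  cd <- as.data.frame(colData(x))
  if (!"sample_status" %in% colnames(cd))
    return(data.frame(sample_id = colnames(x),
                      status = rep("available", ncol(x))))
  data.frame(sample_id = colnames(x), status = cd$sample_status)
}

setMethod("show", "NPXExperiment", function(object) {
  cat("NPXExperiment:", nrow(object), "proteins x", ncol(object),
      "samples\n")
  m <- assay(object, "npx")
  cat("  NPX (log2): NA", sum(is.na(m)), "| below LOD",
      sum(assay(object, "belowLOD")), "\n")
  cd <- colnames(colData(object))
  if (length(cd))
    cat("  colData:", paste(utils::head(cd, 8), collapse = ", "),
        if (length(cd) > 8) "..." else "", "\n")
})

setMethod("show", "PreprocessReport", function(object) {
  cat("PreprocessReport\n")
  cat(sprintf("  samples:  %d -> %d (%d removed)\n", object@nSamplesIn,
              object@nSamplesOut, nrow(object@removedSamples)))
  cat(sprintf("  proteins: %d -> %d (%d removed)\n", object@nProteinsIn,
              object@nProteinsOut, nrow(object@removedProteins)))
  cat(sprintf("  values rescaled %d | set NA %d | imputed %d\n",
              object@nValuesRescaled, object@nValuesSetNA,
              object@nValuesImputed))
})

setMethod("show", "RandomSurvivalForest", function(object) {
  cat("RandomSurvivalForest:", length(object@trees), "trees,",
      length(object@proteinIds), "proteins,",
      length(object@grid), "event times\n")
  cat("  params: mtry", object@params$maxFeatures,
      "| minLeaf", object@params$minSamplesLeaf,
      "| minSplit", object@params$minSamplesSplit,
      "| seed", object@seed, "\n")
})

setMethod("show", "TuningResult", function(object) {
  cat("TuningResult:", nrow(object@candidates), "candidate configurations\n")
  cat("  best median CV C =", format(max(object@candidates$median_c)), "\n")
})

setMethod("show", "RFEResult", function(object) {
  cat("RFEResult: selected", object@selectedSize, "of",
      nrow(object@curve), "proteins\n")
  cat("  markers:", paste(object@selectedSet, collapse = ", "), "\n")
  cat("  best median test C =",
      format(max(object@curve$median_test_c)), "\n")
})

# report constructor used throughout preprocessing
newReport <- function(nSamplesIn, nSamplesOut, nProteinsIn, nProteinsOut,
                      removedSamples = NULL, removedProteins = NULL,
                      nValuesRescaled = 0L, nValuesSetNA = 0L,
                      nValuesImputed = 0L) {
  if (is.null(removedSamples))
    removedSamples <- data.frame(sample_id = character(),
                                 reason = character())
  if (is.null(removedProteins))
    removedProteins <- data.frame(protein_id = character(),
                                  below_lod_fraction = numeric())
  methods::new("PreprocessReport",
    nSamplesIn = as.integer(nSamplesIn), nSamplesOut = as.integer(nSamplesOut),
    nProteinsIn = as.integer(nProteinsIn),
    nProteinsOut = as.integer(nProteinsOut),
    removedSamples = removedSamples, removedProteins = removedProteins,
    nValuesRescaled = as.integer(nValuesRescaled),
    nValuesSetNA = as.integer(nValuesSetNA),
    nValuesImputed = as.integer(nValuesImputed))
}
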
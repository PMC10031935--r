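## NPX preprocessing: sample-exclusion accounting, LOD-fraction filtering,
## LOD rescaling with NA censoring, and kNN imputation. Pipeline order is
## fixed: exclusions -> LOD filter -> rescale/censor -> impute.

validStatusCodes <- function() {
  c("available", "no_sample", "qc_fail", "insufficient_material")
}

#' Apply sample-availability exclusions
#'
#' Retains exactly the samples flagged \code{available} in the manifest and
#' itemizes exclusions by reason, reproducing the sample-accounting flowchart
#' of a serum-sampling study (enrolled minus lost/QC-failed/insufficient).
#'
#' @param x an \linkS4class{NPXExperiment} with a \code{sample_status}
#'   colData column, or a manifest data.frame with columns \code{sample_id}
#'   and \code{status}.
#' @return a list with \code{retained} (the filtered object, or the retained
#'   sample ids when a manifest was given) and \code{report}
#'   (\linkS4class{PreprocessReport}).
#' @export
applySampleExclusions <- function(x) {
  if (methods::is(x, "NPXExperiment")) {
    manifest <- sampleManifest(x)
  } else {
    manifest <- as.data.frame(x)
    if (!all(c("sample_id", "status") %in% colnames(manifest)))
      stop("manifest needs columns sample_id and status")
  }
  bad <- !manifest$status %in% validStatusCodes()
  if (any(bad))
    stop("unknown status code for sample(s): ",
         paste(manifest$sample_id[bad], collapse = ", "))
  keep <- manifest$status == "available"
  removed <- data.frame(sample_id = manifest$sample_id[!keep],
                        reason = manifest$status[!keep])
  report <- newReport(nSamplesIn = nrow(manifest), nSamplesOut = sum(keep),
                      nProteinsIn = 0L, nProteinsOut = 0L,
                      removedSamples = removed)
  if (methods::is(x, "NPXExperiment")) {
    report@nProteinsIn <- nrow(x)
    report@nProteinsOut <- nrow(x)
    list(retained = x[, keep], report = report)
  } else {
    list(retained = manifest$sample_id[keep], report = report)
  }
}

#' Filter proteins and samples by below-LOD fraction
#'
#' Removes proteins whose below-LOD fraction over the current samples
#' strictly exceeds \code{maxFraction}, then samples whose below-LOD
#' fraction over the retained proteins strictly exceeds \code{maxFraction}
#' (proteins first; the boundary is strict, so exactly 15\% is kept).
#'
#' @param x an \linkS4class{NPXExperiment}.
#' @param maxFraction threshold fraction, default 0.15.
#' @return list(retained = filtered \linkS4class{NPXExperiment},
#'   report = \linkS4class{PreprocessReport}).
#' @export
filterByLOD <- function(x, maxFraction = 0.15) {
  mask <- belowLOD(x)
  protFrac <- rowMeans(mask)
  dropProt <- protFrac > maxFraction
  removedProteins <- data.frame(protein_id = rownames(x)[dropProt],
                                below_lod_fraction = protFrac[dropProt],
                                row.names = NULL)
  x2 <- x[!dropProt, ]
  if (nrow(x2) == 0)
    stop("all proteins removed by the LOD filter")
  mask2 <- belowLOD(x2)
  sampFrac <- colMeans(mask2)
  dropSamp <- sampFrac > maxFraction
  removedSamples <- data.frame(sample_id = colnames(x2)[dropSamp],
                               reason = rep("below_lod_fraction",
                                            sum(dropSamp)),
                               below_lod_fraction = unname(
                                 sampFrac[dropSamp]),
                               row.names = NULL)
  x3 <- x2[, !dropSamp]
  if (ncol(x3) == 0)
    stop("all samples removed by the LOD filter")
  report <- newReport(nSamplesIn = ncol(x), nSamplesOut = ncol(x3),
                      nProteinsIn = nrow(x), nProteinsOut = nrow(x3),
                      removedSamples = removedSamples,
                      removedProteins = removedProteins)
  list(retained = x3, report = report)
}

#' Rescale NPX by the LOD and censor deep below-LOD values
#'
#' Every value v becomes v - LOD(protein); values already below
#' LOD(protein) - 2 * lodSD(protein) (on the original NPX scale) are assigned
#' NA instead. With the default lodSD of 0, every below-LOD value becomes NA.
#'
#' @param x an \linkS4class{NPXExperiment}.
#' @return list(retained, report).
#' @export
rescaleAndCensor <- function(x) {
  lod <- lodValues(x)
  if (any(is.na(lod)))
    stop("missing LOD for protein(s): ",
         paste(rownames(x)[is.na(lod)], collapse = ", "))
  sdv <- lodSD(x)
  m <- npxValues(x)
  censorMask <- sweep(m, 1, lod - 2 * sdv, "<") & !is.na(m)
  nRescaled <- sum(!is.na(m) & !censorMask)
  out <- sweep(m, 1, lod, "-")
  out[censorMask] <- NA
  assay(x, "npx") <- out
  report <- newReport(nSamplesIn = ncol(x), nSamplesOut = ncol(x),
                      nProteinsIn = nrow(x), nProteinsOut = nrow(x),
                      nValuesRescaled = nRescaled,
                      nValuesSetNA = sum(censorMask))
  list(retained = x, report = report)
}

# brute-force kNN mean imputation with the stated distance: Euclidean over
# proteins observed in both samples, normalized by the shared-protein count;
# neighbor ties broken by sample order
knnImputeMatrix <- function(M, k) {
  # M: samples x proteins
  n <- nrow(M)
  if (k >= n) stop("k must be smaller than the number of samples")
  obs <- !is.na(M)
  if (any(rowSums(obs) == 0))
    stop("sample(s) with no observed values: ",
         paste(rownames(M)[rowSums(obs) == 0], collapse = ", "))
  allNA <- colSums(obs) == 0
  if (any(allNA))
    stop("protein(s) NA in all samples: ",
         paste(colnames(M)[allNA], collapse = ", "))
  out <- M
  nImputed <- 0L
  for (i in seq_len(n)) {
    miss <- which(is.na(M[i, ]))
    if (!length(miss)) next
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j == i) next
      shared <- obs[i, ] & obs[j, ]
      ns <- sum(shared)
      if (ns == 0) next
      d[j] <- sum((M[i, shared] - M[j, shared])^2) / ns
    }
    ord <- order(d, seq_len(n))  # ties by sample order
    for (pj in miss) {
      donors <- ord[obs[ord, pj] & is.finite(d[ord])]
      donors <- donors[seq_len(min(k, length(donors)))]
      if (!length(donors))
        stop("no donor for protein ", colnames(M)[pj], " in sample ",
             rownames(M)[i])
      out[i, pj] <- mean(M[donors, pj])
      nImputed <- nImputed + 1L
    }
  }
  attr(out, "nImputed") <- nImputed
  out
}

#' kNN imputation of missing NPX values
#'
#' Each NA is replaced by the unweighted mean of the k nearest samples'
#' observed values for that protein; the distance between two samples is the
#' Euclidean distance over proteins observed in both, normalized by the
#' shared-protein count. Observed values are never altered.
#'
#' @param x an \linkS4class{NPXExperiment}.
#' @param k number of neighbors, default 5.
#' @return list(retained, report); the output has no NA.
#' @export
imputeKNN <- function(x, k = 5L) {
  if (k < 1) stop("k must be at least 1")
  M <- t(npxValues(x))
  out <- knnImputeMatrix(M, k)
  nImp <- attr(out, "nImputed")
  attr(out, "nImputed") <- NULL
  assay(x, "npx") <- t(out)
  report <- newReport(nSamplesIn = ncol(x), nSamplesOut = ncol(x),
                      nProteinsIn = nrow(x), nProteinsOut = nrow(x),
                      nValuesImputed = nImp)
  list(retained = x, report = report)
}

#' Full NPX preprocessing pipeline
#'
#' Fixed order: sample exclusions, below-LOD filtering, LOD rescaling with
#' NA censoring, kNN imputation. Returns the preprocessed object and the
#' per-stage reports.
#'
#' @param x an \linkS4class{NPXExperiment}.
#' @param maxFraction below-LOD filter threshold.
#' @param k kNN neighbors.
#' @param outDir optional directory; when given, the preprocessed wide TSV
#'   (samples x proteins) and a per-stage report JSON are written there.
#' @return list(retained, reports = named list of
#'   \linkS4class{PreprocessReport}).
#' @export
preprocessNPX <- function(x, maxFraction = 0.15, k = 5L, outDir = NULL) {
  s1 <- applySampleExclusions(x)
  s2 <- filterByLOD(s1$retained, maxFraction)
  s3 <- rescaleAndCensor(s2$retained)
  s4 <- imputeKNN(s3$retained, k)
  reports <- list(exclusions = s1$report, lodFilter = s2$report,
                  rescale = s3$report, impute = s4$report)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    m <- npxValues(s4$retained)
    wide <- data.frame(sample_id = colnames(m), check.names = FALSE)
    for (pr in rownames(m)) wide[[pr]] <- fmtNum(m[pr, ])
    writeTSV(wide, file.path(outDir, "npx_preprocessed.tsv"))
    jsonlite::write_json(
      lapply(reports, function(r) list(
        n_samples_in = r@nSamplesIn, n_samples_out = r@nSamplesOut,
        n_proteins_in = r@nProteinsIn, n_proteins_out = r@nProteinsOut,
        removed_samples = r@removedSamples,
        removed_proteins = r@removedProteins,
        n_values_rescaled = r@nValuesRescaled,
        n_values_set_na = r@nValuesSetNA,
        n_values_imputed = r@nValuesImputed)),
      file.path(outDir, "preprocess_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(retained = s4$retained, reports = reports)
}
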
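## Cohort I/O: Olink-style long CSV, wide NPX TSV (samples x proteins),
## clinical TSV, outcomes TSV and a truth JSON. Numbers are written at full
## precision (%.17g) so a write/read round trip reproduces the in-memory
## cohort exactly.

#' Write a cohort to a directory
#'
#' Emits \code{npx_long.csv} (SampleID, Assay, NPX, LOD), \code{npx_wide.tsv}
#' (samples x proteins), \code{clinical.tsv}, \code{outcomes.tsv} and
#' \code{truth.json}. Below-LOD values are written as measured; flagging them
#' is a preprocessing decision, not an I/O one.
#'
#' @param cohort an \linkS4class{NPXExperiment}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  npx <- npxValues(cohort)
  lod <- lodValues(cohort)
  samp <- colnames(npx)
  prot <- rownames(npx)

  long <- data.frame(
    SampleID = rep(samp, each = length(prot)),
    Assay = rep(prot, times = length(samp)),
    NPX = fmtNum(as.vector(npx)),
    LOD = fmtNum(rep(lod, times = length(samp))))
  pathLong <- file.path(dir, "npx_long.csv")
  utils::write.csv(long, pathLong, row.names = FALSE, quote = FALSE)

  wide <- data.frame(sample_id = samp, check.names = FALSE)
  for (pr in prot) wide[[pr]] <- fmtNum(npx[pr, ])
  pathWide <- file.path(dir, "npx_wide.tsv")
  writeTSV(wide, pathWide)

  lodTab <- data.frame(protein_id = prot, lod = fmtNum(lod),
                       lod_sd = fmtNum(lodSD(cohort)))
  pathLod <- file.path(dir, "lod.tsv")
  writeTSV(lodTab, pathLod)

  cd <- as.data.frame(colData(cohort))
  clinCols <- intersect(c(clinicalFactorNames(), "sample_status"),
                        colnames(cd))
  clin <- cbind(data.frame(sample_id = samp),
                as.data.frame(lapply(cd[clinCols], as.character)))
  pathClin <- file.path(dir, "clinical.tsv")
  writeTSV(clin, pathClin)

  outc <- data.frame(sample_id = samp,
                     os_months = fmtNum(cd$os_months),
                     os_event = cd$os_event,
                     pfs_months = fmtNum(cd$pfs_months),
                     pfs_event = cd$pfs_event)
  pathOut <- file.path(dir, "outcomes.tsv")
  writeTSV(outc, pathOut)

  truth <- metadata(cohort)$truth
  pathTruth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(planted_effects_os = as.list(truth$plantedEffectsOS),
         planted_effects_pfs = as.list(truth$plantedEffectsPFS),
         covariate_effects = as.list(truth$covariateEffects)),
    pathTruth, auto_unbox = TRUE, digits = NA)

  invisible(c(pathLong, pathWide, pathLod, pathClin, pathOut, pathTruth))
}

#' Read a cohort directory written by writeCohort
#'
#' Also accepts third-party exports of the same shape; the long CSV is used
#' when the wide TSV is absent.
#'
#' @param dir directory containing the cohort files.
#' @return an \linkS4class{NPXExperiment}.
#' @export
readCohort <- function(dir) {
  pathWide <- file.path(dir, "npx_wide.tsv")
  pathLong <- file.path(dir, "npx_long.csv")
  pathLod <- file.path(dir, "lod.tsv")
  if (file.exists(pathWide)) {
    wide <- readTSV(pathWide)
    samp <- wide$sample_id
    npx <- t(as.matrix(wide[, -1, drop = FALSE]))
    colnames(npx) <- samp
    lodTab <- readTSV(pathLod)
    lod <- setNames(lodTab$lod, lodTab$protein_id)[rownames(npx)]
    lodSDv <- setNames(lodTab$lod_sd, lodTab$protein_id)[rownames(npx)]
  } else if (file.exists(pathLong)) {
    long <- utils::read.csv(pathLong, stringsAsFactors = FALSE)
    need <- c("SampleID", "Assay", "NPX", "LOD")
    if (!all(need %in% colnames(long)))
      stop("long CSV must have columns ", paste(need, collapse = ", "))
    samp <- unique(long$SampleID)
    prot <- unique(long$Assay)
    npx <- matrix(NA_real_, nrow = length(prot), ncol = length(samp),
                  dimnames = list(prot, samp))
    npx[cbind(match(long$Assay, prot), match(long$SampleID, samp))] <-
      long$NPX
    lod <- vapply(split(long$LOD, long$Assay), function(v) v[1],
                  numeric(1))[prot]
    lodSDv <- if (file.exists(pathLod)) {
      lodTab <- readTSV(pathLod)
      setNames(lodTab$lod_sd, lodTab$protein_id)[prot]
    } else rep(0, length(prot))
  } else {
    stop("no NPX file found in ", dir)
  }

  cd <- NULL
  pathClin <- file.path(dir, "clinical.tsv")
  if (file.exists(pathClin)) {
    clin <- readTSV(pathClin)
    rownames(clin) <- clin$sample_id
    clin <- clin[colnames(npx), setdiff(colnames(clin), "sample_id"),
                 drop = FALSE]
    lv <- clinicalLevels()
    for (nm in intersect(names(lv), colnames(clin)))
      clin[[nm]] <- factor(clin[[nm]], levels = lv[[nm]])
    cd <- clin
  }
  pathOut <- file.path(dir, "outcomes.tsv")
  if (file.exists(pathOut)) {
    outc <- readTSV(pathOut)
    rownames(outc) <- outc$sample_id
    outc <- outc[colnames(npx), setdiff(colnames(outc), "sample_id"),
                 drop = FALSE]
    cd <- if (is.null(cd)) outc else cbind(cd, outc)
  }
  x <- NPXExperiment(npx, lod = as.numeric(lod), lodSD = as.numeric(lodSDv),
                     colData = cd)
  pathTruth <- file.path(dir, "truth.json")
  if (file.exists(pathTruth)) {
    tr <- jsonlite::read_json(pathTruth, simplifyVector = TRUE)
    metadata(x)$truth <- list(
      plantedEffectsOS = unlist(tr$planted_effects_os),
      plantedEffectsPFS = unlist(tr$planted_effects_pfs),
      covariateEffects = unlist(tr$covariate_effects))
  }
  x
}
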
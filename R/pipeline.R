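## End-to-end orchestration: simulate or load a cohort, preprocess,
## residualize, screen, (optionally) tune, cross-validate, run recursive
## feature elimination, validate with classical and penalized Cox models,
## build rank-concordance and clinicopathological association tables, and
## write a reproducible report bundle.

#' Named analysis profiles
#'
#' \code{full} is the documented protocol (5-fold x 100 tuning CV,
#' 10-fold x 100 evaluation CV); \code{desk} is a reduced-repeat profile
#' (5-fold x 5 tuning, 10-fold x 5 evaluation, 10 RFE repeats) for
#' desk-scale runs.
#'
#' @param name \code{"full"} or \code{"desk"}.
#' @return list of stage repeat settings.
#' @export
analysisProfile <- function(name = c("desk", "full")) {
  name <- match.arg(name)
  if (name == "full")
    list(screenRepeats = 10L, tune = TRUE, tuneCandidates = 25L,
         tuneFolds = 5L, tuneRepeats = 100L, cvFolds = 10L,
         cvRepeats = 100L, rfeFolds = 10L, rfeRepeats = 10L,
         impRepeats = 10L)
  else
    list(screenRepeats = 3L, tune = FALSE, tuneCandidates = 5L,
         tuneFolds = 5L, tuneRepeats = 5L, cvFolds = 10L, cvRepeats = 5L,
         rfeFolds = 3L, rfeRepeats = 1L, impRepeats = 3L)
}

#' Build a run configuration
#'
#' Either \code{inputDir} (a cohort directory readable by
#' \code{\link{readCohort}}) or \code{simulate} (a
#' \linkS4class{CohortConfig}) must be given, not both. A YAML file with the
#' same fields can be supplied instead via \code{yamlPath}; its
#' \code{simulate} block is passed to \code{\link{cohortConfig}}.
#'
#' @param inputDir cohort directory, or NULL.
#' @param simulate a \linkS4class{CohortConfig}, or NULL.
#' @param endpoints subset of c("os", "pfs").
#' @param outDir output directory for the report bundle (NULL = no files).
#' @param profile profile name or list, see \code{\link{analysisProfile}}.
#' @param enetAlpha elastic-net mixing.
#' @param fdrPanelSize panel size m for BH adjustment (NULL = panel width).
#' @param maxLODFraction,knnK preprocessing settings.
#' @param seed global seed.
#' @param yamlPath optional YAML file with these fields.
#' @return validated config list.
#' @export
runConfig <- function(inputDir = NULL, simulate = NULL,
                      endpoints = c("os", "pfs"), outDir = NULL,
                      profile = "desk", enetAlpha = 0.5,
                      fdrPanelSize = NULL, maxLODFraction = 0.15,
                      knnK = 5L, seed = 1L, yamlPath = NULL) {
  if (!is.null(yamlPath)) {
    y <- yaml::read_yaml(yamlPath)
    if (!is.null(y$simulate)) simulate <- do.call(cohortConfig, y$simulate)
    inputDir <- y$input_dir
    if (!is.null(y$endpoints)) endpoints <- y$endpoints
    outDir <- y$out_dir
    if (!is.null(y$profile)) profile <- y$profile
    if (!is.null(y$enet_alpha)) enetAlpha <- y$enet_alpha
    if (!is.null(y$fdr_panel_size)) fdrPanelSize <- y$fdr_panel_size
    if (!is.null(y$seed)) seed <- y$seed
  }
  if (!is.null(inputDir) && !is.null(simulate))
    stop("give either inputDir or a simulate block, not both")
  if (is.null(inputDir) && is.null(simulate))
    stop("one of inputDir or simulate is required")
  if (is.character(profile)) profile <- analysisProfile(profile)
  endpoints <- match.arg(endpoints, c("os", "pfs"), several.ok = TRUE)
  list(inputDir = inputDir, simulate = simulate, endpoints = endpoints,
       outDir = outDir, profile = profile, enetAlpha = enetAlpha,
       fdrPanelSize = fdrPanelSize, maxLODFraction = maxLODFraction,
       knnK = as.integer(knnK), seed = as.integer(seed))
}

#' Set intersection / union sizes of two marker lists
#'
#' @param selectedA,selectedB character vectors of unique protein ids.
#' @return list(intersection, union).
#' @export
reportOverlap <- function(selectedA, selectedB) {
  if (anyDuplicated(selectedA) || anyDuplicated(selectedB))
    stop("marker lists must not contain duplicates")
  list(intersection = length(intersect(selectedA, selectedB)),
       union = length(union(selectedA, selectedB)))
}

formatTable <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 10))
  df
}

#' Run the full analysis pipeline
#'
#' Executes, per endpoint: exclusions, preprocessing, residualization,
#' survival-forest prescreen, optional randomized-grid tuning, repeated
#' cross-validation, recursive feature elimination, univariable and
#' adjusted Cox models with BH q-values for the selected proteins,
#' elastic-net penalized Cox on regressed and un-regressed data, a
#' cross-model rank-concordance table and the clinicopathological
#' association grid; then the OS/PFS marker-set overlap. With the same
#' config and seed, every output is reproduced byte-for-byte.
#'
#' @param config a \code{\link{runConfig}} list.
#' @return list with per-endpoint results, overlap, manifest, and (when
#'   \code{outDir} is set) the written file paths.
#' @export
runPipeline <- function(config) {
  seed <- config$seed
  prof <- config$profile
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("input", {
    if (!is.null(config$simulate)) simulateCohort(config$simulate)
    else readCohort(config$inputDir)
  })
  manifest <- list(seed = seed,
                   n_enrolled = ncol(cohort),
                   endpoints = config$endpoints)

  pp <- stage("preprocess",
              preprocessNPX(cohort, maxFraction = config$maxLODFraction,
                            k = config$knnK))
  x <- pp$retained
  manifest$n_analyzable <- pp$reports$exclusions@nSamplesOut
  manifest$n_samples <- ncol(x)
  manifest$n_proteins <- nrow(x)
  panelSize <- if (is.null(config$fdrPanelSize)) nrow(x)
               else config$fdrPanelSize

  clinical <- clinicalCovariates(x)
  resX <- stage("residualize", residualize(sampleMatrix(x), clinical))
  rawX <- sampleMatrix(x)

  perEndpoint <- list()
  for (ep in config$endpoints) {
    epSeed <- childSeed(seed, match(ep, c("os", "pfs")))
    outc <- survivalOutcome(x, ep)
    scr <- stage("rf_screen",
                 rfScreen(resX, outc, nRepeats = prof$screenRepeats,
                          params = prof$screenParams,
                          seed = childSeed(epSeed, 1)))
    X20 <- resX[, scr$top, drop = FALSE]
    if (isTRUE(prof$tune)) {
      tuned <- stage("tune_rsf",
                     tuneRSF(X20, outc, nCandidates = prof$tuneCandidates,
                             nFolds = prof$tuneFolds,
                             nRepeats = prof$tuneRepeats,
                             seed = childSeed(epSeed, 2)))
      params <- tuned@bestParams
    } else {
      tuned <- NULL
      params <- if (!is.null(prof$params)) prof$params
                else rsfParams(nEstimators = 200L, maxFeatures = 5L,
                               minSamplesLeaf = 5L, minSamplesSplit = 10L)
    }
    cv <- stage("crossval_rsf",
                crossvalRSF(X20, outc, params, nFolds = prof$cvFolds,
                            nRepeats = prof$cvRepeats,
                            seed = childSeed(epSeed, 3)))
    rfe <- stage("rfe",
                 recursiveFeatureElimination(
                   X20, outc, params, nFolds = prof$rfeFolds,
                   nRepeats = prof$rfeRepeats,
                   impRepeats = prof$impRepeats,
                   seed = childSeed(epSeed, 4)))
    selected <- rfe@selectedSet

    coxTab <- stage("cox",
                    coxPanelTable(rawX, outc, clinical,
                                  proteins = selected, m = panelSize,
                                  endpoint = ep))
    enetReg <- stage("enet_regressed",
                     fitElasticNetCox(X20, outc, alpha = config$enetAlpha,
                                      seed = childSeed(epSeed, 5)))
    enetRaw <- stage("enet_unregressed",
                     fitElasticNetCox(rawX[, scr$top, drop = FALSE], outc,
                                      alpha = config$enetAlpha,
                                      seed = childSeed(epSeed, 6)))

    # cross-model ranks over the screened top-20 universe
    univ <- scr$top
    scrImp <- scr$importance[match(univ, scr$importance$protein), ]
    uvP <- vapply(univ, function(pr)
      fitCox(rawX[, pr], outc)$p, numeric(1))
    rfeImp <- match(univ, rfe@ranking)
    rankings <- list(
      rf_screen = rank(-scrImp$median_importance, ties.method = "first"),
      rsf = rank(rfeImp, ties.method = "first"),
      cox = rank(uvP, ties.method = "first"),
      enet_regressed = rank(-enetReg$weights[univ], ties.method = "first"),
      enet_unregressed = rank(-enetRaw$weights[univ],
                              ties.method = "first"))
    rankings <- lapply(rankings, function(r) setNames(r, univ))
    conc <- stage("rank_concordance", rankConcordance(rankings))

    assoc <- stage("associations",
                   associationTable(rawX[, selected, drop = FALSE],
                                    clinical[, setdiff(colnames(clinical),
                                                       "age"),
                                             drop = FALSE]))
    perEndpoint[[ep]] <- list(screen = scr, tuning = tuned, params = params,
                              cv = cv, rfe = rfe, selected = selected,
                              coxTable = coxTab, enetRegressed = enetReg,
                              enetUnregressed = enetRaw,
                              rankConcordance = conc,
                              associations = assoc)
    manifest[[paste0("selected_", ep)]] <- selected
    manifest[[paste0("median_test_c_", ep)]] <- cv$medianTestC
    manifest[[paste0("median_train_c_", ep)]] <- cv$medianTrainC
  }

  overlap <- if (length(config$endpoints) == 2)
    reportOverlap(perEndpoint$os$selected, perEndpoint$pfs$selected)
  else NULL
  if (!is.null(overlap)) {
    manifest$overlap_intersection <- overlap$intersection
    manifest$overlap_union <- overlap$union
  }

  files <- character(0)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    for (ep in names(perEndpoint)) {
      res <- perEndpoint[[ep]]
      w <- function(df, name) {
        path <- file.path(config$outDir, sprintf("%s_%s.tsv", name, ep))
        writeTSV(formatTable(df), path)
        path
      }
      files <- c(files,
                 w(res$coxTable, "cox_table"),
                 w(res$rfe@curve, "rfe_curve"),
                 w(res$screen$importance, "importance"),
                 w(res$rankConcordance$ranks, "rank_concordance"),
                 w(res$associations, "associations"))
    }
    mPath <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, mPath)
  }
  list(endpoints = perEndpoint, overlap = overlap, manifest = manifest,
       files = files)
}
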
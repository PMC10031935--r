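## Cascaded feature selection: covariate residualization, survival-forest
## prescreen (drop the lowest-importance 25%, keep the top 20), randomized
## grid tuning with repeated k-fold CV, repeated 10-fold CV evaluation,
## recursive feature elimination against Harrell's C, and cross-model rank
## concordance.

#' Build the clinical covariate design matrix
#'
#' One shared design builder (used by residualization and the adjusted Cox
#' models, so the two cannot drift): age continuous, the seven categorical
#' factors dummy-coded against their first-listed reference level.
#'
#' @param clinical data.frame with the columns of
#'   \code{\link{clinicalCovariates}}.
#' @param intercept include an intercept column (default TRUE).
#' @return numeric design matrix, samples x columns.
#' @export
covariateDesign <- function(clinical, intercept = TRUE) {
  lv <- clinicalLevels()
  need <- clinicalFactorNames()
  missing <- setdiff(need, colnames(clinical))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  df <- clinical[, need, drop = FALSE]
  for (nm in names(lv)) df[[nm]] <- factor(df[[nm]], levels = lv[[nm]])
  df$age <- as.numeric(df$age)
  df$ctc_ge5 <- as.numeric(df$ctc_ge5)
  fml <- ~ age + ecog + mfi + n_met_sites + site + subtype + nhg + ctc_ge5
  mf <- stats::model.frame(fml, df, na.action = stats::na.pass)
  mm <- model.matrix(fml, mf)
  if (!intercept) mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  mm
}

#' Residualize NPX on the clinical covariates
#'
#' For each protein independently, ordinary least squares of NPX on the
#' eight-covariate design; the output is the residual matrix, orthogonal to
#' every design column.
#'
#' @param X samples x proteins matrix with no NA, or an
#'   \linkS4class{NPXExperiment}.
#' @param clinical clinical covariate data.frame aligned to samples; taken
#'   from \code{colData} when X is an NPXExperiment.
#' @param design optional pre-built design matrix (overrides
#'   \code{clinical}); supply e.g. an intercept-only matrix for mean
#'   centering.
#' @return residual matrix, samples x proteins.
#' @export
residualize <- function(X, clinical = NULL, design = NULL) {
  if (methods::is(X, "NPXExperiment")) {
    if (is.null(clinical)) clinical <- clinicalCovariates(X)
    X <- sampleMatrix(X)
  }
  X <- asSampleMatrix(X)
  if (anyNA(X)) stop("X must not contain NA (run preprocessing first)")
  if (is.null(design)) design <- covariateDesign(clinical)
  if (nrow(design) != nrow(X)) stop("design rows must align with X")
  if (anyNA(design))
    stop("missing covariate values; residualization requires complete ",
         "covariates")
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    dropped <- colnames(design)[qrD$pivot[(qrD$rank + 1):ncol(design)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- X - qr.fitted(qrD, X)
  dimnames(res) <- dimnames(X)
  res
}

medianImportanceTable <- function(impRepeats) {
  # impRepeats: proteins x repeats matrix
  med <- apply(impRepeats, 1, median)
  data.frame(protein = rownames(impRepeats), median_importance = med,
             rank = rank(-med, ties.method = "first"), row.names = NULL)
}

#' Survival-forest prescreen
#'
#' Fits \code{nRepeats} seeded forests with fixed default parameters
#' (untuned survival forests, 500 trees, sqrt features) and permutation
#' importance, takes the per-protein median importance across repeats,
#' removes the ceiling(25\%) lowest-median proteins, and passes the 20
#' highest-median proteins among those retained forward.
#'
#' @param X residualized matrix, samples x proteins (>= 21 proteins).
#' @param outcomes outcomes for one endpoint.
#' @param nRepeats number of seeded forest repeats.
#' @param params screening forest parameters.
#' @param seed integer.
#' @param nTop number of proteins passed forward (default 20).
#' @param dropFraction fraction eliminated (default 0.25).
#' @return list(importance = ImportanceTable data.frame, retained =
#'   character, top = character).
#' @export
rfScreen <- function(X, outcomes, nRepeats = 5L, params = NULL, seed = 1L,
                     nTop = 20L, dropFraction = 0.25) {
  if (nRepeats < 1) stop("nRepeats must be at least 1")
  X <- asSampleMatrix(X)
  if (ncol(X) < nTop + 1) stop("need at least ", nTop + 1, " proteins")
  if (is.null(params))
    params <- rsfParams(nEstimators = 500L, maxFeatures = "sqrt")
  reps <- matrix(NA_real_, nrow = ncol(X), ncol = nRepeats,
                 dimnames = list(colnames(X), NULL))
  for (r in seq_len(nRepeats)) {
    pr <- params
    pr$seed <- childSeed(seed, r)
    forest <- fitRSF(X, outcomes, pr)
    imp <- permutationImportance(forest, X, outcomes, nRepeats = 1L,
                                 seed = childSeed(seed, 1000 + r), oob = TRUE)
    reps[, r] <- imp$importance
  }
  tab <- medianImportanceTable(reps)
  nDrop <- ceiling(dropFraction * ncol(X))
  ord <- order(tab$median_importance, seq_len(nrow(tab)))
  dropped <- tab$protein[ord[seq_len(nDrop)]]
  retained <- setdiff(tab$protein, dropped)
  retTab <- tab[tab$protein %in% retained, ]
  topOrd <- retTab$protein[order(-retTab$median_importance,
                                 seq_len(nrow(retTab)))]
  list(importance = tab, retained = retained,
       top = topOrd[seq_len(min(nTop, length(topOrd)))])
}

#' Repeated k-fold cross-validation of a survival forest
#'
#' Fold assignment is seeded per repeat. Per fold, a forest is fit on the
#' training folds and Harrell's C of the ensemble-mortality risk is scored
#' on both the training and the held-out fold.
#'
#' @param X samples x proteins matrix.
#' @param outcomes outcomes aligned to rows.
#' @param params \code{\link{rsfParams}}.
#' @param nFolds folds (protocol default 10).
#' @param nRepeats repeats (protocol default 100; desk-scale runs use fewer).
#' @param seed integer.
#' @return list(trainC, testC — numeric of length nFolds * nRepeats,
#'   medianTrainC, medianTestC).
#' @export
crossvalRSF <- function(X, outcomes, params = rsfParams(), nFolds = 10L,
                        nRepeats = 100L, seed = 1L) {
  X <- asSampleMatrix(X)
  o <- asOutcome(outcomes)
  n <- nrow(X)
  if (nFolds > n) stop("more folds than samples")
  trainC <- testC <- numeric(0)
  for (r in seq_len(nRepeats)) {
    folds <- foldAssignment(n, nFolds, childSeed(seed, r))
    for (f in seq_len(nFolds)) {
      tr <- folds != f
      pr <- params
      pr$seed <- childSeed(seed, r * 100 + f)
      forest <- fitRSF(X[tr, , drop = FALSE],
                       list(time = o$time[tr], event = o$event[tr]), pr)
      riskTr <- predictRisk(forest, X[tr, , drop = FALSE])
      riskTe <- predictRisk(forest, X[!tr, , drop = FALSE])
      trainC <- c(trainC, harrellC(list(time = o$time[tr],
                                        event = o$event[tr]), riskTr))
      testC <- c(testC, harrellC(list(time = o$time[!tr],
                                      event = o$event[!tr]), riskTe))
    }
  }
  list(trainC = trainC, testC = testC,
       medianTrainC = median(trainC), medianTestC = median(testC))
}

#' Randomized-grid hyperparameter tuning
#'
#' Samples \code{nCandidates} configurations uniformly from the grid and
#' scores each by repeated \code{nFolds}-fold cross-validated test C
#' (protocol: 5-fold repeated 100 times); returns the configuration with the
#' maximal median test C.
#'
#' @param X the 20-protein matrix from \code{\link{rfScreen}}.
#' @param outcomes outcomes aligned to rows.
#' @param grid named list of candidate values for \code{nEstimators},
#'   \code{maxFeatures}, \code{minSamplesLeaf}, \code{minSamplesSplit}.
#' @param nCandidates configurations to sample.
#' @param nFolds,nRepeats CV shape (protocol 5 x 100).
#' @param seed integer.
#' @return a \linkS4class{TuningResult}.
#' @export
tuneRSF <- function(X, outcomes, grid = defaultTuningGrid(),
                    nCandidates = 25L, nFolds = 5L, nRepeats = 100L,
                    seed = 1L) {
  if (nCandidates < 1) stop("nCandidates must be at least 1")
  need <- c("nEstimators", "maxFeatures", "minSamplesLeaf",
            "minSamplesSplit")
  if (!all(need %in% names(grid)) ||
      any(vapply(grid[need], length, 1L) == 0))
    stop("grid must cover ", paste(need, collapse = ", "))
  set.seed(childSeed(seed, 77))
  draw <- function(v) v[sample.int(length(v), 1)]
  cands <- list()
  guard <- 0
  while (length(cands) < nCandidates && guard < nCandidates * 50) {
    guard <- guard + 1
    cand <- list(nEstimators = draw(grid$nEstimators),
                 maxFeatures = draw(grid$maxFeatures),
                 minSamplesLeaf = draw(grid$minSamplesLeaf),
                 minSamplesSplit = draw(grid$minSamplesSplit))
    if (cand$minSamplesSplit < 2 * cand$minSamplesLeaf) next
    cands[[length(cands) + 1]] <- cand
  }
  if (!length(cands)) stop("grid admits no valid configuration")
  cvC <- vector("list", length(cands))
  meds <- numeric(length(cands))
  for (i in seq_along(cands)) {
    pr <- rsfParams(cands[[i]]$nEstimators, cands[[i]]$maxFeatures,
                    cands[[i]]$minSamplesLeaf, cands[[i]]$minSamplesSplit)
    cv <- crossvalRSF(X, outcomes, pr, nFolds = nFolds,
                      nRepeats = nRepeats, seed = childSeed(seed, i))
    cvC[[i]] <- cv$testC
    meds[i] <- cv$medianTestC
  }
  candDF <- do.call(rbind, lapply(cands, function(cand)
    data.frame(nEstimators = cand$nEstimators,
               maxFeatures = as.character(cand$maxFeatures),
               minSamplesLeaf = cand$minSamplesLeaf,
               minSamplesSplit = cand$minSamplesSplit)))
  candDF$median_c <- meds
  best <- which.max(meds)
  bestParams <- rsfParams(cands[[best]]$nEstimators,
                          cands[[best]]$maxFeatures,
                          cands[[best]]$minSamplesLeaf,
                          cands[[best]]$minSamplesSplit)
  methods::new("TuningResult", candidates = candDF, cvC = cvC,
               bestParams = bestParams)
}

#' Default randomized tuning grid
#' @return named list of candidate hyperparameter values.
#' @export
defaultTuningGrid <- function() {
  list(nEstimators = seq(100L, 1000L, by = 100L),
       maxFeatures = 2:10,
       minSamplesLeaf = 3:15,
       minSamplesSplit = 6:30)
}

#' Recursive feature elimination against Harrell's C
#'
#' Orders proteins by descending median cross-validated permutation
#' importance, evaluates the top-k set for k = 1..p by
#' \code{\link{crossvalRSF}}, and selects the k maximizing the median test
#' C (ties broken toward smaller k).
#'
#' @param X samples x proteins matrix (the screened top-20 set).
#' @param outcomes outcomes aligned to rows.
#' @param params \code{\link{rsfParams}} (the tuned best parameters).
#' @param importance optional data.frame(protein, median_importance); when
#'   absent it is computed by CV permutation importance with
#'   \code{impRepeats} repeats.
#' @param nFolds,nRepeats CV shape for the per-k curve.
#' @param impRepeats permutation-importance repeats.
#' @param seed integer.
#' @return an \linkS4class{RFEResult}.
#' @export
recursiveFeatureElimination <- function(X, outcomes, params = rsfParams(),
                                        importance = NULL, nFolds = 10L,
                                        nRepeats = 3L, impRepeats = 3L,
                                        seed = 1L) {
  X <- asSampleMatrix(X)
  if (is.null(importance)) {
    imp <- cvImportance(X, outcomes, params, nRepeats = impRepeats,
                        seed = childSeed(seed, 31))
  } else {
    if (!all(colnames(X) %in% importance$protein))
      stop("importance table missing protein(s): ",
           paste(setdiff(colnames(X), importance$protein), collapse = ", "))
    imp <- importance[match(colnames(X), importance$protein), ]
  }
  ranking <- imp$protein[order(-imp$median_importance,
                               seq_len(nrow(imp)))]
  p <- ncol(X)
  medC <- numeric(p)
  for (k in seq_len(p)) {
    sel <- ranking[seq_len(k)]
    cv <- crossvalRSF(X[, sel, drop = FALSE], outcomes, params,
                      nFolds = nFolds, nRepeats = nRepeats, seed = seed)
    medC[k] <- cv$medianTestC
  }
  bestK <- which(medC >= max(medC) - 1e-12)[1]  # parsimony on ties
  methods::new("RFEResult",
    curve = data.frame(n_features = seq_len(p), median_test_c = medC),
    ranking = ranking,
    selectedSet = ranking[seq_len(bestK)], selectedSize = as.integer(bestK),
    settings = list(nFolds = nFolds, nRepeats = nRepeats, seed = seed))
}

# median permutation importance across seeded forests (used when RFE is not
# handed an importance table)
cvImportance <- function(X, outcomes, params, nRepeats = 3L, seed = 1L) {
  reps <- matrix(NA_real_, nrow = ncol(X), ncol = nRepeats,
                 dimnames = list(colnames(X), NULL))
  for (r in seq_len(nRepeats)) {
    pr <- params
    pr$seed <- childSeed(seed, r)
    forest <- fitRSF(X, outcomes, pr)
    imp <- permutationImportance(forest, X, outcomes, nRepeats = 1L,
                                 seed = childSeed(seed, 500 + r), oob = TRUE)
    reps[, r] <- imp$importance
  }
  medianImportanceTable(reps)
}

#' Cross-model rank concordance
#'
#' Table of per-model ranks per protein, Spearman rank correlation between
#' every model pair, and top-k set-overlap summaries.
#'
#' @param rankings named list: model name -> named numeric of per-protein
#'   ranks (1 = most important) over a shared protein universe.
#' @param k top-k size for the overlap summaries (default 10).
#' @return list(ranks = data.frame, spearman = matrix, overlap = data.frame).
#' @export
rankConcordance <- function(rankings, k = 10L) {
  if (length(rankings) < 2) stop("need at least two models")
  univ <- Reduce(intersect, lapply(rankings, names))
  if (!length(univ)) stop("models share no proteins")
  ranks <- vapply(rankings, function(r) r[univ], numeric(length(univ)))
  rownames(ranks) <- univ
  sp <- stats::cor(ranks, method = "spearman")
  models <- colnames(ranks)
  ov <- list()
  for (i in seq_along(models)) for (j in seq_along(models)) {
    if (j <= i) next
    ti <- univ[order(ranks[, i])][seq_len(min(k, length(univ)))]
    tj <- univ[order(ranks[, j])][seq_len(min(k, length(univ)))]
    ov[[length(ov) + 1]] <- data.frame(
      model_a = models[i], model_b = models[j],
      intersection = length(intersect(ti, tj)),
      union = length(union(ti, tj)))
  }
  list(ranks = data.frame(protein = univ, ranks, check.names = FALSE,
                          row.names = NULL),
       spearman = sp, overlap = do.call(rbind, ov))
}
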
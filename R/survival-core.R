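## Right-censored survival machinery: Harrell's C, Nelson-Aalen, the
## two-group log-rank statistic, and the random survival forest (log-rank
## splits, Nelson-Aalen leaves, ensemble-mortality risk). The tree engine
## lives in src/rsf.cpp.

#' Harrell's concordance index
#'
#' Over comparable pairs (i, j) with time_i < time_j and event_i = 1, credit
#' 1 when risk_i > risk_j, 0.5 on risk ties, 0 otherwise; pairs tied on time
#' are not comparable. Invariant under strictly monotone transforms of the
#' risk score.
#'
#' @param outcomes a \code{survival::Surv} object or data.frame(time, event).
#' @param risk numeric per-sample risk score (higher = higher risk).
#' @return concordance fraction in [0, 1].
#' @export
harrellC <- function(outcomes, risk) {
  o <- asOutcome(outcomes)
  if (length(risk) != length(o$time))
    stop("risk must align with outcomes")
  cval <- cppHarrellC(o$time, o$event, as.numeric(risk))
  if (cval < 0) stop("no comparable pair (all samples censored?)")
  cval
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' At each distinct event time t the hazard increments by d(t) / n_at_risk(t);
#' censored-only times contribute no increment.
#'
#' @param outcomes a Surv object or data.frame(time, event).
#' @return data.frame with columns \code{time} (distinct event times) and
#'   \code{hazard} (non-decreasing cumulative hazard).
#' @export
nelsonAalen <- function(outcomes) {
  o <- asOutcome(outcomes)
  if (!length(o$time)) stop("empty input")
  ord <- order(o$time)
  t <- o$time[ord]; e <- o$event[ord]
  ut <- unique(t[e == 1])
  if (!length(ut))
    return(data.frame(time = numeric(0), hazard = numeric(0)))
  H <- 0
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(e == 1 & t == ut[i])
    nrisk <- sum(t >= ut[i])
    H <- H + d / nrisk
    out[i] <- H
  }
  data.frame(time = ut, hazard = out)
}

#' Two-group log-rank split statistic
#'
#' Standardized statistic (O - E)^2 / V summed over distinct event times with
#' the hypergeometric variance; larger values indicate better separation.
#' Degenerate groups (no at-risk mass) yield 0.
#'
#' @param outcomes a Surv object or data.frame(time, event).
#' @param membership logical or 0/1 vector (left/right group).
#' @return non-negative statistic.
#' @export
logrankSplitStat <- function(outcomes, membership) {
  o <- asOutcome(outcomes)
  grp <- as.integer(membership)
  if (length(grp) != length(o$time))
    stop("membership must align with outcomes")
  if (all(grp == grp[1])) stop("both groups must be non-empty")
  cppLogrankStat(o$time, o$event, grp)
}

#' Random survival forest parameters
#'
#' @param nEstimators number of trees.
#' @param maxFeatures candidate proteins per split: an integer, or a fraction
#'   in (0, 1] of the protein count, or \code{"sqrt"}.
#' @param minSamplesLeaf minimum (bootstrap) samples per leaf.
#' @param minSamplesSplit minimum samples to attempt a split; must be at
#'   least \code{2 * minSamplesLeaf}.
#' @param seed integer.
#' @return a validated parameter list.
#' @export
rsfParams <- function(nEstimators = 500L, maxFeatures = "sqrt",
                      minSamplesLeaf = 5L, minSamplesSplit = 10L,
                      seed = 1L) {
  p <- list(nEstimators = as.integer(nEstimators), maxFeatures = maxFeatures,
            minSamplesLeaf = as.integer(minSamplesLeaf),
            minSamplesSplit = as.integer(minSamplesSplit),
            seed = as.integer(seed))
  if (p$nEstimators < 1 || p$minSamplesLeaf < 1 || p$minSamplesSplit < 2)
    stop("rsf parameters must be positive")
  if (p$minSamplesSplit < 2 * p$minSamplesLeaf)
    stop("minSamplesSplit must be >= 2 * minSamplesLeaf")
  p
}

resolveMtry <- function(maxFeatures, p) {
  if (identical(maxFeatures, "sqrt")) return(max(1L, as.integer(sqrt(p))))
  if (!is.numeric(maxFeatures) || maxFeatures <= 0)
    stop("maxFeatures must be positive, a fraction, or \"sqrt\"")
  if (maxFeatures < 1) return(max(1L, as.integer(maxFeatures * p)))
  min(as.integer(maxFeatures), p)
}

#' Fit a random survival forest
#'
#' Grows \code{nEstimators} trees on bootstrap resamples. At each node,
#' \code{maxFeatures} candidate proteins are drawn without replacement and
#' the best (protein, threshold) pair by the log-rank statistic is taken,
#' with thresholds at midpoints between sorted distinct values and ties
#' broken toward the lowest protein index then lowest threshold. Leaves
#' store Nelson-Aalen cumulative hazards on the shared event-time grid.
#'
#' @param X numeric matrix, samples x proteins (no NA).
#' @param outcomes a Surv object or data.frame(time, event) aligned to rows.
#' @param params an \code{\link{rsfParams}} list.
#' @return a \linkS4class{RandomSurvivalForest}.
#' @export
fitRSF <- function(X, outcomes, params = rsfParams()) {
  X <- asSampleMatrix(X)
  if (anyNA(X)) stop("X must not contain NA (run preprocessing first)")
  o <- asOutcome(outcomes)
  if (nrow(X) != length(o$time)) stop("X rows must align with outcomes")
  if (sum(o$event) < params$minSamplesLeaf)
    stop("fewer events than minSamplesLeaf")
  mtry <- resolveMtry(params$maxFeatures, ncol(X))
  fit <- cppFitRSF(X, o$time, o$event, params$nEstimators, mtry,
                   params$minSamplesLeaf, params$minSamplesSplit,
                   params$seed)
  methods::new("RandomSurvivalForest",
    trees = fit$trees, grid = as.numeric(fit$grid), inbag = fit$inbag,
    proteinIds = colnames(X), params = params, seed = params$seed)
}

#' Predict ensemble-mortality risk
#'
#' The risk score is the ensemble mortality: the mean over trees of the leaf
#' cumulative hazard summed over the shared event-time grid. Higher scores
#' mean higher predicted risk.
#'
#' @param forest a \linkS4class{RandomSurvivalForest}.
#' @param X samples x proteins matrix containing the forest's proteins.
#' @param oob if TRUE, average only over trees where each sample is
#'   out-of-bag (X must then be the training matrix, row-aligned).
#' @return numeric risk per sample.
#' @export
predictRisk <- function(forest, X, oob = FALSE) {
  X <- asSampleMatrix(X, forest@proteinIds)
  if (oob) {
    if (nrow(X) != nrow(forest@inbag))
      stop("oob prediction requires the training matrix")
    cppPredictMortality(forest@trees, X, forest@inbag)
  } else {
    cppPredictMortality(forest@trees, X, NULL)
  }
}

#' Permutation importance
#'
#' importance(p) = mean over repeats of C(original) - C(X with column p
#' permuted), evaluated out-of-bag (default) or on a supplied evaluation
#' set. A protein never used in any split has importance exactly 0.
#'
#' @param forest a \linkS4class{RandomSurvivalForest}.
#' @param X evaluation matrix, samples x proteins.
#' @param outcomes outcomes aligned to X rows.
#' @param nRepeats number of permutation repeats.
#' @param seed permutation RNG seed.
#' @param oob evaluate out-of-bag (X must be the training matrix).
#' @return data.frame: protein, importance (mean over repeats), and the
#'   per-repeat matrix as attribute \code{"repeats"}.
#' @export
permutationImportance <- function(forest, X, outcomes, nRepeats = 5L,
                                  seed = 1L, oob = TRUE) {
  if (nRepeats < 1) stop("nRepeats must be at least 1")
  X <- asSampleMatrix(X, forest@proteinIds)
  o <- asOutcome(outcomes)
  if (nrow(X) != length(o$time)) stop("X rows must align with outcomes")
  imp <- cppPermImportance(forest@trees, X, o$time, o$event,
                           as.integer(nRepeats), as.integer(seed),
                           if (oob) forest@inbag else NULL)
  rownames(imp) <- forest@proteinIds
  res <- data.frame(protein = forest@proteinIds,
                    importance = rowMeans(imp), row.names = NULL)
  attr(res, "repeats") <- imp
  res
}

#' Serialize a forest to JSON
#'
#' @param forest a \linkS4class{RandomSurvivalForest}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeForestJSON <- function(forest, path) {
  jsonlite::write_json(
    list(grid = forest@grid, params = forest@params,
         proteins = forest@proteinIds,
         trees = lapply(forest@trees, function(tr)
           list(var = tr$var, thr = tr$thr, left = tr$left,
                right = tr$right, leafRow = tr$leafRow,
                leafCHF = tr$leafCHF))),
    path, digits = NA)
  invisible(path)
}
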
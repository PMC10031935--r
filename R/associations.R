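## Median-dichotomized marker associations with clinicopathological
## features: Fisher's exact test for two-level features, logistic-regression
## odds ratios (vs the first-listed reference level) for multi-level ones.

#' Dichotomize a marker at its median
#'
#' Values <= median are labelled \code{low}, values > median \code{high}
#' (ties at the median go to low, for determinism).
#'
#' @param values per-sample NPX for one protein (>= 2 samples).
#' @param protein optional protein id carried in the result.
#' @return list(protein, cutoff, labels — factor low/high).
#' @export
dichotomizeAtMedian <- function(values, protein = NA_character_) {
  if (length(values) < 2) stop("need at least 2 samples")
  if (anyNA(values)) stop("values must not contain NA")
  if (length(unique(values)) == 1)
    stop("all values identical; no contrast at the median")
  cutoff <- median(values)
  labels <- factor(ifelse(values > cutoff, "high", "low"),
                   levels = c("low", "high"))
  list(protein = protein, cutoff = cutoff, labels = labels)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass method (the sum of hypergeometric
#' probabilities, at fixed margins, of all tables at most as probable as the
#' observed one). The reported OR is the cross-product ratio ad/bc; a zero
#' margin yields p = 1 with OR flagged NA.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list(or, p, flagged).
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(or = NA_real_, p = 1, flagged = TRUE))
  p <- stats::fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(or = or, p = min(p, 1), flagged = FALSE)
}

#' Logistic-regression odds ratios for a multi-level feature
#'
#' Logistic regression of marker-high (outcome) on the dummy-coded feature
#' levels; per-level OR = exp(coefficient) versus the first (reference)
#' level, with Wald CI and p.
#'
#' @param marker a \code{\link{dichotomizeAtMedian}} result (or a low/high
#'   factor).
#' @param feature factor; its first level is the reference.
#' @return data.frame: level, n, or, ci_lower, ci_upper, p, test, flagged
#'   (reference row has or = 1).
#' @export
logisticOR <- function(marker, feature) {
  labels <- if (is.list(marker)) marker$labels else marker
  feature <- droplevels(as.factor(feature))
  if (nlevels(feature) < 2) stop("feature needs at least 2 levels")
  if (any(table(feature) == 0)) stop("every feature level must be non-empty")
  y <- as.integer(labels == "high")
  fit <- suppressWarnings(
    stats::glm(y ~ feature, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-9, maxit = 100)))
  cf <- summary(fit)$coefficients
  lv <- levels(feature)
  out <- data.frame(level = lv[1], n = sum(feature == lv[1]),
                    or = 1, ci_lower = NA_real_, ci_upper = NA_real_,
                    p = NA_real_, test = "logistic", flagged = FALSE)
  for (i in seq_along(lv)[-1]) {
    nm <- paste0("feature", lv[i])
    b <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
    flagged <- !fit$converged || abs(b) > 10 || se > 100
    out <- rbind(out, data.frame(
      level = lv[i], n = sum(feature == lv[i]),
      or = exp(b), ci_lower = exp(b - 1.96 * se),
      ci_upper = exp(b + 1.96 * se),
      p = 2 * stats::pnorm(-abs(b / se)), test = "logistic",
      flagged = flagged))
  }
  out
}

#' Marker x feature association grid
#'
#' For each dichotomized marker and each clinicopathological feature:
#' Fisher's exact test when the feature has two levels, logistic regression
#' odds ratios against the reference level when it has three or more.
#' Samples missing a feature are dropped for that feature and counted.
#'
#' @param X samples x proteins matrix of NPX values for the selected
#'   markers.
#' @param features data.frame of per-sample categorical features (factors;
#'   NA allowed).
#' @return data.frame in a long Table-style layout: marker, feature, level,
#'   n, or, ci_lower, ci_upper, p, test (\code{"fisher"} = a,
#'   \code{"logistic"} = b), n_missing, flagged.
#' @export
associationTable <- function(X, features) {
  X <- asSampleMatrix(X)
  if (nrow(X) != nrow(features))
    stop("features must align with the samples of X")
  rows <- list()
  for (mk in colnames(X)) {
    di <- dichotomizeAtMedian(X[, mk], protein = mk)
    for (ft in colnames(features)) {
      fv <- features[[ft]]
      keep <- !is.na(fv)
      nMissing <- sum(!keep)
      f <- droplevels(as.factor(fv[keep]))
      lab <- di$labels[keep]
      if (nlevels(f) < 2) next
      if (nlevels(f) == 2) {
        tab <- table(f, lab)[, c("low", "high")]
        ft2 <- fisherExact2x2(tab)
        lv <- levels(f)
        rows[[length(rows) + 1]] <- data.frame(
          marker = mk, feature = ft, level = lv[1],
          n = sum(f == lv[1]), or = 1, ci_lower = NA_real_,
          ci_upper = NA_real_, p = NA_real_, test = "fisher",
          n_missing = nMissing, flagged = FALSE)
        # cross-product OR of the level-2 row vs reference
        orTab <- (tab[2, "high"] * tab[1, "low"]) /
          (tab[2, "low"] * tab[1, "high"])
        rows[[length(rows) + 1]] <- data.frame(
          marker = mk, feature = ft, level = lv[2],
          n = sum(f == lv[2]),
          or = ifelse(ft2$flagged, NA_real_, orTab),
          ci_lower = NA_real_, ci_upper = NA_real_, p = ft2$p,
          test = "fisher", n_missing = nMissing, flagged = ft2$flagged)
      } else {
        lr <- logisticOR(lab, f)
        lr$marker <- mk
        lr$feature <- ft
        lr$n_missing <- nMissing
        rows[[length(rows) + 1]] <-
          lr[, c("marker", "feature", "level", "n", "or", "ci_lower",
                 "ci_upper", "p", "test", "n_missing", "flagged")]
      }
    }
  }
  do.call(rbind, rows)
}
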
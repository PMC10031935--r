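## Classical and elastic-net penalized Cox regression with per-doubling
## hazard ratios, Wald inference, Benjamini-Hochberg q-values over the full
## panel, and the two-threshold evidence classification.

#' Univariable / multivariable Cox regression per protein
#'
#' Maximizes the Cox partial likelihood (Efron ties, Newton-Raphson) for one
#' protein's log2 NPX values; because the predictor is on a log2 scale,
#' exp(beta) is the hazard ratio per doubling of protein content. The
#' adjusted model adds the shared eight-covariate design of
#' \code{\link{covariateDesign}}. Samples with missing covariates are
#' dropped complete-case and the dropped count is recorded.
#'
#' @param x numeric per-sample log2 NPX of one protein (no NA).
#' @param outcomes a Surv object or data.frame(time, event).
#' @param adjust optional clinical covariate data.frame (triggers the
#'   multivariable model).
#' @return data.frame row: beta, se, hr, ci_lower, ci_upper, p, n, n_events,
#'   n_dropped, adjusted, converged, flagged (separation / non-convergence).
#' @export
fitCox <- function(x, outcomes, adjust = NULL) {
  o <- asOutcome(outcomes)
  if (anyNA(x)) stop("x must not contain NA")
  if (length(x) != length(o$time)) stop("x must align with outcomes")
  if (sum(o$event) < 2) stop("need at least 2 events")
  df <- data.frame(time = o$time, event = o$event, x = as.numeric(x))
  if (!is.null(adjust)) {
    design <- covariateDesign(adjust, intercept = FALSE)
    keep <- complete.cases(design)
    df <- cbind(df, as.data.frame(design))
    df <- df[keep, , drop = FALSE]
    nDropped <- sum(!keep)
    covNames <- colnames(design)
  } else {
    nDropped <- 0L
    covNames <- character(0)
  }
  rhs <- paste(c("x", sprintf("`%s`", covNames)), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(fml, data = df, ties = "efron",
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 100)))
      attr(f, "flagged") <- conditionMessage(w)
      f
    })
  beta <- unname(stats::coef(fit)["x"])
  se <- sqrt(diag(fit$var))[match("x", names(stats::coef(fit)))]
  flagged <- !is.null(attr(fit, "flagged")) || !is.finite(beta) ||
    !is.finite(se) || abs(beta) > 15
  p <- if (is.finite(beta) && is.finite(se) && se > 0)
    2 * stats::pnorm(-abs(beta / se)) else NA_real_
  data.frame(beta = beta, se = se, hr = exp(beta),
             ci_lower = exp(beta - 1.96 * se),
             ci_upper = exp(beta + 1.96 * se),
             p = p, n = nrow(df), n_events = sum(df$event),
             n_dropped = nDropped, adjusted = !is.null(adjust),
             converged = !flagged, flagged = flagged)
}

#' Elastic-net penalized Cox regression
#'
#' Cyclic coordinate descent on the penalized partial likelihood with the
#' mixing penalty lambda * [alpha L1 + (1 - alpha)/2 L2]; lambda selected by
#' cross-validated partial-likelihood deviance. Variable weights are the
#' absolute standardized coefficients at the selected lambda and are used
#' for ranking.
#'
#' @param X samples x proteins matrix (regressed or un-regressed).
#' @param outcomes outcomes aligned to rows.
#' @param alpha elastic-net mixing in [0, 1] (default 0.5).
#' @param lambda optional lambda path.
#' @param nFolds CV folds.
#' @param seed fold-assignment seed.
#' @param thresh coordinate-descent convergence threshold.
#' @return list(fit, cvfit, lambda, coef — named coefficients on the
#'   original scale at the selected lambda, weights — |standardized
#'   coefficient| ranking weights, allZero flag).
#' @export
fitElasticNetCox <- function(X, outcomes, alpha = 0.5, lambda = NULL,
                             nFolds = 10L, seed = 1L, thresh = 1e-11) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  X <- asSampleMatrix(X)
  o <- asOutcome(outcomes)
  if (sum(o$event) < 2) stop("need at least 2 events")
  y <- survival::Surv(o$time, o$event)
  foldid <- foldAssignment(nrow(X), nFolds, childSeed(seed, 3))
  cvfit <- glmnet::cv.glmnet(X, y, family = "cox", alpha = alpha,
                             lambda = lambda, foldid = foldid,
                             standardize = TRUE, thresh = thresh)
  sel <- cvfit$lambda.min
  cf <- as.numeric(stats::coef(cvfit, s = sel))
  names(cf) <- colnames(X)
  sds <- apply(X, 2, sd)
  weights <- abs(cf * sds)
  list(fit = cvfit$glmnet.fit, cvfit = cvfit, lambda = sel, alpha = alpha,
       coef = cf, weights = weights, allZero = all(cf == 0))
}

#' Benjamini-Hochberg q-values over the protein panel
#'
#' Step-up adjustment with the full panel size m (the protocol uses the full
#' 92-protein panel even when fewer fits converge; non-converged fits carry
#' p = 1): q(i) = min over j >= i of p(j) * m / j on the sorted scale,
#' capped at 1.
#'
#' @param p numeric P values in (0, 1].
#' @param m panel size, at least \code{length(p)}.
#' @return q values in input order.
#' @export
bhQValues <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p values must lie in (0, 1]")
  if (m < length(p)) stop("m must be at least length(p)")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Two-threshold evidence classification
#'
#' \code{significant} for P < 0.005, \code{suggestive} for
#' 0.005 <= P < 0.05, \code{weak} otherwise.
#'
#' @param p numeric P values in (0, 1].
#' @return character vector.
#' @export
classifyEvidence <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p values must lie in (0, 1]")
  ifelse(p < 0.005, "significant",
         ifelse(p < 0.05, "suggestive", "weak"))
}

#' Per-protein Cox validation table
#'
#' Runs univariable and covariate-adjusted Cox models for a set of proteins
#' against one endpoint, attaches BH q-values computed over the full panel
#' (with p = 1 substituted for flagged fits) and the evidence class.
#'
#' @param X samples x proteins matrix of log2 NPX (typically un-regressed).
#' @param outcomes one endpoint's outcomes.
#' @param clinical clinical covariates for the adjusted models.
#' @param proteins proteins to report (default: all columns); q-values are
#'   computed from the P values of all columns of X with panel size
#'   \code{m}.
#' @param m FDR panel size (default \code{ncol(X)}).
#' @param endpoint label stored in the output.
#' @return data.frame in a per-protein table layout: protein, endpoint, then
#'   uv_/mv_ hr, ci, p, q and evidence columns.
#' @export
coxPanelTable <- function(X, outcomes, clinical, proteins = NULL,
                          m = NULL, endpoint = "os") {
  X <- asSampleMatrix(X)
  if (is.null(m)) m <- ncol(X)
  if (is.null(proteins)) proteins <- colnames(X)
  runOne <- function(adjust) {
    rows <- lapply(colnames(X), function(pr)
      fitCox(X[, pr], outcomes, adjust = adjust))
    do.call(rbind, rows)
  }
  uv <- runOne(NULL)
  mv <- runOne(clinical)
  pFix <- function(tab) ifelse(tab$flagged | is.na(tab$p), 1, tab$p)
  qUV <- bhQValues(pFix(uv), m = m)
  qMV <- bhQValues(pFix(mv), m = m)
  idx <- match(proteins, colnames(X))
  data.frame(protein = proteins, endpoint = endpoint,
             uv_hr = uv$hr[idx], uv_ci_lower = uv$ci_lower[idx],
             uv_ci_upper = uv$ci_upper[idx], uv_p = uv$p[idx],
             uv_q = qUV[idx],
             uv_evidence = classifyEvidence(pFix(uv))[idx],
             mv_hr = mv$hr[idx], mv_ci_lower = mv$ci_lower[idx],
             mv_ci_upper = mv$ci_upper[idx], mv_p = mv$p[idx],
             mv_q = qMV[idx],
             mv_evidence = classifyEvidence(pFix(mv))[idx],
             mv_n_dropped = mv$n_dropped[idx],
             flagged = uv$flagged[idx] | mv$flagged[idx],
             row.names = NULL)
}
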
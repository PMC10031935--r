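## Synthetic cohort generation: the generative mirror of the analysis model.
## Latent log2 NPX from a block-correlated Gaussian, covariate-linked shifts,
## Weibull proportional-hazards OS/PFS whose linear predictor is
## sum(per-doubling log-HR x centered NPX) + covariate effects + shared
## frailty, independent exponential censoring calibrated to a target rate,
## empirical per-protein LOD quantiles, and an availability manifest.

clinicalFactorNames <- function() {
  c("age", "ecog", "mfi", "n_met_sites", "site", "subtype", "nhg", "ctc_ge5")
}

clinicalLevels <- function() {
  list(ecog = c("0", "1", "2"),
       mfi = c("0", "0-3", ">=3"),
       n_met_sites = c("<3", ">=3"),
       site = c("non_visceral", "visceral"),
       subtype = c("ER+HER2-", "HER2+", "TNBC"),
       nhg = c("I-II", "III"))
}

# category frequencies of a newly diagnosed MBC cohort (observational-study
# baseline tables): ECOG 0 ~57%, visceral ~59%, ER+HER2- ~71%, etc.
clinicalFrequencies <- function() {
  list(ecog = c(0.57, 0.27, 0.16),
       mfi = c(0.21, 0.18, 0.61),
       n_met_sites = c(0.71, 0.29),
       site = c(0.41, 0.59),
       subtype = c(0.71, 0.11, 0.18),
       nhg = c(0.62, 0.38),
       ctc_ge5 = 0.51)
}

#' Synthetic cohort configuration
#'
#' Builds a \linkS4class{CohortConfig}. Defaults emulate a 156-patient
#' metastatic breast cancer cohort profiled on a 92-protein immuno-oncology
#' NPX panel: three correlated protein blocks, 5\% LOD quantile, ~13\% of
#' samples unavailable or QC-failed, Weibull baseline with median OS around
#' 36 months and median PFS around 9 months, 30\% censoring.
#'
#' @param nSamples,nProteins cohort dimensions.
#' @param correlationBlocks list of \code{c(size, rho)}; proteins not covered
#'   by a block are independent.
#' @param plantedEffectsOS,plantedEffectsPFS named numeric, log hazard ratio
#'   per doubling (per NPX unit) keyed by protein id (\code{"P001"}...).
#' @param covariateEffects named numeric of log-HRs keyed by design column
#'   (see \code{\link{covariateDesign}}).
#' @param confounding data.frame with columns \code{protein},
#'   \code{covariate_column}, \code{shift} (NPX units per design-column unit).
#' @param lodQuantile fraction of each protein's distribution below its LOD.
#' @param lodSD per-protein SD of the LOD estimate (NPX units).
#' @param censoringRate target censored fraction per endpoint.
#' @param baselineShape,baselineScaleOS,baselineScalePFS Weibull baseline;
#'   default scales put median OS at 36 and median PFS at 9 months.
#' @param frailtySD SD of the per-sample Gaussian frailty shared by the OS
#'   and PFS linear predictors (couples the two endpoints).
#' @param missingSampleFraction fraction of samples flagged unavailable.
#' @param seed integer.
#' @return a \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nSamples = 156L, nProteins = 92L,
                         correlationBlocks = list(c(10, 0.6), c(10, 0.4),
                                                  c(8, 0.3)),
                         plantedEffectsOS = numeric(0),
                         plantedEffectsPFS = numeric(0),
                         covariateEffects = c("age" = 0.01, "ecog1" = 0.2,
                                              "ecog2" = 0.5,
                                              "sitevisceral" = 0.3,
                                              "n_met_sites>=3" = 0.3,
                                              "subtypeTNBC" = 0.4,
                                              "ctc_ge5" = 0.4),
                         confounding = NULL,
                         lodQuantile = 0.05, lodSD = 0.1,
                         censoringRate = 0.3,
                         baselineShape = 1.2,
                         baselineScaleOS = 36 / log(2)^(1 / 1.2),
                         baselineScalePFS = 9 / log(2)^(1 / 1.2),
                         frailtySD = 0.5,
                         missingSampleFraction = 0,
                         seed = 1L) {
  if (is.null(confounding))
    confounding <- data.frame(protein = character(),
                              covariate_column = character(),
                              shift = numeric())
  methods::new("CohortConfig",
    nSamples = as.integer(nSamples), nProteins = as.integer(nProteins),
    correlationBlocks = correlationBlocks,
    plantedEffectsOS = plantedEffectsOS,
    plantedEffectsPFS = plantedEffectsPFS,
    covariateEffects = covariateEffects, confounding = confounding,
    lodQuantile = lodQuantile, lodSD = lodSD,
    censoringRate = censoringRate, baselineShape = baselineShape,
    baselineScaleOS = baselineScaleOS, baselineScalePFS = baselineScalePFS,
    frailtySD = frailtySD,
    missingSampleFraction = missingSampleFraction,
    seed = as.integer(seed))
}

# draw clinical covariates from the cohort's category frequencies
simulateClinical <- function(n) {
  lv <- clinicalLevels()
  fq <- clinicalFrequencies()
  pick <- function(levels, prob)
    factor(sample(levels, n, replace = TRUE, prob = prob), levels = levels)
  age <- round(pmin(pmax(rnorm(n, 64.5, 11), 18), 95))
  data.frame(
    age = age,
    ecog = pick(lv$ecog, fq$ecog),
    mfi = pick(lv$mfi, fq$mfi),
    n_met_sites = pick(lv$n_met_sites, fq$n_met_sites),
    site = pick(lv$site, fq$site),
    subtype = pick(lv$subtype, fq$subtype),
    nhg = pick(lv$nhg, fq$nhg),
    ctc_ge5 = rbinom(n, 1, fq$ctc_ge5))
}

# Weibull PH sampling: S(t|lp) = exp(-(t/scale)^shape * exp(lp))
rWeibullPH <- function(n, shape, scale, lp) {
  u <- runif(n)
  scale * (-log(u) * exp(-lp))^(1 / shape)
}

# exponential censoring rate hitting the target expected censored fraction
# for the realized event times: mean(1 - exp(-r * t)) = target
censoringRateFor <- function(times, target) {
  if (target <= 0) return(0)
  f <- function(r) mean(1 - exp(-r * times)) - target
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the configuration's generative model. Identical
#' config and seed reproduce the cohort bit-for-bit. The latent NPX matrix
#' (assay \code{"npxTrue"}) drives the survival model; the reported assay
#' \code{"npx"} equals it, with values below the per-protein LOD flagged in
#' the \code{"belowLOD"} mask (truncation is a downstream preprocessing
#' decision, so below-LOD values are still recorded). Planted effects and
#' covariate effects are kept in \code{metadata(x)$truth}.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return an \linkS4class{NPXExperiment} with outcome and manifest columns.
#' @export
simulateCohort <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  n <- config@nSamples
  p <- config@nProteins
  prot <- proteinIdsFor(p)
  samp <- sprintf("S%04d", seq_len(n))

  # block-correlated latent NPX: compound symmetry within blocks via a
  # shared block factor; protein means 5, total SD 1 (log2 units)
  npx <- matrix(rnorm(p * n), nrow = p, ncol = n)
  pos <- 1L
  for (b in config@correlationBlocks) {
    size <- as.integer(b[[1]]); rho <- b[[2]]
    if (size < 1) next
    idx <- pos:(pos + size - 1L)
    z <- rnorm(n)
    npx[idx, ] <- sqrt(rho) * matrix(z, nrow = size, ncol = n, byrow = TRUE) +
      sqrt(1 - rho) * npx[idx, , drop = FALSE]
    pos <- pos + size
  }
  npx <- npx + 5
  dimnames(npx) <- list(prot, samp)

  clinical <- simulateClinical(n)
  rownames(clinical) <- samp
  design <- covariateDesign(clinical)

  # covariate-linked NPX shifts (confounding)
  if (nrow(config@confounding)) {
    for (i in seq_len(nrow(config@confounding))) {
      cf <- config@confounding[i, ]
      if (!cf$protein %in% prot)
        stop("confounding refers to unknown protein ", cf$protein)
      if (!cf$covariate_column %in% colnames(design))
        stop("confounding refers to unknown design column ",
             cf$covariate_column)
      npx[cf$protein, ] <- npx[cf$protein, ] +
        cf$shift * design[, cf$covariate_column]
    }
  }

  # linear predictors: planted protein effects on centered NPX + covariates
  covCols <- names(config@covariateEffects)
  unknown <- setdiff(covCols, c(colnames(design)))
  if (length(unknown))
    stop("covariate effects refer to unknown design columns: ",
         paste(unknown, collapse = ", "))
  designC <- design
  if ("age" %in% colnames(designC)) designC[, "age"] <- designC[, "age"] - 65
  lpCov <- as.numeric(designC[, covCols, drop = FALSE] %*%
                        config@covariateEffects)
  lpProt <- function(effects) {
    if (!length(effects)) return(rep(0, n))
    as.numeric(crossprod(npx[names(effects), , drop = FALSE] - 5, effects))
  }
  frailty <- if (config@frailtySD > 0) rnorm(n, 0, config@frailtySD)
             else rep(0, n)
  lpOS <- lpProt(config@plantedEffectsOS) + lpCov + frailty
  lpPFS <- lpProt(config@plantedEffectsPFS) + lpCov + frailty
  if (any(!is.finite(exp(lpOS))) || any(!is.finite(exp(lpPFS))))
    stop("linear predictor overflows; reduce planted effect sizes")

  drawEndpoint <- function(lp, scale) {
    t <- rWeibullPH(n, config@baselineShape, scale, lp)
    t <- pmax(t, 1e-6)
    if (config@censoringRate > 0) {
      r <- censoringRateFor(t, config@censoringRate)
      cens <- rexp(n, r)
      list(time = pmin(t, cens), event = as.integer(t <= cens))
    } else {
      list(time = t, event = rep(1L, n))
    }
  }
  os <- drawEndpoint(lpOS, config@baselineScaleOS)
  pfs <- drawEndpoint(lpPFS, config@baselineScalePFS)

  # availability manifest (reasons in proportions 14:5:1, the pattern of
  # serum-sample loss in baseline-sampling studies)
  status <- rep("available", n)
  nMiss <- round(config@missingSampleFraction * n)
  if (nMiss > 0) {
    missIdx <- sample(n, nMiss)
    status[missIdx] <- sample(
      c("no_sample", "qc_fail", "insufficient_material"), nMiss,
      replace = TRUE, prob = c(14, 5, 1) / 20)
  }

  # per-protein empirical LOD at the configured quantile
  lod <- apply(npx, 1, quantile, probs = config@lodQuantile, names = FALSE)
  lodSDvec <- rep(config@lodSD, p)

  cd <- cbind(clinical,
              data.frame(os_months = os$time, os_event = os$event,
                         pfs_months = pfs$time, pfs_event = pfs$event,
                         sample_status = status, row.names = samp))
  x <- NPXExperiment(npx, lod = lod, lodSD = lodSDvec, colData = cd)
  assays(x, withDimnames = FALSE)$npxTrue <- npx
  metadata(x)$truth <- list(
    plantedEffectsOS = config@plantedEffectsOS,
    plantedEffectsPFS = config@plantedEffectsPFS,
    covariateEffects = config@covariateEffects)
  metadata(x)$config <- config
  x
}

#' @rdname npx-accessors
#' @export
plantedEffects <- function(x) metadata(x)$truth
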
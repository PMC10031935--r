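# Independent oracles (kept deliberately naive) and small fixture builders.

# O(n^2) pair enumeration for Harrell's C with the strict comparable-pair
# convention: time_i < time_j and event_i = 1; 0.5 credit for tied risks.
oracleHarrellC <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[i] < time[j]) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Benjamini-Hochberg step-up by direct enumeration
oracleBH <- function(p, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(p)
  q <- numeric(k)
  for (i in seq_len(k)) {
    # min over j >= i of p_(j) * m / j
    q[i] <- min(ps[i:k] * m / seq(i, k))
  }
  q <- pmin(q, 1)
  out <- numeric(k)
  out[ord] <- q
  out
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
# (probability-mass method)
oracleFisherP <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    stats::dhyper(x, r1, r2, c1), numeric(1))
  pObs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# dense two-stage grid search of the Cox partial log-likelihood (continuous
# times, no ties; Breslow = Efron in that case)
oracleCoxGrid <- function(time, event, x) {
  logPL <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      atRisk <- time >= time[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[atRisk])))
    }
    s
  }
  coarse <- seq(-4, 4, by = 0.001)
  ll <- vapply(coarse, logPL, numeric(1))
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.002, b0 + 0.002, by = 1e-5)
  llf <- vapply(fine, logPL, numeric(1))
  fine[which.max(llf)]
}

# cohort with no extraneous heterogeneity (no frailty, no covariate effects,
# independent proteins): the configuration for estimator-calibration checks
cleanCohortConfig <- function(n, nProteins = 92L, plantedOS = numeric(0),
                              plantedPFS = numeric(0), censoring = 0.2,
                              seed = 1L, blocks = list()) {
  cohortConfig(nSamples = n, nProteins = nProteins,
               correlationBlocks = blocks,
               plantedEffectsOS = plantedOS,
               plantedEffectsPFS = plantedPFS,
               covariateEffects = numeric(0), frailtySD = 0,
               censoringRate = censoring, missingSampleFraction = 0,
               seed = seed)
}

# tiny hand-built NPXExperiment
toyNPX <- function(values, lod, lodSD = NULL, colData = NULL) {
  NPXExperiment(values, lod = lod, lodSD = lodSD, colData = colData)
}

# clinical table with every factor at a valid level, for design building
toyClinical <- function(n, seed = 42) {
  set.seed(seed)
  lv <- list(ecog = c("0", "1", "2"), mfi = c("0", "0-3", ">=3"),
             n_met_sites = c("<3", ">=3"),
             site = c("non_visceral", "visceral"),
             subtype = c("ER+HER2-", "HER2+", "TNBC"), nhg = c("I-II", "III"))
  data.frame(age = round(runif(n, 40, 90)),
             ecog = factor(sample(lv$ecog, n, TRUE), levels = lv$ecog),
             mfi = factor(sample(lv$mfi, n, TRUE), levels = lv$mfi),
             n_met_sites = factor(sample(lv$n_met_sites, n, TRUE),
                                  levels = lv$n_met_sites),
             site = factor(sample(lv$site, n, TRUE), levels = lv$site),
             subtype = factor(sample(lv$subtype, n, TRUE),
                              levels = lv$subtype),
             nhg = factor(sample(lv$nhg, n, TRUE), levels = lv$nhg),
             ctc_ge5 = rbinom(n, 1, 0.5))
}
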
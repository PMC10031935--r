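test_that("Cox fit reproduces the closed-form toy and symmetry", {
  # times (1,2,3), all events, x = (1,0,1): score equation 1 - 2 u^2 = 0,
  # u = exp(beta), so beta = -log(2)/2
  fit <- fitCox(c(1, 0, 1), data.frame(time = 1:3, event = 1L))
  expect_equal(fit$beta, -log(2) / 2, tolerance = 1e-6)
  expect_equal(fit$hr, 2^(-1 / 2), tolerance = 1e-6)
  # two groups with identical time/event multisets: beta = 0
  fit0 <- fitCox(c(0, 0, 1, 1),
                 data.frame(time = c(1, 2, 1, 2), event = 1L))
  expect_equal(fit0$beta, 0, tolerance = 1e-8)
  expect_equal(fit0$hr, 1, tolerance = 1e-8)
})

test_that("Cox estimates match a dense partial-likelihood grid search", {
  set.seed(61)
  for (i in 1:60) {
    n <- sample(15:40, 1)
    x <- rnorm(n)
    time <- rexp(n, exp(0.5 * x) * 0.1)  # continuous: no ties
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 3) next
    fit <- fitCox(x, data.frame(time = time, event = event))
    if (fit$flagged) next
    bStar <- oracleCoxGrid(time, event, x)
    if (abs(bStar) > 3.5) next  # maximizer at the grid edge: skip
    expect_lt(abs(fit$beta - bStar), 1e-4)
  }
})

test_that("per-doubling HR is invariant to the log base of the predictor", {
  set.seed(62)
  n <- 200
  x2 <- rnorm(n, mean = 5)          # log2 abundance
  xe <- x2 * log(2)                 # natural-log abundance
  time <- rexp(n, exp(0.4 * x2) * 0.05)
  event <- rbinom(n, 1, 0.8)
  o <- data.frame(time = time, event = event)
  f2 <- fitCox(x2, o)
  fe <- fitCox(xe, o)
  expect_equal(fe$beta * log(2), f2$beta, tolerance = 1e-6)
  # HR per doubling identical: exp(beta2) == exp(betaE * ln 2)
  expect_equal(exp(fe$beta * log(2)), f2$hr, tolerance = 1e-6)
  # Wald CI brackets the HR, symmetric on the log scale
  expect_true(f2$ci_lower < f2$hr && f2$hr < f2$ci_upper)
  expect_equal(log(f2$hr) - log(f2$ci_lower),
               log(f2$ci_upper) - log(f2$hr), tolerance = 1e-10)
})

test_that("adjusted models drop incomplete covariates and report the count", {
  co <- simulateCohort(cohortConfig(nSamples = 80, nProteins = 4,
                                    correlationBlocks = list(),
                                    missingSampleFraction = 0, seed = 3))
  clin <- clinicalCovariates(co)
  clin$subtype[1:2] <- NA
  fit <- fitCox(sampleMatrix(co)[, "P001"], survivalOutcome(co, "os"),
                adjust = clin)
  expect_equal(fit$n_dropped, 2L)
  expect_equal(fit$n, 78L)
  expect_true(fit$adjusted)
})

test_that("elastic net at lambda ~ 0 matches the unpenalized multi-protein fit", {
  co <- simulateCohort(cleanCohortConfig(n = 300, nProteins = 5,
                                         plantedOS = c(P001 = 0.5,
                                                       P003 = -0.4),
                                         seed = 71))
  X <- sampleMatrix(co)
  o <- survivalOutcome(co, "os")
  en <- fitElasticNetCox(X, o, alpha = 0.5,
                         lambda = c(1, 0.1, 0.001, 0), seed = 2)
  ref <- survival::coxph(survivalOutcome(co, "os") ~ X, ties = "breslow")
  b0 <- as.numeric(stats::coef(en$fit, s = 0))
  expect_lt(max(abs(b0 - unname(stats::coef(ref)))), 1e-4)
})

test_that("large penalties zero the path; planted effects top the weights", {
  co <- simulateCohort(cleanCohortConfig(n = 250, nProteins = 20,
                                         plantedOS = c(P005 = 0.8),
                                         seed = 81))
  X <- sampleMatrix(co)
  o <- survivalOutcome(co, "os")
  en <- fitElasticNetCox(X, o, alpha = 0.5, lambda = c(100, 50), seed = 3)
  expect_true(en$allZero)
  en2 <- fitElasticNetCox(X, o, alpha = 0.5, seed = 3)
  expect_equal(names(which.max(en2$weights)), "P005")
  expect_error(fitElasticNetCox(X, o, alpha = 1.5), "alpha")
})

test_that("BH q-values match the step-up enumeration", {
  expect_equal(bhQValues(0.03, m = 1), 0.03)
  expect_equal(bhQValues(c(0.001, 0.01, 0.02, 0.04), m = 4),
               c(0.004, 0.02, 4 * 0.02 / 3, 0.04))
  expect_equal(bhQValues(rep(0.2, 5)), rep(0.2, 5))
  set.seed(91)
  for (i in 1:200) {
    k <- sample(1:50, 1)
    p <- runif(k)
    m <- k + sample(0:50, 1)
    q <- bhQValues(p, m)
    expect_equal(q, oracleBH(p, m))
    expect_true(all(q >= p - 1e-15))
    # monotone in p within the analysis
    ordp <- order(p)
    expect_true(all(diff(q[ordp]) >= -1e-15))
  }
  expect_error(bhQValues(c(0.1, 0)), "0, 1")
  expect_error(bhQValues(c(0.1, 0.2), m = 1), "at least")
})

test_that("evidence classification follows the two-threshold convention", {
  expect_equal(classifyEvidence(0.0031), "significant")
  expect_equal(classifyEvidence(0.030), "suggestive")
  expect_equal(classifyEvidence(0.05), "weak")
  expect_equal(classifyEvidence(c(0.004999, 0.005, 0.0499, 0.9)),
               c("significant", "suggestive", "suggestive", "weak"))
})

test_that("the panel table carries UV/MV HRs, q-values and evidence classes", {
  co <- simulateCohort(cohortConfig(nSamples = 100, nProteins = 10,
                                    correlationBlocks = list(),
                                    plantedEffectsOS = c(P001 = 0.8),
                                    missingSampleFraction = 0, seed = 15))
  tab <- coxPanelTable(sampleMatrix(co), survivalOutcome(co, "os"),
                       clinicalCovariates(co), proteins = c("P001", "P002"),
                       m = 92, endpoint = "os")
  expect_equal(nrow(tab), 2)
  expect_true(all(c("uv_hr", "uv_q", "mv_hr", "mv_q", "uv_evidence")
                  %in% colnames(tab)))
  expect_true(all(tab$uv_q >= tab$uv_p, na.rm = TRUE))
  expect_true(all(tab$uv_ci_lower < tab$uv_hr & tab$uv_hr < tab$uv_ci_upper))
})
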
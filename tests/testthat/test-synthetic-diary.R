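test_that("phase sequences follow the regimen definitions", {
  expect_identical(sum(simulatePhaseSequence(phaseRegimen("natural_cycle"),
                                             28L)), 5L)
  nat <- simulatePhaseSequence(phaseRegimen("natural_cycle"), 56L)
  expect_identical(which(nat == 1L), c(1:5, 29:33))
  # default OC pack: 21 active then 7 inactive
  oc <- simulatePhaseSequence(phaseRegimen("oc_regimen"), 28L)
  expect_identical(sum(oc), 7L)
  expect_identical(which(oc == 1L), 22:28)
  expect_identical(sum(simulatePhaseSequence(phaseRegimen("menopause_post"),
                                             100L)), 0L)
  # pre-menopausal women cycle naturally
  expect_identical(simulatePhaseSequence(phaseRegimen("menopause_pre"), 30L),
                   simulatePhaseSequence(phaseRegimen("natural_cycle"), 30L))
  # perimenopause: irregular but seed-deterministic, bleeds within range
  peri <- phaseRegimen("menopause_peri", periRange = c(21, 60))
  a <- simulatePhaseSequence(peri, 200L, seed = 4L)
  b <- simulatePhaseSequence(peri, 200L, seed = 4L)
  expect_identical(a, b)
  runs <- rle(a)
  bleedRuns <- runs$lengths[runs$values == 1L]
  expect_true(all(bleedRuns <= 5L))
  gaps <- diff(which(diff(c(0L, a)) == 1L))
  expect_true(all(gaps >= 21 & gaps <= 60))
})

test_that("the structural-VAR generator matches its closed-form moments", {
  p <- 2
  # degenerate: iid standard normal
  iid <- simTruth(matrix(0, p, p), matrix(0, p, p), diag(p))
  y <- simulateUSEM(iid, 5000L, seed = 1L)
  ac <- sapply(1:p, function(j) cor(y[-5000, j], y[-1, j]))
  expect_lt(max(abs(ac)), 0.05)
  expect_lt(max(abs(colMeans(y))), 0.06)

  # AR(1): lag-1 autocorrelation equals phi
  ar <- simTruth(matrix(0, p, p), diag(0.5, p), diag(p))
  y2 <- simulateUSEM(ar, 5000L, seed = 2L)
  ac2 <- sapply(1:p, function(j) cor(y2[-5000, j], y2[-1, j]))
  expect_lt(max(abs(ac2 - 0.5)), 0.05)

  # single contemporaneous path: same-day regression recovers it
  A <- matrix(0, p, p); A[2, 1] <- 0.4
  con <- simTruth(A, matrix(0, p, p), diag(p))
  y3 <- simulateUSEM(con, 5000L, seed = 3L)
  b <- coef(lm(y3[, 2] ~ y3[, 1]))[2]
  expect_lt(abs(b - 0.4), 0.05)

  # with A = 0 the sample covariance solves the Lyapunov relation
  Phi <- matrix(c(0.5, 0.2, 0, 0.3), 2, 2, byrow = TRUE)
  ly <- simTruth(matrix(0, p, p), Phi, diag(c(0.8, 0.6)))
  y4 <- simulateUSEM(ly, 5000L, seed = 4L)
  Sig <- cov(y4)
  expect_lt(max(abs(Sig - (Phi %*% Sig %*% t(Phi) + ly@Psi))), 0.08)

  # non-stationary truth refused before simulation
  expect_error(simTruth(matrix(0, 1, 1), matrix(1.05, 1, 1),
                        matrix(1, 1, 1)), "stationary")
})

test_that("the moderated recall generator encodes the phase-shifted slope", {
  set.seed(10)
  fem <- rnorm(2000)
  phase <- rep(c(0L, 1L), 1000)
  # null interaction: fitted interaction is near zero
  r0 <- simulateModeratedOutcome(fem, phase, s0 = 0.3, s1 = 0, ar = 0,
                                 noiseSd = 0.5, seed = 5L)
  b0 <- coef(lm(r0 ~ fem * phase))
  expect_lt(abs(b0["fem:phase"]), 0.08)
  # plug-in truth: low-milieu slope s0 + s1 = -0.4
  r1 <- simulateModeratedOutcome(fem, phase, s0 = 0.2, s1 = -0.6, ar = 0,
                                 noiseSd = 0.5, seed = 6L)
  b1 <- coef(lm(r1 ~ fem * phase))
  expect_lt(abs((b1["fem"] + b1["fem:phase"]) - (-0.4)), 0.05)
  # ar = 0: AR(1) residualization returns (approximately) the centered series
  res <- residualizeAR1(r0)
  expect_lt(abs(res$phi), 0.08)
  expect_error(simulateModeratedOutcome(fem, phase, 0.2, 0, ar = 1,
                                        noiseSd = 1), "ar")
})

test_that("Likert discretization clips, rounds and handles degenerate input", {
  set.seed(3)
  x <- rnorm(500, 2, 3)
  recall <- scaleSpec("recall", 0, 5, integerValued = TRUE)
  d <- discretizeToScale(x, recall)
  expect_true(all(d >= 0 & d <= 5))
  expect_true(all(d == round(d)))
  expect_gt(length(unique(d)), 3)
  fem <- scaleSpec("femininity", 1, 5)
  dc <- discretizeToScale(x, fem)
  expect_true(all(dc >= 1 & dc <= 5))
  expect_false(all(dc == round(dc)))
  expect_identical(unique(discretizeToScale(rep(2, 50), fem)), 3)
  # NA days stay NA
  x[7] <- NA
  expect_identical(is.na(discretizeToScale(x, fem)), is.na(x))
})

test_that("diary-compliance missingness is MCAR at the configured rate", {
  vals <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  s <- personSeries("p1", vals, phase = rep(0L, 100))
  expect_identical(applyMissingness(s, 0), s)
  m1 <- applyMissingness(s, 0.2, seed = 8L)
  m2 <- applyMissingness(s, 0.2, seed = 8L)
  expect_identical(seriesObserved(m1), seriesObserved(m2))
  # whole-day: a missing day drops every variable and the phase report
  dropped <- !seriesObserved(m1)[, 1]
  expect_true(all(!seriesObserved(m1)[dropped, ]))
  expect_true(all(is.na(seriesPhase(m1)[dropped])))
  # binomial mean: observed fraction averages 0.80 over seeds
  fr <- vapply(1:500, function(sd)
    mean(seriesObserved(applyMissingness(s, 0.2, seed = sd))[, 1]),
    numeric(1))
  expect_lt(abs(mean(fr) - 0.80), 0.01)
  expect_error(applyMissingness(s, 0.5), "rate")
})

test_that("simulateStudy is deterministic and matches the requested design", {
  cfg <- simConfig(nullTruth(seed = 42L), nDays = 60L, nPersons = 2L,
                   recallVariable = "recall")
  sim1 <- simulateStudy(cfg)
  sim2 <- simulateStudy(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeDiary(sim1$study, f1, schemaPath = NA)
  writeDiary(sim2$study, f2, schemaPath = NA)
  expect_identical(readLines(f1), readLines(f2))
  p <- getPerson(sim1$study, "sim01")
  expect_identical(seriesVariables(p),
                   c("masculinity", "femininity", "depression",
                     "sensation_seeking", "recall"))
  # continuous output is not confined to the Likert grid
  expect_lt(min(seriesValues(p)[, "depression"], na.rm = TRUE), 0)

  disc <- simConfig(nullTruth(seed = 42L), nDays = 60L, discretize = TRUE)
  sd1 <- simulateStudy(disc)
  v <- seriesValues(getPerson(sd1$study, "sim01"))
  expect_true(all(v[, "depression"] >= 0 & v[, "depression"] <= 2,
                  na.rm = TRUE))
  expect_true(all(v[, "femininity"] >= 1 & v[, "femininity"] <= 5,
                  na.rm = TRUE))
})

test_that("standardized truths really have unit stationary variances", {
  tr <- threePathTruth()
  y <- simulateUSEM(tr, 20000L, seed = 12L)
  expect_lt(max(abs(apply(y, 2, var) - 1)), 0.06)
  # sample variance is stable across halves (stationarity guard)
  v1 <- apply(y[1:10000, ], 2, var)
  v2 <- apply(y[10001:20000, ], 2, var)
  expect_lt(max(abs(v1 - v2)), 0.1)
})
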
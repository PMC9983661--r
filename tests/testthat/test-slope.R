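test_that("fitSlope reproduces the hand-computed reference case", {
  st <- fitSlope(c(0, 1, 2, 3), c(1, 2, 1, 4))
  expect_equal(betaHat(st), 0.8)
  expect_equal(st@interceptHat, 0.8)
  expect_equal(seBeta(st), sqrt(0.28), tolerance = 1e-6)
  expect_equal(tStat(st), 0.8 / sqrt(0.28), tolerance = 1e-6)
  expect_equal(degreesOfFreedom(st), 2)
  # closed-form df=2 CDF: F(t) = 1/2 + t / (2*sqrt(2)*sqrt(1 + t^2/2))
  t <- 0.8 / sqrt(0.28)
  pRef <- 2 * (1 - (0.5 + t / (2 * sqrt(2) * sqrt(1 + t^2 / 2))))
  expect_equal(pValue(st), pRef, tolerance = 1e-12)
  expect_equal(pValue(st), 0.26970, tolerance = 1e-4)
})

test_that("degenerate regressions are handled as documented", {
  expect_error(fitSlope(c(1, 1, 1), c(1, 2, 3)),
               class = "zero_variance_error")
  expect_error(fitSlope(c(1, 2), c(1, 2)),
               class = "insufficient_data_error")
  st <- fitSlope(c(0, 1, 2, 3), rep(5, 4))   # constant response
  expect_equal(betaHat(st), 0)
  expect_equal(tStat(st), 0)
  expect_equal(pValue(st), 1)
  # exact linear relation: p = 0 with a warning, not an exception
  expect_warning(stp <- fitSlope(c(0, 1, 2, 3), c(1, 3, 5, 7)),
                 class = "perfect_fit_warning")
  expect_equal(pValue(stp), 0)
  expect_true(stp@perfectFit)
  expect_equal(betaHat(stp), 2)
})

test_that("fitSlope agrees with a refining grid-search least-squares oracle", {
  set.seed(303)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    x <- round(runif(n, -3, 3), 2)
    if (length(unique(x)) < 2) x[1] <- x[1] + 1
    y <- runif(n, -5, 5)
    st <- suppressWarnings(fitSlope(x, y))
    or <- gridSearchOLS(x, y)
    expect_equal(betaHat(st), unname(or["slope"]), tolerance = 1e-8)
    expect_equal(st@interceptHat, unname(or["intercept"]), tolerance = 1e-8)
  }
})

test_that("fitSlope agrees with stats::lm as an independent cross-check", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    st <- fitSlope(x, y)
    sm <- summary(stats::lm(y ~ x))$coefficients
    expect_equal(betaHat(st), sm["x", "Estimate"], tolerance = 1e-10)
    expect_equal(seBeta(st), sm["x", "Std. Error"], tolerance = 1e-10)
    expect_equal(pValue(st), sm["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("two-sided t p-values match numerical integration of the density", {
  # density written directly from its definition; integrate() is the oracle
  dtDensity <- function(u, df)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  set.seed(13)
  for (df in c(1:5, 10, 20, 30)) {
    for (t in c(0.3, 1, 1.51186, 2.5, 7)) {
      tail <- integrate(dtDensity, t, Inf, df = df,
                        rel.tol = 1e-12, abs.tol = 1e-14)$value
      expect_equal(studentTTwoSidedP(t, df), 2 * tail, tolerance = 1e-8)
      expect_equal(studentTTwoSidedP(-t, df), studentTTwoSidedP(t, df))
    }
  }
  # df = 1 Cauchy closed form
  expect_equal(studentTTwoSidedP(1, 1), 0.5)
  expect_equal(studentTTwoSidedP(0, 8), 1)
  expect_error(studentTTwoSidedP(1, 0), class = "validation_error")
})

test_that("slope tests are affine equivariant in the response", {
  set.seed(17)
  x <- rep(c(0, 0.001, 0.01), each = 3)
  y <- rnorm(9, 8, 0.3)
  st <- fitSlope(x, y)
  sh <- fitSlope(x, y + 5)        # shift: slope, t, p unchanged
  expect_equal(betaHat(sh), betaHat(st))
  expect_equal(tStat(sh), tStat(st))
  expect_equal(pValue(sh), pValue(st))
  sc <- fitSlope(x, 3 * y)        # scale: slope and se scale, t and p fixed
  expect_equal(betaHat(sc), 3 * betaHat(st))
  expect_equal(seBeta(sc), 3 * seBeta(st))
  expect_equal(tStat(sc), tStat(st), tolerance = 1e-12)
  expect_equal(pValue(sc), pValue(st), tolerance = 1e-12)
})

test_that("rejection rate is monotone in effect size", {
  set.seed(71)
  x <- rep(c(0, 0.001, 0.01), each = 3)
  reps <- 2000
  rates <- vapply(c(0, 20, 60, 120), function(b) {
    Y <- matrix(rnorm(9 * reps, 0, 0.2), nrow = 9) + b * x
    mean(olsMany(x, Y)$p < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.1)
  expect_gt(rates[4], 0.9)
})

test_that("entropyTrendTest joins, filters and recovers a simulated dose effect", {
  se <- simulateExperiment(SimulationConfig(genes = 500, libSize = 50000,
    baselineEntropy = 7, doseEffect = -50, noiseSd = 0.02, seed = 12))
  div <- diversityTable(se)
  sheet <- simulatedSampleSheet(se)
  st <- entropyTrendTest(div, sheet, covariate = "dose", strain = "p50",
                         treatments = c("control", "mulberry"))
  expect_lt(betaHat(st), 0)
  expect_equal(st@n, 9L)
  # filter down to a single dose level -> zero-variance covariate
  ctrl <- sheet[sheet$dose == 0, ]
  expect_error(entropyTrendTest(div[div$sample_id %in% ctrl$sample_id, ],
                                sheet, covariate = "dose"),
               class = "zero_variance_error")
  # join mismatch lists missing ids
  div2 <- div; div2$sample_id[1] <- "SXX"
  expect_error(entropyTrendTest(div2, sheet, covariate = "dose"),
               class = "join_error")
  # too-small subset
  expect_error(entropyTrendTest(div[1:2, ], sheet, covariate = "dose"),
               class = "insufficient_data_error")
})

test_that("time-course p-values are uniform under a null generator", {
  # beta = 0: hours do not affect entropy; p over repeated simulated
  # time courses should be uniform
  ps <- vapply(1:150, function(k) {
    se <- simulateExperiment(
      SimulationConfig(genes = 150, libSize = 30000, baselineEntropy = 5.5,
                       doseEffect = 0, noiseSd = 0.05,
                       doses = c(0, 12, 24, 48), reps = 3, seed = 1000 + k),
      covariate = "time_h", strain = "Sawa-J")
    st <- entropyTrendTest(diversityTable(se), simulatedSampleSheet(se),
                           covariate = "time_h")
    pValue(st)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("log-dose encoding is available and changes only the x scale", {
  se <- simulateExperiment(SimulationConfig(genes = 300, libSize = 30000,
    baselineEntropy = 6.5, doseEffect = -50, noiseSd = 0.02, seed = 4))
  div <- diversityTable(se)
  sheet <- simulatedSampleSheet(se)
  st <- entropyTrendTest(div, sheet, covariate = "dose", encoding = "log10")
  expect_equal(st@encoding, "log10")
  expect_lt(betaHat(st), 0)
})
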
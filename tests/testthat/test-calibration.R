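test_that("gamma calibration projects (1,1) onto the isometabolic line", {
  g <- calibrateGammas(CalibrationWindow(1.25, -0.2, 0.1))
  expect_equal(unname(g), c(0.655172413793103, 0.862068965517241),
               tolerance = 1e-12)
  expect_equal(round(unname(g), 4), c(0.6552, 0.8621))
  # the calibrated model returns exactly 1 at the summary
  expect_equal(model1(1.25, -0.2, 0.1, g[["gammaR"]], g[["gammaT"]]), 1,
               tolerance = 1e-14)
  # a summary already satisfied at (1,1) keeps the anchor
  b <- 0.1; rcbf <- 1.2
  a <- invertModel1ForHbr(1, rcbf, b)
  expect_equal(unname(calibrateGammas(CalibrationWindow(rcbf, a, b))),
               c(1, 1), tolerance = 1e-12)
  # one-dimensional solve when the HbR term vanishes
  expect_equal(unname(calibrateGammas(CalibrationWindow(1.25, 0, 0.1))),
               c(1, 2.5))
  # degenerate cases
  expect_equal(unname(calibrateGammas(CalibrationWindow(1, 0, 0))), c(1, 1))
  expect_error(calibrateGammas(CalibrationWindow(1.25, 0, 0)), "infeasible")
})

test_that("gamma projection matches a dense line-search oracle", {
  set.seed(14)
  for (i in 1:12) {
    rcbf <- runif(1, 0.8, 2.4)
    a <- runif(1, -0.35, 0.25)
    b <- runif(1, -0.15, 0.35)
    if (abs(rcbf * a) < 1e-3 && abs(b) < 1e-3) next
    g <- calibrateGammas(CalibrationWindow(rcbf, a, b))
    ref <- bruteForceGammas(rcbf, a, b)
    expect_lt(max(abs(g - ref)), 1e-6)
    expect_equal(model1(rcbf, a, b, g[["gammaR"]], g[["gammaT"]]), 1,
                 tolerance = 1e-12)
  }
})

test_that("per-timepoint gamma variant stays near the window solution", {
  run <- generateRun(hypercapniaParadigm(),
                     GroundTruth(rcbfPeak = 1.5, gammaRTrue = 0.72,
                                 gammaTTrue = 1.52, seed = 6L))
  sm <- co2ResponseSummary(run)
  w <- sm@window
  sel <- function(tr) traceValues(traceWindow(tr, w[1], w[2]))
  traces <- list(rcbf = sel(sm@traces$rcbf), a = sel(sm@traces$a),
                 b = sel(sm@traces$b))
  s <- calibrationWindow(sm)
  gFit <- calibrateGammas(s, perTimepoint = TRUE, traces = traces)
  gProj <- calibrateGammas(s)
  # plateau samples are nearly identical, so both solutions agree closely
  expect_lt(max(abs(gFit - gProj)), 0.05)
  expect_error(calibrateGammas(s, perTimepoint = TRUE), "traces")
})

test_that("single-wavelength calibration coefficient is the closed form", {
  expect_equal(calibrateK(CalibrationWindow(1, NA, NA, -0.02), 0.38), 0)
  k <- calibrateK(CalibrationWindow(2, NA, NA, -0.02), 0.38)
  expect_equal(k, (2^(-0.62) - 1) / (-0.02))
  expect_equal(round(k, 2), 17.47)
  # round trip: the calibrated model returns exactly 1 at the summary
  set.seed(3)
  for (i in 1:10) {
    rcbf <- runif(1, 1.1, 2.5)
    x <- runif(1, -0.05, -0.005)
    al <- runif(1, 0.2, 0.6)
    kk <- calibrateK(CalibrationWindow(rcbf, NA, NA, x), al)
    expect_equal(model3(rcbf, x, kk, al), 1, tolerance = 1e-12)
  }
  expect_error(calibrateK(CalibrationWindow(2, NA, NA, 0), 0.38),
               "infeasible")
})

test_that("Grubb exponent estimation inverts the power law", {
  expect_equal(estimateAlpha(2, 2^0.38), 0.38)
  expect_equal(estimateAlpha(1.7, 1.7), 1)
  expect_error(estimateAlpha(1, 1.1), "undefined")
  expect_error(estimateAlpha(-2, 1.1), "positive")
})

test_that("alpha is identified from noise-free Grubb-coupled runs", {
  truth <- GroundTruth(rcbfPeak = 1.9, alphaTrue = 0.41, tauRiseS = 10,
                       seed = 8L)
  run <- generateRun(hypercapniaParadigm(stimS = 200), truth)
  sm <- co2ResponseSummary(run)
  aHat <- estimateAlpha(sm@means[["rcbf"]], 1 + sm@means[["b"]])
  expect_equal(aHat, 0.41, tolerance = 1e-9)
})

test_that("run-level calibration satisfies unity for all three models", {
  run <- generateRun(hypercapniaParadigm(), hypercapniaTruth("8%", seed = 4L))
  sm <- co2ResponseSummary(run)
  cal <- calibrateRun(sm)
  s <- calibrationWindow(sm)
  expect_equal(model1(s@rcbfMean, s@aMean, s@bMean, cal@gammaR, cal@gammaT),
               1, tolerance = 1e-9)
  expect_equal(model2(s@aMean, s@bMean, cal@gammaR, cal@gammaT, cal@alpha),
               1, tolerance = 1e-9)
  expect_equal(model3(s@rcbfMean, s@dA620Mean, cal@k, cal@alpha), 1,
               tolerance = 1e-9)
  expect_equal(model3(s@rcbfMean, s@aMean, cal@kIdeal, cal@alpha), 1,
               tolerance = 1e-9)
  # flow-free calibration computes the same gammas as the flow-based one:
  # (1 + b)^(1/alpha) with the run's own alpha equals the measured flow mean
  expect_equal((1 + s@bMean)^(1 / cal@alpha), s@rcbfMean, tolerance = 1e-12)
})

test_that("aggregation pools coefficients with sample standard deviations", {
  mk <- function(gR, gT, k, al) new("CalibrationResult", gammaR = gR,
                                    gammaT = gT, k = k, kIdeal = k + 1,
                                    alpha = al, n = 1L)
  one <- aggregateCalibrations(list(mk(0.6, 1.4, 12, 0.35)))
  expect_equal(one@gammaR, 0.6)
  expect_equal(one@gammaRSd, 0)
  two <- aggregateCalibrations(list(mk(0.6, 1.4, 12, 0.35),
                                    mk(0.8, 1.6, 16, 0.41)))
  expect_equal(two@gammaR, 0.7)
  expect_equal(two@gammaRSd, sd(c(0.6, 0.8)))
  expect_equal(two@k, 14)
  expect_equal(two@n, 2L)
  expect_error(aggregateCalibrations(list()), "empty")
})
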
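test_that("flow traces are flat at rest and reach the stated plateau", {
  par <- hypercapniaParadigm()
  null <- generateCbfTrace(par, GroundTruth(rcbfPeak = 1))
  expect_equal(traceValues(null), rep(1, length(null)))
  tr <- generateCbfTrace(par, GroundTruth(rcbfPeak = 1.30))
  expect_equal(traceValues(traceWindow(tr, -30, 0)), rep(1, 300))
  # analytic plateau mean over the last 30 s of a 90 s stimulus:
  # 1 + 0.3 * (1 - mean(exp(-t/10), t in [60, 90)))
  expect_equal(windowMean(tr, 60, 90), 1.30, tolerance = 1e-3)
  # the 8% CO2 group-mean plateau
  tr8 <- generateCbfTrace(par, GroundTruth(rcbfPeak = 2.1367))
  expect_equal(windowMean(tr8, 60, 90), 2.1367, tolerance = 3e-3)
  expect_error(hypercapniaParadigm(restS = -1), "positive")
})

test_that("model inversion for deoxy-hemoglobin is the exact inverse", {
  expect_identical(invertModel1ForHbr(1, 1, 0), 0)
  expect_equal(invertModel1ForHbr(1, 1.25, 0.1), 1.1 / 1.25 - 1)
  expect_equal(invertModel1ForHbr(1, 1.25, 0.1), -0.12)
  set.seed(31)
  for (i in 1:25) {
    m <- runif(1, 0.8, 1.3)
    rcbf <- runif(1, 0.7, 2.3)
    b <- runif(1, -0.15, 0.5)
    g <- runif(2, 0.4, 1.8)
    a <- invertModel1ForHbr(m, rcbf, b, g[1], g[2])
    expect_equal(model1(rcbf, a, b, g[1], g[2]), m, tolerance = 1e-14)
  }
  expect_error(invertModel1ForHbr(1, 1, 0, gammaR = 0), "non-invertible")
})

test_that("a null experiment emits constant signals", {
  run <- generateRun(hypercapniaParadigm(),
                     GroundTruth(rcbfPeak = 1, rcmro2Peak = 1, seed = 2L))
  expect_equal(traceValues(run@i580), rep(1000, 3900))
  expect_equal(traceValues(run@i620), rep(1000, 3900))
  expect_equal(traceValues(run@ldf), rep(250, 39000))
})

test_that("analysis-side unmixing reproduces the generator internals", {
  truth <- GroundTruth(rcbfPeak = 1.6, rcmro2Peak = 0.97, alphaTrue = 0.3,
                       gammaRTrue = 0.8, gammaTTrue = 1.4, seed = 5L)
  run <- generateRun(hypercapniaParadigm(), truth)
  sm <- co2ResponseSummary(run)
  # reconstruct the generator's own concentration paths
  rcbf <- traceValues(generateCbfTrace(run@paradigm, truth, noiseSd = 0))
  b <- rcbf^truth@alphaTrue - 1
  # the metabolic profile shares the flow kernel
  m <- 1 + (truth@rcmro2Peak - 1) * (rcbf - 1) / (truth@rcbfPeak - 1)
  a <- invertModel1ForHbr(m, rcbf, b, truth@gammaRTrue, truth@gammaTTrue)
  bc <- baselineConcentrations(run@baseline)
  relErr <- function(x, y) max(abs(x - y)) / max(abs(y))
  expect_lt(relErr(traceValues(sm@traces$dHbR), a * bc[["cHbR0"]]), 1e-10)
  expect_lt(relErr(traceValues(sm@traces$dHbT), b * run@baseline@cHbT0), 1e-10)
  expect_lt(relErr(traceValues(sm@traces$rcbf), rcbf), 1e-10)
  # conservation at every sample
  expect_equal(traceValues(sm@traces$dHbT),
               traceValues(sm@traces$dHbO) + traceValues(sm@traces$dHbR))
})

test_that("isometabolic runs give unit flow-model output under the true gammas", {
  truth <- GroundTruth(rcbfPeak = 1.45, rcmro2Peak = 1, gammaRTrue = 0.72,
                       gammaTTrue = 1.52, seed = 9L)
  run <- generateRun(hypercapniaParadigm(), truth)
  sm <- co2ResponseSummary(run)
  out <- model1(traceValues(sm@traces$rcbf), traceValues(sm@traces$a),
                traceValues(sm@traces$b), 0.72, 1.52)
  expect_equal(out, rep(1, length(out)), tolerance = 1e-9)
  expect_equal(windowMean(SampledTrace(out, 10, sm@traces$rcbf@t0S), 60, 90),
               1, tolerance = 1e-10)
})

test_that("identical seeds give bit-identical runs", {
  mk <- function() generateRun(
    whiskerParadigm(), whiskerTruth(seed = 17L, noiseSd = 0.01))
  r1 <- mk(); r2 <- mk()
  expect_identical(traceValues(r1@i580), traceValues(r2@i580))
  expect_identical(traceValues(r1@ldf), traceValues(r2@ldf))
  r3 <- generateRun(whiskerParadigm(), whiskerTruth(seed = 18L,
                                                    noiseSd = 0.01))
  expect_false(identical(traceValues(r3@i580), traceValues(r1@i580)))
})

test_that("excessive noise yielding non-positive intensities is refused", {
  expect_error(
    generateRun(hypercapniaParadigm(restS = 5, stimS = 10, recoveryS = 5),
                GroundTruth(noiseSd = 5, seed = 3L)),
    "noise")
})

test_that("single-wavelength forward mode embeds a recoverable k", {
  truth <- GroundTruth(rcbfPeak = 1.8, rcmro2Peak = 1, kTrue = 14,
                       tauRiseS = 10, seed = 12L)
  run <- generateRun(hypercapniaParadigm(stimS = 200), truth,
                     mode = "model3")
  sm <- co2ResponseSummary(run)
  s <- CalibrationWindow(sm@means[["rcbf"]], sm@means[["a"]],
                         sm@means[["b"]], sm@means[["dA620"]],
                         window = c(170, 200))
  kHat <- calibrateK(s, alpha = truth@alphaTrue, source = "rCHbR")
  expect_equal(kHat, 14, tolerance = 1e-6)
  expect_error(generateRun(hypercapniaParadigm(), GroundTruth(seed = 1L),
                           mode = "model3"), "kTrue")
})
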
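test_that("translation estimation is exact for identity and integer shifts", {
  ref <- testTexture(32, seed = 3)
  expect_equal(estimateTranslation(ref, ref), c(dy = 0, dx = 0))
  # integer shifts on a random texture match the brute-force oracle exactly
  set.seed(7)
  raw <- matrix(rnorm(32 * 32), 32, 32)
  for (sh in list(c(-3, 4), c(5, -2), c(0, 7))) {
    fr <- translateFrame(raw, sh[1], sh[2])
    est <- estimateTranslation(fr, raw, upsample = 1)
    expect_equal(unname(est), sh)
    expect_equal(unname(est), bruteForceShift(fr, raw))
  }
  expect_error(estimateTranslation(matrix(1, 8, 8), matrix(1, 8, 8)),
               "constant")
})

test_that("sub-pixel shifts are recovered within 0.05 px at upsample 20", {
  ref <- testTexture(48, seed = 5)
  for (sh in list(c(2.35, -1.60), c(-0.45, 0.30), c(0.05, 3.85))) {
    fr <- translateFrame(ref, sh[1], sh[2])
    est <- estimateTranslation(fr, ref, upsample = 20)
    expect_lt(max(abs(est - sh)), 0.05)
  }
})

test_that("stack registration undoes known smooth motion", {
  par <- hypercapniaParadigm(restS = 2, stimS = 2, recoveryS = 2)
  # static content: injected trajectory is recovered to the sub-pixel grid
  still <- generateRun(par, GroundTruth(rcbfPeak = 1, tauRiseS = 1,
                                        tauFallS = 1, seed = 21L))
  spec <- ImageStackSpec(32, 32, motionAmplitude = 1.5)
  stacks <- generateImageStack(still, spec)
  reg <- registerStack(stacks$stack580, upsample = 20)
  truthRel <- sweep(stacks$shifts, 2, stacks$shifts[1, ])
  expect_lt(max(abs(reg$shifts - truthRel)), 0.05)
  # dynamic ROI content: residual after correction stays below 0.1 px
  dyn <- generateRun(par, GroundTruth(rcbfPeak = 1.3, tauRiseS = 1,
                                      tauFallS = 1, seed = 21L))
  dstacks <- generateImageStack(dyn, spec)
  dreg <- registerStack(dstacks$stack580, upsample = 20)
  resid <- registerStack(dreg$stack, upsample = 20)
  expect_lt(max(abs(resid$shifts)), 0.1)
  # an already-aligned static stack is returned unchanged
  spec0 <- ImageStackSpec(32, 32, motionAmplitude = 0)
  aligned <- generateImageStack(still, spec0)$stack580
  reg0 <- registerStack(aligned, upsample = 20)
  expect_true(all(reg0$shifts == 0))
  expect_identical(reg0$stack, aligned)
  # single-frame stack is the identity
  one <- registerStack(aligned[, , 1, drop = FALSE])
  expect_identical(one$stack, aligned[, , 1, drop = FALSE])
})

test_that("illumination correction removes common-mode drift only", {
  spec <- ImageStackSpec(24, 24)
  pat <- testTexture(24, seed = 9)
  nf <- 60
  # drift-free stack with a constant control trace: correction is a no-op
  flat <- array(rep(pat, nf), dim = c(24, 24, nf))
  expect_warning(out <- intensityCorrect(flat, spec@controlMask), "constant")
  expect_lt(max(abs(out - flat)), 1e-10)
  # pure common-mode drift applied to all pixels: ROI trace becomes constant
  g <- 1 + 0.02 * sin(2 * pi * seq_len(nf) / 20)
  drifted <- array(as.vector(pat) %o% g, dim = c(24, 24, nf))
  corr <- intensityCorrect(drifted, spec@controlMask)
  roiTrace <- traceValues(extractRoi(corr, spec@roiMask))
  expect_lt(diff(range(roiTrace)) / mean(roiTrace), 1e-6)
  expect_error(intensityCorrect(flat, spec@roiMask & spec@controlMask),
               "empty")
})

test_that("drift is carried by the control region and removed from the ROI", {
  run <- generateRun(hypercapniaParadigm(restS = 3, stimS = 6, recoveryS = 3),
                     GroundTruth(rcbfPeak = 1.4, tauRiseS = 1, tauFallS = 2,
                                 seed = 33L))
  spec <- ImageStackSpec(32, 32, illuminationDriftAmplitude = 0.02)
  stacks <- generateImageStack(run, spec)
  # the control-region mean trace carries the drift exactly
  ctl <- traceValues(extractRoi(stacks$stack580, spec@controlMask))
  expect_equal(ctl / ctl[1], (1 + stacks$drift) / (1 + stacks$drift[1]),
               tolerance = 1e-12)
})

test_that("correction preserves an ROI response orthogonal to the drift", {
  spec <- ImageStackSpec(24, 24)
  pat <- testTexture(24, seed = 13)
  nf <- 120
  s <- -0.04 * exp(-(seq_len(nf) - 40)^2 / 200)      # ROI response shape
  g0 <- sin(2 * pi * seq_len(nf) / 30)
  sc <- s - mean(s)
  g0 <- g0 - sum(g0 * sc) / sum(sc^2) * sc            # orthogonalize
  g <- 0.005 * g0 / max(abs(g0))
  st <- array(0, dim = c(24, 24, nf))
  for (f in seq_len(nf)) {
    fr <- pat
    fr[spec@roiMask] <- fr[spec@roiMask] * (1 + s[f])
    st[, , f] <- fr * (1 + g[f])
  }
  corr <- intensityCorrect(st, spec@controlMask)
  roi <- traceValues(extractRoi(corr, spec@roiMask))
  recovered <- roi / mean(roi[1:10]) - 1
  reference <- (1 + s) / mean(1 + s[1:10]) - 1
  expect_lt(max(abs(recovered - reference)) / diff(range(reference)), 0.01)
})

test_that("ROI extraction is the per-frame mean over masked pixels", {
  st <- array(2.5, dim = c(8, 8, 4))
  mask <- matrix(FALSE, 8, 8); mask[3, 4] <- TRUE
  expect_equal(traceValues(extractRoi(st, mask)), rep(2.5, 4))
  st[3, 4, ] <- 1:4
  expect_equal(traceValues(extractRoi(st, mask)), 1:4)
  # checkerboard mask: mean over the selected half only
  chk <- outer(seq_len(8), seq_len(8), function(i, j) (i + j) %% 2 == 0)
  st2 <- array(0, dim = c(8, 8, 2))
  st2[, , 1][chk] <- 6
  st2[, , 2][chk] <- 10
  expect_equal(traceValues(extractRoi(st2, chk)), c(6, 10))
  expect_error(extractRoi(st, matrix(FALSE, 8, 8)), "empty")
})

test_that("image stack export round-trips through TIFF text formats", {
  run <- generateRun(hypercapniaParadigm(restS = 2, stimS = 2, recoveryS = 2),
                     GroundTruth(seed = 41L))
  spec <- ImageStackSpec(16, 16, motionAmplitude = 0.5,
                         illuminationDriftAmplitude = 0.01)
  stacks <- generateImageStack(run, spec)
  dir <- withr::local_tempdir()
  writeImageStack(stacks, dir)
  back <- readImageStack(dir)
  expect_lt(max(abs(back$stack580 - stacks$stack580)), 1e-7)
  expect_identical(back$roiMask, spec@roiMask)
  expect_equal(back$shifts, stacks$shifts)
})
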
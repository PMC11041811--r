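test_that("absorbance change is -ln(I/I0)", {
  expect_equal(absorbanceChange(1000, 1000), 0)
  expect_equal(absorbanceChange(1000 * exp(-0.05), 1000), 0.05)
  tr <- SampledTrace(rep(500, 30), rateHz = 10, t0S = -3)
  dA <- absorbanceChange(tr, windowMean(tr, -3, 0))
  expect_equal(windowMean(dA, -3, 0), 0)
  expect_error(absorbanceChange(c(1, -1), 1), "positive")
  expect_error(absorbanceChange(10, 0), "i0 > 0")
})

test_that("baseline compartment concentrations split by saturation", {
  expect_equal(baselineConcentrations(BaselineConfig(280, 0.75)),
               c(cHbO0 = 210, cHbR0 = 70))
  expect_equal(baselineConcentrations(BaselineConfig(140, 0.75)),
               c(cHbO0 = 105, cHbR0 = 35))
  expect_equal(baselineConcentrations(BaselineConfig(280, 0.55)),
               c(cHbO0 = 154, cHbR0 = 126))
  expect_error(BaselineConfig(280, 1.2), "between 0 and 1")
})

test_that("unmixing solves the two-wavelength system per sample", {
  # hand-checkable system: matrix [[2, 1], [1, 3]], dA = (5, 10)
  op <- OpticsTable(c(580, 620), epsHbO = c(2, 1), epsHbR = c(1, 3),
                    pathlength = c(1, 1))
  res <- unmix(5, 10, op)
  expect_equal(res$dCHbO, 1)
  expect_equal(res$dCHbR, 3)
  expect_equal(res$dCHbT, 4)
  expect_equal(unmix(0, 0, op)$dCHbT, 0)
  expect_error(unmix(1:3, 1:2, op), "equal length")
})

test_that("forward and inverse Beer-Lambert are exact round trips", {
  op <- defaultOptics()
  set.seed(11)
  for (i in 1:5) {
    dHbO <- rnorm(50, sd = 20)
    dHbR <- rnorm(50, sd = 8)
    fa <- forwardAbsorbance(dHbO, dHbR, op)
    back <- unmix(fa$dA1, fa$dA2, op)
    expect_lt(max(abs(back$dCHbO - dHbO)) / max(abs(dHbO)), 1e-12)
    expect_lt(max(abs(back$dCHbR - dHbR)) / max(abs(dHbR)), 1e-12)
    # conservation holds exactly after unmixing
    expect_identical(back$dCHbT, back$dCHbO + back$dCHbR)
  }
})

test_that("forward Beer-Lambert is linear and matches its matrix columns", {
  op <- defaultOptics()
  m <- mbllMatrix(op)
  one <- forwardAbsorbance(1, 0, op)
  expect_equal(c(one$dA1, one$dA2), unname(m[, "dCHbO"]))
  set.seed(2)
  x1 <- rnorm(10); y1 <- rnorm(10); x2 <- rnorm(10); y2 <- rnorm(10)
  fsum <- forwardAbsorbance(x1 + x2, y1 + y2, op)
  f1 <- forwardAbsorbance(x1, y1, op)
  f2 <- forwardAbsorbance(x2, y2, op)
  expect_equal(fsum$dA1, f1$dA1 + f2$dA1)
  expect_equal(fsum$dA2, f1$dA2 + f2$dA2)
})

test_that("scaling pathlengths by c scales recovered concentrations by 1/c", {
  op <- defaultOptics()
  op2 <- OpticsTable(op@wavelengths, op@epsHbO, op@epsHbR,
                     op@pathlength * 2)
  r1 <- unmix(0.01, -0.002, op)
  r2 <- unmix(0.01, -0.002, op2)
  expect_equal(r2$dCHbO, r1$dCHbO / 2)
  expect_equal(r2$dCHbR, r1$dCHbR / 2)
})

test_that("degenerate optics are rejected", {
  expect_error(OpticsTable(c(580, 620), c(1, 2), c(2, 4), c(1, 1)),
               "singular|ill-conditioned")
  expect_error(OpticsTable(c(580, 620), c(1, 1), c(2, 2.0000001), c(1, 1)),
               "ill-conditioned|singular")
})

test_that("log10 extinction tables are converted to the natural-log scale", {
  nat <- OpticsTable(c(580, 620), c(1, 2), c(3, 1), c(1, 1))
  dec <- OpticsTable(c(580, 620), c(1, 2) / log(10), c(3, 1) / log(10),
                     c(1, 1), base = "log10")
  expect_equal(mbllMatrix(nat), mbllMatrix(dec))
})
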
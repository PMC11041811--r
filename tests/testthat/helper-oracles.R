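# Independent oracles and small fixtures shared across the suite.

# Dense line search for the compartment-coefficient calibration: walk the
# constraint line rcbf*(1 + gR*a) = 1 + gT*b in its parametric form and
# return the sampled point closest to (1, 1), refined over three passes.
bruteForceGammas <- function(rcbfMean, aMean, bMean) {
  A <- rcbfMean * aMean
  B <- -bMean
  C <- rcbfMean - 1
  # a feasible anchor point on the line
  p0 <- if (abs(B) >= abs(A)) c(1, (A * 1 + C) / (-B))
        else c((-C - B * 1) / A, 1)
  d <- c(-B, A) / sqrt(A^2 + B^2)   # unit direction along the line
  # the squared distance is quadratic (unimodal) in the line parameter, so
  # coarse-to-fine bracketing over a wide range converges safely
  lo <- -1e4; hi <- 1e4
  for (pass in 1:5) {
    s <- seq(lo, hi, length.out = 40001)
    pts <- cbind(p0[1] + s * d[1], p0[2] + s * d[2])
    dist2 <- (pts[, 1] - 1)^2 + (pts[, 2] - 1)^2
    i <- which.min(dist2)
    best <- s[i]
    step <- s[2] - s[1]
    lo <- best - 2 * step; hi <- best + 2 * step
  }
  c(gammaR = p0[1] + best * d[1], gammaT = p0[2] + best * d[2])
}

# Brute-force integer-shift registration: exhaustive circular
# cross-correlation. Returns (dy, dx) with frame(y, x) ~ ref(y - dy, x - dx).
bruteForceShift <- function(frame, ref) {
  nr <- nrow(ref); nc <- ncol(ref)
  circ <- function(m, dy, dx)
    m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
  best <- c(0, 0); bestScore <- -Inf
  for (dy in seq(-nr %/% 2, nr %/% 2 - 1)) for (dx in seq(-nc %/% 2, nc %/% 2 - 1)) {
    sc <- sum(frame * circ(ref, dy, dx))
    if (sc > bestScore) { bestScore <- sc; best <- c(dy, dx) }
  }
  best
}

# Paired t statistic and two-sided p from the textbook formula.
directPairedT <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Smooth deterministic test texture.
testTexture <- function(n = 48, seed = 1) {
  set.seed(seed)
  p <- matrix(rnorm(n * n), n, n)
  # mild low-pass in Fourier space so sub-pixel shifts are well posed
  f <- fft(p)
  u <- c(0:(n / 2 - 1), -(n / 2):-1)
  w <- exp(-(outer(u^2, rep(1, n)) + outer(rep(1, n), u^2)) / (2 * (n / 8)^2))
  Re(fft(f * w, inverse = TRUE)) / (n * n) + 5
}

# One synthetic animal: an isometabolic hypercapnia calibration run plus a
# whisker run with a known metabolic response.
makeAnimal <- function(seed, noiseSd = 0, rcmro2Peak = 1.06) {
  list(
    cal = generateRun(hypercapniaParadigm(),
                      hypercapniaTruth("5%", seed = seed,
                                       rcbfPeak = 1.30, noiseSd = noiseSd)),
    stim = generateRun(whiskerParadigm(),
                       whiskerTruth(rcmro2Peak = rcmro2Peak,
                                    seed = seed + 5000L,
                                    noiseSd = noiseSd)))
}

# Model 1-Cal change (%) recovered for a cohort of animals.
cohortRecovery <- function(seeds, noiseSd = 0, rcmro2Peak = 1.06) {
  changes <- vapply(seeds, function(s) {
    an <- makeAnimal(s, noiseSd = noiseSd, rcmro2Peak = rcmro2Peak)
    cal <- calibrateRun(co2ResponseSummary(an$cal))
    sm <- whiskerTrialSummary(an$stim)
    tab <- evaluateScenarios(sm, cal = cal,
                             scenarios = list(ModelScenario(1, "Cal")))
    tab$change_pct
  }, numeric(1))
  mean(changes)
}
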
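## Forward-model generator: every downstream stage is testable against the
## ground truth stored alongside the emitted traces.

withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Normalized response kernel s(t) in [0, 1]: exponential rise toward 1
## during each stimulus, exponential relaxation afterwards. One event for
## hypercapnia, one per trial for whisker runs.
responseKernel <- function(paradigm, tauRiseS, tauFallS, times, holdS = 0) {
  onsets <- if (paradigm@kind == "hypercapnia") 0
            else (seq_len(paradigm@nTrials) - 1L) * paradigm@interTrialS
  s <- numeric(length(times))
  tEnd <- paradigm@stimS + holdS
  for (on in onsets) {
    tl <- times - on
    during <- tl >= 0 & tl < paradigm@stimS
    hold <- tl >= paradigm@stimS & tl < tEnd
    after <- tl >= tEnd
    sEnd <- 1 - exp(-paradigm@stimS / tauRiseS)
    s[during] <- s[during] + (1 - exp(-tl[during] / tauRiseS))
    s[hold] <- s[hold] + sEnd
    s[after] <- s[after] + sEnd * exp(-(tl[after] - tEnd) / tauFallS)
  }
  s
}

#' Generate a ground-truth rCBF trace
#'
#' Builds the noise-free flow ratio: exactly 1 throughout rest, rising with
#' the stated time constant toward the plateau \code{rcbfPeak} during
#' stimulation, and relaxing back during recovery. When \code{noiseSd > 0},
#' independent multiplicative Gaussian noise of that fractional sd is added.
#'
#' @param paradigm a [StimulusParadigm-class].
#' @param truth a [GroundTruth-class].
#' @param rateHz output sampling rate.
#' @param noiseSd fractional noise sd; defaults to the value in
#'   \code{truth}. Noise draws consume the RNG stream (seed the caller).
#' @return a ratio-valued [SampledTrace-class] with \code{t0S = -restS}.
#' @examples
#' tr <- generateCbfTrace(hypercapniaParadigm(), GroundTruth(rcbfPeak = 1.3))
#' windowMean(tr, 60, 90)  # ~1.3 at plateau
#' @export
generateCbfTrace <- function(paradigm, truth, rateHz = 10,
                             noiseSd = truth@noiseSd) {
  stopifnot(is(paradigm, "StimulusParadigm"), is(truth, "GroundTruth"))
  n <- round(paradigmDuration(paradigm) * rateHz)
  times <- -paradigm@restS + (seq_len(n) - 1) / rateHz
  s <- responseKernel(paradigm, truth@tauRiseS, truth@tauFallS, times,
                      truth@holdS)
  v <- 1 + (truth@rcbfPeak - 1) * s
  if (noiseSd > 0)
    v <- v * (1 + stats::rnorm(n, sd = noiseSd))
  SampledTrace(v, rateHz = rateHz, t0S = -paradigm@restS, units = "ratio")
}

#' Invert the two-wavelength model for the deoxy-hemoglobin change
#'
#' Solves model family 1 for a = dC_HbR/C_HbR,0 given the target rCMRO2:
#' a = ((rcmro2/rcbf) * (1 + gammaT * b) - 1) / gammaR, so that the model
#' evaluated at (rcbf, a, b) reproduces \code{rcmro2} exactly. This is the
#' generator's route to deoxy-hemoglobin dynamics consistent with a chosen
#' metabolic ground truth.
#'
#' @param rcmro2 target rCMRO2 ratio(s).
#' @param rcbf flow ratio(s) (> 0).
#' @param b fractional total-hemoglobin change(s), with 1 + gammaT*b > 0.
#' @param gammaR,gammaT compartment coefficients; gammaR must be nonzero.
#' @return a, the fractional deoxy-hemoglobin change(s).
#' @examples
#' invertModel1ForHbr(1, 1.25, 0.1)  # -0.12
#' @export
invertModel1ForHbr <- function(rcmro2, rcbf, b, gammaR = 1, gammaT = 1) {
  if (gammaR == 0) stop("non-invertible: gammaR = 0")
  if (any(rcbf <= 0)) stop("rcbf must be positive")
  if (any(1 + gammaT * b <= 0))
    stop("nonphysical state: 1 + gammaT * b must be positive")
  ((rcmro2 / rcbf) * (1 + gammaT * b) - 1) / gammaR
}

#' Generate a complete synthetic run
#'
#' Forward-models one experiment: the flow trace follows the paradigm
#' kernel; total hemoglobin is Grubb-coupled (rC_HbT = rCBF^alpha); the
#' deoxy-hemoglobin trace is obtained by inverting the chosen model family
#' against the ground-truth rCMRO2 profile (which follows the same temporal
#' kernel scaled to \code{rcmro2Peak}); oxy-hemoglobin closes the mass
#' balance; absorbance changes follow the forward Beer-Lambert matrix; and
#' camera intensities are emitted as I = I0 * exp(-dA), at 10 Hz, with
#' multiplicative Gaussian noise of fractional sd \code{noiseSd}. The LDF
#' trace is emitted at 100 Hz with independent noise. All stochastic draws
#' are governed by \code{truth@seed}; identical seeds give bit-identical
#' runs.
#'
#' @param paradigm a [StimulusParadigm-class].
#' @param truth a [GroundTruth-class]; for \code{mode = "model3"},
#'   \code{kTrue} must be set.
#' @param baseline a [BaselineConfig-class].
#' @param optics an [OpticsTable-class].
#' @param mode which model family shapes the deoxy-hemoglobin dynamics:
#'   \code{"model1"} (default, via [invertModel1ForHbr()] with the
#'   ground-truth gammas) or \code{"model3"} (idealized single-wavelength
#'   inversion a = (rcmro2 * rcbf^(alpha-1) - 1)/kTrue, making kTrue
#'   identifiable).
#' @param i0 baseline camera intensities at 580 and 620 nm, counts.
#' @param ldfBase baseline LDF level, arbitrary perfusion units.
#' @return a [SyntheticRun-class].
#' @examples
#' run <- generateRun(hypercapniaParadigm(), GroundTruth(seed = 7))
#' run
#' @export
generateRun <- function(paradigm, truth, baseline = BaselineConfig(),
                        optics = defaultOptics(),
                        mode = c("model1", "model3"),
                        i0 = c(1000, 1000), ldfBase = 250) {
  stopifnot(is(paradigm, "StimulusParadigm"), is(truth, "GroundTruth"),
            is(baseline, "BaselineConfig"), is(optics, "OpticsTable"))
  mode <- match.arg(mode)
  m <- mbllMatrix(optics)
  if (abs(det(m)) < .Machine$double.eps) stop("optics matrix is singular")
  withSeed(truth@seed, {
    rcbf10 <- generateCbfTrace(paradigm, truth, rateHz = 10, noiseSd = 0)
    # flow is held constant within each imaging frame, so block-mean
    # downsampling of the emitted LDF recovers the 10 Hz profile exactly
    rcbf100 <- rep(traceValues(rcbf10), each = 10L)
    t10 <- traceTimes(rcbf10)
    s10 <- responseKernel(paradigm, truth@tauRiseS, truth@tauFallS, t10,
                          truth@holdS)
    rcmro2 <- 1 + (truth@rcmro2Peak - 1) * s10
    b <- traceValues(rcbf10)^truth@alphaTrue - 1
    a <- if (mode == "model1") {
      invertModel1ForHbr(rcmro2, traceValues(rcbf10), b,
                         truth@gammaRTrue, truth@gammaTTrue)
    } else {
      if (!is.finite(truth@kTrue) || truth@kTrue == 0)
        stop("mode 'model3' requires a nonzero kTrue")
      (rcmro2 * traceValues(rcbf10)^(truth@alphaTrue - 1) - 1) / truth@kTrue
    }
    bc <- baselineConcentrations(baseline)
    dHbR <- a * bc[["cHbR0"]]
    dHbT <- b * baseline@cHbT0
    dHbO <- dHbT - dHbR
    dA <- forwardAbsorbance(dHbO, dHbR, optics)
    n10 <- length(t10)
    noise1 <- if (truth@noiseSd > 0) stats::rnorm(n10, sd = truth@noiseSd)
              else numeric(n10)
    noise2 <- if (truth@noiseSd > 0) stats::rnorm(n10, sd = truth@noiseSd)
              else numeric(n10)
    I580 <- i0[1] * exp(-dA$dA1) * (1 + noise1)
    I620 <- i0[2] * exp(-dA$dA2) * (1 + noise2)
    if (any(I580 <= 0) || any(I620 <= 0))
      stop("generated non-positive intensity: noise level too large")
    nl <- length(rcbf100)
    ldfNoise <- if (truth@noiseSd > 0) stats::rnorm(nl, sd = truth@noiseSd)
                else numeric(nl)
    ldf <- ldfBase * rcbf100 * (1 + ldfNoise)
    new("SyntheticRun",
        ldf = SampledTrace(ldf, 100, -paradigm@restS, "perfusion-units"),
        i580 = SampledTrace(I580, 10, -paradigm@restS, "counts"),
        i620 = SampledTrace(I620, 10, -paradigm@restS, "counts"),
        truth = truth, paradigm = paradigm, baseline = baseline,
        optics = optics)
  })
}

#' Convenience ground truths for the two study conditions
#'
#' \code{hypercapniaTruth} parameterizes an isometabolic CO2 challenge with
#' the group-mean flow plateau of the corresponding CO2 level (+29.17
#' percent at 5 percent CO2, +113.67 percent at 8 percent CO2) and the slow
#' hypercapnic response kinetics. \code{whiskerTruth} parameterizes an
#' evoked sensory response: a 1 s rise constant, a 2 s post-stimulus hold
#' (evoked hemodynamic responses outlast the stimulus by a couple of
#' seconds), a 5 s recovery constant and a modest flow increase, with the
#' metabolic response under study as \code{rcmro2Peak}.
#'
#' @param level CO2 level, \code{"5%"} or \code{"8%"}.
#' @param rcbfPeak,rcmro2Peak plateau ratios (\code{rcbfPeak = NULL} takes
#'   the group mean of the CO2 level).
#' @param seed RNG seed.
#' @param ... further arguments to [GroundTruth()].
#' @return a [GroundTruth-class].
#' @export
hypercapniaTruth <- function(level = c("5%", "8%"), seed = 1L,
                             rcbfPeak = NULL, ...) {
  level <- match.arg(level)
  if (is.null(rcbfPeak))
    rcbfPeak <- if (level == "5%") 1.2917 else 2.1367
  GroundTruth(rcbfPeak = rcbfPeak, rcmro2Peak = 1, tauRiseS = 10,
              tauFallS = 20, seed = seed, ...)
}

#' @rdname hypercapniaTruth
#' @export
whiskerTruth <- function(rcbfPeak = 1.15, rcmro2Peak = 1.055, seed = 1L,
                         ...) {
  GroundTruth(rcbfPeak = rcbfPeak, rcmro2Peak = rcmro2Peak,
              tauRiseS = 1, tauFallS = 5, holdS = 2, seed = seed, ...)
}

## Smooth band-limited baseline pattern in [lo, hi]; deterministic per seed.
.basePattern <- function(height, width, seed, lo = 0.3, hi = 0.7) {
  withSeed(seed, {
    yy <- matrix(seq_len(height), height, width)
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    p <- matrix(0, height, width)
    for (j in 1:4) {
      fy <- stats::runif(1, 0.5, 3) / height
      fx <- stats::runif(1, 0.5, 3) / width
      ph <- stats::runif(2, 0, 2 * pi)
      p <- p + stats::runif(1, 0.5, 1) *
        sin(2 * pi * fy * yy + ph[1]) * cos(2 * pi * fx * xx + ph[2])
    }
    lo + (hi - lo) * (p - min(p)) / (max(p) - min(p))
  })
}

#' Generate toy two-wavelength image stacks for a run
#'
#' Renders each optical trace of the run into an image stack: every frame is
#' a fixed smooth baseline pattern whose ROI pixels are scaled by the
#' temporal intensity ratio I(t)/I0 of the run, multiplied everywhere
#' (control region included) by a common-mode illumination drift
#' 1 + A*sin(2*pi*t/60), and rigidly translated by a smooth sub-pixel motion
#' trajectory of the requested amplitude. Translation is applied in the
#' Fourier domain, so the injected shifts are recoverable exactly up to the
#' registration precision. The ground-truth shifts and drift are returned
#' alongside the stacks.
#'
#' @param run a [SyntheticRun-class] (use a short paradigm; one frame per
#'   optical sample is rendered).
#' @param spec an [ImageStackSpec-class].
#' @return list with 3D arrays \code{stack580}, \code{stack620}
#'   (height x width x frames), matrix \code{shifts} (frames x 2, columns
#'   dy, dx), numeric \code{drift}, and the \code{spec}.
#' @export
generateImageStack <- function(run, spec) {
  stopifnot(is(run, "SyntheticRun"), is(spec, "ImageStackSpec"))
  times <- traceTimes(run@i580)
  nf <- length(times)
  pat <- .basePattern(spec@height, spec@width, run@truth@seed + 1000L)
  drift <- spec@illuminationDriftAmplitude * sin(2 * pi * times / 60)
  dy <- spec@motionAmplitude * sin(2 * pi * times / 37)
  dx <- spec@motionAmplitude * cos(2 * pi * times / 53)
  mkStack <- function(intensity) {
    i0 <- intensity@values[1]
    st <- array(0, dim = c(spec@height, spec@width, nf))
    for (f in seq_len(nf)) {
      ratio <- intensity@values[f] / i0
      frame <- pat
      frame[spec@roiMask] <- frame[spec@roiMask] * ratio
      frame <- frame * (1 + drift[f])
      if (dy[f] != 0 || dx[f] != 0)
        frame <- translateFrame(frame, dy[f], dx[f])
      st[, , f] <- frame
    }
    st
  }
  list(stack580 = mkStack(run@i580), stack620 = mkStack(run@i620),
       shifts = cbind(dy = dy, dx = dx), drift = drift, spec = spec)
}
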
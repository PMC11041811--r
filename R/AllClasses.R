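#' @import methods
NULL

#' Uniformly sampled scalar time series
#'
#' Container for any uniformly sampled scalar signal handled by the package:
#' raw camera intensity, laser-Doppler flow, absorbance change, hemoglobin
#' concentration change, or a baseline-normalized ratio. Time is expressed
#' relative to stimulus onset: the first sample lies at \code{t0S} seconds
#' and subsequent samples follow at \code{1/rateHz} spacing.
#'
#' @slot values numeric vector of samples (finite).
#' @slot rateHz sampling rate in samples per second (> 0).
#' @slot t0S time of the first sample in seconds relative to stimulus onset.
#' @slot units free-text unit label (e.g. \code{"counts"}, \code{"ratio"}).
#' @seealso [SampledTrace()], [traceTimes()], [windowMean()]
#' @exportClass SampledTrace
setClass("SampledTrace",
  representation(values = "numeric", rateHz = "numeric", t0S = "numeric",
                 units = "character"),
  prototype(values = numeric(), rateHz = 10, t0S = 0, units = ""))

setValidity("SampledTrace", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1L || !is.finite(object@rateHz) ||
      object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive finite number")
  if (length(object@t0S) != 1L || !is.finite(object@t0S))
    msg <- c(msg, "t0S must be a single finite number")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(object@units) != 1L)
    msg <- c(msg, "units must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a SampledTrace
#'
#' @param values numeric vector of samples.
#' @param rateHz sampling rate in Hz.
#' @param t0S time of the first sample in seconds relative to stimulus onset.
#' @param units unit label.
#' @return A [SampledTrace-class] object.
#' @examples
#' tr <- SampledTrace(sin(seq(0, 2 * pi, length.out = 100)), rateHz = 10)
#' traceRate(tr)
#' @export
SampledTrace <- function(values, rateHz = 10, t0S = 0, units = "") {
  new("SampledTrace", values = as.numeric(values), rateHz = as.numeric(rateHz),
      t0S = as.numeric(t0S), units = as.character(units))
}

#' Per-wavelength extinction coefficients and pathlength factors
#'
#' Holds the two-wavelength optical constants that define the modified
#' Beer-Lambert system: molar extinction coefficients for oxy- and
#' deoxy-hemoglobin and the differential pathlength factor at each
#' wavelength. The implied 2x2 unmixing matrix must be well conditioned.
#'
#' @slot wavelengths wavelengths in nm (two entries).
#' @slot epsHbO extinction coefficients of HbO2, 1/(uM*mm), natural-log base.
#' @slot epsHbR extinction coefficients of HbR, 1/(uM*mm), natural-log base.
#' @slot pathlength differential pathlength factor per wavelength, mm.
#' @seealso [OpticsTable()], [defaultOptics()], [mbllMatrix()]
#' @exportClass OpticsTable
setClass("OpticsTable",
  representation(wavelengths = "numeric", epsHbO = "numeric",
                 epsHbR = "numeric", pathlength = "numeric"))

setValidity("OpticsTable", function(object) {
  msg <- character()
  for (s in c("wavelengths", "epsHbO", "epsHbR", "pathlength"))
    if (length(slot(object, s)) != 2L || any(!is.finite(slot(object, s))))
      msg <- c(msg, sprintf("%s must be two finite numbers", s))
  if (!length(msg)) {
    if (any(object@pathlength <= 0))
      msg <- c(msg, "pathlength factors must be positive")
    m <- cbind(object@epsHbO * object@pathlength,
               object@epsHbR * object@pathlength)
    if (abs(det(m)) < .Machine$double.eps || kappa(m, exact = TRUE) > 1e8)
      msg <- c(msg, "extinction/pathlength matrix is singular or ill-conditioned")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OpticsTable
#'
#' @param wavelengths wavelengths in nm.
#' @param epsHbO,epsHbR extinction coefficients per wavelength, 1/(uM*mm).
#' @param pathlength differential pathlength factor per wavelength, mm.
#' @param base \code{"natural"} if the extinction coefficients are already on
#'   the natural-log scale (the package convention), \code{"log10"} to convert
#'   decadic tabulations by multiplying with \code{log(10)}.
#' @return An [OpticsTable-class] object.
#' @export
OpticsTable <- function(wavelengths, epsHbO, epsHbR, pathlength,
                        base = c("natural", "log10")) {
  base <- match.arg(base)
  f <- if (base == "log10") log(10) else 1
  new("OpticsTable", wavelengths = as.numeric(wavelengths),
      epsHbO = as.numeric(epsHbO) * f, epsHbR = as.numeric(epsHbR) * f,
      pathlength = as.numeric(pathlength))
}

#' Default optical constants for 580/620 nm reflectance imaging
#'
#' Extinction coefficients are taken from the standard tabulated hemoglobin
#' absorption spectra (Prahl compilation; 50104 and 37020 1/(cm*M) for HbO2
#' and HbR at 580 nm, 942 and 6509.6 1/(cm*M) at 620 nm), converted to
#' natural-log units of 1/(uM*mm). Pathlength factors are literature-typical
#' values for cortical reflectance imaging: short at the strongly absorbed
#' 580 nm, long at 620 nm. Every unmixing result in the package is validated
#' by forward/inverse round trips, so no downstream quantity depends on these
#' particular constants; supply your own table for quantitative work.
#'
#' @return An [OpticsTable-class] with wavelengths 580 and 620 nm.
#' @examples
#' mbllMatrix(defaultOptics())
#' @export
defaultOptics <- function() {
  OpticsTable(wavelengths = c(580, 620),
              epsHbO = c(50104, 942) * 1e-7,
              epsHbR = c(37020, 6509.6) * 1e-7,
              pathlength = c(0.45, 1.70),
              base = "log10")
}

#' Baseline hemodynamic state
#'
#' Baseline total-hemoglobin concentration and blood oxygen saturation, from
#' which the compartment baselines C_HbO,0 = S0*C_HbT,0 and
#' C_HbR,0 = (1 - S0)*C_HbT,0 follow.
#'
#' @slot cHbT0 baseline total hemoglobin concentration, uM (> 0).
#' @slot s0 baseline blood oxygen saturation, fraction in (0, 1).
#' @seealso [BaselineConfig()], [baselineConcentrations()]
#' @exportClass BaselineConfig
setClass("BaselineConfig",
  representation(cHbT0 = "numeric", s0 = "numeric"),
  prototype(cHbT0 = 280, s0 = 0.75))

setValidity("BaselineConfig", function(object) {
  msg <- character()
  if (length(object@cHbT0) != 1L || !is.finite(object@cHbT0) ||
      object@cHbT0 <= 0)
    msg <- c(msg, "cHbT0 must be a single positive number")
  if (length(object@s0) != 1L || !is.finite(object@s0) ||
      object@s0 <= 0 || object@s0 >= 1)
    msg <- c(msg, "s0 must lie strictly between 0 and 1")
  if (length(msg)) msg else TRUE
})

#' Construct a BaselineConfig
#'
#' Defaults are the conventional cortical values: 280 uM total hemoglobin at
#' 75 percent oxygen saturation.
#'
#' @param cHbT0 baseline total hemoglobin concentration, uM.
#' @param s0 baseline oxygen saturation, fraction.
#' @return A [BaselineConfig-class] object.
#' @export
BaselineConfig <- function(cHbT0 = 280, s0 = 0.75) {
  new("BaselineConfig", cHbT0 = as.numeric(cHbT0), s0 = as.numeric(s0))
}

#' Stimulation paradigm
#'
#' Timing of a hypercapnia or whisker-stimulation experiment. Hypercapnia
#' runs are single-trial (30 s rest, 90 s CO2, 270 s recovery by default);
#' whisker runs deliver \code{nTrials} stimuli of \code{stimS} seconds every
#' \code{interTrialS} seconds after an initial rest period.
#'
#' @slot kind \code{"hypercapnia"} or \code{"whisker"}.
#' @slot restS rest before the first stimulus onset, s.
#' @slot stimS stimulus duration, s.
#' @slot recoveryS recovery after the last trial window, s.
#' @slot nTrials number of trials (1 for hypercapnia).
#' @slot interTrialS onset-to-onset interval for repeated trials, s.
#' @seealso [hypercapniaParadigm()], [whiskerParadigm()]
#' @exportClass StimulusParadigm
setClass("StimulusParadigm",
  representation(kind = "character", restS = "numeric", stimS = "numeric",
                 recoveryS = "numeric", nTrials = "integer",
                 interTrialS = "numeric"))

setValidity("StimulusParadigm", function(object) {
  msg <- character()
  if (!object@kind %in% c("hypercapnia", "whisker"))
    msg <- c(msg, "kind must be 'hypercapnia' or 'whisker'")
  if (object@restS <= 0 || object@stimS <= 0 || object@recoveryS < 0)
    msg <- c(msg, "durations must be positive (recovery may be 0)")
  if (object@nTrials < 1L)
    msg <- c(msg, "nTrials must be at least 1")
  if (object@nTrials > 1L && object@interTrialS < object@stimS)
    msg <- c(msg, "interTrialS must be at least stimS")
  if (length(msg)) msg else TRUE
})

#' @describeIn StimulusParadigm-class single-trial CO2 challenge paradigm.
#' @param restS,stimS,recoveryS,interTrialS,nTrials timing parameters, s.
#' @return A [StimulusParadigm-class] object.
#' @export
hypercapniaParadigm <- function(restS = 30, stimS = 90, recoveryS = 270) {
  new("StimulusParadigm", kind = "hypercapnia", restS = restS, stimS = stimS,
      recoveryS = recoveryS, nTrials = 1L, interTrialS = stimS + recoveryS)
}

#' @describeIn StimulusParadigm-class repeated air-puff whisker paradigm.
#' @export
whiskerParadigm <- function(restS = 10, stimS = 6, interTrialS = 36,
                            nTrials = 12, recoveryS = 0) {
  new("StimulusParadigm", kind = "whisker", restS = restS, stimS = stimS,
      recoveryS = recoveryS, nTrials = as.integer(nTrials),
      interTrialS = interTrialS)
}

#' Total run duration implied by a paradigm
#' @param paradigm a [StimulusParadigm-class].
#' @return duration in seconds from the start of rest to the end of recovery.
#' @export
paradigmDuration <- function(paradigm) {
  stopifnot(is(paradigm, "StimulusParadigm"))
  if (paradigm@kind == "hypercapnia")
    paradigm@restS + paradigm@stimS + paradigm@recoveryS
  else
    paradigm@restS + paradigm@nTrials * paradigm@interTrialS +
      paradigm@recoveryS
}

#' Generative ground truth for a synthetic run
#'
#' Parameters that fully determine a forward-modeled experiment: the flow
#' and oxygen-metabolism plateau ratios, the Grubb flow-volume exponent, the
#' compartment coefficients used to shape the deoxy-hemoglobin dynamics, the
#' single-wavelength calibration coefficient (forward mode only), the
#' response-shape time constants, the fractional measurement-noise level,
#' and the RNG seed.
#'
#' @slot rcbfPeak plateau rCBF ratio (> 0).
#' @slot rcmro2Peak plateau rCMRO2 ratio (1 for isometabolic runs).
#' @slot alphaTrue Grubb exponent, in (0, 1).
#' @slot gammaRTrue,gammaTTrue compartment volume-fraction coefficients.
#' @slot kTrue single-wavelength calibration coefficient (1/ratio units;
#'   used only by the \code{"model3"} forward mode, otherwise \code{NA}).
#' @slot tauRiseS,tauFallS exponential rise/fall time constants, s.
#' @slot holdS post-stimulus hold: seconds the response stays at its
#'   end-of-stimulus level before relaxing (hemodynamic responses lag
#'   stimulus offset; 0 for an immediate decay).
#' @slot noiseSd fractional standard deviation of multiplicative
#'   measurement noise (0 = noise-free).
#' @slot seed integer RNG seed (mandatory for any stochastic draw).
#' @seealso [GroundTruth()], [generateRun()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(rcbfPeak = "numeric", rcmro2Peak = "numeric",
                 alphaTrue = "numeric", gammaRTrue = "numeric",
                 gammaTTrue = "numeric", kTrue = "numeric",
                 tauRiseS = "numeric", tauFallS = "numeric",
                 holdS = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (object@rcbfPeak <= 0) msg <- c(msg, "rcbfPeak must be positive")
  if (object@rcmro2Peak <= 0) msg <- c(msg, "rcmro2Peak must be positive")
  if (!is.finite(object@alphaTrue) || object@alphaTrue <= 0 ||
      object@alphaTrue >= 1)
    msg <- c(msg, "alphaTrue must lie in (0, 1)")
  if (object@gammaRTrue == 0) msg <- c(msg, "gammaRTrue must be nonzero")
  if (object@tauRiseS <= 0 || object@tauFallS <= 0)
    msg <- c(msg, "time constants must be positive")
  if (object@holdS < 0) msg <- c(msg, "holdS must be nonnegative")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' Construct a GroundTruth
#'
#' Defaults describe an isometabolic 5 percent CO2 hypercapnia condition:
#' a 30 percent flow increase, unchanged oxygen metabolism, Grubb exponent
#' 0.38, unity compartment coefficients, a 10 s rise constant and no noise.
#' For whisker-type runs shorten the time constants (about 1 s rise) and set
#' \code{rcmro2Peak} to the metabolic response under study.
#'
#' @param rcbfPeak,rcmro2Peak,alphaTrue,gammaRTrue,gammaTTrue,kTrue,tauRiseS,tauFallS,holdS,noiseSd,seed see [GroundTruth-class].
#' @return A [GroundTruth-class] object.
#' @export
GroundTruth <- function(rcbfPeak = 1.30, rcmro2Peak = 1, alphaTrue = 0.38,
                        gammaRTrue = 1, gammaTTrue = 1, kTrue = NA_real_,
                        tauRiseS = 10, tauFallS = 20, holdS = 0,
                        noiseSd = 0, seed = 1L) {
  new("GroundTruth", rcbfPeak = rcbfPeak, rcmro2Peak = rcmro2Peak,
      alphaTrue = alphaTrue, gammaRTrue = gammaRTrue,
      gammaTTrue = gammaTTrue, kTrue = kTrue, tauRiseS = tauRiseS,
      tauFallS = tauFallS, holdS = holdS, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' A complete synthetic experiment
#'
#' Laser-Doppler flow at 100 Hz plus the two optical intensity traces at
#' 10 Hz, together with the generative ground truth, paradigm, baseline
#' state and optics used to produce them.
#'
#' @slot ldf [SampledTrace-class], 100 Hz perfusion trace (arbitrary units).
#' @slot i580,i620 [SampledTrace-class], 10 Hz camera intensities (counts).
#' @slot truth the generating [GroundTruth-class].
#' @slot paradigm the [StimulusParadigm-class].
#' @slot baseline the [BaselineConfig-class] used in generation.
#' @slot optics the [OpticsTable-class] used in generation.
#' @seealso [generateRun()], [writeRun()]
#' @exportClass SyntheticRun
setClass("SyntheticRun",
  representation(ldf = "SampledTrace", i580 = "SampledTrace",
                 i620 = "SampledTrace", truth = "GroundTruth",
                 paradigm = "StimulusParadigm", baseline = "BaselineConfig",
                 optics = "OpticsTable"))

setValidity("SyntheticRun", function(object) {
  msg <- character()
  if (any(object@i580@values <= 0) || any(object@i620@values <= 0))
    msg <- c(msg, "intensities must be strictly positive")
  dur <- paradigmDuration(object@paradigm)
  for (s in c("ldf", "i580", "i620")) {
    tr <- slot(object, s)
    if (abs(length(tr@values) / tr@rateHz - dur) > 1 / tr@rateHz + 1e-9)
      msg <- c(msg, sprintf("%s length inconsistent with paradigm", s))
  }
  if (length(msg)) msg else TRUE
})

#' Geometry of a synthetic image stack
#'
#' @slot height,width frame size in pixels.
#' @slot roiMask,controlMask logical matrices (height x width); disjoint and
#'   nonempty. The control mask mimics regions over bone or head-bar that
#'   see illumination drift but no hemodynamic signal.
#' @slot motionAmplitude peak-to-peak/2 amplitude of the injected smooth
#'   sub-pixel motion, pixels.
#' @slot illuminationDriftAmplitude fractional amplitude of the common-mode
#'   illumination drift.
#' @seealso [ImageStackSpec()], [generateImageStack()]
#' @exportClass ImageStackSpec
setClass("ImageStackSpec",
  representation(height = "integer", width = "integer", roiMask = "matrix",
                 controlMask = "matrix", motionAmplitude = "numeric",
                 illuminationDriftAmplitude = "numeric"))

setValidity("ImageStackSpec", function(object) {
  msg <- character()
  d <- c(object@height, object@width)
  if (!all(dim(object@roiMask) == d) || !all(dim(object@controlMask) == d))
    msg <- c(msg, "masks must be height x width")
  if (!any(object@roiMask)) msg <- c(msg, "roiMask is empty")
  if (!any(object@controlMask)) msg <- c(msg, "controlMask is empty")
  if (any(object@roiMask & object@controlMask))
    msg <- c(msg, "roi and control masks must be disjoint")
  if (object@motionAmplitude < 0 || object@illuminationDriftAmplitude < 0)
    msg <- c(msg, "amplitudes must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageStackSpec
#'
#' When masks are omitted, a centered oval ROI and a top-left control block
#' are laid out automatically.
#'
#' @param height,width frame size in pixels.
#' @param roiMask,controlMask logical matrices; see [ImageStackSpec-class].
#' @param motionAmplitude injected motion amplitude, px.
#' @param illuminationDriftAmplitude fractional drift amplitude.
#' @return An [ImageStackSpec-class] object.
#' @export
ImageStackSpec <- function(height = 32, width = 32, roiMask = NULL,
                           controlMask = NULL, motionAmplitude = 0,
                           illuminationDriftAmplitude = 0) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.null(roiMask)) {
    yy <- matrix(seq_len(height), height, width)
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    roiMask <- ((yy - height / 2) / (height / 5))^2 +
      ((xx - width / 2) / (width / 4))^2 <= 1
  }
  if (is.null(controlMask)) {
    controlMask <- matrix(FALSE, height, width)
    controlMask[seq_len(max(2L, height %/% 6)),
                seq_len(max(2L, width %/% 6))] <- TRUE
    controlMask[roiMask] <- FALSE
  }
  new("ImageStackSpec", height = height, width = width,
      roiMask = roiMask, controlMask = controlMask,
      motionAmplitude = as.numeric(motionAmplitude),
      illuminationDriftAmplitude = as.numeric(illuminationDriftAmplitude))
}

#' Calibration coefficients from one run (or an aggregate)
#'
#' Holds the compartment coefficients (gammaR, gammaT) solved from an
#' isometabolic hypercapnia run, the single-wavelength calibration
#' coefficient for both the measured (620 nm absorbance) and idealized
#' (rC_HbR) signal sources, and the Grubb exponent. Aggregates across runs
#' carry per-coefficient standard deviations and the number of runs pooled.
#'
#' @slot gammaR,gammaT compartment coefficients (dimensionless).
#' @slot k calibration coefficient for the 620 nm absorbance source.
#' @slot kIdeal calibration coefficient for the rC_HbR source.
#' @slot alpha Grubb flow-volume exponent.
#' @slot gammaRSd,gammaTSd,kSd,kIdealSd,alphaSd sample standard deviations
#'   (NA for a single run).
#' @slot n number of runs pooled (1 for a single run).
#' @slot source run identifier.
#' @slot co2Level label of the CO2 level, e.g. "5%".
#' @seealso [calibrateRun()], [aggregateCalibrations()]
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(gammaR = "numeric", gammaT = "numeric", k = "numeric",
                 kIdeal = "numeric", alpha = "numeric",
                 gammaRSd = "numeric", gammaTSd = "numeric", kSd = "numeric",
                 kIdealSd = "numeric", alphaSd = "numeric", n = "integer",
                 source = "character", co2Level = "character"),
  prototype(gammaRSd = NA_real_, gammaTSd = NA_real_, kSd = NA_real_,
            kIdealSd = NA_real_, alphaSd = NA_real_, n = 1L, source = "",
            co2Level = ""))

#' Calibration-window summary of a hypercapnia run
#'
#' Window means over the calibration window (by default the last 30 s of
#' CO2 stimulation) of the normalized flow, the fractional hemoglobin
#' changes a = dC_HbR/C_HbR0 and b = dC_HbT/C_HbT0, and the 620 nm
#' absorbance change.
#'
#' @slot rcbfMean window-mean rCBF ratio.
#' @slot aMean window-mean fractional deoxy-hemoglobin change.
#' @slot bMean window-mean fractional total-hemoglobin change.
#' @slot dA620Mean window-mean 620 nm absorbance change.
#' @slot window the half-open window \code{[start, end)} in seconds.
#' @seealso [calibrationWindow()], [calibrateGammas()], [calibrateK()]
#' @exportClass CalibrationWindow
setClass("CalibrationWindow",
  representation(rcbfMean = "numeric", aMean = "numeric", bMean = "numeric",
                 dA620Mean = "numeric", window = "numeric"))

#' Construct a CalibrationWindow summary directly
#'
#' @param rcbfMean,aMean,bMean,dA620Mean window means; see
#'   [CalibrationWindow-class].
#' @param window half-open window in seconds relative to stimulus onset.
#' @return A [CalibrationWindow-class] object.
#' @export
CalibrationWindow <- function(rcbfMean, aMean, bMean, dA620Mean = NA_real_,
                              window = c(60, 90)) {
  new("CalibrationWindow", rcbfMean = as.numeric(rcbfMean),
      aMean = as.numeric(aMean), bMean = as.numeric(bMean),
      dA620Mean = as.numeric(dA620Mean), window = as.numeric(window))
}

#' A model/case evaluation scenario
#'
#' Names one of the pre-registered model scenarios: model family 1, 2 or 3
#' combined with a parameter case. Cases: \code{"Cal"} (per-run calibrated),
#' \code{"Avg"} (cross-run average coefficients), \code{"One"} (gammaR =
#' gammaT = 1), and for model 3 \code{"Ideal"} (the rC_HbR signal source in
#' place of the 620 nm approximation).
#'
#' @slot model model family, 1, 2 or 3.
#' @slot case parameter case.
#' @slot hbrSource \code{"dA620"} or \code{"rCHbR"} (model 3 only).
#' @seealso [ModelScenario()], [defaultScenarios()], [evaluateScenarios()]
#' @exportClass ModelScenario
setClass("ModelScenario",
  representation(model = "integer", case = "character",
                 hbrSource = "character"))

setValidity("ModelScenario", function(object) {
  msg <- character()
  if (!object@model %in% 1:3) msg <- c(msg, "model must be 1, 2 or 3")
  if (!object@case %in% c("Cal", "Avg", "One", "Ideal"))
    msg <- c(msg, "case must be Cal, Avg, One or Ideal")
  if (object@case == "Ideal" &&
      !(object@model == 3L && object@hbrSource == "rCHbR"))
    msg <- c(msg, "case 'Ideal' is only valid for model 3 with source rCHbR")
  if (object@model == 3L && object@case == "One")
    msg <- c(msg, "model 3 has no 'One' case")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelScenario
#' @param model model family, 1, 2 or 3.
#' @param case \code{"Cal"}, \code{"Avg"}, \code{"One"} or \code{"Ideal"}.
#' @param hbrSource HbR-signal source for model 3.
#' @return A [ModelScenario-class] object.
#' @export
ModelScenario <- function(model, case,
                          hbrSource = if (case == "Ideal") "rCHbR" else "dA620") {
  new("ModelScenario", model = as.integer(model), case = case,
      hbrSource = hbrSource)
}

#' Per-run analysis summary
#'
#' Baseline-normalized traces and response-window scalars for one run. For
#' hypercapnia runs the traces span the whole run and the response window is
#' the last 30 s of stimulation; for whisker runs the traces are
#' trial-averaged epochs (5 s pre to 30 s post onset) and scalars are 2 s
#' means centered on each signal's own peak.
#'
#' @slot kind paradigm kind.
#' @slot traces named list of [SampledTrace-class]: \code{rcbf}, \code{dA580},
#'   \code{dA620}, \code{a}, \code{b}, \code{dHbO}, \code{dHbR}, \code{dHbT}.
#' @slot means named numeric of response-window scalars.
#' @slot window response/search window \code{[start, end)} in seconds.
#' @slot stimS stimulus duration, s.
#' @seealso [co2ResponseSummary()], [whiskerTrialSummary()]
#' @exportClass RunSummary
setClass("RunSummary",
  representation(kind = "character", traces = "list", means = "numeric",
                 window = "numeric", stimS = "numeric"))
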
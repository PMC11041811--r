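#' @rdname trace-accessors
#' @export
setMethod("traceValues", "SampledTrace", function(x) x@values)

#' @rdname trace-accessors
#' @export
setMethod("traceRate", "SampledTrace", function(x) x@rateHz)

#' @rdname trace-accessors
#' @export
setMethod("traceUnits", "SampledTrace", function(x) x@units)

#' @rdname trace-accessors
#' @export
setMethod("traceTimes", "SampledTrace", function(x)
  x@t0S + (seq_along(x@values) - 1) / x@rateHz)

#' @describeIn SampledTrace-class number of samples.
#' @param x a \code{SampledTrace}.
#' @export
setMethod("length", "SampledTrace", function(x) length(x@values))

setMethod("show", "SampledTrace", function(object) {
  n <- length(object@values)
  cat(sprintf("SampledTrace: %d samples @ %g Hz, t = [%g, %g) s%s\n",
              n, object@rateHz, object@t0S, object@t0S + n / object@rateHz,
              if (nzchar(object@units)) paste0(" [", object@units, "]")
              else ""))
  if (n) cat(sprintf("  range [%.6g, %.6g]\n",
                     min(object@values), max(object@values)))
})

setMethod("show", "OpticsTable", function(object) {
  cat("OpticsTable (natural-log extinction, 1/(uM*mm); pathlength, mm)\n")
  print(data.frame(wavelength_nm = object@wavelengths,
                   epsHbO = object@epsHbO, epsHbR = object@epsHbR,
                   pathlength = object@pathlength))
  cat(sprintf("  condition number of unmixing matrix: %.3g\n",
              kappa(mbllMatrix(object), exact = TRUE)))
})

setMethod("show", "BaselineConfig", function(object) {
  bc <- baselineConcentrations(object)
  cat(sprintf("BaselineConfig: C_HbT,0 = %g uM, S0 = %g (C_HbO,0 = %g, C_HbR,0 = %g uM)\n",
              object@cHbT0, object@s0, bc[["cHbO0"]], bc[["cHbR0"]]))
})

setMethod("show", "StimulusParadigm", function(object) {
  cat(sprintf("StimulusParadigm <%s>: rest %g s, stim %g s x %d trial(s)",
              object@kind, object@restS, object@stimS, object@nTrials))
  if (object@nTrials > 1L)
    cat(sprintf(" every %g s", object@interTrialS))
  cat(sprintf(", recovery %g s (total %g s)\n",
              object@recoveryS, paradigmDuration(object)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(paste0("GroundTruth: rCBF peak %.4g, rCMRO2 peak %.4g, ",
                     "alpha %.3g, gamma (%.3g, %.3g)\n"),
              object@rcbfPeak, object@rcmro2Peak, object@alphaTrue,
              object@gammaRTrue, object@gammaTTrue))
  cat(sprintf("  tau rise/fall %g/%g s, noise sd %g, seed %d\n",
              object@tauRiseS, object@tauFallS, object@noiseSd, object@seed))
})

setMethod("show", "SyntheticRun", function(object) {
  cat("SyntheticRun\n")
  show(object@paradigm)
  cat(sprintf("  LDF: %d samples @ %g Hz; optical: %d samples @ %g Hz per wavelength\n",
              length(object@ldf@values), object@ldf@rateHz,
              length(object@i580@values), object@i580@rateHz))
  show(object@truth)
})

setMethod("show", "CalibrationResult", function(object) {
  fmt <- function(m, s) if (is.na(s)) sprintf("%.4g", m)
                        else sprintf("%.4g (+/- %.3g)", m, s)
  cat(sprintf("CalibrationResult [n = %d%s]\n", object@n,
              if (nzchar(object@source)) paste0(", ", object@source) else ""))
  cat(sprintf("  gammaR = %s, gammaT = %s\n",
              fmt(object@gammaR, object@gammaRSd),
              fmt(object@gammaT, object@gammaTSd)))
  cat(sprintf("  k = %s, kIdeal = %s, alpha = %s\n",
              fmt(object@k, object@kSd), fmt(object@kIdeal, object@kIdealSd),
              fmt(object@alpha, object@alphaSd)))
})

setMethod("show", "RunSummary", function(object) {
  cat(sprintf("RunSummary <%s>: window [%g, %g) s\n", object@kind,
              object@window[1], object@window[2]))
  print(round(object@means, 6))
})

#' @rdname windowMean
#' @export
setMethod("windowMean", "SampledTrace", function(x, start, end) {
  t <- traceTimes(x)
  idx <- t >= start & t < end
  if (!any(idx))
    stop("window [", start, ", ", end, ") contains no samples")
  mean(x@values[idx])
})

#' Extract the sub-trace within a half-open window
#'
#' @param x a [SampledTrace-class].
#' @param start,end window bounds in seconds (half-open).
#' @return a [SampledTrace-class] restricted to \code{start <= t < end}.
#' @export
traceWindow <- function(x, start, end) {
  t <- traceTimes(x)
  idx <- which(t >= start & t < end)
  if (!length(idx)) stop("window [", start, ", ", end, ") is empty")
  SampledTrace(x@values[idx], rateHz = x@rateHz, t0S = t[idx[1]],
               units = x@units)
}

#' Downsample a flow trace by block averaging
#'
#' Reduces the laser-Doppler sampling rate (100 Hz) to the imaging rate
#' (10 Hz) by non-overlapping block means. Block means act as a moving
#' average before decimation, so aliasing of broadband noise is suppressed
#' and the mean over complete blocks is preserved exactly. A trailing
#' partial block is dropped with a warning.
#'
#' @param trace a [SampledTrace-class].
#' @param targetHz target rate; the input rate must be an integer multiple.
#' @return a [SampledTrace-class] at \code{targetHz}.
#' @examples
#' downsampleLdf(SampledTrace(1:10, rateHz = 100), targetHz = 10)
#' @export
downsampleLdf <- function(trace, targetHz = 10) {
  stopifnot(is(trace, "SampledTrace"))
  factor <- trace@rateHz / targetHz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("sampling rate ", trace@rateHz,
         " Hz is not an integer multiple of ", targetHz, " Hz")
  factor <- as.integer(round(factor))
  n <- length(trace@values)
  nblock <- n %/% factor
  if (nblock == 0L) stop("trace shorter than one block")
  if (n %% factor != 0L)
    warning(n %% factor, " trailing sample(s) dropped in downsampling")
  v <- colMeans(matrix(trace@values[seq_len(nblock * factor)], nrow = factor))
  SampledTrace(v, rateHz = targetHz, t0S = trace@t0S, units = trace@units)
}

#' Normalize a trace by its baseline-window mean
#'
#' Divides the trace by its mean over the half-open baseline window, turning
#' it into a ratio relative to the pre-stimulus state. Default windows are
#' paradigm-specific at the call sites: 30 s before CO2 onset, 5 s before
#' whisker onset.
#'
#' @param trace a [SampledTrace-class].
#' @param window numeric length-2, half-open \code{[start, end)} in seconds.
#' @return a ratio-valued [SampledTrace-class] whose baseline-window mean is
#'   exactly 1.
#' @export
normalizeToBaseline <- function(trace, window) {
  stopifnot(is(trace, "SampledTrace"), length(window) == 2L)
  m <- windowMean(trace, window[1], window[2])
  scale <- max(abs(trace@values), 1)
  if (!is.finite(m) || abs(m) < 1e-12 * scale)
    stop("baseline-window mean is zero or near zero; cannot normalize")
  SampledTrace(trace@values / m, rateHz = trace@rateHz, t0S = trace@t0S,
               units = "ratio")
}
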
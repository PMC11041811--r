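#' Accessors for SampledTrace
#'
#' @param x a [SampledTrace-class].
#' @return \code{traceValues}: the numeric samples; \code{traceRate}: the
#'   sampling rate in Hz; \code{traceUnits}: the unit label;
#'   \code{traceTimes}: sample times in seconds relative to stimulus onset.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname trace-accessors
#' @export
setGeneric("traceRate", function(x) standardGeneric("traceRate"))

#' @rdname trace-accessors
#' @export
setGeneric("traceUnits", function(x) standardGeneric("traceUnits"))

#' @rdname trace-accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' Mean of a trace over a half-open time window
#'
#' Windows are half-open, \code{[start, end)}, with t = 0 at stimulus onset.
#'
#' @param x a [SampledTrace-class].
#' @param start,end window bounds in seconds.
#' @return the arithmetic mean of the samples with \code{start <= t < end}.
#' @export
setGeneric("windowMean", function(x, start, end) standardGeneric("windowMean"))
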
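## Paradigm-aware windowing, scenario evaluation, percent-error tables,
## paired tests and the baseline-condition sensitivity sweep.

## Shared tail of both summaries: absorbance -> concentrations -> fractions.
.hemoFromAbsorbance <- function(dA580, dA620, baseline, optics) {
  hb <- unmix(dA580, dA620, optics)
  bc <- baselineConcentrations(baseline)
  list(dHbO = hb$dCHbO, dHbR = hb$dCHbR, dHbT = hb$dCHbT,
       a = hb$dCHbR / bc[["cHbR0"]], b = hb$dCHbT / baseline@cHbT0)
}

#' Summarize a hypercapnia run
#'
#' Signal conditioning and windowing for a CO2 challenge: the LDF trace is
#' block-downsampled to the imaging rate and normalized by the 30 s before
#' onset; each intensity trace is referenced to its baseline-window mean to
#' form absorbance changes, which are unmixed into hemoglobin concentration
#' changes and fractional changes a and b. The response window is the last
#' 30 s of stimulation, \code{[stimS - 30, stimS)} (half-open; a sample at
#' exactly t = stimS is excluded).
#'
#' @param run a [SyntheticRun-class] (or object with the same slots holding
#'   measured traces).
#' @param baseline a [BaselineConfig-class]; defaults to the run's own.
#' @param optics an [OpticsTable-class]; defaults to the run's own.
#' @return a [RunSummary-class] with traces \code{rcbf}, \code{dA580},
#'   \code{dA620}, \code{a}, \code{b}, \code{dHbO}, \code{dHbR}, \code{dHbT}
#'   and window means of each.
#' @export
co2ResponseSummary <- function(run, baseline = run@baseline,
                               optics = run@optics) {
  stopifnot(is(run, "SyntheticRun"))
  par <- run@paradigm
  if (par@kind != "hypercapnia")
    stop("co2ResponseSummary expects a hypercapnia paradigm")
  need <- paradigmDuration(par)
  if (length(run@i580@values) / run@i580@rateHz < need - 1e-9)
    stop("optical trace shorter than the paradigm")
  bw <- c(-par@restS, 0)
  rw <- c(par@stimS - 30, par@stimS)
  ldf10 <- if (run@ldf@rateHz > 10) downsampleLdf(run@ldf, 10) else run@ldf
  rcbf <- normalizeToBaseline(ldf10, bw)
  dA580 <- absorbanceChange(run@i580, windowMean(run@i580, bw[1], bw[2]))
  dA620 <- absorbanceChange(run@i620, windowMean(run@i620, bw[1], bw[2]))
  hemo <- .hemoFromAbsorbance(dA580, dA620, baseline, optics)
  rate <- run@i580@rateHz
  t0 <- run@i580@t0S
  traces <- list(
    rcbf = rcbf, dA580 = dA580, dA620 = dA620,
    a = SampledTrace(hemo$a, rate, t0, "fraction"),
    b = SampledTrace(hemo$b, rate, t0, "fraction"),
    dHbO = SampledTrace(hemo$dHbO, rate, t0, "uM"),
    dHbR = SampledTrace(hemo$dHbR, rate, t0, "uM"),
    dHbT = SampledTrace(hemo$dHbT, rate, t0, "uM"))
  means <- vapply(traces, windowMean, numeric(1), start = rw[1], end = rw[2])
  names(means) <- names(traces)
  new("RunSummary", kind = "hypercapnia", traces = traces, means = means,
      window = rw, stimS = par@stimS)
}

## Index range of the epoch [onset - preS, onset + postS) on a trace.
.epochIndices <- function(trace, onset, preS, postS) {
  i0 <- round((onset - preS - trace@t0S) * trace@rateHz) + 1
  n <- round((preS + postS) * trace@rateHz)
  if (i0 < 1 || i0 + n - 1 > length(trace@values))
    stop("trace too short for a full trial epoch")
  seq.int(i0, length.out = n)
}

#' Mean over a 2 s window centered on a trace's peak deviation
#'
#' Locates the maximum absolute deviation from \code{base} within the
#' half-open search window, breaking ties toward the earliest time, and
#' returns the mean over the window of \code{halfWidthS} seconds on either
#' side of the peak (clipped to the trace).
#'
#' @param trace a [SampledTrace-class].
#' @param searchWindow half-open \code{[start, end)} window, seconds.
#' @param base reference level deviations are measured from.
#' @param halfWidthS half-width of the averaging window, seconds.
#' @return the windowed mean (on the trace's own scale).
#' @export
peakWindowMean <- function(trace, searchWindow, base = 1, halfWidthS = 1) {
  t <- traceTimes(trace)
  idx <- which(t >= searchWindow[1] & t < searchWindow[2])
  if (!length(idx)) stop("empty peak-search window")
  pk <- idx[which.max(abs(trace@values[idx] - base))]
  tpk <- t[pk]
  sel <- t >= tpk - halfWidthS & t < tpk + halfWidthS
  mean(trace@values[sel])
}

#' Summarize a whisker-stimulation run
#'
#' Trial handling for repeated air-puff stimulation: every signal is
#' epoch-extracted from \code{preS} s before to \code{postS} s after each
#' onset, normalized per trial by the 5 s preceding that trial's onset (LDF
#' first block-downsampled to the imaging rate), and averaged across trials
#' on the common time base. Absorbance changes of the trial-averaged
#' intensities are unmixed into hemoglobin changes. The scalar change of
#' each signal is the mean over the 2 s window centered on that signal's own
#' peak deviation within \code{[0, stimS + 4)} s.
#'
#' @param run a [SyntheticRun-class] with a whisker paradigm.
#' @param baseline a [BaselineConfig-class]; defaults to the run's own.
#' @param optics an [OpticsTable-class]; defaults to the run's own.
#' @param preS,postS epoch extent around each onset, seconds.
#' @return a [RunSummary-class] whose traces are trial-averaged epochs with
#'   \code{t0S = -preS}.
#' @export
whiskerTrialSummary <- function(run, baseline = run@baseline,
                                optics = run@optics, preS = 5, postS = 30) {
  stopifnot(is(run, "SyntheticRun"))
  par <- run@paradigm
  if (par@kind != "whisker")
    stop("whiskerTrialSummary expects a whisker paradigm")
  if (par@nTrials < 1L) stop("need at least one trial")
  onsets <- (seq_len(par@nTrials) - 1L) * par@interTrialS
  ldf10 <- if (run@ldf@rateHz > 10) downsampleLdf(run@ldf, 10) else run@ldf
  avgEpoch <- function(trace, normalize) {
    acc <- NULL
    for (on in onsets) {
      idx <- .epochIndices(trace, on, preS, postS)
      v <- trace@values[idx]
      if (normalize) {
        tt <- traceTimes(trace)[idx]
        b <- mean(v[tt >= on - 5 & tt < on])
        v <- v / b
      }
      acc <- if (is.null(acc)) v else acc + v
    }
    acc / length(onsets)
  }
  rcbfV <- avgEpoch(ldf10, TRUE)
  i580V <- avgEpoch(run@i580, TRUE)   # per-trial normalized: I/I0 ratios
  i620V <- avgEpoch(run@i620, TRUE)
  dA580 <- -log(i580V)
  dA620 <- -log(i620V)
  hemo <- .hemoFromAbsorbance(dA580, dA620, baseline, optics)
  rate <- run@i580@rateHz
  traces <- list(
    rcbf = SampledTrace(rcbfV, rate, -preS, "ratio"),
    dA580 = SampledTrace(dA580, rate, -preS, "absorbance"),
    dA620 = SampledTrace(dA620, rate, -preS, "absorbance"),
    a = SampledTrace(hemo$a, rate, -preS, "fraction"),
    b = SampledTrace(hemo$b, rate, -preS, "fraction"),
    dHbO = SampledTrace(hemo$dHbO, rate, -preS, "uM"),
    dHbR = SampledTrace(hemo$dHbR, rate, -preS, "uM"),
    dHbT = SampledTrace(hemo$dHbT, rate, -preS, "uM"))
  sw <- c(0, par@stimS + 4)
  bases <- c(rcbf = 1, dA580 = 0, dA620 = 0, a = 0, b = 0,
             dHbO = 0, dHbR = 0, dHbT = 0)
  means <- vapply(names(traces), function(nm)
    peakWindowMean(traces[[nm]], sw, base = bases[[nm]]), numeric(1))
  new("RunSummary", kind = "whisker", traces = traces, means = means,
      window = sw, stimS = par@stimS)
}

#' Calibration-window summary from a hypercapnia RunSummary
#'
#' @param summary a hypercapnia [RunSummary-class].
#' @return a [CalibrationWindow-class] carrying the window means.
#' @export
calibrationWindow <- function(summary) {
  stopifnot(is(summary, "RunSummary"))
  if (summary@kind != "hypercapnia")
    stop("calibration requires a hypercapnia summary")
  CalibrationWindow(rcbfMean = summary@means[["rcbf"]],
                    aMean = summary@means[["a"]],
                    bMean = summary@means[["b"]],
                    dA620Mean = summary@means[["dA620"]],
                    window = summary@window)
}

#' The nine pre-registered model scenarios
#'
#' Model 1-Cal/Avg/1, Model 2-Cal/Avg/1, Model 3-Cal/Avg/Ideal.
#'
#' @return list of [ModelScenario-class] objects.
#' @export
defaultScenarios <- function() {
  list(ModelScenario(1, "Cal"), ModelScenario(1, "Avg"),
       ModelScenario(1, "One"),
       ModelScenario(2, "Cal"), ModelScenario(2, "Avg"),
       ModelScenario(2, "One"),
       ModelScenario(3, "Cal"), ModelScenario(3, "Avg"),
       ModelScenario(3, "Ideal"))
}

.scenarioLabel <- function(sc) {
  suffix <- switch(sc@case, Cal = "Cal", Avg = "Avg", One = "1",
                   Ideal = "Ideal")
  sprintf("Model %d-%s", sc@model, suffix)
}

## rCMRO2 trace for one scenario on one summary.
.scenarioTrace <- function(sc, summary, cal, avg) {
  needCal <- function() {
    if (is.null(cal)) stop("scenario ", .scenarioLabel(sc),
                           " needs a per-run calibration")
    cal
  }
  needAvg <- function() {
    if (is.null(avg)) stop("scenario ", .scenarioLabel(sc),
                           " needs an aggregated calibration")
    avg
  }
  tr <- summary@traces
  rcbf <- traceValues(tr$rcbf)
  a <- traceValues(tr$a)
  b <- traceValues(tr$b)
  v <- if (sc@model == 1L) {
    g <- switch(sc@case, Cal = needCal(), Avg = needAvg(), One = NULL)
    if (is.null(g)) model1(rcbf, a, b, 1, 1)
    else model1(rcbf, a, b, g@gammaR, g@gammaT)
  } else if (sc@model == 2L) {
    g <- switch(sc@case, Cal = needCal(), Avg = needAvg(), One = NULL)
    al <- switch(sc@case, Cal = needCal()@alpha, needAvg()@alpha)
    if (is.null(g)) model2(a, b, 1, 1, al)
    else model2(a, b, g@gammaR, g@gammaT, al)
  } else {
    src <- switch(sc@case, Cal = needCal(), Avg = needAvg(),
                  Ideal = needCal())
    x <- if (sc@hbrSource == "dA620") traceValues(tr$dA620) else a
    k <- if (sc@case == "Ideal") src@kIdeal else src@k
    model3(rcbf, x, k, src@alpha)
  }
  SampledTrace(v, traceRate(tr$rcbf), tr$rcbf@t0S, "ratio")
}

## Scalar rCMRO2 change (%) over the paradigm-specific response window.
.scenarioChange <- function(trace, summary) {
  m <- if (summary@kind == "hypercapnia")
    windowMean(trace, summary@window[1], summary@window[2])
  else
    peakWindowMean(trace, summary@window, base = 1)
  100 * (m - 1)
}

#' Evaluate model scenarios on one run summary
#'
#' Computes the rCMRO2 trace of every scenario (models evaluated per time
#' sample), reduces each to its scalar change over the paradigm-specific
#' response window (window mean for hypercapnia; 2 s peak-centered mean for
#' whisker runs), and tabulates percent errors against the reference
#' scenario. Percent error is change-relative,
#' 100*|change - change_ref|/|change_ref| with change = rCMRO2 - 1; a
#' ratio-relative variant 100*|m - m_ref|/m_ref on the rCMRO2 ratios is
#' reported alongside.
#'
#' @param summary a [RunSummary-class].
#' @param cal per-run [CalibrationResult-class] (needed by Cal/Ideal cases).
#' @param avg aggregated [CalibrationResult-class] (needed by Avg cases and
#'   by model 2's uncalibrated alpha).
#' @param scenarios list of [ModelScenario-class]; default the nine
#'   pre-registered ones.
#' @param reference label of the reference row.
#' @return a \code{data.frame} (scenario table) with columns
#'   \code{scenario}, \code{model}, \code{case}, \code{change_pct},
#'   \code{pct_error}, \code{pct_error_ratio}; the traces are attached as
#'   attribute \code{"traces"}.
#' @export
evaluateScenarios <- function(summary, cal = NULL, avg = NULL,
                              scenarios = defaultScenarios(),
                              reference = "Model 1-Cal") {
  stopifnot(is(summary, "RunSummary"))
  labels <- vapply(scenarios, .scenarioLabel, character(1))
  traces <- lapply(scenarios, .scenarioTrace, summary = summary,
                   cal = cal, avg = avg)
  names(traces) <- labels
  change <- vapply(traces, .scenarioChange, numeric(1), summary = summary)
  tab <- data.frame(
    scenario = labels,
    model = vapply(scenarios, function(s) s@model, integer(1)),
    case = vapply(scenarios, function(s) s@case, character(1)),
    change_pct = unname(change),
    row.names = NULL)
  if (reference %in% labels) {
    cref <- change[[reference]]
    tab$pct_error <- vapply(change, function(cm) {
      if (cm == cref) 0
      else if (cref == 0) NA_real_   # undefined against a null reference
      else percentError(cm, cref)
    }, numeric(1))
    tab$pct_error_ratio <- 100 * abs(change - cref) / abs(100 + cref)
  }
  attr(tab, "traces") <- traces
  tab
}

#' Change-relative percent error
#'
#' 100 * |change_model - change_ref| / |change_ref|, with both changes
#' expressed as rCMRO2 - 1 (in percent or as fractions, consistently).
#'
#' @param changeModel,changeRef scalar changes; the reference must be
#'   nonzero.
#' @return percent error.
#' @examples
#' percentError(5.0, 5.9)  # 15.25
#' @export
percentError <- function(changeModel, changeRef) {
  if (any(changeRef == 0))
    stop("percent error undefined for a zero reference change")
  100 * abs(changeModel - changeRef) / abs(changeRef)
}

#' Two-sided paired t-test with degenerate-case conventions
#'
#' Wraps [stats::t.test()] on the paired differences. All-zero differences
#' return t = 0, p = 1 by convention; zero-variance nonzero-mean differences
#' are flagged degenerate (infinite t, p = 0).
#'
#' @param x,y matched numeric vectors, length >= 2.
#' @return list with \code{t}, \code{p}, \code{degenerate}.
#' @export
pairedTTest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (all(d == 0))
    return(list(t = 0, p = 1, degenerate = FALSE))
  if (stats::sd(d) == 0)
    return(list(t = sign(mean(d)) * Inf, p = 0, degenerate = TRUE))
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Baseline-condition sensitivity sweep
#'
#' Re-runs calibration and scenario evaluation over a grid of baseline
#' assumptions: for every combination of baseline total-hemoglobin
#' concentration and oxygen saturation, the hypercapnia runs are
#' re-summarized and re-calibrated under that baseline, the coefficients
#' aggregated, and all scenarios re-evaluated on the stimulus runs; the
#' scenario changes are averaged across stimulus runs. With the default
#' single-point grid this reproduces the unswept pipeline bit-exactly.
#'
#' @param calRuns list of hypercapnia [SyntheticRun-class] objects.
#' @param stimRuns list of stimulus runs (whisker or hypercapnia).
#' @param chbt0Grid baseline C_HbT,0 values to sweep, uM.
#' @param s0Grid baseline saturations to sweep.
#' @param scenarios list of [ModelScenario-class].
#' @return tidy \code{data.frame}: \code{cHbT0}, \code{s0}, \code{scenario},
#'   \code{change_pct} (mean across stimulus runs).
#' @export
baselineSensitivitySweep <- function(calRuns, stimRuns, chbt0Grid = 280,
                                     s0Grid = 0.75,
                                     scenarios = defaultScenarios()) {
  if (!length(calRuns) || !length(stimRuns))
    stop("need at least one calibration and one stimulus run")
  out <- list()
  for (c0 in chbt0Grid) for (s0 in s0Grid) {
    bl <- BaselineConfig(c0, s0)
    cals <- lapply(calRuns, function(r)
      calibrateRun(co2ResponseSummary(r, baseline = bl)))
    avg <- aggregateCalibrations(cals)
    perRun <- mapply(function(r, calRes) {
      sm <- if (r@paradigm@kind == "whisker")
        whiskerTrialSummary(r, baseline = bl)
      else co2ResponseSummary(r, baseline = bl)
      tab <- evaluateScenarios(sm, cal = calRes, avg = avg,
                               scenarios = scenarios)
      tab$change_pct
    }, stimRuns, rep_len(cals, length(stimRuns)))
    perRun <- matrix(perRun, ncol = length(stimRuns))
    out[[length(out) + 1L]] <- data.frame(
      cHbT0 = c0, s0 = s0,
      scenario = vapply(scenarios, .scenarioLabel, character(1)),
      change_pct = rowMeans(perRun), row.names = NULL)
  }
  do.call(rbind, out)
}
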
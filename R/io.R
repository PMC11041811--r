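## Plain-text/TIFF serialization of synthetic runs and image stacks.

.truthToList <- function(truth)
  list(rcbf_peak = truth@rcbfPeak, rcmro2_peak = truth@rcmro2Peak,
       alpha_true = truth@alphaTrue, gammaR_true = truth@gammaRTrue,
       gammaT_true = truth@gammaTTrue, k_true = truth@kTrue,
       tau_rise_s = truth@tauRiseS, tau_fall_s = truth@tauFallS,
       hold_s = truth@holdS, noise_sd = truth@noiseSd, seed = truth@seed)

#' Write a synthetic run to a directory
#'
#' Layout: \code{ldf.csv} (time_s, value), \code{ois_580.csv} and
#' \code{ois_620.csv} (time_s, intensity), \code{truth.json} (ground truth
#' plus the baseline and optics used), \code{paradigm.yaml}.
#'
#' @param run a [SyntheticRun-class].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeRun <- function(run, dir) {
  stopifnot(is(run, "SyntheticRun"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(trace, file, valueName) {
    df <- data.frame(time_s = traceTimes(trace), v = trace@values)
    names(df)[2] <- valueName
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  wcsv(run@ldf, "ldf.csv", "value")
  wcsv(run@i580, "ois_580.csv", "intensity")
  wcsv(run@i620, "ois_620.csv", "intensity")
  meta <- list(
    truth = .truthToList(run@truth),
    baseline = list(c_hbt0_um = run@baseline@cHbT0, s0 = run@baseline@s0),
    optics = list(wavelengths_nm = run@optics@wavelengths,
                  eps_hbo = run@optics@epsHbO, eps_hbr = run@optics@epsHbR,
                  pathlength_mm = run@optics@pathlength))
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  par <- run@paradigm
  yaml::write_yaml(list(kind = par@kind, rest_s = par@restS,
                        stim_s = par@stimS, recovery_s = par@recoveryS,
                        n_trials = par@nTrials,
                        inter_trial_s = par@interTrialS),
                   file.path(dir, "paradigm.yaml"))
  invisible(dir)
}

#' Read a synthetic run back from a directory
#'
#' @param dir directory written by [writeRun()].
#' @return a [SyntheticRun-class].
#' @export
readRun <- function(dir) {
  rcsv <- function(file, units) {
    df <- utils::read.csv(file.path(dir, file))
    dt <- diff(df$time_s[1:2])
    # guard against float error in the stored time axis (1/0.0999... Hz)
    rate <- round(1 / dt, 6)
    SampledTrace(df[[2]], rateHz = rate, t0S = df$time_s[1], units = units)
  }
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  par <- yaml::read_yaml(file.path(dir, "paradigm.yaml"))
  paradigm <- if (par$kind == "hypercapnia")
    hypercapniaParadigm(par$rest_s, par$stim_s, par$recovery_s)
  else
    whiskerParadigm(par$rest_s, par$stim_s, par$inter_trial_s, par$n_trials,
                    par$recovery_s)
  tr <- meta$truth
  truth <- GroundTruth(rcbfPeak = tr$rcbf_peak, rcmro2Peak = tr$rcmro2_peak,
                       alphaTrue = tr$alpha_true,
                       gammaRTrue = tr$gammaR_true,
                       gammaTTrue = tr$gammaT_true,
                       kTrue = if (is.null(tr$k_true)) NA_real_
                               else tr$k_true,
                       tauRiseS = tr$tau_rise_s, tauFallS = tr$tau_fall_s,
                       holdS = if (is.null(tr$hold_s)) 0 else tr$hold_s,
                       noiseSd = tr$noise_sd, seed = tr$seed)
  new("SyntheticRun",
      ldf = rcsv("ldf.csv", "perfusion-units"),
      i580 = rcsv("ois_580.csv", "counts"),
      i620 = rcsv("ois_620.csv", "counts"),
      truth = truth, paradigm = paradigm,
      baseline = BaselineConfig(meta$baseline$c_hbt0_um, meta$baseline$s0),
      optics = OpticsTable(meta$optics$wavelengths_nm, meta$optics$eps_hbo,
                           meta$optics$eps_hbr, meta$optics$pathlength_mm))
}

#' Write image stacks as multi-page TIFF
#'
#' Each wavelength's stack is stored as a 32-bit float multi-page TIFF.
#' Frames are rescaled into [0, 1] (the float range the TIFF writer
#' preserves) by a global scale recorded in \code{stacks.json}, together
#' with the ground-truth shifts and drift; \code{masks.tif} stores the ROI
#' (page 1) and control (page 2) masks.
#'
#' @param stacks the list returned by [generateImageStack()].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeImageStack <- function(stacks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(stacks$stack580, stacks$stack620)
  wtif <- function(st, file) {
    pages <- lapply(seq_len(dim(st)[3]), function(f) st[, , f] / scale)
    tiff::writeTIFF(pages, file.path(dir, file), bits.per.sample = 32L)
  }
  wtif(stacks$stack580, "stack_580.tif")
  wtif(stacks$stack620, "stack_620.tif")
  spec <- stacks$spec
  tiff::writeTIFF(list(spec@roiMask * 1, spec@controlMask * 1),
                  file.path(dir, "masks.tif"), bits.per.sample = 8L)
  jsonlite::write_json(
    list(scale = scale, shifts = unname(stacks$shifts),
         drift = stacks$drift,
         motion_amplitude = spec@motionAmplitude,
         illumination_drift_amplitude = spec@illuminationDriftAmplitude),
    file.path(dir, "stacks.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read image stacks written by [writeImageStack()]
#'
#' @param dir directory containing the TIFF/JSON files.
#' @return list with \code{stack580}, \code{stack620}, \code{shifts},
#'   \code{drift}, \code{roiMask}, \code{controlMask}.
#' @export
readImageStack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stacks.json"),
                              simplifyVector = TRUE)
  rtif <- function(file) {
    pages <- tiff::readTIFF(file.path(dir, file), all = TRUE)
    st <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (f in seq_along(pages)) st[, , f] <- pages[[f]] * meta$scale
    st
  }
  masks <- tiff::readTIFF(file.path(dir, "masks.tif"), all = TRUE)
  list(stack580 = rtif("stack_580.tif"), stack620 = rtif("stack_620.tif"),
       shifts = matrix(meta$shifts, ncol = 2,
                       dimnames = list(NULL, c("dy", "dx"))),
       drift = meta$drift,
       roiMask = masks[[1]] > 0.5, controlMask = masks[[2]] > 0.5)
}
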
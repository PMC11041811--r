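#' Solve the compartment coefficients from an isometabolic run
#'
#' An isometabolic hypercapnia run pins rCMRO2 = 1 over the calibration
#' window, which constrains (gammaR, gammaT) to the line
#' rCBF * (1 + gammaR * a) = 1 + gammaT * b in coefficient space (one linear
#' constraint from the window means, hence a non-unique solution). Following
#' the convention of anchoring at the uninformed assumption, the returned
#' pair is the point on that line closest to (1, 1) in the Euclidean sense
#' (orthogonal projection). [model1()] evaluated at the summary with the
#' returned pair equals 1 exactly.
#'
#' A per-timepoint variant (\code{perTimepoint = TRUE}) instead minimizes
#' the sum of squared per-sample constraint residuals
#' rCBF_t * (1 + gammaR * a_t) - (1 + gammaT * b_t) with a ridge penalty
#' \code{lambda * ||gamma - (1,1)||^2} pulling toward the anchor.
#'
#' @param s a [CalibrationWindow-class] summary.
#' @param perTimepoint use the regularized per-sample least-squares variant.
#' @param lambda ridge weight for the per-timepoint variant.
#' @param traces named list with numeric vectors \code{rcbf}, \code{a},
#'   \code{b} restricted to the calibration window (per-timepoint variant
#'   only).
#' @return named numeric: \code{gammaR}, \code{gammaT}.
#' @examples
#' calibrateGammas(CalibrationWindow(1.25, -0.2, 0.1))  # (0.6552, 0.8621)
#' @export
calibrateGammas <- function(s, perTimepoint = FALSE, lambda = 1e-3,
                            traces = NULL) {
  stopifnot(is(s, "CalibrationWindow"))
  if (s@rcbfMean <= 0) stop("rcbfMean must be positive")
  if (perTimepoint) {
    if (is.null(traces))
      stop("per-timepoint calibration needs the window traces")
    rc <- traces$rcbf; a <- traces$a; b <- traces$b
    # residual: rc*(1 + gR*a) - (1 + gT*b) = (rc*a)*gR + (-b)*gT + (rc - 1)
    X <- cbind(rc * a, -b)
    y <- -(rc - 1)
    A <- crossprod(X) + lambda * diag(2)
    rhs <- crossprod(X, y) + lambda * c(1, 1)
    g <- solve(A, rhs)
    return(c(gammaR = g[1], gammaT = g[2]))
  }
  A <- s@rcbfMean * s@aMean
  B <- -s@bMean
  C <- s@rcbfMean - 1
  if (A == 0 && B == 0) {
    if (abs(C) < 1e-12) return(c(gammaR = 1, gammaT = 1))
    stop("infeasible calibration: no hemoglobin change but rCBF != 1")
  }
  f <- (A + B + C) / (A^2 + B^2)
  c(gammaR = 1 - f * A, gammaT = 1 - f * B)
}

#' Solve the single-wavelength calibration coefficient
#'
#' Forces the single-wavelength model to unity on the calibration window:
#' k = (rCBF^(alpha - 1) - 1) / x, the unique value with
#' rCBF^(1 - alpha) * (1 + k * x) = 1 at the window means. x is the
#' window-mean 620 nm absorbance change (measured source) or the mean of
#' rC_HbR - 1 = a (idealized source).
#'
#' @param s a [CalibrationWindow-class].
#' @param alpha Grubb exponent used inside the model.
#' @param source \code{"dA620"} or \code{"rCHbR"}.
#' @return k (scalar).
#' @examples
#' calibrateK(CalibrationWindow(2.1367, NA, NA, dA620Mean = -0.02622),
#'            alpha = 0.38)  # ~14.32
#' @export
calibrateK <- function(s, alpha, source = c("dA620", "rCHbR")) {
  stopifnot(is(s, "CalibrationWindow"))
  source <- match.arg(source)
  if (s@rcbfMean <= 0) stop("rcbfMean must be positive")
  x <- if (source == "dA620") s@dA620Mean else s@aMean
  if (!is.finite(x)) stop("calibration signal mean is not available")
  num <- s@rcbfMean^(alpha - 1) - 1
  if (x == 0) {
    if (abs(num) < 1e-12) return(0)
    stop("infeasible calibration: zero HbR signal but rCBF != 1")
  }
  num / x
}

#' Estimate the Grubb flow-volume exponent
#'
#' Under Grubb's power law rCBV = rCBF^alpha (with total hemoglobin as the
#' blood-volume proxy), alpha = ln(rC_HbT) / ln(rCBF) at matched window
#' means.
#'
#' @param rcbfMean window-mean flow ratio (> 0, != 1).
#' @param rchbtMean window-mean total-hemoglobin ratio (> 0).
#' @return alpha (scalar).
#' @examples
#' estimateAlpha(2.1367, 1.33445)  # 0.3800
#' @export
estimateAlpha <- function(rcbfMean, rchbtMean) {
  if (rcbfMean <= 0 || rchbtMean <= 0)
    stop("flow and volume ratios must be positive")
  if (abs(rcbfMean - 1) < 1e-12)
    stop("undefined exponent: rCBF = 1 carries no volume-coupling information")
  log(rchbtMean) / log(rcbfMean)
}

#' Calibrate all three models on one hypercapnia summary
#'
#' Convenience wrapper producing a [CalibrationResult-class] for a single
#' run: (gammaR, gammaT) by orthogonal projection, the Grubb exponent from
#' the run's own (rCBF, rC_HbT) window means, and the single-wavelength
#' coefficient for both signal sources using that exponent (override via
#' \code{alpha}). The two-wavelength flow-free model reuses the same
#' (gammaR, gammaT): replacing the measured flow mean by
#' (1 + b)^(1/alpha) with the run's own alpha leaves the calibration
#' constraint unchanged because (1 + b)^(1/alpha) equals the measured flow
#' mean by construction of alpha.
#'
#' @param summary a hypercapnia [RunSummary-class] (from
#'   [co2ResponseSummary()]) or a [CalibrationWindow-class].
#' @param alpha optional fixed Grubb exponent (e.g. a cross-animal mean);
#'   default is the run's own estimate.
#' @param source run identifier stored in the result.
#' @param co2Level label stored in the result.
#' @return a [CalibrationResult-class].
#' @export
calibrateRun <- function(summary, alpha = NULL, source = "", co2Level = "") {
  s <- if (is(summary, "RunSummary")) calibrationWindow(summary) else summary
  stopifnot(is(s, "CalibrationWindow"))
  g <- calibrateGammas(s)
  a <- if (is.null(alpha)) estimateAlpha(s@rcbfMean, 1 + s@bMean) else alpha
  new("CalibrationResult", gammaR = unname(g["gammaR"]),
      gammaT = unname(g["gammaT"]),
      k = calibrateK(s, a, "dA620"), kIdeal = calibrateK(s, a, "rCHbR"),
      alpha = a, n = 1L, source = source, co2Level = co2Level)
}

#' Pool calibration coefficients across runs
#'
#' Arithmetic mean of each coefficient across runs (runs at different CO2
#' levels are pooled into one mean), with the sample (n - 1) standard
#' deviation recorded. A single input is returned as itself with sd 0.
#'
#' @param results list of [CalibrationResult-class] objects.
#' @return an aggregated [CalibrationResult-class].
#' @export
aggregateCalibrations <- function(results) {
  if (!length(results)) stop("cannot aggregate an empty list")
  stopifnot(all(vapply(results, is, logical(1), "CalibrationResult")))
  pull <- function(slotName) vapply(results, slot, numeric(1), slotName)
  sdOr0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  vals <- lapply(c("gammaR", "gammaT", "k", "kIdeal", "alpha"), pull)
  names(vals) <- c("gammaR", "gammaT", "k", "kIdeal", "alpha")
  new("CalibrationResult",
      gammaR = mean(vals$gammaR), gammaT = mean(vals$gammaT),
      k = mean(vals$k), kIdeal = mean(vals$kIdeal),
      alpha = mean(vals$alpha),
      gammaRSd = sdOr0(vals$gammaR), gammaTSd = sdOr0(vals$gammaT),
      kSd = sdOr0(vals$k), kIdealSd = sdOr0(vals$kIdeal),
      alphaSd = sdOr0(vals$alpha),
      n = length(results), source = "aggregate",
      co2Level = paste(unique(vapply(results, slot, character(1),
                                     "co2Level")), collapse = "+"))
}
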
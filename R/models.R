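#' Relative oxygen extraction fraction
#'
#' Under steady-state Fick's law with all oxygen hemoglobin-bound, the OEF
#' equals C_HbR/C_HbT, so its ratio to baseline is
#' rOEF = (1 + a)/(1 + b) with a = dC_HbR/C_HbR,0 and b = dC_HbT/C_HbT,0.
#'
#' @param a fractional deoxy-hemoglobin change(s).
#' @param b fractional total-hemoglobin change(s).
#' @return rOEF, same length as the inputs.
#' @examples
#' roef(-0.1660, 0.1129)  # ~0.7494, a 5% CO2 operating point
#' @export
roef <- function(a, b) {
  if (any(1 + b <= 0))
    stop("nonphysical state: 1 + b must be positive")
  (1 + a) / (1 + b)
}

#' Two-wavelength rCMRO2 model with measured flow (model family 1)
#'
#' rCMRO2 = rCBF * (1 + gammaR * a) / (1 + gammaT * b). The compartment
#' coefficients gammaR and gammaT weight the fractional deoxy- and
#' total-hemoglobin changes by the venous volume fraction they represent;
#' with gammaR = gammaT = 1 the model reduces to plain Fick scaling
#' rCBF * rOEF.
#'
#' @param rcbf flow ratio(s) relative to baseline (> 0).
#' @param a,b fractional deoxy- and total-hemoglobin changes.
#' @param gammaR,gammaT compartment coefficients.
#' @return rCMRO2 ratio(s).
#' @examples
#' model1(1.2917, -0.1660, 0.1129)  # ~0.968
#' @export
model1 <- function(rcbf, a, b, gammaR = 1, gammaT = 1) {
  if (any(rcbf <= 0)) stop("rcbf must be positive")
  den <- 1 + gammaT * b
  if (any(den <= 0))
    stop("nonphysical state: 1 + gammaT * b must be positive")
  rcbf * (1 + gammaR * a) / den
}

#' Two-wavelength rCMRO2 model without flow measurements (model family 2)
#'
#' Flow is estimated from total hemoglobin through Grubb's power law
#' rCBV = rCBF^alpha, giving
#' rCMRO2 = (1 + b)^(1/alpha) * (1 + gammaR * a) / (1 + gammaT * b).
#' Identical to [model1()] whenever rcbf = (1 + b)^(1/alpha) exactly.
#'
#' @param a,b fractional deoxy- and total-hemoglobin changes.
#' @param gammaR,gammaT compartment coefficients.
#' @param alpha Grubb exponent, in (0, 1).
#' @return rCMRO2 ratio(s).
#' @export
model2 <- function(a, b, gammaR = 1, gammaT = 1, alpha = 0.38) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single positive number")
  if (any(1 + b <= 0))
    stop("nonphysical state: 1 + b must be positive")
  model1((1 + b)^(1 / alpha), a, b, gammaR, gammaT)
}

#' Single-wavelength calibrated rCMRO2 model (model family 3)
#'
#' The calibrated-fMRI-style form rCMRO2 = rCBF^(1 - alpha) * (1 + k * x),
#' where x is the deoxy-hemoglobin-sensitive signal: the 620 nm absorbance
#' change dA620 (measured variant, using rC_HbR ~ 1 + dA620) or rC_HbR - 1
#' (idealized variant). The calibration coefficient k absorbs the baseline
#' deoxy-hemoglobin concentration, the compartment coefficient and the
#' optical constants, so x is used as-is with no rescaling.
#'
#' @param rcbf flow ratio(s) (> 0).
#' @param x HbR-change signal(s).
#' @param k calibration coefficient (1/absorbance or 1/ratio units, matching
#'   the source of \code{x}).
#' @param alpha Grubb exponent.
#' @return rCMRO2 ratio(s).
#' @examples
#' model3(2.1367, -0.02622, k = 14.32, alpha = 0.38)  # ~1
#' @export
model3 <- function(rcbf, x, k, alpha = 0.38) {
  if (any(rcbf <= 0)) stop("rcbf must be positive")
  rcbf^(1 - alpha) * (1 + k * x)
}
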
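#' The modified Beer-Lambert unmixing matrix
#'
#' Builds the 2x2 matrix M with rows indexed by wavelength and columns by
#' chromophore, M[lambda, ] = (eps_HbO(lambda), eps_HbR(lambda)) * D(lambda),
#' so that (dA_580, dA_620)' = M (dC_HbO, dC_HbR)'.
#'
#' @param optics an [OpticsTable-class].
#' @return a 2x2 numeric matrix (absorbance per uM).
#' @export
mbllMatrix <- function(optics) {
  stopifnot(is(optics, "OpticsTable"))
  m <- cbind(optics@epsHbO * optics@pathlength,
             optics@epsHbR * optics@pathlength)
  dimnames(m) <- list(paste0("dA", optics@wavelengths), c("dCHbO", "dCHbR"))
  m
}

#' Absorbance change from an intensity trace
#'
#' dA(t) = -ln(I(t)/I0), natural logarithm. I0 is typically the
#' baseline-window mean of the same trace, so that dA averages to zero over
#' the baseline.
#'
#' @param intensity a [SampledTrace-class] (or numeric vector) of strictly
#'   positive intensities.
#' @param i0 reference intensity (> 0).
#' @return absorbance-change trace of the same shape as the input.
#' @examples
#' absorbanceChange(SampledTrace(1000 * exp(-0.05), rateHz = 10), i0 = 1000)
#' @export
absorbanceChange <- function(intensity, i0) {
  stopifnot(length(i0) == 1L, is.finite(i0), i0 > 0)
  v <- if (is(intensity, "SampledTrace")) intensity@values else intensity
  if (any(v <= 0)) stop("intensity must be strictly positive")
  dA <- -log(v / i0)
  if (is(intensity, "SampledTrace"))
    SampledTrace(dA, rateHz = intensity@rateHz, t0S = intensity@t0S,
                 units = "absorbance")
  else dA
}

#' Baseline compartment concentrations
#'
#' C_HbO,0 = S0 * C_HbT,0 and C_HbR,0 = (1 - S0) * C_HbT,0.
#'
#' @param baseline a [BaselineConfig-class].
#' @return named numeric: \code{cHbO0}, \code{cHbR0} in uM.
#' @examples
#' baselineConcentrations(BaselineConfig(280, 0.75))  # 210, 70 uM
#' @export
baselineConcentrations <- function(baseline) {
  stopifnot(is(baseline, "BaselineConfig"))
  c(cHbO0 = baseline@s0 * baseline@cHbT0,
    cHbR0 = (1 - baseline@s0) * baseline@cHbT0)
}

#' Forward Beer-Lambert: concentrations to absorbance changes
#'
#' Applies the MBLL matrix per sample (generator side of the round trip).
#'
#' @param dCHbO,dCHbR numeric vectors of concentration changes, uM.
#' @param optics an [OpticsTable-class].
#' @return list with numeric vectors \code{dA1} and \code{dA2} (in the order
#'   of \code{optics@wavelengths}).
#' @export
forwardAbsorbance <- function(dCHbO, dCHbR, optics) {
  stopifnot(length(dCHbO) == length(dCHbR))
  m <- mbllMatrix(optics)
  list(dA1 = m[1, 1] * dCHbO + m[1, 2] * dCHbR,
       dA2 = m[2, 1] * dCHbO + m[2, 2] * dCHbR)
}

#' Unmix absorbance changes into hemoglobin concentration changes
#'
#' Solves the 2x2 modified Beer-Lambert system independently at every sample
#' (no temporal regularization) for (dC_HbO, dC_HbR); dC_HbT is their sum,
#' so conservation dC_HbT = dC_HbO + dC_HbR holds exactly by construction.
#'
#' @param dA1,dA2 absorbance-change traces ([SampledTrace-class] or numeric)
#'   at the first and second wavelength of \code{optics}; equal length and
#'   alignment required.
#' @param optics an [OpticsTable-class]; its matrix must be well conditioned
#'   (condition number below 1e8).
#' @return list of numeric vectors \code{dCHbO}, \code{dCHbR}, \code{dCHbT}
#'   (uM).
#' @examples
#' op <- defaultOptics()
#' fa <- forwardAbsorbance(2.5, -1.0, op)
#' unmix(fa$dA1, fa$dA2, op)  # recovers 2.5 and -1.0
#' @export
unmix <- function(dA1, dA2, optics) {
  v1 <- if (is(dA1, "SampledTrace")) dA1@values else dA1
  v2 <- if (is(dA2, "SampledTrace")) dA2@values else dA2
  if (length(v1) != length(v2))
    stop("absorbance traces must have equal length")
  m <- mbllMatrix(optics)
  if (kappa(m, exact = TRUE) > 1e8)
    stop("unmixing matrix is ill-conditioned (condition number > 1e8)")
  sol <- solve(m, rbind(v1, v2))
  list(dCHbO = unname(sol[1, ]), dCHbR = unname(sol[2, ]),
       dCHbT = unname(sol[1, ] + sol[2, ]))
}
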
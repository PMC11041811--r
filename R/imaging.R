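## Sub-pixel rigid registration via Fourier cross-correlation with local
## upsampled-DFT refinement, plus illumination correction and ROI extraction.

fftfreqInts <- function(n)
  c(0:(ceiling(n / 2) - 1), -(n %/% 2):-1)[seq_len(n)]

## Upsampled portion of the inverse DFT of `inp` (matrix-multiply DFT):
## an nor x noc patch at resolution 1/usf px, offset by (roff, coff).
.dftUpsample <- function(inp, nor, noc, usf, roff, coff) {
  nr <- nrow(inp); nc <- ncol(inp)
  kernc <- exp((2i * pi / (nc * usf)) *
                 outer(fftfreqInts(nc), (0:(noc - 1)) - coff))
  kernr <- exp((2i * pi / (nr * usf)) *
                 outer((0:(nor - 1)) - roff, fftfreqInts(nr)))
  kernr %*% inp %*% kernc
}

#' Estimate the rigid translation between two frames
#'
#' 2D Fourier-based, translation-only registration: the integer shift
#' maximizing the cross-correlation is found from the full inverse FFT of
#' the cross-power product, then refined to 1/\code{upsample} pixel by an
#' upsampled discrete Fourier transform evaluated only in a +/- 0.75 px
#' neighborhood of the integer peak. The returned shift \code{(dy, dx)} is
#' the displacement of \code{frame} relative to \code{reference}:
#' \code{frame(y, x) ~ reference(y - dy, x - dx)}.
#'
#' @param frame,reference numeric matrices of equal size.
#' @param upsample refinement factor (>= 1); 20 gives 0.05 px resolution.
#' @return named numeric \code{c(dy, dx)} in pixels.
#' @examples
#' ref <- outer(sin(seq_len(32) / 3), cos(seq_len(32) / 5)) + 2
#' sh <- estimateTranslation(translateFrame(ref, 2.4, -1.6), ref)
#' round(sh, 2)
#' @export
estimateTranslation <- function(frame, reference, upsample = 20) {
  stopifnot(is.matrix(frame), is.matrix(reference),
            all(dim(frame) == dim(reference)), upsample >= 1)
  if (stats::sd(frame) == 0 || stats::sd(reference) == 0)
    stop("undefined registration: constant (zero-variance) image")
  nr <- nrow(frame); nc <- ncol(frame)
  Ff <- stats::fft(frame)
  Fr <- stats::fft(reference)
  R <- Ff * Conj(Fr)
  cc <- Re(stats::fft(R, inverse = TRUE))
  pk <- which.max(cc)
  r0 <- (pk - 1) %% nr
  c0 <- (pk - 1) %/% nr
  if (r0 > nr / 2) r0 <- r0 - nr
  if (c0 > nc / 2) c0 <- c0 - nc
  usf <- as.integer(round(upsample))
  if (usf > 1L) {
    noe <- ceiling(usf * 1.5)
    dftshift <- noe %/% 2
    patch <- .dftUpsample(R, noe, noe, usf,
                          dftshift - r0 * usf, dftshift - c0 * usf)
    pk2 <- which.max(Re(patch))
    rloc <- (pk2 - 1) %% noe
    cloc <- (pk2 - 1) %/% noe
    r0 <- r0 + (rloc - dftshift) / usf
    c0 <- c0 + (cloc - dftshift) / usf
  }
  c(dy = r0, dx = c0)
}

#' Translate a frame by a (sub-pixel) shift in the Fourier domain
#'
#' Applies the phase ramp exp(-2*pi*i*(u*dy/nr + v*dx/nc)), producing
#' \code{out(y, x) = frame(y - dy, x - dx)} with circular boundary
#' conditions; exact for band-limited content.
#'
#' @param frame numeric matrix.
#' @param dy,dx shift in pixels (may be fractional).
#' @return translated matrix.
#' @export
translateFrame <- function(frame, dy, dx) {
  nr <- nrow(frame); nc <- ncol(frame)
  u <- fftfreqInts(nr); v <- fftfreqInts(nc)
  ramp <- exp(-2i * pi * (outer(u, rep(1, nc)) * dy / nr +
                            outer(rep(1, nr), v) * dx / nc))
  Re(stats::fft(stats::fft(frame) * ramp, inverse = TRUE)) / (nr * nc)
}

#' Register an image stack to a reference frame
#'
#' Estimates each frame's translation relative to the reference frame (the
#' first frame by default, matching the convention of using the first image
#' of an experiment) and translates it back by the negative shift in the
#' Fourier domain. The reference frame is returned unchanged.
#'
#' @param stack 3D numeric array, height x width x frames.
#' @param referenceIndex index of the reference frame.
#' @param upsample sub-pixel refinement factor; see [estimateTranslation()].
#' @return list with the registered \code{stack} and the \code{shifts}
#'   matrix (frames x 2, columns dy, dx).
#' @export
registerStack <- function(stack, referenceIndex = 1, upsample = 20) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] >= 1L)
  nf <- dim(stack)[3]
  ref <- stack[, , referenceIndex]
  shifts <- matrix(0, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  out <- stack
  for (f in seq_len(nf)) {
    if (f == referenceIndex) next
    sh <- estimateTranslation(stack[, , f], ref, upsample)
    shifts[f, ] <- sh
    if (any(sh != 0))
      out[, , f] <- translateFrame(stack[, , f], -sh[1], -sh[2])
  }
  list(stack = out, shifts = shifts)
}

#' Remove common-mode illumination fluctuations
#'
#' Regresses the control-region mean trace (regions over bone or head-bar,
#' which carry illumination drift but no hemodynamics) out of every pixel's
#' time course. Each pixel is fit by least squares onto an intercept plus
#' the control trace, and only the control-trace component is removed, so
#' the pixel's temporal mean -- and with it the absolute baseline intensity
#' needed for absorbance computation -- is preserved. A control trace with
#' zero variance carries no drift information; the stack is then returned
#' unchanged with a warning.
#'
#' @param stack 3D numeric array, height x width x frames.
#' @param controlMask logical matrix selecting the control pixels.
#' @return corrected stack of the same shape.
#' @export
intensityCorrect <- function(stack, controlMask) {
  stopifnot(length(dim(stack)) == 3L, is.logical(controlMask),
            all(dim(controlMask) == dim(stack)[1:2]))
  if (!any(controlMask)) stop("control mask is empty")
  d <- dim(stack)
  nf <- d[3]
  P <- matrix(stack, nrow = d[1] * d[2], ncol = nf)  # pixels x time
  g <- colMeans(P[as.vector(controlMask), , drop = FALSE])
  gc <- g - mean(g)
  ss <- sum(gc^2)
  if (ss < 1e-12 * max(mean(g)^2, 1)) {
    warning("control-region trace is constant; no correction applied")
    return(stack)
  }
  beta <- (P %*% gc) / ss            # per-pixel slope on the drift regressor
  P <- P - beta %*% gc               # removes drift, keeps temporal mean
  array(P, dim = d)
}

#' Extract the ROI mean time course from a stack
#'
#' Per-frame mean over the masked pixels (the oval placed over the LDF
#' sampling area in the experimental convention).
#'
#' @param stack 3D numeric array, height x width x frames.
#' @param roiMask logical matrix selecting the ROI pixels.
#' @param rateHz,t0S,units metadata for the returned trace.
#' @return a [SampledTrace-class].
#' @export
extractRoi <- function(stack, roiMask, rateHz = 10, t0S = 0,
                       units = "counts") {
  stopifnot(length(dim(stack)) == 3L, is.logical(roiMask),
            all(dim(roiMask) == dim(stack)[1:2]))
  if (!any(roiMask)) stop("ROI mask is empty")
  d <- dim(stack)
  P <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])
  SampledTrace(colMeans(P[as.vector(roiMask), , drop = FALSE]),
               rateHz = rateHz, t0S = t0S, units = units)
}
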
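# Classical (non-learned) EMI removal: the transverse-gradient detector used
# before the learned approach, plus representative median/Gaussian filters.
# The detector illustrates the classical failure mode: one-column vessel
# cross-sections look exactly like streaks to a transverse gradient test.

#' Detect streak pixels by transverse gradient
#'
#' Flags pixel (i, j) when its value exceeds both transverse neighbours
#' (columns j-1 and j+1, circular over the 360-degree scan) by more than
#' \code{factor * thermalLevel}. Flags depend only on the local transverse
#' neighbourhood and the global threshold.
#'
#' @param img envelope matrix with at least 3 columns.
#' @param factor positive multiplier over the thermal level.
#' @param thermalLevel background noise level (see
#'   \code{\link{estimateThermalLevel}}).
#' @return Logical H x W matrix of flagged pixels.
#' @export
gradientDetect <- function(img, factor = 2, thermalLevel) {
  stopifnot(is.matrix(img))
  if (ncol(img) < 3L) stop("need at least 3 angular columns")
  if (factor <= 0) stop("factor must be > 0")
  W <- ncol(img)
  left <- img[, c(W, seq_len(W - 1L)), drop = FALSE]
  right <- img[, c(seq_len(W)[-1], 1L), drop = FALSE]
  thr <- factor * thermalLevel
  (img - left > thr) & (img - right > thr)
}

#' Replace flagged pixels by the minimum of their transverse neighbours
#'
#' Mirrors the ground-truth cleaning rule applied to detected pixels:
#' a flagged pixel takes the smaller of its left/right neighbours' original
#' values (never exceeding its own original value); unflagged pixels are
#' bit-identical.
#'
#' @param img envelope matrix.
#' @param mask logical matrix of flagged pixels.
#' @return The repaired matrix.
#' @export
replaceFlagged <- function(img, mask) {
  checkSameShape(img, mask)
  W <- ncol(img)
  left <- img[, c(W, seq_len(W - 1L)), drop = FALSE]
  right <- img[, c(seq_len(W)[-1], 1L), drop = FALSE]
  repl <- pmin(img, left, right)
  out <- img
  out[mask] <- repl[mask]
  out
}

#' Transverse-gradient denoiser
#'
#' Convenience composition of \code{\link{gradientDetect}} and
#' \code{\link{replaceFlagged}} with the same method interface as the
#' networks.
#'
#' @inheritParams gradientDetect
#' @return The repaired matrix.
#' @export
gradientDenoise <- function(img, factor = 2, thermalLevel) {
  replaceFlagged(img, gradientDetect(img, factor, thermalLevel))
}

#' Classical 2-D filters
#'
#' Representative stand-ins for generic classical denoising: 2-D median
#' filtering (odd kernel side) or Gaussian smoothing. Filtering is done with
#' EBImage; for the median the image is rescaled to [0, 1] and back because
#' the constant-time median bins intensities.
#'
#' @param img envelope matrix.
#' @param kind \code{"median"} or \code{"gaussian"}.
#' @param size odd kernel side for the median filter.
#' @param sigma Gaussian scale in pixels.
#' @return The filtered matrix.
#' @export
classicalFilter <- function(img, kind = c("median", "gaussian"), size = 3L,
                            sigma = 1) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(img))
  if (kind == "median") {
    size <- as.integer(size)
    if (size %% 2L == 0L) stop("median kernel side must be odd")
    m <- max(img)
    if (m == 0) return(img)
    m * EBImage::medianFilter(img / m, (size - 1L) %/% 2L)
  } else {
    if (sigma <= 0.05) return(img)  # below half a pixel the kernel is a delta
    EBImage::gblur(img, sigma)
  }
}
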
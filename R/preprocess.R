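# Data preparation: Hilbert-envelope detection along the depth direction,
# upper-region cropping, threshold-based ground-truth cleaning outside the
# segmented tissue region, dataset splitting and paired translation
# augmentation.

#' Envelope detection along the depth direction
#'
#' Computes, per A-line (per column), the magnitude of the analytic signal
#' obtained by zeroing the negative-frequency half of the FFT spectrum; this
#' is the Hilbert-transform envelope used to convert raw RF B-scans into
#' nonnegative envelope images.
#'
#' @param raw signed H x W RF matrix (H >= 2).
#' @return Nonnegative H x W envelope matrix.
#' @examples
#' t <- seq(0, 1, length.out = 128)
#' env <- envelopeDetect(matrix(3 * sin(2 * pi * 16 * t), ncol = 1))
#' @export
envelopeDetect <- function(raw) {
  stopifnot(is.matrix(raw))
  if (nrow(raw) < 2L) stop("need at least 2 depth samples")
  stopIfNotFinite(raw, "raw B-scan")
  N <- nrow(raw)
  h <- numeric(N)
  h[1] <- 1
  if (N %% 2 == 0) {
    h[N / 2 + 1] <- 1
    if (N > 2) h[2:(N / 2)] <- 2
  } else {
    h[2:((N + 1) / 2)] <- 2
  }
  analytic <- mvfft(mvfft(raw) * h, inverse = TRUE) / N
  Mod(analytic)
}

#' Crop the upper (shallow) region of a B-scan
#'
#' Keeps rows 1..\code{rows} of every column unchanged; used to extract the
#' information-bearing 304 x 800 region from raw 400 x 800 scans.
#'
#' @param img H x W matrix.
#' @param rows number of shallow rows to keep (default 304).
#' @return The \code{rows} x W cropped matrix.
#' @export
cropUpper <- function(img, rows = 304L) {
  stopifnot(is.matrix(img))
  rows <- as.integer(rows)
  if (rows > nrow(img)) stop("rows exceeds image height")
  img[seq_len(rows), , drop = FALSE]
}

#' Estimate the thermal noise level
#'
#' Mean envelope amplitude over a signal-free background region. In the
#' envelope domain the noise floor is a positive offset, so the mean (not the
#' standard deviation) is the natural level; the cleaning threshold is then
#' \code{thresholdFactor} times this level (default factor 2).
#'
#' @param img envelope matrix.
#' @param background logical matrix of the same shape marking background
#'   pixels (e.g. the complement of the tissue mask).
#' @return Scalar mean background amplitude.
#' @export
estimateThermalLevel <- function(img, background) {
  checkSameShape(img, background)
  if (!any(background)) stop("background region is empty")
  mean(img[background])
}

#' Clean noise outside the tissue mask
#'
#' Pixels inside the mask are left bit-identical. An outside-mask pixel whose
#' value exceeds \code{threshold} is replaced by the minimum of its
#' 4-neighbours' original (pre-pass) values, which makes the pass independent
#' of traversal order; the replacement is clamped so it never raises a pixel
#' above its original value. Other pixels are unchanged. Columns are treated
#' circularly (360-degree geometry), rows are not.
#'
#' @param img envelope matrix.
#' @param mask logical matrix, TRUE inside the tissue region to preserve.
#' @param threshold positive scalar, typically
#'   \code{2 * estimateThermalLevel(...)}.
#' @return The cleaned matrix.
#' @export
cleanOutsideMask <- function(img, mask, threshold) {
  checkSameShape(img, mask)
  if (threshold <= 0) stop("threshold must be > 0")
  H <- nrow(img); W <- ncol(img)
  up <- rbind(Inf, img[-H, , drop = FALSE])
  down <- rbind(img[-1, , drop = FALSE], Inf)
  left <- img[, c(W, seq_len(W - 1L)), drop = FALSE]
  right <- img[, c(seq_len(W)[-1], 1L), drop = FALSE]
  if (W == 1L) { left[] <- Inf; right[] <- Inf }
  nmin <- pmin(up, down, left, right)
  out <- img
  fire <- !mask & img > threshold
  out[fire] <- pmin(img[fire], nmin[fire])
  out
}

#' Randomly partition image indices into training and validation sets
#'
#' A seeded uniform partition: \code{round(n * trainFraction)} indices go to
#' training, the remainder to validation (the 1000-image protocol with
#' fraction 0.7 gives 700/300).
#'
#' @param n number of images.
#' @param trainFraction fraction assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return A \linkS4class{DatasetSplit}.
#' @export
splitDataset <- function(n, trainFraction = 0.7, seed = NA_integer_) {
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 images to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  withSeed(seed, {
    perm <- sample.int(n)
    k <- as.integer(round(n * trainFraction))
    k <- min(max(k, 1L), n - 1L)
    new("DatasetSplit", train = sort(perm[seq_len(k)]),
        val = sort(perm[(k + 1L):n]), test = integer(),
        seed = as.integer(seed))
  })
}

# Shift a matrix by (dr, dc): circular in columns (360-degree wrap),
# zero-filled in rows (depth does not wrap). Positive dr moves content down.
shiftImage <- function(img, dr, dc) {
  H <- nrow(img); W <- ncol(img)
  if (dc %% W != 0) {
    dc <- ((dc %% W) + W) %% W
    img <- img[, c((W - dc + 1L):W, seq_len(W - dc)), drop = FALSE]
  }
  if (dr != 0) {
    out <- matrix(0, H, W)
    if (dr > 0 && dr < H) out[(dr + 1L):H, ] <- img[seq_len(H - dr), ]
    else if (dr < 0 && -dr < H) out[seq_len(H + dr), ] <- img[(-dr + 1L):H, ]
    img <- out
  }
  img
}

#' Random paired translation augmentation
#'
#' Draws one displacement uniformly in \code{[-maxShift, +maxShift]} (rows
#' and columns independently) and applies it identically to the noisy and
#' clean members of a training pair. Horizontal shifts are circular
#' (360-degree continuity); vertical shifts fill vacated rows with zeros.
#'
#' @param noisy,clean matched H x W matrices.
#' @param maxShift integer(2) maximum absolute shift \code{c(rows, cols)}.
#' @param seed integer seed, or NA to use the current RNG stream.
#' @return List with shifted \code{noisy}, \code{clean} and the drawn
#'   \code{shift = c(dr, dc)}.
#' @export
augmentTranslate <- function(noisy, clean, maxShift = c(30L, 80L),
                             seed = NA_integer_) {
  checkSameShape(noisy, clean)
  if (any(maxShift >= dim(noisy)))
    stop("maxShift must be smaller than the image dimensions")
  withSeed(seed, {
    dr <- runifInt(1L, -maxShift[1], maxShift[1])
    dc <- runifInt(1L, -maxShift[2], maxShift[2])
    list(noisy = shiftImage(noisy, dr, dc),
         clean = shiftImage(clean, dr, dc), shift = c(dr, dc))
  })
}
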
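# Volume-level products: slice-wise denoising, radial maximum amplitude
# projection (RMAP) into an en-face angle x slice vasculature map, and a
# polar rendering of circular B-scan cross-sections.

#' Apply a denoiser slice-by-slice to a C-scan volume
#'
#' The method runs independently on every B-scan slice; slice order and
#' count are preserved. A failure on any slice aborts with the slice index.
#'
#' @param method a \linkS4class{NetworkModel} or function(matrix) -> matrix.
#' @param volume a \linkS4class{CScanVolume}.
#' @return The denoised \linkS4class{CScanVolume}.
#' @export
denoiseVolume <- function(method, volume) {
  stopifnot(is(volume, "CScanVolume"))
  fn <- asDenoiser(method)
  out <- vector("list", length(volume))
  for (s in seq_along(volume@slices)) {
    out[[s]] <- tryCatch(fn(volume@slices[[s]]),
                         error = function(e)
                           stop("denoising failed on slice ", s, ": ",
                                conditionMessage(e)))
  }
  cscanVolume(out)
}

#' @rdname denoiseVolume
#' @param object a \linkS4class{NetworkModel}.
#' @param x a \linkS4class{CScanVolume}.
#' @param ... unused.
#' @export
setMethod("denoise", signature("NetworkModel", "CScanVolume"),
          function(object, x, ...) denoiseVolume(object, x))

#' Radial maximum amplitude projection
#'
#' For each slice and angular column, takes the maximum over depth of that
#' A-line, producing the angle x slice en-face vasculature map used to
#' present pullback volumes.
#'
#' @param volume a \linkS4class{CScanVolume} of H x W slices.
#' @return W x S matrix (rows: angular position, columns: slice).
#' @export
rmap <- function(volume) {
  stopifnot(is(volume, "CScanVolume"))
  if (length(volume) < 1L) stop("empty volume")
  vapply(volume@slices, function(s) apply(s, 2, max),
         numeric(ncol(volume@slices[[1]])))
}

#' Render a B-scan as a circular cross-section
#'
#' Maps (depth row r, angle column w) to the Cartesian position at radius
#' \code{probeRadiusPx + r - 1} and angle \code{2*pi*(w-1)/W} about the
#' image centre (angle 0 points right), with nearest-neighbour lookup;
#' pixels outside the annulus are zero.
#'
#' @param bscan H x W envelope matrix.
#' @param probeRadiusPx inner (probe surface) radius in pixels.
#' @param outputSize side of the square output; must accommodate the outer
#'   radius.
#' @return outputSize x outputSize matrix.
#' @export
polarRender <- function(bscan, probeRadiusPx = 20, outputSize = NULL) {
  stopifnot(is.matrix(bscan))
  H <- nrow(bscan); W <- ncol(bscan)
  outer <- probeRadiusPx + H - 1
  if (is.null(outputSize)) outputSize <- as.integer(2 * outer + 3)
  if (outputSize < 2 * outer + 1)
    stop("outputSize too small for outer radius ", outer)
  n <- as.integer(outputSize)
  ctr <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n) - ctr   # x: column offset
  ys <- matrix(rep(seq_len(n), times = n), n, n) - ctr  # y: row offset
  rr <- sqrt(xs^2 + ys^2)
  ri <- round(rr - probeRadiusPx) + 1
  th <- atan2(ys, xs) %% (2 * pi)
  wi <- (round(th / (2 * pi) * W) %% W) + 1
  ok <- ri >= 1 & ri <= H
  out <- matrix(0, n, n)
  out[ok] <- bscan[cbind(ri[ok], wi[ok])]
  out
}
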
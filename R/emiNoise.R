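# Parametric rain-like EMI streak model: each streak is a contiguous run of
# elevated samples within one A-line (one angular column).

#' Sample a random streak list
#'
#' Draws the per-image streak count uniformly from
#' \code{[countMin, countMax]}, angular positions uniformly over columns,
#' lengths uniformly from the configured range, and depth starts uniformly
#' subject to the streak fitting inside the image.
#'
#' @param cfg a \linkS4class{NoiseConfig}.
#' @param H,W image dimensions the streaks must fit in.
#' @return A data frame with columns \code{angleCol}, \code{depthStart},
#'   \code{length}, \code{amplitude} (1-based indices).
#' @examples
#' s <- sampleStreaks(noiseConfig(countMin = 3L, countMax = 3L, seed = 1L),
#'                    100L, 200L)
#' @export
sampleStreaks <- function(cfg, H, W) {
  stopifnot(is(cfg, "NoiseConfig"))
  validObject(cfg)
  H <- as.integer(H); W <- as.integer(W)
  if (H < 1L || W < 1L) stop("H and W must be >= 1")
  lmin <- as.integer(cfg@lengthRange[1])
  lmax <- if (is.na(cfg@lengthRange[2])) H else as.integer(cfg@lengthRange[2])
  if (lmin > H) stop("minimum streak length exceeds image height")
  lmax <- min(lmax, H)
  withSeed(cfg@seed, {
    n <- runifInt(1L, cfg@countMin, cfg@countMax)
    if (n == 0L)
      return(data.frame(angleCol = integer(), depthStart = integer(),
                        length = integer(), amplitude = numeric()))
    len <- runifInt(n, lmin, lmax)
    data.frame(
      angleCol = runifInt(n, 1L, W),
      depthStart = runifInt(n, 1L, H - len + 1L),
      length = len,
      amplitude = runif(n, cfg@amplitudeRange[1], cfg@amplitudeRange[2]))
  })
}

#' Inject EMI streaks into a clean envelope B-scan
#'
#' Additive superposition: within each streak footprint the amplitude (times
#' an optional per-row profile) is added to the clean image, then saturated
#' at \code{dynamicRange}. Pixels outside every footprint are bit-identical
#' to the clean image, and the noisy image never falls below the clean one.
#'
#' @param clean nonnegative H x W envelope matrix.
#' @param streaks streak data frame as returned by \code{\link{sampleStreaks}};
#'   an optional list column \code{profile} holds per-row multipliers.
#' @param dynamicRange saturation ceiling (default 255, the generator's).
#' @return The noisy H x W matrix.
#' @export
injectStreaks <- function(clean, streaks, dynamicRange = 255) {
  stopifnot(is.matrix(clean))
  H <- nrow(clean); W <- ncol(clean)
  noisy <- clean
  if (nrow(streaks) == 0L) return(noisy)
  for (s in seq_len(nrow(streaks))) {
    a <- streaks$angleCol[s]; d0 <- streaks$depthStart[s]
    len <- streaks$length[s]; amp <- streaks$amplitude[s]
    if (a < 1L || a > W || d0 < 1L || len < 1L || d0 + len - 1L > H)
      stop(sprintf(
        "streak %d out of bounds (angleCol=%d, depthStart=%d, length=%d for %d x %d image)",
        s, a, d0, len, H, W))
    if (amp <= 0) stop(sprintf("streak %d has non-positive amplitude", s))
    prof <- if (!is.null(streaks$profile)) streaks$profile[[s]] else rep(1, len)
    if (length(prof) != len)
      stop(sprintf("streak %d profile length %d != streak length %d",
                   s, length(prof), len))
    rows <- d0:(d0 + len - 1L)
    noisy[rows, a] <- pmin(noisy[rows, a] + amp * prof, dynamicRange)
  }
  noisy
}

#' Write / read a streak list as CSV
#'
#' Plain-text serialisation (angleCol, depthStart, length, amplitude) for
#' fixture reuse; per-row profiles are not serialised.
#'
#' @param streaks streak data frame.
#' @param path CSV file path.
#' @return \code{readStreakCSV} returns the streak data frame.
#' @export
writeStreakCSV <- function(streaks, path) {
  write.csv(streaks[c("angleCol", "depthStart", "length", "amplitude")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStreakCSV
#' @export
readStreakCSV <- function(path) {
  df <- read.csv(path)
  df$angleCol <- as.integer(df$angleCol)
  df$depthStart <- as.integer(df$depthStart)
  df$length <- as.integer(df$length)
  df
}
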
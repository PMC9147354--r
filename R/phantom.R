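# Synthetic OR-PAE phantoms: a tissue band with bright vessel cross-sections
# over a Rayleigh envelope-noise floor, plus matched RF B-scans and C-scan
# volumes with slowly drifting vessels.

# Band row interval at angular column j (1-based), honouring undulation.
bandRowsAt <- function(config, j) {
  off <- if (config@wallUndulation > 0)
    round(config@wallUndulation * sin(2 * pi * (j - 1) / config@angleCols))
  else 0L
  lo <- config@wallBand[1] + 1L + off
  hi <- config@wallBand[2] + off
  c(max(1L, lo), min(config@depthRows, hi))
}

# Core generator; must run inside withSeed(). Consumes RNG draws in a fixed
# order so that generateVolume(n = 1) reproduces generatePhantom exactly.
phantomCore <- function(config) {
  H <- config@depthRows; W <- config@angleCols
  mask <- matrix(FALSE, H, W)
  for (j in seq_len(W)) {
    b <- bandRowsAt(config, j)
    mask[b[1]:b[2], j] <- TRUE
  }
  # Rayleigh envelope noise (envelope of white Gaussian RF noise)
  img <- if (config@thermalSigma > 0)
    matrix(config@thermalSigma * sqrt(-2 * log(runif(H * W))), H, W)
  else matrix(0, H, W)
  vessels <- NULL
  if (config@vesselCount > 0L) {
    col <- runifInt(config@vesselCount, 1L, W)
    rowu <- runif(config@vesselCount)
    rad <- runif(config@vesselCount, config@vesselRadiusRange[1],
                 config@vesselRadiusRange[2])
    amp <- runif(config@vesselCount, config@vesselAmplitudeRange[1],
                 config@vesselAmplitudeRange[2])
    row <- integer(config@vesselCount)
    for (v in seq_len(config@vesselCount)) {
      b <- bandRowsAt(config, col[v])
      row[v] <- b[1] + as.integer(floor(rowu[v] * (b[2] - b[1] + 1L)))
      row[v] <- min(row[v], b[2])
    }
    vessels <- data.frame(row = row, col = col, radius = rad, amplitude = amp)
    img <- stampVessels(img, vessels, W)
  }
  img <- pmin(img, config@dynamicRange)
  list(image = img, mask = mask,
       vessels = if (is.null(vessels))
         data.frame(row = integer(), col = integer(), radius = numeric(),
                    amplitude = numeric()) else vessels)
}

# Paint filled discs (columns wrap circularly); overlaps take the max.
stampVessels <- function(img, vessels, W) {
  H <- nrow(img)
  for (v in seq_len(nrow(vessels))) {
    r <- vessels$radius[v]; ri <- ceiling(r)
    rows <- (vessels$row[v] - ri):(vessels$row[v] + ri)
    cols <- (vessels$col[v] - ri):(vessels$col[v] + ri)
    for (i in rows) {
      if (i < 1 || i > H) next
      for (j in cols) {
        jj <- ((j - 1) %% W) + 1L
        if ((i - vessels$row[v])^2 + (j - vessels$col[v])^2 <= r^2)
          img[i, jj] <- max(img[i, jj], vessels$amplitude[v])
      }
    }
  }
  img
}

#' Generate a clean envelope B-scan phantom
#'
#' Produces a nonnegative depth x angle envelope image containing
#' \code{vesselCount} filled-disc vessel cross-sections placed inside the
#' intestine-wall band, over a Rayleigh thermal-noise background, together
#' with the wall-band mask. Identical seeds give bit-identical output.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return A list with elements \code{image} (H x W matrix), \code{mask}
#'   (logical H x W, TRUE inside the wall band) and \code{vessels} (data frame
#'   of disc centres, radii and amplitudes).
#' @examples
#' ph <- generatePhantom(phantomConfig(depthRows = 304L, seed = 7L))
#' dim(ph$image)
#' @export
generatePhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  withSeed(config@seed, phantomCore(config))
}

#' Generate a raw RF B-scan with a known modulating envelope
#'
#' Each A-line is the phantom envelope modulated by a cosine carrier at
#' \code{carrierFrequency} sampled at \code{samplingRate} (five samples per
#' cycle at the 40 MHz / 200 MHz defaults). The intended envelope is returned
#' so envelope detection can be checked against it.
#'
#' @param config a \linkS4class{PhantomConfig}; requires
#'   \code{samplingRate > 2 * carrierFrequency}.
#' @return A list with \code{raw} (signed H x W RF matrix),
#'   \code{envelope} (the modulating envelope) and \code{mask}.
#' @export
generateRawBScan <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  if (config@samplingRate <= 2 * config@carrierFrequency)
    stop("undersampled carrier: samplingRate must exceed 2 * carrierFrequency")
  ph <- generatePhantom(config)
  t <- (seq_len(config@depthRows) - 1) / config@samplingRate
  carrier <- cos(2 * pi * config@carrierFrequency * t)
  raw <- ph$image * carrier  # column-wise recycling down each A-line
  list(raw = raw, envelope = ph$image, mask = ph$mask)
}

#' Generate a C-scan volume with smoothly drifting vessels
#'
#' Emulates probe pullback: vessel positions follow a per-vessel AR(1) drift
#' whose correlation length is \code{continuity} slices, so adjacent slices
#' are more alike than distant ones. Thermal noise is redrawn per slice. The
#' first slice reproduces \code{generatePhantom(config)} exactly.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param nSlices number of B-scan slices (full-scale emulation: 3000).
#' @param continuity drift correlation length in slices.
#' @param driftAmp maximum lateral drift amplitude in columns.
#' @return A list with \code{volume} (a \linkS4class{CScanVolume}) and
#'   \code{masks} (list of wall-band masks, one per slice).
#' @export
generateVolume <- function(config, nSlices = 3000L, continuity = 50,
                           driftAmp = 10) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  nSlices <- as.integer(nSlices)
  if (nSlices < 1L) stop("nSlices must be >= 1")
  withSeed(config@seed, {
    base <- phantomCore(config)
    slices <- vector("list", nSlices)
    masks <- vector("list", nSlices)
    slices[[1]] <- base$image
    masks[[1]] <- base$mask
    if (nSlices > 1L) {
      rho <- exp(-1 / max(continuity, 1e-6))
      nv <- nrow(base$vessels)
      zc <- numeric(nv); zr <- numeric(nv)
      W <- config@angleCols
      for (s in 2:nSlices) {
        if (nv > 0) {
          zc <- rho * zc + sqrt(1 - rho^2) * rnorm(nv)
          zr <- rho * zr + sqrt(1 - rho^2) * rnorm(nv)
        }
        noise <- if (config@thermalSigma > 0)
          matrix(config@thermalSigma *
                 sqrt(-2 * log(runif(config@depthRows * W))),
                 config@depthRows, W)
        else matrix(0, config@depthRows, W)
        if (nv > 0) {
          vs <- base$vessels
          vs$col <- ((vs$col - 1L + as.integer(round(driftAmp * zc))) %% W) + 1L
          newRow <- vs$row + as.integer(round(driftAmp / 3 * zr))
          for (v in seq_len(nv)) {
            b <- bandRowsAt(config, vs$col[v])
            newRow[v] <- min(max(newRow[v], b[1]), b[2])
          }
          vs$row <- newRow
          noise <- stampVessels(noise, vs, W)
        }
        slices[[s]] <- pmin(noise, config@dynamicRange)
        masks[[s]] <- base$mask
      }
    }
    list(volume = cscanVolume(slices), masks = masks)
  })
}
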
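#' Configuration of the OR-PAE phantom generator
#'
#' Describes the geometry and signal statistics of a synthetic
#' optical-resolution photoacoustic endoscopy (OR-PAE) B-scan: a
#' \code{depthRows x angleCols} envelope image (rows are depth samples along
#' an A-line, columns are angular scan steps over one 360-degree rotation;
#' columns wrap circularly) containing an intestine-wall band with bright
#' vessel cross-sections over a Rayleigh thermal-noise floor.
#'
#' @slot depthRows integer, A-line length in samples (raw acquisition: 400).
#' @slot angleCols integer, angular steps per B-scan (800).
#' @slot wallBand integer(2), zero-based half-open \code{c(start, end)} depth
#'   rows of the tissue band; the band occupies R rows \code{(start+1):end}.
#' @slot vesselCount integer, number of vessel cross-sections.
#' @slot vesselRadiusRange numeric(2), disc radius bounds in pixels.
#' @slot vesselAmplitudeRange numeric(2), vessel envelope amplitude bounds.
#' @slot thermalSigma numeric, Rayleigh scale of the envelope noise floor.
#' @slot wallUndulation numeric, amplitude (rows) of a sinusoidal band
#'   undulation around the circumference; 0 keeps the band flat.
#' @slot carrierFrequency numeric, acoustic carrier in Hz (40 MHz default).
#' @slot samplingRate numeric, RF sampling rate in Hz (200 MHz default).
#' @slot dynamicRange numeric, saturation ceiling L of the envelope units
#'   (also the L used by the SSIM stabilisation constants).
#' @slot seed integer, RNG seed (NA uses the current stream).
#' @export
setClass("PhantomConfig", representation(
  depthRows = "integer", angleCols = "integer", wallBand = "integer",
  vesselCount = "integer", vesselRadiusRange = "numeric",
  vesselAmplitudeRange = "numeric", thermalSigma = "numeric",
  wallUndulation = "numeric", carrierFrequency = "numeric",
  samplingRate = "numeric", dynamicRange = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@depthRows < 1L || object@angleCols < 1L)
    msg <- c(msg, "all dimensions must be >= 1")
  b <- object@wallBand
  if (length(b) != 2L || b[1] < 0L || b[1] >= b[2] || b[2] > object@depthRows)
    msg <- c(msg, "wallBand must satisfy 0 <= start < end <= depthRows")
  if (object@vesselCount < 0L) msg <- c(msg, "vesselCount must be >= 0")
  if (object@thermalSigma < 0) msg <- c(msg, "thermalSigma must be >= 0")
  if (any(object@vesselRadiusRange <= 0) ||
      diff(object@vesselRadiusRange) < 0)
    msg <- c(msg, "vesselRadiusRange must be positive and ordered")
  if (any(object@vesselAmplitudeRange < 0) ||
      diff(object@vesselAmplitudeRange) < 0)
    msg <- c(msg, "vesselAmplitudeRange must be nonnegative and ordered")
  if (object@dynamicRange <= 0) msg <- c(msg, "dynamicRange must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomConfig
#'
#' Defaults mirror the raw acquisition geometry: 400-sample A-lines at
#' 200 MHz sampling with a 40 MHz carrier, 800 angular steps per revolution.
#' Wall-band placement and vessel statistics are generator choices (the source
#' data quantify neither) and are fully configurable.
#'
#' @param depthRows,angleCols image dimensions.
#' @param wallBand zero-based half-open depth-row interval of the tissue band.
#' @param vesselCount number of vessel discs.
#' @param vesselRadiusRange,vesselAmplitudeRange uniform draw bounds.
#' @param thermalSigma Rayleigh scale of the envelope background.
#' @param wallUndulation sinusoidal band undulation amplitude in rows.
#' @param carrierFrequency,samplingRate RF carrier and sampling rate in Hz.
#' @param dynamicRange saturation ceiling (envelope units).
#' @param seed integer RNG seed, or NA.
#' @return A \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig(vesselCount = 5L, seed = 1L)
#' @export
phantomConfig <- function(depthRows = 400L, angleCols = 800L,
                          wallBand = c(60L, 200L), vesselCount = 30L,
                          vesselRadiusRange = c(1, 4),
                          vesselAmplitudeRange = c(80, 200),
                          thermalSigma = 4, wallUndulation = 0,
                          carrierFrequency = 40e6, samplingRate = 200e6,
                          dynamicRange = 255, seed = NA_integer_) {
  new("PhantomConfig", depthRows = as.integer(depthRows),
      angleCols = as.integer(angleCols), wallBand = as.integer(wallBand),
      vesselCount = as.integer(vesselCount),
      vesselRadiusRange = as.numeric(vesselRadiusRange),
      vesselAmplitudeRange = as.numeric(vesselAmplitudeRange),
      thermalSigma = as.numeric(thermalSigma),
      wallUndulation = as.numeric(wallUndulation),
      carrierFrequency = as.numeric(carrierFrequency),
      samplingRate = as.numeric(samplingRate),
      dynamicRange = as.numeric(dynamicRange), seed = as.integer(seed))
}

#' Parametric model of rain-like EMI streak noise
#'
#' EMI corrupts a contiguous run of samples within a single A-line, so a
#' streak occupies one angular column over \code{length} depth rows. A streak
#' list is a data frame with columns \code{angleCol}, \code{depthStart},
#' \code{length}, \code{amplitude} (1-based indices).
#'
#' @slot countMin,countMax integer bounds of the per-image streak count.
#' @slot lengthRange numeric(2) streak length bounds in rows (NA max = image
#'   height).
#' @slot amplitudeRange numeric(2) additive amplitude bounds, in the envelope
#'   units of the clean image (defaults sit at 0.5-1.5x the default vessel
#'   amplitude scale so streaks are visually comparable to vessels).
#' @slot widthCols integer streak width; EMI affects single A-lines, so 1.
#' @slot seed integer RNG seed.
#' @export
setClass("NoiseConfig", representation(
  countMin = "integer", countMax = "integer", lengthRange = "numeric",
  amplitudeRange = "numeric", widthCols = "integer", seed = "integer"))

setValidity("NoiseConfig", function(object) {
  msg <- character()
  if (object@countMin < 0L || object@countMax < object@countMin)
    msg <- c(msg, "need 0 <= countMin <= countMax")
  if (!is.na(object@lengthRange[1]) && object@lengthRange[1] < 1)
    msg <- c(msg, "minimum streak length must be >= 1")
  if (any(object@amplitudeRange <= 0, na.rm = TRUE))
    msg <- c(msg, "amplitude bounds must be positive")
  if (object@widthCols < 1L) msg <- c(msg, "widthCols must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a NoiseConfig
#'
#' The default count range of 100-400 streaks per image matches the test
#' protocol used for the architecture comparison.
#'
#' @param countMin,countMax streak count bounds (uniform draw).
#' @param lengthRange streak length bounds in depth rows; NA max means the
#'   full image height.
#' @param amplitudeRange additive amplitude bounds in envelope units.
#' @param widthCols streak width in angular columns (1 = single A-line).
#' @param seed integer RNG seed, or NA.
#' @return A \linkS4class{NoiseConfig}.
#' @export
noiseConfig <- function(countMin = 100L, countMax = 400L,
                        lengthRange = c(10, NA), amplitudeRange = c(70, 210),
                        widthCols = 1L, seed = NA_integer_) {
  new("NoiseConfig", countMin = as.integer(countMin),
      countMax = as.integer(countMax), lengthRange = as.numeric(lengthRange),
      amplitudeRange = as.numeric(amplitudeRange),
      widthCols = as.integer(widthCols), seed = as.integer(seed))
}

#' Architecture specification for the convolutional regressors
#'
#' @slot name one of \code{"unet"}, \code{"segnet"}, \code{"fcn16s"},
#'   \code{"fcn8s"}.
#' @slot levels encoder depth (number of 2x2 poolings).
#' @slot baseChannels feature channels at the first encoder level.
#' @slot inputShape integer(2) \code{c(H, W)}; both divisible by 2^levels.
#' @slot dropoutRate bottleneck dropout fraction.
#' @export
setClass("ArchitectureSpec", representation(
  name = "character", levels = "integer", baseChannels = "integer",
  inputShape = "integer", dropoutRate = "numeric"))

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  if (!object@name %in% c("unet", "segnet", "fcn16s", "fcn8s"))
    msg <- c(msg, "name must be unet, segnet, fcn16s or fcn8s")
  if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  d <- 2L^object@levels
  if (any(object@inputShape %% d != 0L))
    msg <- c(msg, sprintf("input shape must be divisible by 2^levels = %d", d))
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@name == "fcn16s" && object@levels < 2L)
    msg <- c(msg, "fcn16s needs levels >= 2")
  if (object@name == "fcn8s" && object@levels < 3L)
    msg <- c(msg, "fcn8s needs levels >= 3")
  if (length(msg)) msg else TRUE
})

#' Construct an ArchitectureSpec
#'
#' Full scale for the U-Net is \code{levels = 4}, \code{baseChannels = 64},
#' input 304 x 800 (bottleneck 19 x 50 x 1024). The desk-scale preset used
#' throughout the tests is \code{levels = 3}, \code{baseChannels = 8},
#' input 96 x 160.
#'
#' @param name architecture name.
#' @param levels encoder depth.
#' @param baseChannels first-level channel count.
#' @param inputShape \code{c(H, W)}.
#' @param dropoutRate bottleneck dropout fraction (regularisation only; it
#'   never changes tensor shapes).
#' @return An \linkS4class{ArchitectureSpec}.
#' @export
architectureSpec <- function(name = "unet", levels = 4L, baseChannels = 64L,
                             inputShape = c(304L, 800L), dropoutRate = 0.5) {
  new("ArchitectureSpec", name = match.arg(name,
        c("unet", "segnet", "fcn16s", "fcn8s")),
      levels = as.integer(levels), baseChannels = as.integer(baseChannels),
      inputShape = as.integer(inputShape), dropoutRate = as.numeric(dropoutRate))
}

#' A convolutional regression network
#'
#' Holds the static computation graph (a topologically ordered node list),
#' the trainable weights, and non-trainable state (batch-normalisation
#' running statistics). The forward pass maps an H x W x 1 image to an
#' H x W x 1 image; there is no softmax and no classification head anywhere
#' in the graph -- the output layer is a linear 1-channel regression.
#'
#' @slot spec the \linkS4class{ArchitectureSpec}.
#' @slot graph list of op nodes (see \code{\link{modelLayers}}).
#' @slot params named list of numeric arrays (weights ".w", biases ".b",
#'   batch-norm gain ".g" and shift ".be").
#' @slot state named list (batch-norm running means/vars).
#' @export
setClass("NetworkModel", representation(
  spec = "ArchitectureSpec", graph = "list", params = "list", state = "list"))

#' Training configuration
#'
#' Mirrors the training protocol of the study: Adam, mini-batch size 1,
#' piecewise-constant learning-rate schedule with drop factor 0.3 every 10
#' epochs, validation RMSE and loss checked every 50 weight updates, and an
#' L2 weight penalty \code{lambda * ||theta||^2} in the loss.
#'
#' @slot initialLr initial learning rate.
#' @slot epochs number of passes over the training set.
#' @slot lambda L2 regularisation weight.
#' @slot lrDropFactor,lrDropPeriod schedule parameters (0.3 / 10 epochs).
#' @slot batchSize mini-batch size K (1).
#' @slot valInterval validation cadence in iterations (50).
#' @slot seed RNG seed covering shuffling, augmentation and dropout.
#' @slot augment logical, apply random paired translations per draw.
#' @slot maxShift integer(2) augmentation bounds (rows, cols).
#' @export
setClass("TrainConfig", representation(
  initialLr = "numeric", epochs = "integer", lambda = "numeric",
  lrDropFactor = "numeric", lrDropPeriod = "integer", batchSize = "integer",
  valInterval = "integer", seed = "integer", augment = "logical",
  maxShift = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@initialLr <= 0) msg <- c(msg, "initialLr must be > 0")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@lrDropFactor <= 0) msg <- c(msg, "lrDropFactor must be > 0")
  if (object@lrDropPeriod < 1L) msg <- c(msg, "lrDropPeriod must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@valInterval < 1L) msg <- c(msg, "valInterval must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#' @param initialLr initial learning rate.
#' @param epochs training epochs (one pass over the training set each).
#' @param lambda L2 weight-penalty coefficient.
#' @param lrDropFactor,lrDropPeriod learning-rate schedule (default 0.3 / 10).
#' @param batchSize mini-batch size K.
#' @param valInterval iterations between validation checks.
#' @param seed integer RNG seed.
#' @param augment apply random paired translations during training.
#' @param maxShift augmentation bounds \code{c(rows, cols)}.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(initialLr = 2e-4, epochs = 10L, lambda = 0,
                        lrDropFactor = 0.3, lrDropPeriod = 10L,
                        batchSize = 1L, valInterval = 50L, seed = NA_integer_,
                        augment = FALSE, maxShift = c(30L, 80L)) {
  new("TrainConfig", initialLr = as.numeric(initialLr),
      epochs = as.integer(epochs), lambda = as.numeric(lambda),
      lrDropFactor = as.numeric(lrDropFactor),
      lrDropPeriod = as.integer(lrDropPeriod), batchSize = as.integer(batchSize),
      valInterval = as.integer(valInterval), seed = as.integer(seed),
      augment = as.logical(augment), maxShift = as.integer(maxShift))
}

#' Hyperparameter search space
#'
#' @slot lrRange,epochsRange,lambdaRange parameter bounds.
#' @slot trials number of configurations evaluated (default 10).
#' @slot strategy \code{"bayesian"} (Gaussian-process guided expected
#'   improvement) or \code{"random"} (uniform over the space).
#' @export
setClass("SearchSpace", representation(
  lrRange = "numeric", epochsRange = "integer", lambdaRange = "numeric",
  trials = "integer", strategy = "character"))

setValidity("SearchSpace", function(object) {
  msg <- character()
  if (object@trials < 1L) msg <- c(msg, "trials must be >= 1")
  if (any(object@lrRange <= 0) || diff(object@lrRange) < 0)
    msg <- c(msg, "lrRange must be positive and ordered")
  if (!object@strategy %in% c("bayesian", "random"))
    msg <- c(msg, "strategy must be bayesian or random")
  if (length(msg)) msg else TRUE
})

#' Construct a SearchSpace
#' @param lrRange learning-rate bounds (searched on a log scale).
#' @param epochsRange integer epoch bounds.
#' @param lambdaRange L2-penalty bounds (log scale; first element may be 0
#'   only in random mode).
#' @param trials number of trial configurations.
#' @param strategy \code{"bayesian"} or \code{"random"}.
#' @return A \linkS4class{SearchSpace}.
#' @export
searchSpace <- function(lrRange = c(1e-5, 1e-2), epochsRange = c(2L, 10L),
                        lambdaRange = c(1e-4, 1e-1), trials = 10L,
                        strategy = c("bayesian", "random")) {
  new("SearchSpace", lrRange = as.numeric(lrRange),
      epochsRange = as.integer(epochsRange),
      lambdaRange = as.numeric(lambdaRange), trials = as.integer(trials),
      strategy = match.arg(strategy))
}

#' A C-scan volume of envelope B-scans
#'
#' An ordered stack of same-sized nonnegative envelope B-scans acquired
#' during probe pullback (one slice per pullback position).
#'
#' @slot slices list of H x W numeric matrices.
#' @export
setClass("CScanVolume", representation(slices = "list"))

setValidity("CScanVolume", function(object) {
  s <- object@slices
  if (length(s) < 1L) return("a volume needs at least one slice")
  d <- dim(s[[1]])
  for (i in seq_along(s)) {
    if (!is.matrix(s[[i]]) || !identical(dim(s[[i]]), d))
      return("all slices must be matrices of identical shape")
    if (!all(is.finite(s[[i]]))) return("slices must be finite")
    if (min(s[[i]]) < 0) return("envelope slices must be nonnegative")
  }
  TRUE
})

#' Construct a CScanVolume
#' @param slices list of H x W nonnegative matrices (envelope B-scans).
#' @return A \linkS4class{CScanVolume}.
#' @export
cscanVolume <- function(slices) new("CScanVolume", slices = slices)

#' @describeIn cscanVolume number of slices.
#' @param x a CScanVolume.
#' @export
setMethod("length", "CScanVolume", function(x) length(x@slices))

#' Extract one slice of a volume
#' @param x a \linkS4class{CScanVolume}.
#' @param i slice index.
#' @return The H x W slice matrix.
#' @export
setMethod("[[", "CScanVolume", function(x, i) x@slices[[i]])

#' Metric configuration
#'
#' @slot dynamicRange intensity range L entering the SSIM constants.
#' @slot k1,k2 SSIM stabilisation factors; \code{c1 = (k1 L)^2},
#'   \code{c2 = (k2 L)^2}.
#' @slot ssimMode \code{"global"} (single whole-image statistic, the default)
#'   or \code{"windowed"} (mean of local SSIM over a sliding window).
#' @slot windowSize window side for windowed mode.
#' @export
setClass("MetricsConfig", representation(
  dynamicRange = "numeric", k1 = "numeric", k2 = "numeric",
  ssimMode = "character", windowSize = "integer"))

setValidity("MetricsConfig", function(object) {
  msg <- character()
  if (object@dynamicRange <= 0) msg <- c(msg, "dynamicRange must be > 0")
  if (object@k1 <= 0 || object@k2 <= 0) msg <- c(msg, "k1, k2 must be > 0")
  if (!object@ssimMode %in% c("global", "windowed"))
    msg <- c(msg, "ssimMode must be global or windowed")
  if (length(msg)) msg else TRUE
})

#' Construct a MetricsConfig
#' @param dynamicRange intensity range L (defaults to the generator's 255).
#' @param k1,k2 SSIM stabilisation factors (0.01 and 0.03).
#' @param ssimMode \code{"global"} or \code{"windowed"}.
#' @param windowSize local window side for windowed SSIM.
#' @return A \linkS4class{MetricsConfig}.
#' @export
metricsConfig <- function(dynamicRange = 255, k1 = 0.01, k2 = 0.03,
                          ssimMode = c("global", "windowed"),
                          windowSize = 11L) {
  new("MetricsConfig", dynamicRange = as.numeric(dynamicRange),
      k1 = as.numeric(k1), k2 = as.numeric(k2),
      ssimMode = match.arg(ssimMode), windowSize = as.integer(windowSize))
}

#' Train/validation/test index partition
#'
#' @slot train,val,test disjoint 1-based index vectors covering 1..n.
#' @slot seed the seed that produced the partition.
#' @export
setClass("DatasetSplit", representation(
  train = "integer", val = "integer", test = "integer", seed = "integer"))

setValidity("DatasetSplit", function(object) {
  all_ <- c(object@train, object@val, object@test)
  if (anyDuplicated(all_)) return("index groups must be disjoint")
  if (!setequal(all_, seq_len(length(all_))))
    return("indices must cover 1..n without gaps")
  TRUE
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %d x %d, wall band [%d,%d), %d vessels, sigma=%g\n",
              object@depthRows, object@angleCols, object@wallBand[1],
              object@wallBand[2], object@vesselCount, object@thermalSigma))
})

setMethod("show", "NoiseConfig", function(object) {
  cat(sprintf("NoiseConfig: %d-%d streaks, length [%s,%s], amplitude [%g,%g]\n",
              object@countMin, object@countMax, object@lengthRange[1],
              object@lengthRange[2], object@amplitudeRange[1],
              object@amplitudeRange[2]))
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec: %s, levels=%d, base=%d, input %d x %d\n",
              object@name, object@levels, object@baseChannels,
              object@inputShape[1], object@inputShape[2]))
})

setMethod("show", "NetworkModel", function(object) {
  cat(sprintf("NetworkModel <%s>: %d graph nodes, %d trainable arrays, %s parameters\n",
              object@spec@name, length(object@graph), length(object@params),
              format(countParameters(object), big.mark = ",")))
})

setMethod("show", "CScanVolume", function(object) {
  d <- dim(object@slices[[1]])
  cat(sprintf("CScanVolume: %d slices of %d x %d\n",
              length(object@slices), d[1], d[2]))
})
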
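# Plain-format I/O: multi-page 32-bit float TIFF for B-scans and volumes,
# YAML for configurations, CSV for streak lists and metric reports.

#' Write / read envelope B-scans as multi-page TIFF
#'
#' Images are stored as 32-bit float, one page per slice. TIFF float samples
#' are defined on [0, 1], so pixel values are mapped through the affine
#' transform \code{(x - offset) / scale} on write and inverted on read; the
#' defaults cover the package's envelope images, whose dynamic range is
#' [0, 255]. Writing errors if any transformed value leaves [0, 1] (pick a
#' wider \code{scale}/\code{offset}, e.g. \code{offset = -255, scale = 510}
#' for raw radio-frequency scans). Use the same transform parameters when
#' reading a file back.
#'
#' @param x a matrix, a list of matrices, or a \linkS4class{CScanVolume}.
#' @param path file path.
#' @param scale,offset affine normalisation applied before storage.
#' @return \code{readBScanTIFF} returns a list of matrices (use
#'   \code{cscanVolume()} to rebuild a volume).
#' @export
writeBScanTIFF <- function(x, path, scale = 255, offset = 0) {
  if (is(x, "CScanVolume")) x <- x@slices
  if (is.matrix(x)) x <- list(x)
  x <- lapply(x, function(p) (p - offset) / scale)
  rng <- range(vapply(x, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("values outside [offset, offset + scale]; stored range would be [",
         signif(rng[1], 4), ", ", signif(rng[2], 4),
         "] - widen scale/offset")
  tiff::writeTIFF(x, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname writeBScanTIFF
#' @export
readBScanTIFF <- function(path, scale = 255, offset = 0) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * scale + offset
  })
}

configClassTag <- c(PhantomConfig = "phantom", NoiseConfig = "noise",
                    TrainConfig = "train", ArchitectureSpec = "architecture",
                    MetricsConfig = "metrics")

#' Round-trip configurations through YAML
#'
#' Serialises any of the package's configuration classes
#' (\linkS4class{PhantomConfig}, \linkS4class{NoiseConfig},
#' \linkS4class{TrainConfig}, \linkS4class{ArchitectureSpec},
#' \linkS4class{MetricsConfig}) to a tagged YAML mapping and back.
#'
#' @param cfg a configuration object.
#' @param path YAML file path.
#' @return \code{readConfigYAML} returns the reconstructed object.
#' @export
writeConfigYAML <- function(cfg, path) {
  cls <- class(cfg)[1]
  if (!cls %in% names(configClassTag)) stop("unsupported config class: ", cls)
  lst <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(lst) <- slotNames(cfg)
  yaml::write_yaml(c(list(type = configClassTag[[cls]]), lst), path)
  invisible(path)
}

#' @rdname writeConfigYAML
#' @export
readConfigYAML <- function(path) {
  lst <- yaml::read_yaml(path)
  type <- lst$type
  lst$type <- NULL
  cls <- names(configClassTag)[match(type, configClassTag)]
  if (is.na(cls)) stop("unknown config type in ", path)
  # NA integers serialise as ~; restore slot types from the class prototype
  proto <- new(cls)
  for (nm in names(lst)) {
    tgt <- class(slot(proto, nm))
    v <- lst[[nm]]
    if (is.null(v)) v <- NA
    slot(proto, nm) <- if (tgt == "integer") as.integer(v)
      else if (tgt == "numeric") as.numeric(v)
      else if (tgt == "logical") as.logical(v)
      else as.character(v)
  }
  validObject(proto)
  proto
}

#' Save / load model weights
#'
#' Plain-text checkpoint: the architecture spec as YAML plus one CSV of
#' flattened parameter and state values, so checkpoints survive text-only
#' pipelines.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param dir checkpoint directory (created if missing).
#' @return \code{loadModel} returns the restored model.
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeConfigYAML(model@spec, file.path(dir, "spec.yaml"))
  flat <- function(lst) data.frame(
    name = rep(names(lst), vapply(lst, length, 0L)),
    value = unlist(lapply(lst, as.numeric), use.names = FALSE))
  write.csv(flat(model@params), file.path(dir, "params.csv"), row.names = FALSE)
  if (length(model@state))
    write.csv(flat(model@state), file.path(dir, "state.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  spec <- readConfigYAML(file.path(dir, "spec.yaml"))
  model <- buildModel(spec, seed = 1L)  # shapes only; values overwritten
  fill <- function(lst, df) {
    vals <- split(df$value, factor(df$name, levels = unique(df$name)))
    for (nm in names(lst)) {
      v <- vals[[nm]]
      if (is.null(v) || length(v) != length(lst[[nm]]))
        stop("checkpoint mismatch for ", nm)
      a <- lst[[nm]]; a[] <- v; lst[[nm]] <- a
    }
    lst
  }
  model@params <- fill(model@params, read.csv(file.path(dir, "params.csv")))
  sp <- file.path(dir, "state.csv")
  if (file.exists(sp) && length(model@state))
    model@state <- fill(model@state, read.csv(sp))
  model
}
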
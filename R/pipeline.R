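# Single entry point wiring the stages into a reproducible, seeded
# experiment directory: simulate -> inject -> train -> evaluate -> rmap.

#' Default pipeline configuration
#'
#' \code{"full"} mirrors the full study protocol: 1000 ground-truth images
#' (700/300 train/validation split), 200 test images, noise levels up to 400
#' streaks, raw 400 x 800 scans cropped to 304 x 800. \code{"desk"} is the
#' reduced preset (30 ground-truth pairs at 96 x 160, 8 test images, levels
#' 10-60) that runs on one CPU in minutes.
#'
#' @param scale \code{"desk"} or \code{"full"}.
#' @param seed integer seed.
#' @return A named configuration list accepted by \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(scale = c("desk", "full"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "full")
    list(scale = "full", seed = seed, nImages = 1000L, trainFraction = 0.7,
         nTest = 200L, levels = c(100L, 200L, 300L, 400L),
         arch = "unet", epochs = 70L, initialLr = 2e-4, lambda = 0.0465,
         nSlices = 3000L,
         stages = c("simulate", "inject", "train", "evaluate", "rmap"))
  else
    list(scale = "desk", seed = seed, nImages = 30L, trainFraction = 0.7,
         nTest = 8L, levels = c(10L, 30L, 60L),
         arch = "unet", epochs = 4L, initialLr = 2e-3, lambda = 0,
         nSlices = 12L,
         stages = c("simulate", "inject", "train", "evaluate", "rmap"))
}

pipePhantomConfig <- function(cfg, seed) {
  if (cfg$scale == "desk") {
    pc <- deskPhantomConfig(); pc@seed <- seed; pc
  } else phantomConfig(depthRows = 304L, seed = seed)
}

pipeNoiseConfig <- function(cfg, seed) {
  nc <- if (cfg$scale == "desk") deskNoiseConfig() else noiseConfig()
  nc@seed <- seed
  nc
}

#' Run the end-to-end experiment pipeline
#'
#' Executes the requested stages into \code{outDir} and writes a manifest
#' (config echo, seeds, package version, per-stage file hashes). Every stage
#' reads only what earlier stages wrote, so a directory is reproducible from
#' its manifest alone; identical config and seed give byte-identical output.
#'
#' @param config configuration list (see \code{\link{defaultPipelineConfig}})
#'   or the path of a YAML file containing one.
#' @param outDir experiment directory (created).
#' @param verbose print per-stage progress.
#' @return \code{outDir}, invisibly.
#' @export
runPipeline <- function(config, outDir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultPipelineConfig(config$scale %||% "desk",
                                                 config$seed %||% 1L), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()

  if ("simulate" %in% cfg$stages) {
    say("stage simulate: ", cfg$nImages, " phantoms + ", cfg$nTest, " test")
    clean <- lapply(seq_len(cfg$nImages + cfg$nTest), function(i)
      generatePhantom(pipePhantomConfig(cfg, childSeed(cfg$seed, i)))$image)
    writeBScanTIFF(clean[seq_len(cfg$nImages)], file.path(outDir, "clean.tiff"))
    writeBScanTIFF(clean[cfg$nImages + seq_len(cfg$nTest)],
                   file.path(outDir, "test_clean.tiff"))
  }

  if ("inject" %in% cfg$stages) {
    clean <- readBScanTIFF(file.path(outDir, "clean.tiff"))
    say("stage inject: streaks into ", length(clean), " images")
    noisy <- lapply(seq_along(clean), function(i) {
      nc <- pipeNoiseConfig(cfg, childSeed(cfg$seed, 50000L + i))
      s <- sampleStreaks(nc, nrow(clean[[i]]), ncol(clean[[i]]))
      injectStreaks(clean[[i]], s)
    })
    writeBScanTIFF(noisy, file.path(outDir, "noisy.tiff"))
  }

  model <- NULL
  if ("train" %in% cfg$stages) {
    clean <- readBScanTIFF(file.path(outDir, "clean.tiff"))
    noisy <- readBScanTIFF(file.path(outDir, "noisy.tiff"))
    pairs <- Map(function(n, c) list(noisy = n, clean = c), noisy, clean)
    split <- splitDataset(length(pairs), cfg$trainFraction,
                          childSeed(cfg$seed, 2L))
    spec <- if (cfg$scale == "desk") deskArchitectureSpec(cfg$arch)
            else architectureSpec(cfg$arch)
    model <- buildModel(spec, seed = childSeed(cfg$seed, 3L))
    tc <- trainConfig(initialLr = cfg$initialLr, epochs = cfg$epochs,
                      lambda = cfg$lambda, seed = childSeed(cfg$seed, 4L))
    say("stage train: ", cfg$arch, ", ", cfg$epochs, " epochs on ",
        length(split@train), " pairs")
    fit <- trainModel(model, pairs[split@train], pairs[split@val], tc)
    model <- fit$model
    saveModel(model, file.path(outDir, "model"))
    write.csv(fit$history$checkpoints, file.path(outDir, "checkpoints.csv"),
              row.names = FALSE)
  }

  if ("evaluate" %in% cfg$stages) {
    test <- readBScanTIFF(file.path(outDir, "test_clean.tiff"))
    if (is.null(model) && dir.exists(file.path(outDir, "model")))
      model <- loadModel(file.path(outDir, "model"))
    methods <- list(identity = function(x) x)
    if (!is.null(model)) methods[[model@spec@name]] <- asDenoiser(model)
    lvl <- estimateThermalLevel(test[[1]],
                                matrix(TRUE, nrow(test[[1]]), ncol(test[[1]])))
    methods$gradient <- function(x) gradientDenoise(x, 2, lvl)
    methods$median <- function(x) classicalFilter(x, "median", 3L)
    say("stage evaluate: ", length(methods), " methods x ",
        length(cfg$levels), " levels x ", length(test), " images")
    rep_ <- do.call(rbind, lapply(names(methods), function(m) {
      r <- sweepNoiseLevels(methods[[m]], test, cfg$levels,
                            pipeNoiseConfig(cfg, NA_integer_),
                            seed = childSeed(cfg$seed, 5L))
      cbind(method = m, r)
    }))
    write.csv(rep_, file.path(outDir, "metrics.csv"), row.names = FALSE)
  }

  if ("rmap" %in% cfg$stages) {
    pc <- pipePhantomConfig(cfg, childSeed(cfg$seed, 6L))
    vol <- generateVolume(pc, nSlices = cfg$nSlices, continuity = 10)$volume
    say("stage rmap: ", length(vol), " slices")
    writeBScanTIFF(rmap(vol), file.path(outDir, "rmap.tiff"))
  }

  files <- setdiff(list.files(outDir, recursive = TRUE), "manifest.yaml")
  manifest <- list(
    config = cfg, seed = cfg$seed,
    package = as.character(utils::packageVersion("paedenoise")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    hashes = as.list(tools::md5sum(file.path(outDir, files))))
  names(manifest$hashes) <- files
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
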
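# Desk-scale presets: the reduced study conditions used by the examples and
# the test suite. They keep the structure of the full protocol (wall band,
# vessel statistics, streaks comparable to vessels) at sizes a single CPU
# handles in minutes.

#' Desk-scale phantom configuration
#'
#' 96 x 160 B-scans with a 50-row wall band, 12 vessel cross-sections of
#' radius 1-3 px and amplitude 80-200, thermal Rayleigh scale 4 (so the
#' default cleaning threshold 2x the thermal level sits well below vessel
#' amplitudes).
#'
#' @param seed integer seed.
#' @return A \linkS4class{PhantomConfig}.
#' @export
deskPhantomConfig <- function(seed = NA_integer_) {
  phantomConfig(depthRows = 96L, angleCols = 160L, wallBand = c(20L, 70L),
                vesselCount = 12L, vesselRadiusRange = c(1, 3),
                vesselAmplitudeRange = c(80, 200), thermalSigma = 4,
                seed = seed)
}

#' Desk-scale noise configuration
#'
#' 20-60 streaks per 96 x 160 image (the full-scale 100-400 streaks on
#' 304 x 800 images corrupt a comparable fraction of A-lines), lengths
#' 5 rows up to the image height, amplitudes 70-210 (0.5-1.5x the default
#' vessel amplitude scale, making streaks visually comparable to vessels).
#'
#' @param seed integer seed.
#' @return A \linkS4class{NoiseConfig}.
#' @export
deskNoiseConfig <- function(seed = NA_integer_) {
  noiseConfig(countMin = 20L, countMax = 60L, lengthRange = c(5, NA),
              amplitudeRange = c(70, 210), seed = seed)
}

#' Desk-scale training configuration
#'
#' The reduced learning experiment: 10 epochs, batch size 1, Adam, the
#' 0.3-per-10-epochs learning-rate schedule, validation every 50 iterations.
#' The initial learning rate 1e-3 (larger than the full-scale tuned 2e-4)
#' compensates for the far smaller images and dataset.
#'
#' @param seed integer seed.
#' @return A \linkS4class{TrainConfig}.
#' @export
deskTrainConfig <- function(seed = NA_integer_) {
  trainConfig(initialLr = 1e-3, epochs = 10L, lambda = 0, seed = seed)
}

#' Generate a paired noisy/clean desk-scale dataset
#'
#' Convenience wrapper: n phantoms, each with an independently sampled
#' streak set injected, ready for \code{\link{trainModel}}.
#'
#' @param n number of pairs.
#' @param seed integer base seed.
#' @param phantomCfg,noiseCfg configuration templates (seeds are derived per
#'   image from \code{seed}).
#' @return List of \code{list(noisy, clean, mask)} pairs.
#' @export
deskDataset <- function(n, seed = 1L, phantomCfg = deskPhantomConfig(),
                        noiseCfg = deskNoiseConfig()) {
  lapply(seq_len(n), function(i) {
    pc <- phantomCfg; pc@seed <- childSeed(seed, i)
    ph <- generatePhantom(pc)
    nc <- noiseCfg; nc@seed <- childSeed(seed, 100000L + i)
    streaks <- sampleStreaks(nc, nrow(ph$image), ncol(ph$image))
    list(noisy = injectStreaks(ph$image, streaks, pc@dynamicRange),
         clean = ph$image, mask = ph$mask)
  })
}
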
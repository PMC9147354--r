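# Restoration metrics (RMSE, MAE, global SSIM), per-noise-level sweeps and
# pixelwise error maps.

#' Root-mean-squared error between two images
#'
#' \code{sqrt(mean((y - x)^2))} over all H x W pixels. \code{mse} is the
#' no-root variant, kept for comparison.
#'
#' @param y,x same-shape matrices (ground truth and restored image; the
#'   metric is symmetric).
#' @return Scalar error.
#' @export
rmse <- function(y, x) {
  checkSameShape(y, x)
  sqrt(mean((y - x)^2))
}

#' @rdname rmse
#' @export
mse <- function(y, x) {
  checkSameShape(y, x)
  mean((y - x)^2)
}

#' Mean absolute error between two images
#' @inheritParams rmse
#' @return Scalar error.
#' @export
mae <- function(y, x) {
  checkSameShape(y, x)
  mean(abs(y - x))
}

ssimFromStats <- function(mx, my, vx, vy, cxy, c1, c2) {
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Structural similarity index (SSIM)
#'
#' Global mode (the default) computes the single-statistic SSIM
#' \deqn{\mathrm{SSIM}(x,y)=\frac{(2\mu_x\mu_y+c_1)(2\sigma_{xy}+c_2)}
#'   {(\mu_x^2+\mu_y^2+c_1)(\sigma_x^2+\sigma_y^2+c_2)}}
#' over the whole image, with \code{c1 = (k1 L)^2}, \code{c2 = (k2 L)^2} and
#' population (1/N) variance and cross-covariance. Windowed mode averages
#' the same statistic over sliding local windows. Values can in principle be
#' negative for anticorrelated images; they are reported raw (with a
#' warning), never clipped.
#'
#' @param x,y same-shape matrices (restored and ground-truth image).
#' @param cfg a \linkS4class{MetricsConfig}.
#' @param details if TRUE, also return the component statistics.
#' @return Scalar SSIM, or (with \code{details}) a list \code{value},
#'   \code{terms} (mux, muy, sigx, sigy, sigxy, c1, c2).
#' @export
ssim <- function(x, y, cfg = metricsConfig(), details = FALSE) {
  checkSameShape(x, y)
  c1 <- (cfg@k1 * cfg@dynamicRange)^2
  c2 <- (cfg@k2 * cfg@dynamicRange)^2
  if (cfg@ssimMode == "global") {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    val <- ssimFromStats(mx, my, vx, vy, cxy, c1, c2)
  } else {
    w <- cfg@windowSize
    kern <- matrix(1 / (w * w), w, w)
    mx <- EBImage::filter2(x, kern, boundary = "replicate")
    my <- EBImage::filter2(y, kern, boundary = "replicate")
    vx <- EBImage::filter2(x * x, kern, boundary = "replicate") - mx^2
    vy <- EBImage::filter2(y * y, kern, boundary = "replicate") - my^2
    cxy <- EBImage::filter2(x * y, kern, boundary = "replicate") - mx * my
    val <- mean(ssimFromStats(mx, my, pmax(vx, 0), pmax(vy, 0), cxy, c1, c2))
  }
  if (val < 0)
    warning("negative SSIM (", signif(val, 4), "): strongly anticorrelated images")
  if (!details) return(val)
  if (cfg@ssimMode != "global")
    return(list(value = val, terms = NULL))
  list(value = val,
       terms = list(mux = mx, muy = my, sigx = sqrt(vx), sigy = sqrt(vy),
                    sigxy = cxy, c1 = c1, c2 = c2))
}

#' Evaluate a denoising method across noise levels
#'
#' For every clean test image and every streak count in \code{levels},
#' injects exactly that many streaks (seeded per image/level), applies the
#' method, and computes RMSE, SSIM and MAE against the clean image. A method
#' failure on one image is recorded in the row's \code{error} column, never
#' silently dropped.
#'
#' @param method a denoiser: function(matrix) -> matrix, or a
#'   \linkS4class{NetworkModel}.
#' @param cleanImages list of clean envelope matrices (the test set; the
#'   full-scale protocol uses 200).
#' @param levels integer vector of streak counts (e.g.
#'   \code{c(100, 200, 300, 400)}).
#' @param noiseCfg \linkS4class{NoiseConfig} providing streak length and
#'   amplitude distributions (count bounds are overridden per level).
#' @param metricsCfg \linkS4class{MetricsConfig}.
#' @param seed integer base seed.
#' @return data.frame with one row per (image, level): \code{id},
#'   \code{level}, \code{rmse}, \code{ssim}, \code{mae}, \code{error}.
#'   Use \code{\link{summariseSweep}} for per-level aggregates.
#' @export
sweepNoiseLevels <- function(method, cleanImages, levels,
                             noiseCfg = noiseConfig(),
                             metricsCfg = metricsConfig(),
                             seed = NA_integer_) {
  if (length(levels) == 0L) stop("levels must be nonempty")
  fn <- asDenoiser(method)
  rows <- vector("list", length(cleanImages) * length(levels))
  r <- 0L
  for (i in seq_along(cleanImages)) {
    clean <- cleanImages[[i]]
    for (li in seq_along(levels)) {
      lv <- levels[li]
      cfg <- noiseCfg
      cfg@countMin <- as.integer(lv); cfg@countMax <- as.integer(lv)
      cfg@seed <- childSeed(seed, i * 1000L + li)
      streaks <- sampleStreaks(cfg, nrow(clean), ncol(clean))
      noisy <- injectStreaks(clean, streaks, metricsCfg@dynamicRange)
      r <- r + 1L
      rows[[r]] <- tryCatch({
        den <- fn(noisy)
        data.frame(id = i, level = lv, rmse = rmse(clean, den),
                   ssim = ssim(den, clean, metricsCfg), mae = mae(clean, den),
                   error = NA_character_)
      }, error = function(e)
        data.frame(id = i, level = lv, rmse = NA_real_, ssim = NA_real_,
                   mae = NA_real_, error = conditionMessage(e)))
    }
  }
  do.call(rbind, rows)
}

#' Per-level aggregates of a sweep report
#' @param report data.frame from \code{\link{sweepNoiseLevels}}.
#' @return data.frame of mean and sd of each metric per level.
#' @export
summariseSweep <- function(report) {
  ok <- report[is.na(report$error), ]
  agg <- lapply(split(ok, ok$level), function(d)
    data.frame(level = d$level[1], n = nrow(d),
               rmseMean = mean(d$rmse), rmseSd = sd(d$rmse),
               ssimMean = mean(d$ssim), ssimSd = sd(d$ssim),
               maeMean = mean(d$mae), maeSd = sd(d$mae)))
  out <- do.call(rbind, agg)
  out[order(out$level), ]
}

#' Pixelwise error map against averaged outputs
#'
#' The elementwise absolute difference between the ground truth and the mean
#' of the supplied network outputs (e.g. one output per tested noise level).
#'
#' @param ground ground-truth matrix.
#' @param outputs nonempty list of same-shape output matrices.
#' @return H x W matrix of absolute errors.
#' @export
errorMap <- function(ground, outputs) {
  if (length(outputs) == 0L) stop("outputs must be nonempty")
  avg <- Reduce(`+`, outputs) / length(outputs)
  checkSameShape(ground, avg)
  abs(ground - avg)
}
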
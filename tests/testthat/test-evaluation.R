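test_that("metric identities hold for arbitrary images", {
  y <- withSeed(1L, matrix(runif(200, 0, 255), 10, 20))
  expect_identical(rmse(y, y), 0)
  expect_identical(mae(y, y), 0)
  expect_equal(ssim(y, y), 1)
})

test_that("rmse and mae reproduce their 2x2 hand cases", {
  y <- matrix(0, 2, 2)
  x <- matrix(c(2, 0, 0, 0), 2, 2)
  expect_identical(rmse(y, x), 1)       # sqrt(4 / 4)
  expect_identical(mae(y, x), 0.5)      # 2 / 4
  expect_identical(mse(y, x), 1)
  expect_error(rmse(matrix(0, 2, 2), matrix(0, 2, 3)))
})

test_that("mse is the square of rmse and mae is scale-equivariant", {
  y <- withSeed(2L, matrix(runif(64, 0, 10), 8, 8))
  x <- withSeed(3L, matrix(runif(64, 0, 10), 8, 8))
  expect_equal(mse(y, x), rmse(y, x)^2)
  expect_equal(mae(3 * y, 3 * x), 3 * mae(y, x))
  # symmetry
  expect_identical(rmse(y, x), rmse(x, y))
  expect_identical(mae(y, x), mae(x, y))
  expect_equal(ssim(y, x), ssim(x, y))
})

test_that("rmse dominates mae on 100 seeded random pairs", {
  withSeed(4L, for (i in 1:100) {
    y <- matrix(runif(64, 0, 255), 8, 8)
    x <- matrix(runif(64, 0, 255), 8, 8)
    expect_gte(rmse(y, x), mae(y, x))
  })
})

test_that("global SSIM matches an independent evaluation of its formula", {
  y <- matrix(c(0, 0, 1, 1), 2, 2)
  x <- matrix(c(0, 1, 0, 1), 2, 2)
  cfg <- metricsConfig(dynamicRange = 1)
  c1 <- 0.01^2; c2 <- 0.03^2
  mx <- 0.5; my <- 0.5
  vx <- 0.25; vy <- 0.25                      # population (1/N) variance
  cxy <- mean((y - my) * (x - mx))            # = 0 for this pair
  byHand <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  expect_equal(ssim(x, y, cfg), byHand)
  d <- ssim(x, y, cfg, details = TRUE)
  expect_equal(d$value, byHand)
  expect_equal(d$terms$mux, mx)
  expect_equal(d$terms$sigx, 0.5)
  expect_equal(d$terms$sigxy, cxy)
})

test_that("constant-zero images have SSIM 1 and nonneg images stay <= 1", {
  z <- matrix(0, 4, 4)
  expect_equal(ssim(z, z), 1)
  withSeed(5L, for (i in 1:20) {
    a <- matrix(runif(64, 0, 255), 8, 8)
    b <- matrix(runif(64, 0, 255), 8, 8)
    # small random pairs can anticorrelate; negativity warnings are expected
    expect_lte(suppressWarnings(ssim(a, b)), 1)
  })
})

test_that("negative SSIM is reported raw with a warning, never clipped", {
  x <- matrix(c(0, 1, 0, 1, 0, 1), 2, 3)
  y <- 1 - x   # perfectly anticorrelated
  cfg <- metricsConfig(dynamicRange = 0.01)  # constants too small to mask it
  expect_warning(v <- ssim(x, y, cfg), "negative")
  expect_lt(v, 0)
})

test_that("windowed SSIM is exact on identical inputs and bounded", {
  y <- withSeed(6L, matrix(runif(400, 0, 255), 20, 20))
  cfg <- metricsConfig(ssimMode = "windowed", windowSize = 5L)
  expect_equal(ssim(y, y, cfg), 1)
  x <- withSeed(7L, matrix(runif(400, 0, 255), 20, 20))
  expect_lte(ssim(x, y, cfg), 1)
})

test_that("noise sweeps cover every image x level with seeded injection", {
  clean <- lapply(1:3, function(i)
    generatePhantom(deskPhantomConfig(seed = i))$image)
  rep_ <- sweepNoiseLevels(function(x) x, clean, c(5L, 20L, 40L),
                           deskNoiseConfig(), seed = 10L)
  expect_identical(nrow(rep_), 9L)
  expect_identical(sum(!is.na(rep_$error)), 0L)
  # identity method: RMSE grows with streak count
  s <- summariseSweep(rep_)
  expect_identical(s$level, c(5L, 20L, 40L))
  expect_true(all(diff(s$rmseMean) > 0))
  # repeatable
  rep2 <- sweepNoiseLevels(function(x) x, clean, c(5L, 20L, 40L),
                           deskNoiseConfig(), seed = 10L)
  expect_identical(rep_$rmse, rep2$rmse)
})

test_that("an oracle denoiser scores perfectly at every level", {
  clean <- list(generatePhantom(deskPhantomConfig(seed = 30L))$image)
  oracle <- function(x) clean[[1]]
  rep_ <- sweepNoiseLevels(oracle, clean, c(5L, 25L), deskNoiseConfig(),
                           seed = 31L)
  expect_equal(rep_$rmse, c(0, 0))
  expect_equal(rep_$mae, c(0, 0))
  expect_equal(rep_$ssim, c(1, 1))
})

test_that("method failures are recorded per row, not dropped", {
  clean <- lapply(1:2, function(i)
    generatePhantom(deskPhantomConfig(seed = 40L + i))$image)
  flaky <- local({
    calls <- 0L
    function(x) {
      calls <<- calls + 1L
      if (calls == 1L) stop("boom") else x
    }
  })
  rep_ <- sweepNoiseLevels(flaky, clean, c(10L), deskNoiseConfig(), seed = 41L)
  expect_identical(nrow(rep_), 2L)
  expect_match(rep_$error[1], "boom")
  expect_true(is.na(rep_$error[2]))
  expect_true(is.na(rep_$rmse[1]) && !is.na(rep_$rmse[2]))
})

test_that("error maps average the outputs before differencing", {
  g <- withSeed(50L, matrix(runif(36, 0, 10), 6, 6))
  expect_true(all(errorMap(g, list(g, g)) == 0))
  expect_equal(errorMap(g, list(g + 2)), matrix(2, 6, 6))
  # ground +1 and ground -1 cancel in the mean
  expect_true(all(errorMap(g, list(g + 1, g - 1)) == 0))
  expect_error(errorMap(g, list()), "nonempty")
})
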
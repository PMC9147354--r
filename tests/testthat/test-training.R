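test_that("the half-MSE loss reproduces its hand cases", {
  y <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_identical(halfMSELoss(y, y), 0)
  # identical outputs, lambda = 1, sum of squared weights = 2.5
  expect_identical(halfMSELoss(y, y, params = list(a.w = c(1.5, 0.5)),
                               lambda = 1), 2.5)
  # K = 1, 2x2 differences (1, -1, 2, 0) -> 0.5 * (1 + 1 + 4) = 3
  x <- y + matrix(c(1, -1, 2, 0), 2, 2)
  expect_identical(halfMSELoss(x, y), 3)
  # K = 2 averages the per-image half sums
  expect_identical(halfMSELoss(list(x, y), list(y, y)), 1.5)
  expect_error(halfMSELoss(matrix(0, 2, 2), matrix(0, 3, 2)))
})

test_that("only weight matrices enter the L2 penalty", {
  y <- matrix(0, 2, 2)
  p <- list(conv.w = c(2, 1), conv.b = c(100, 100), bn.g = 5)
  expect_identical(halfMSELoss(y, y, p, lambda = 1), 5)
})

test_that("the learning-rate schedule drops 0.3 every 10 epochs", {
  cfg <- trainConfig(initialLr = 2e-4)
  expect_identical(lrAt(0, cfg), 2e-4)
  expect_identical(lrAt(9, cfg), 2e-4)
  expect_equal(lrAt(10, cfg), 0.3 * 2e-4)
  expect_equal(lrAt(25, cfg), 0.09 * 2e-4)
  expect_true(all(diff(vapply(0:40, lrAt, 0, cfg = cfg)) <= 0))
  expect_error(lrAt(-1, cfg))
})

test_that("training checkpoints at exact validation-interval multiples", {
  pairs <- deskDataset(15, seed = 51L)
  m <- buildModel(deskArchitectureSpec("unet"), seed = 52L)
  # 12 train pairs x 5 epochs = 60 iterations, valInterval 10 -> {10,...,60}
  cfg <- trainConfig(initialLr = 1e-3, epochs = 5L, valInterval = 10L,
                     seed = 53L)
  fit <- trainModel(m, pairs[1:12], pairs[13:15], cfg)
  expect_identical(fit$history$checkpoints$iteration, seq(10L, 60L, 10L))
  expect_identical(nrow(fit$history$iterationLoss), 60L)
  expect_true(any(fit$history$checkpoints$best))
  expect_equal(min(fit$history$checkpoints$valRMSE),
               fit$history$bestValRMSE)
})

test_that("training is deterministic under a seed", {
  pairs <- deskDataset(6, seed = 61L)
  cfg <- trainConfig(initialLr = 1e-3, epochs = 1L, seed = 62L)
  m <- buildModel(deskArchitectureSpec("unet"), seed = 63L)
  f1 <- trainModel(m, pairs[1:4], pairs[5:6], cfg)
  f2 <- trainModel(m, pairs[1:4], pairs[5:6], cfg)
  expect_identical(f1$history$iterationLoss$loss,
                   f2$history$iterationLoss$loss)
  expect_identical(f1$model@params, f2$model@params)
})

test_that("a short desk run already beats the identity baseline", {
  fx <- miniFitFixture()
  val <- fx$pairs[13:16]
  noisyRMSE <- mean(vapply(val, function(p) rmse(p$noisy, p$clean), 0))
  expect_lt(fx$fit$history$bestValRMSE, noisyRMSE)
})

test_that("augmented training runs and keeps the loss finite", {
  pairs <- deskDataset(5, seed = 71L)
  cfg <- trainConfig(initialLr = 1e-3, epochs = 1L, seed = 72L,
                     augment = TRUE, maxShift = c(10L, 40L))
  m <- buildModel(deskArchitectureSpec("unet"), seed = 73L)
  fit <- trainModel(m, pairs[1:3], pairs[4:5], cfg)
  expect_true(all(is.finite(fit$history$iterationLoss$loss)))
})

test_that("non-finite losses abort with the iteration number", {
  m <- buildModel(deskArchitectureSpec("unet"), seed = 81L)
  bad <- list(noisy = matrix(1, 96, 160), clean = matrix(NaN, 96, 160))
  expect_error(trainModel(m, list(bad), list(bad),
                          trainConfig(epochs = 1L, seed = 82L)),
               "iteration 1")
})

test_that("hyperparameter search recovers a synthetic optimum", {
  # objective depends on the learning rate only, minimised at lr* = 1e-3
  obj <- function(cfg) (log10(cfg$initialLr) + 3)^2
  space <- searchSpace(lrRange = c(1e-6, 1e-1), epochsRange = c(2L, 4L),
                       lambdaRange = c(1e-6, 1e-2), trials = 10L)
  for (strategy in c("bayesian", "random")) {
    space@strategy <- strategy
    r <- tuneHyperparameters(space, obj, seed = 91L)
    expect_identical(nrow(r$trials), 10L)
    expect_equal(r$best$score, min(r$trials$score))
    expect_lt(abs(log10(r$best$initialLr) + 3), 1)  # within one decade
  }
})

test_that("a single-trial search returns that configuration", {
  space <- searchSpace(trials = 1L, strategy = "random")
  r <- tuneHyperparameters(space, function(cfg) cfg$initialLr, seed = 95L)
  expect_identical(nrow(r$trials), 1L)
  expect_equal(r$best$initialLr, r$trials$initialLr[1])
})

test_that("a search where every trial diverges is an error", {
  space <- searchSpace(trials = 3L, strategy = "random")
  expect_error(tuneHyperparameters(space, function(cfg) NaN, seed = 96L),
               "diverged")
})
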
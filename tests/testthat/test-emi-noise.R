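test_that("streak count respects the configured bounds", {
  cfg <- noiseConfig(countMin = 0L, countMax = 0L, seed = 1L)
  expect_identical(nrow(sampleStreaks(cfg, 50, 80)), 0L)
  cfg <- noiseConfig(countMin = 5L, countMax = 9L, lengthRange = c(3, 20),
                     seed = 2L)
  counts <- vapply(1:50, function(i) {
    cfg@seed <- childSeed(2L, i)
    nrow(sampleStreaks(cfg, 50, 80))
  }, 0L)
  expect_true(all(counts >= 5L & counts <= 9L))
})

test_that("streaks fit inside the image and are single-column", {
  cfg <- noiseConfig(countMin = 30L, countMax = 30L, lengthRange = c(2, NA),
                     seed = 3L)
  s <- sampleStreaks(cfg, 40, 60)
  expect_identical(nrow(s), 30L)
  expect_true(all(s$angleCol >= 1 & s$angleCol <= 60))
  expect_true(all(s$depthStart >= 1))
  expect_true(all(s$depthStart + s$length - 1 <= 40))
  expect_true(all(s$amplitude > 0))
})

test_that("streak counts are uniform over [countMin, countMax]", {
  cfg <- noiseConfig(countMin = 3L, countMax = 8L, lengthRange = c(2, 10))
  counts <- withSeed(99L, vapply(1:4000, function(i)
    nrow(sampleStreaks(cfg, 20, 30)), 0L))
  p <- suppressWarnings(
    chisq.test(table(factor(counts, levels = 3:8)))$p.value)
  expect_gt(p, 0.01)
})

test_that("a single unclipped streak changes exactly length pixels in its column", {
  clean <- matrix(0, 30, 20)
  s <- data.frame(angleCol = 7L, depthStart = 5L, length = 12L, amplitude = 50)
  noisy <- injectStreaks(clean, s, dynamicRange = 255)
  diff <- which(noisy != clean, arr.ind = TRUE)
  expect_identical(nrow(diff), 12L)
  expect_true(all(diff[, "col"] == 7L))
  expect_true(all(diff[, "row"] %in% 5:16))
  expect_true(all(noisy[5:16, 7] == 50))
})

test_that("injection conserves the added energy when nothing clips", {
  clean <- matrix(1, 40, 25)
  s <- data.frame(angleCol = c(3L, 3L, 10L), depthStart = c(1L, 20L, 4L),
                  length = c(5L, 10L, 8L), amplitude = c(20, 30, 40))
  noisy <- injectStreaks(clean, s, dynamicRange = 1e6)
  expect_equal(sum(noisy) - sum(clean), sum(s$amplitude * s$length))
  expect_true(all(noisy >= clean))
})

test_that("injection clips at the dynamic range", {
  clean <- matrix(200, 10, 5)
  s <- data.frame(angleCol = 2L, depthStart = 1L, length = 10L, amplitude = 100)
  noisy <- injectStreaks(clean, s, dynamicRange = 255)
  expect_true(all(noisy[, 2] == 255))
  expect_true(all(noisy[, -2] == 200))
})

test_that("empty streak list is the identity", {
  clean <- matrix(runif(100), 10, 10)
  expect_identical(injectStreaks(clean, sampleStreaks(
    noiseConfig(countMin = 0L, countMax = 0L, seed = 1L), 10, 10)), clean)
})

test_that("nested streak sets give monotone RMSE severity", {
  clean <- generatePhantom(deskPhantomConfig(seed = 12L))$image
  cfg <- noiseConfig(countMin = 40L, countMax = 40L, lengthRange = c(5, NA),
                     seed = 13L)
  s <- sampleStreaks(cfg, nrow(clean), ncol(clean))
  a <- injectStreaks(clean, s[1:15, ])
  b <- injectStreaks(clean, s)
  expect_gte(rmse(clean, b), rmse(clean, a))
})

test_that("out-of-bounds streaks error naming the offender", {
  clean <- matrix(0, 10, 10)
  bad <- data.frame(angleCol = 4L, depthStart = 8L, length = 6L, amplitude = 10)
  expect_error(injectStreaks(clean, bad), "streak")
})

test_that("streak lists round-trip through CSV", {
  cfg <- noiseConfig(countMin = 10L, countMax = 10L, lengthRange = c(2, 20),
                     seed = 8L)
  s <- sampleStreaks(cfg, 40, 60)
  f <- tempfile(fileext = ".csv")
  writeStreakCSV(s, f)
  s2 <- readStreakCSV(f)
  expect_equal(s2$angleCol, s$angleCol)
  expect_equal(s2$depthStart, s$depthStart)
  expect_equal(s2$length, s$length)
  expect_equal(s2$amplitude, s$amplitude)
})
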
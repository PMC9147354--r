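test_that("envelope detection is exact on constant-amplitude tones", {
  t <- 0:399
  amps <- c(1, 3, 7.5)
  raw <- vapply(amps, function(A) A * sin(2 * pi * 0.2 * t), numeric(400))
  env <- envelopeDetect(raw)
  core <- 11:390  # away from the 10 boundary samples
  for (j in seq_along(amps))
    expect_lt(max(abs(env[core, j] - amps[j])) / amps[j], 0.02)
})

test_that("envelope detection basics: zeros, dominance, column locality", {
  expect_true(all(envelopeDetect(matrix(0, 50, 4)) == 0))
  raw <- matrix(rnorm(200), 50, 4)
  env <- envelopeDetect(raw)
  expect_true(all(env >= abs(raw) - 1e-9))
  # operates along depth only: permuting columns commutes
  perm <- c(3, 1, 4, 2)
  expect_equal(envelopeDetect(raw[, perm]), env[, perm])
  expect_error(envelopeDetect(matrix(c(1, NA), 2, 1)), "finite")
})

test_that("cropUpper slices the stated rows unchanged", {
  img <- matrix(seq_len(400 * 8), 400, 8)
  out <- cropUpper(img, 304L)
  expect_identical(dim(out), c(304L, 8L))
  expect_identical(out, img[1:304, ])
  expect_identical(cropUpper(img, 400L), img)
  expect_error(cropUpper(img, 401L))
})

test_that("thermal level estimates the Rayleigh mean within 2%", {
  sigma <- 4
  n <- 1e5
  img <- matrix(withSeed(5L, sigma * sqrt(-2 * log(runif(n)))), 500, 200)
  lvl <- estimateThermalLevel(img, matrix(TRUE, 500, 200))
  expect_lt(abs(lvl - sigma * sqrt(pi / 2)) / (sigma * sqrt(pi / 2)), 0.02)
  expect_identical(estimateThermalLevel(matrix(0, 5, 5), matrix(TRUE, 5, 5)), 0)
  expect_error(estimateThermalLevel(img, matrix(FALSE, 500, 200)), "empty|nonempty")
})

test_that("cleaning rule reproduces the 3x3 hand case", {
  img <- matrix(c(7, 4, 9,
                  3, 10, 6,
                  8, 5, 11), 3, 3)  # column-major: center 10, edges 3,4,5,6
  mask <- matrix(FALSE, 3, 3)
  out <- cleanOutsideMask(img, mask, threshold = 5)
  # center 10 -> min(3, 4, 5, 6) = 3; edge neighbours untouched
  expect_identical(out[2, 2], 3)
  expect_identical(out[1, 2], 3)   # above-center value 3 is <= threshold
  expect_identical(out[2, 1], 4)
  expect_identical(out[2, 3], 5)   # 5 is not strictly above threshold
  expect_identical(out[3, 2], 6)   # fires, but neighbour minimum >= 6: clamped
})

test_that("cleaning preserves the masked region bit-identically on phantoms", {
  for (s in 1:10) {
    ph <- generatePhantom(deskPhantomConfig(seed = s))
    noisy <- injectStreaks(ph$image, sampleStreaks(
      deskNoiseConfig(seed = 100L + s), nrow(ph$image), ncol(ph$image)))
    lvl <- estimateThermalLevel(noisy, !ph$mask)
    out <- cleanOutsideMask(noisy, ph$mask, 2 * lvl)
    expect_identical(out[ph$mask], noisy[ph$mask])
    # the rule never raises a pixel
    expect_true(all(out <= noisy))
  }
})

test_that("cleaning with no above-threshold outside pixel is the identity", {
  img <- matrix(1, 6, 6)
  expect_identical(cleanOutsideMask(img, matrix(FALSE, 6, 6), 2), img)
  expect_error(cleanOutsideMask(img, matrix(FALSE, 5, 6), 2))
})

test_that("dataset split gives the 700/300 protocol and is a seeded partition", {
  sp <- splitDataset(1000, 0.7, seed = 4L)
  expect_identical(length(sp@train), 700L)
  expect_identical(length(sp@val), 300L)
  expect_identical(sort(c(sp@train, sp@val)), 1:1000)
  expect_identical(splitDataset(1000, 0.7, seed = 4L)@train, sp@train)
  expect_false(identical(splitDataset(1000, 0.7, seed = 5L)@train, sp@train))
  expect_error(splitDataset(1, 0.7, seed = 1L))
})

test_that("augmentation applies one shared displacement per pair", {
  img <- generatePhantom(deskPhantomConfig(seed = 9L))$image
  # noisy = clean stays equal under the same displacement
  a <- augmentTranslate(img, img, maxShift = c(10L, 30L), seed = 3L)
  expect_identical(a$noisy, a$clean)
  # zero bound is the identity
  b <- augmentTranslate(img, img, maxShift = c(0L, 0L), seed = 3L)
  expect_identical(b$noisy, img)
  # columns are circular, rows zero-fill
  d <- augmentTranslate(img, img, maxShift = c(0L, 5L), seed = 8L)
  expect_equal(sum(d$noisy), sum(img))  # pure column rotation conserves mass
  expect_identical(dim(d$noisy), dim(img))
})

test_that("augmentation shifts are seeded and bounded", {
  img <- matrix(runif(96 * 160), 96, 160)
  s1 <- augmentTranslate(img, img, maxShift = c(7L, 20L), seed = 11L)
  s2 <- augmentTranslate(img, img, maxShift = c(7L, 20L), seed = 11L)
  expect_identical(s1$shift, s2$shift)
  expect_true(all(abs(s1$shift) <= c(7L, 20L)))
})
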
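specFor <- function(name, levels = 2L) {
  architectureSpec(name, levels = levels, baseChannels = 2L,
                   inputShape = c(16L, 24L), dropoutRate = 0.5)
}

test_that("all four architectures preserve shape and are finite", {
  img <- matrix(runif(16 * 24, 0, 255), 16, 24)
  for (name in c("unet", "segnet", "fcn16s", "fcn8s")) {
    m <- buildModel(specFor(name, levels = if (name == "fcn8s") 3L else 2L),
                    seed = 1L)
    out <- forwardDenoise(m, img)
    expect_identical(dim(out), dim(img))
    expect_true(all(is.finite(out)))
    expect_gte(min(out), 0)
    # dropout inactive: repeated passes bit-identical
    expect_identical(forwardDenoise(m, img), out)
  }
})

test_that("building is seeded and deterministic", {
  a <- buildModel(specFor("unet"), seed = 3L)
  b <- buildModel(specFor("unet"), seed = 3L)
  expect_identical(a@params, b@params)
  c_ <- buildModel(specFor("unet"), seed = 4L)
  expect_false(identical(a@params, c_@params))
})

test_that("indivisible input shapes are rejected with the required divisor", {
  expect_error(architectureSpec("unet", levels = 3L, baseChannels = 4L,
                                inputShape = c(20L, 32L)), "divisible")
})

test_that("toy U-Net parameter count matches the hand-summed layer total", {
  m <- buildModel(architectureSpec("unet", levels = 1L, baseChannels = 2L,
                                   inputShape = c(4L, 4L)), seed = 1L)
  # enc: 3x3 conv 1->2 (20), 3x3 conv 2->2 (38)
  # bottleneck: 3x3 conv 2->4 (76), 3x3 conv 4->4 (148)
  # up: 2x2 tconv 4->2 (34); dec: 3x3 conv 4->2 (74), 3x3 conv 2->2 (38)
  # head: 1x1 conv 2->1 (3)
  expect_identical(countParameters(m), 20L + 38L + 76L + 148L + 34L + 74L + 38L + 3L)
})

test_that("full-scale U-Net hits the published feature-map sizes", {
  s <- architectureSummary(architectureSpec("unet"))
  bott <- s[s$stage == "bottleneck", ]
  expect_identical(c(bott$H, bott$W, bott$channels), c(19L, 50L, 1024L))
  lvl1 <- s[s$stage == "level1", ]
  expect_identical(c(lvl1$H, lvl1$W, lvl1$channels), c(152L, 400L, 128L))
  lvl0 <- s[s$stage == "level0", ]
  expect_identical(c(lvl0$H, lvl0$W, lvl0$channels), c(304L, 800L, 64L))
})

test_that("U-Net encoder channels double per level", {
  s <- architectureSummary(architectureSpec("unet", levels = 3L,
                                            baseChannels = 8L,
                                            inputShape = c(96L, 160L)))
  expect_identical(s$channels, as.integer(8 * 2^(0:3)))
})

test_that("SegNet places batch normalisation after every convolution", {
  m <- buildModel(specFor("segnet"), seed = 1L)
  layers <- modelLayers(m)
  convs <- layers$id[layers$op == "conv" & !layers$head]
  bns <- layers[layers$op == "bn", ]
  expect_identical(sort(bns$inputs), sort(convs))
  # unpool nodes consume recorded pooling indices
  expect_identical(sum(layers$op == "unpool"), sum(layers$op == "pool"))
})

test_that("max-unpooling restores each maximum to its argmax location", {
  x <- array(matrix(c(4, 1, 2, 3,
                      8, 5, 6, 7,
                      9, 12, 10, 11,
                      16, 13, 14, 15), 4, 4, byrow = TRUE), c(4, 4, 1))
  p <- paedenoise:::maxpool2_fwd(x)
  expect_equal(p$y[, , 1], matrix(c(8, 7, 16, 15), 2, 2, byrow = TRUE))
  up <- paedenoise:::scatter_to(p$y, p$idx, 4L, 4L)
  expect_equal(sum(up != 0), 4)
  expect_equal(up[x == 8], 8)
  expect_equal(up[x == 7], 7)
  expect_equal(up[x == 16], 16)
  expect_equal(up[x == 15], 15)
})

test_that("FCN variants fuse the specified number of encoder taps", {
  m16 <- buildModel(specFor("fcn16s"), seed = 1L)
  m8 <- buildModel(specFor("fcn8s", levels = 3L), seed = 1L)
  expect_identical(sum(modelLayers(m16)$tap), 2L)
  expect_identical(sum(modelLayers(m8)$tap), 3L)
  expect_identical(sum(modelLayers(m16)$op == "add"), 1L)
  expect_identical(sum(modelLayers(m8)$op == "add"), 2L)
})

test_that("no architecture contains a softmax or classification output", {
  for (name in c("unet", "segnet", "fcn16s", "fcn8s")) {
    m <- buildModel(specFor(name, levels = if (name == "fcn8s") 3L else 2L),
                    seed = 1L)
    layers <- modelLayers(m)
    expect_false(any(grepl("softmax|classif", layers$op, ignore.case = TRUE)))
    # single-channel linear regression head
    expect_identical(sum(layers$head), 1L)
  }
})

test_that("forwardDenoise pads and crops non-divisible inputs transparently", {
  m <- buildModel(specFor("unet"), seed = 2L)
  img <- matrix(runif(15 * 21, 0, 100), 15, 21)
  out <- forwardDenoise(m, img)
  expect_identical(dim(out), c(15L, 21L))
  expect_error(forwardDenoise(m, matrix(c(1, Inf), 2, 2)), "finite")
})

test_that("analytic gradients match finite differences within 1e-3", {
  # Jitter parameters off their zero-bias init: a fresh decoder sits exactly
  # on relu kinks (zero conv bias + sparse unpool input), where one-sided
  # analytic subgradients and central differences legitimately differ.
  pd <- asNamespace("paedenoise")
  for (name in c("unet", "segnet", "fcn16s", "fcn8s")) {
    spec <- architectureSpec(name, levels = if (name == "fcn8s") 3L else 2L,
                             baseChannels = 2L, inputShape = c(8L, 8L),
                             dropoutRate = 0)
    m <- buildModel(spec, seed = 2L)
    m@params <- withSeed(11L, lapply(m@params, function(p)
      p + rnorm(length(p), sd = 0.05)))
    x <- withSeed(12L, matrix(runif(64, 0, 10), 8, 8))
    y <- withSeed(13L, matrix(runif(64, 0, 10), 8, 8))
    lam <- 0.01
    lossAt <- function(mm)
      halfMSELoss(pd$nnForward(mm, x, training = FALSE)$out[, , 1],
                  y, mm@params, lam)
    fw <- pd$nnForward(m, x, training = FALSE)
    gr <- pd$nnBackward(m, fw, fw$out[, , 1] - y)
    for (nm in names(gr))
      if (grepl("\\.w$", nm)) gr[[nm]] <- gr[[nm]] + 2 * lam * m@params[[nm]]
    idxOf <- withSeed(14L, lapply(gr, function(g)
      sample(seq_along(g), min(2L, length(g)))))
    worst <- 0
    for (nm in names(gr)) {
      for (i in idxOf[[nm]]) {
        eps <- 1e-5
        m2 <- m; m2@params[[nm]][i] <- m2@params[[nm]][i] + eps
        m3 <- m; m3@params[[nm]][i] <- m3@params[[nm]][i] - eps
        num <- (lossAt(m2) - lossAt(m3)) / (2 * eps)
        worst <- max(worst, abs(num - gr[[nm]][i]) /
                            max(abs(num), abs(gr[[nm]][i]), 1e-6))
      }
    }
    expect_lt(worst, 1e-3)
  }
})
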
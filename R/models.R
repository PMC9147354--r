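# The four regression-adapted fully convolutional architectures. All share:
# single-channel input and output, 3x3 same-padded convolutions with ReLU,
# 2x2 max pooling, learned 2x2 stride-2 transposed-convolution upsampling,
# and a linear 1x1 regression head in place of any pixel-classification /
# softmax output.

convRelu <- function(b, id, from, cin, cout) {
  c1 <- addConv(b, paste0(id, "_conv"), from, cin, cout)
  addNode(b, paste0(id, "_relu"), "relu", c1)
}

convBnRelu <- function(b, id, from, cin, cout) {
  c1 <- addConv(b, paste0(id, "_conv"), from, cin, cout)
  bn <- addBN(b, paste0(id, "_bn"), c1, cout)
  addNode(b, paste0(id, "_relu"), "relu", bn)
}

finishModel <- function(b, spec) {
  new("NetworkModel", spec = spec, graph = b$nodes, params = b$params,
      state = b$state)
}

#' Build a U-Net regressor
#'
#' Encoder: per level, two (3x3 convolution + ReLU) blocks with
#' \code{baseChannels * 2^level} channels followed by 2x2 max pooling.
#' Bottleneck: two convolution blocks at \code{baseChannels * 2^levels}
#' channels with dropout. Decoder: transposed-convolution upsampling, depth
#' concatenation with the same-resolution encoder map (the skip connection),
#' and two convolution blocks. Output: linear 1-channel 1x1 convolution.
#' At full scale (levels 4, base 64, input 304 x 800) the bottleneck map is
#' 19 x 50 x 1024 and the second encoder level carries 128 channels.
#'
#' @param spec an \linkS4class{ArchitectureSpec} (name \code{"unet"}).
#' @param seed integer seed for weight initialisation.
#' @return A \linkS4class{NetworkModel}.
#' @examples
#' m <- buildUNet(deskArchitectureSpec("unet"), seed = 1L)
#' @export
buildUNet <- function(spec, seed = NA_integer_) {
  validObject(spec)
  withSeed(seed, {
    b <- newBuilder()
    L <- spec@levels; base <- spec@baseChannels
    prev <- "input"; cin <- 1L
    skips <- character(L)
    for (l in 0:(L - 1)) {
      ch <- base * 2L^l
      prev <- convRelu(b, sprintf("enc%d_a", l), prev, cin, ch)
      prev <- convRelu(b, sprintf("enc%d_b", l), prev, ch, ch)
      skips[l + 1] <- prev
      prev <- addNode(b, sprintf("pool%d", l), "pool", prev)
      cin <- ch
    }
    chB <- base * 2L^L
    prev <- convRelu(b, "bott_a", prev, cin, chB)
    prev <- convRelu(b, "bott_b", prev, chB, chB)
    prev <- addNode(b, "bott_drop", "dropout", prev, rate = spec@dropoutRate)
    cin <- chB
    for (l in (L - 1):0) {
      ch <- base * 2L^l
      prev <- addTconv(b, sprintf("up%d", l), prev, cin, ch)
      prev <- addNode(b, sprintf("cat%d", l), "concat", c(prev, skips[l + 1]))
      prev <- convRelu(b, sprintf("dec%d_a", l), prev, 2L * ch, ch)
      prev <- convRelu(b, sprintf("dec%d_b", l), prev, ch, ch)
      cin <- ch
    }
    addConv(b, "head", prev, cin, 1L, k = 1L, head = TRUE)
    finishModel(b, spec)
  })
}

#' Build a SegNet regressor
#'
#' Encoder blocks are (3x3 convolution + batch normalisation + ReLU) pairs
#' followed by 2x2 max pooling whose argmax indices are recorded. The decoder
#' restores resolution by max-unpooling to those indices (no depth
#' concatenation), followed by convolution + batch normalisation + ReLU
#' blocks; a batch-normalisation layer follows every convolution in the
#' graph except the linear regression head.
#'
#' @inheritParams buildUNet
#' @return A \linkS4class{NetworkModel}.
#' @export
buildSegNet <- function(spec, seed = NA_integer_) {
  validObject(spec)
  withSeed(seed, {
    b <- newBuilder()
    L <- spec@levels; base <- spec@baseChannels
    prev <- "input"; cin <- 1L
    poolIds <- character(L); poolIn <- character(L)
    for (l in 0:(L - 1)) {
      ch <- base * 2L^l
      prev <- convBnRelu(b, sprintf("enc%d_a", l), prev, cin, ch)
      prev <- convBnRelu(b, sprintf("enc%d_b", l), prev, ch, ch)
      poolIn[l + 1] <- prev
      prev <- addNode(b, sprintf("pool%d", l), "pool", prev)
      poolIds[l + 1] <- prev
      cin <- ch
    }
    for (l in (L - 1):0) {
      ch <- base * 2L^l
      prev <- addNode(b, sprintf("unpool%d", l), "unpool", prev,
                      from = poolIds[l + 1], fromInput = poolIn[l + 1])
      target <- if (l > 0) base * 2L^(l - 1) else base
      prev <- convBnRelu(b, sprintf("dec%d_a", l), prev, ch, ch)
      prev <- convBnRelu(b, sprintf("dec%d_b", l), prev, ch, target)
      cin <- target
    }
    addConv(b, "head", prev, cin, 1L, k = 1L, head = TRUE)
    finishModel(b, spec)
  })
}

#' Build an FCN-16s or FCN-8s regressor
#'
#' A VGG-style from-scratch encoder (two convolution + ReLU blocks then a
#' pooling per stage, channels doubling per stage), a dropout-regularised
#' convolutional neck, and 1-channel score maps tapped from the last two
#' (16s) or three (8s) pooling outputs. Score maps are upsampled by 2x2
#' transposed convolutions and fused by elementwise addition, then upsampled
#' to the input resolution; the final transposed convolution is the linear
#' regression output.
#'
#' @param spec an \linkS4class{ArchitectureSpec}.
#' @param variant \code{"16s"} or \code{"8s"} (defaults to the architecture name).
#' @param seed integer seed for weight initialisation.
#' @return A \linkS4class{NetworkModel}.
#' @export
buildFCN <- function(spec, variant = NULL, seed = NA_integer_) {
  validObject(spec)
  if (is.null(variant))
    variant <- if (spec@name == "fcn8s") "8s" else "16s"
  variant <- match.arg(variant, c("16s", "8s"))
  taps <- if (variant == "16s") 2L else 3L
  if (spec@levels < taps)
    stop("FCN-", variant, " needs at least ", taps, " pooling stages")
  withSeed(seed, {
    b <- newBuilder()
    L <- spec@levels; base <- spec@baseChannels
    prev <- "input"; cin <- 1L
    poolOut <- character(L)
    for (l in 0:(L - 1)) {
      ch <- base * 2L^l
      prev <- convRelu(b, sprintf("stage%d_a", l), prev, cin, ch)
      prev <- convRelu(b, sprintf("stage%d_b", l), prev, ch, ch)
      prev <- addNode(b, sprintf("pool%d", l), "pool", prev)
      poolOut[l + 1] <- prev
      cin <- ch
    }
    chN <- base * 2L^L
    prev <- convRelu(b, "neck", prev, cin, chN)
    prev <- addNode(b, "neck_drop", "dropout", prev, rate = spec@dropoutRate)
    cur <- addConv(b, "score_final", prev, chN, 1L, k = 1L, tap = TRUE)
    for (t in seq_len(taps - 1L)) {
      p <- L - 1L - t  # pooling stage index tapped at this fusion step
      cur <- addTconv(b, sprintf("fuse_up%d", t), cur, 1L, 1L)
      sc <- addConv(b, sprintf("score_pool%d", p), poolOut[p + 1],
                    base * 2L^p, 1L, k = 1L, tap = TRUE)
      cur <- addNode(b, sprintf("fuse%d", t), "add", c(cur, sc))
    }
    ups <- L - taps + 1L  # doublings left to reach input resolution
    for (u in seq_len(ups)) {
      last <- u == ups
      cur <- addTconv(b, sprintf("final_up%d", u), cur, 1L, 1L)
      if (last) b$nodes[[length(b$nodes)]]$head <- TRUE
    }
    finishModel(b, spec)
  })
}

#' Build a model from its specification
#'
#' Dispatches on \code{spec@name} to the architecture-specific builder.
#'
#' @inheritParams buildUNet
#' @return A \linkS4class{NetworkModel}.
#' @export
buildModel <- function(spec, seed = NA_integer_) {
  switch(spec@name,
         unet = buildUNet(spec, seed),
         segnet = buildSegNet(spec, seed),
         fcn16s = buildFCN(spec, "16s", seed),
         fcn8s = buildFCN(spec, "8s", seed))
}

#' Desk-scale architecture preset
#'
#' The reduced configuration used throughout the tests and the worked
#' examples: 3 pooling levels, 8 base channels, 96 x 160 input. It preserves
#' the full-scale channel-doubling progression at a size a single CPU
#' handles in minutes.
#'
#' @param name architecture name.
#' @return An \linkS4class{ArchitectureSpec}.
#' @export
deskArchitectureSpec <- function(name = "unet") {
  architectureSpec(name = name, levels = 3L, baseChannels = 8L,
                   inputShape = c(96L, 160L), dropoutRate = 0.5)
}

#' Layer table of a model graph
#'
#' One row per graph node (id, op, flags), for structural inspection: e.g.
#' confirming the absence of softmax/classification ops, counting fusion
#' taps, or checking that batch normalisation follows every convolution.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @return data.frame with columns \code{id}, \code{op}, \code{inputs},
#'   \code{tap}, \code{head}.
#' @export
modelLayers <- function(model) {
  data.frame(
    id = vapply(model@graph, `[[`, "", "id"),
    op = vapply(model@graph, `[[`, "", "op"),
    inputs = vapply(model@graph, function(n) paste(n$inputs, collapse = ","), ""),
    tap = vapply(model@graph, function(n) isTRUE(n$tap), NA),
    head = vapply(model@graph, function(n) isTRUE(n$head), NA))
}

#' Number of trainable parameters
#' @param model a \linkS4class{NetworkModel}.
#' @return Integer-valued count of trainable scalars.
#' @export
countParameters <- function(model) sum(vapply(model@params, length, 0L))

#' Analytic shape summary of an architecture
#'
#' Computes, without allocating any weights, the per-level feature-map shapes
#' of the encoder: level l has \code{baseChannels * 2^l} channels at
#' resolution \code{inputShape / 2^l}, down to the bottleneck at
#' \code{inputShape / 2^levels} with \code{baseChannels * 2^levels} channels.
#'
#' @param spec an \linkS4class{ArchitectureSpec}.
#' @return data.frame with columns \code{stage}, \code{H}, \code{W},
#'   \code{channels}; the last row is the bottleneck.
#' @examples
#' architectureSummary(architectureSpec("unet"))  # bottleneck 19 x 50 x 1024
#' @export
architectureSummary <- function(spec) {
  validObject(spec)
  l <- 0:spec@levels
  data.frame(stage = c(sprintf("level%d", 0:(spec@levels - 1)), "bottleneck"),
             H = as.integer(spec@inputShape[1] %/% 2L^l),
             W = as.integer(spec@inputShape[2] %/% 2L^l),
             channels = as.integer(spec@baseChannels * 2L^l))
}

#' Denoise one envelope B-scan with a trained model
#'
#' Deterministic single forward pass (dropout inactive, batch normalisation
#' in inference mode). Inputs whose dimensions are not divisible by
#' \code{2^levels} are transparently zero-padded at the deep/right edges and
#' cropped back. The output is clamped at zero from below so it remains a
#' valid envelope image.
#'
#' @param model a trained \linkS4class{NetworkModel}.
#' @param img nonnegative H x W envelope matrix.
#' @return The denoised H x W matrix.
#' @export
forwardDenoise <- function(model, img) {
  stopifnot(is.matrix(img))
  stopIfNotFinite(img, "input image")
  d <- 2L^model@spec@levels
  H <- nrow(img); W <- ncol(img)
  Hp <- as.integer(ceiling(H / d) * d); Wp <- as.integer(ceiling(W / d) * d)
  x <- img
  if (Hp != H || Wp != W) {
    x <- matrix(0, Hp, Wp)
    x[seq_len(H), seq_len(W)] <- img
  }
  out <- nnForward(model, x, training = FALSE)$out[, , 1]
  pmax(out[seq_len(H), seq_len(W), drop = FALSE], 0)
}

#' @rdname forwardDenoise
#' @param object a \linkS4class{NetworkModel}.
#' @param x an H x W matrix to denoise.
#' @param ... unused.
#' @export
setGeneric("denoise", function(object, x, ...) standardGeneric("denoise"))

#' @rdname forwardDenoise
#' @export
setMethod("denoise", signature("NetworkModel", "matrix"),
          function(object, x, ...) forwardDenoise(object, x))

#' Turn a model or function into a plain denoiser closure
#'
#' Gives networks and classical baselines the same
#' \code{function(matrix) -> matrix} interface expected by
#' \code{\link{sweepNoiseLevels}} and \code{\link{denoiseVolume}}.
#'
#' @param method a \linkS4class{NetworkModel} or a function.
#' @return A function of one matrix argument.
#' @export
asDenoiser <- function(method) {
  if (is(method, "NetworkModel")) function(img) forwardDenoise(method, img)
  else if (is.function(method)) method
  else stop("method must be a NetworkModel or a function")
}
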
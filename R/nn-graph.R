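# Static-DAG engine for the fully convolutional regressors.
#
# A model graph is a topologically ordered list of op nodes operating on
# (H, W, C) arrays. Supported ops: conv (same-padded, odd k), relu, bn
# (per-channel batch normalisation), pool (2x2 max, stride 2), unpool
# (max-unpooling to the argmax indices recorded by a named pool node),
# tconv (2x2 stride-2 transposed convolution), concat (channel-wise),
# add (elementwise fusion), dropout (inverted, bottleneck regularisation).
# Convolution and pooling kernels are compiled (see src/); the remaining ops
# are thin vectorised R.

newBuilder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list(); env$params <- list(); env$state <- list()
  env
}

addNode <- function(bld, id, op, inputs, ...) {
  bld$nodes[[length(bld$nodes) + 1L]] <- c(list(id = id, op = op,
                                                inputs = inputs), list(...))
  id
}

# He-style initialisation; all draws happen inside the caller's seeded stream.
addConv <- function(b, id, from, cin, cout, k = 3L, ...) {
  wn <- paste0(id, ".w"); bn_ <- paste0(id, ".b")
  b$params[[wn]] <- matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                           k * k * cin, cout)
  b$params[[bn_]] <- numeric(cout)
  addNode(b, id, "conv", from, k = as.integer(k), w = wn, bias = bn_, ...)
}

addTconv <- function(b, id, from, cin, cout) {
  wn <- paste0(id, ".w"); bn_ <- paste0(id, ".b")
  b$params[[wn]] <- array(rnorm(4 * cin * cout, sd = sqrt(2 / cin)),
                          c(2, 2, cin, cout))
  b$params[[bn_]] <- numeric(cout)
  addNode(b, id, "tconv", from, w = wn, bias = bn_)
}

addBN <- function(b, id, from, ch) {
  gn <- paste0(id, ".g"); be <- paste0(id, ".be")
  b$params[[gn]] <- rep(1, ch); b$params[[be]] <- numeric(ch)
  b$state[[paste0(id, ".rm")]] <- numeric(ch)
  b$state[[paste0(id, ".rv")]] <- rep(1, ch)
  addNode(b, id, "bn", from, g = gn, be = be)
}

asCube <- function(x) if (length(dim(x)) == 3L) x else array(x, c(dim(x), 1L))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Run a model forward
#'
#' Executes the graph on one H x W image. In training mode dropout is active
#' (consuming the current RNG stream) and batch normalisation uses
#' within-image statistics while accumulating running averages; in inference
#' mode the pass is deterministic and uses the running statistics.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param x H x W matrix or H x W x 1 array, H and W divisible by
#'   \code{2^levels}.
#' @param training logical.
#' @return List with \code{out} (H x W x 1 array), per-node outputs
#'   \code{outs}, op caches, and \code{stateNew} (updated running statistics,
#'   non-empty only in training mode).
#' @keywords internal
nnForward <- function(model, x, training = FALSE) {
  outs <- list(input = asCube(x))
  cache <- list()
  stateNew <- list()
  P <- model@params
  for (node in model@graph) {
    a <- outs[[node$inputs[1]]]
    out <- switch(node$op,
      conv = conv2d_fwd(a, P[[node$w]], P[[node$bias]], node$k),
      relu = pmax(a, 0),
      bn = {
        d <- dim(a); C <- d[3]
        xm <- matrix(a, d[1] * d[2], C)
        if (training) {
          mu <- colMeans(xm)
          v <- colMeans(xm * xm) - mu^2
          stateNew[[paste0(node$id, ".rm")]] <-
            (1 - BN_MOMENTUM) * model@state[[paste0(node$id, ".rm")]] + BN_MOMENTUM * mu
          stateNew[[paste0(node$id, ".rv")]] <-
            (1 - BN_MOMENTUM) * model@state[[paste0(node$id, ".rv")]] + BN_MOMENTUM * v
        } else {
          mu <- model@state[[paste0(node$id, ".rm")]]
          v <- model@state[[paste0(node$id, ".rv")]]
        }
        istd <- 1 / sqrt(v + BN_EPS)
        xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
        cache[[node$id]] <- list(xhat = xhat, istd = istd)
        ym <- sweep(sweep(xhat, 2, P[[node$g]], `*`), 2, P[[node$be]], `+`)
        array(ym, d)
      },
      pool = {
        r <- maxpool2_fwd(a)
        cache[[node$id]] <- r$idx
        r$y
      },
      unpool = {
        idx <- cache[[node$from]]
        d <- dim(outs[[node$fromInput]])
        scatter_to(a, idx, d[1], d[2])
      },
      tconv = tconvFwd(a, P[[node$w]], P[[node$bias]]),
      concat = {
        b2 <- outs[[node$inputs[2]]]
        d <- dim(a)
        array(c(a, b2), c(d[1], d[2], d[3] + dim(b2)[3]))
      },
      add = a + outs[[node$inputs[2]]],
      dropout = {
        if (training && node$rate > 0) {
          keep <- 1 - node$rate
          m <- (array(runif(length(a)), dim(a)) < keep) / keep
          cache[[node$id]] <- m
          a * m
        } else a
      },
      stop("unknown op: ", node$op))
    outs[[node$id]] <- out
  }
  last <- model@graph[[length(model@graph)]]$id
  list(out = outs[[last]], outs = outs, cache = cache, stateNew = stateNew,
       training = training)
}

tconvFwd <- function(x, w, b) {
  d <- dim(x); h <- d[1]; wd <- d[2]; cin <- d[3]; cout <- dim(w)[4]
  xm <- matrix(x, h * wd, cin)
  out <- array(0, c(2 * h, 2 * wd, cout))
  for (di in 1:2) for (dj in 1:2) {
    wdd <- matrix(w[di, dj, , ], cin, cout)
    out[seq(di, 2 * h, 2), seq(dj, 2 * wd, 2), ] <- array(xm %*% wdd, c(h, wd, cout))
  }
  out + rep(b, each = 4 * h * wd)
}

tconvBwd <- function(x, w, gy) {
  d <- dim(x); h <- d[1]; wd <- d[2]; cin <- d[3]; cout <- dim(w)[4]
  xm <- matrix(x, h * wd, cin)
  gw <- array(0, dim(w)); gx <- matrix(0, h * wd, cin)
  for (di in 1:2) for (dj in 1:2) {
    gdd <- matrix(gy[seq(di, 2 * h, 2), seq(dj, 2 * wd, 2), , drop = FALSE],
                  h * wd, cout)
    gw[di, dj, , ] <- crossprod(xm, gdd)
    gx <- gx + gdd %*% t(matrix(w[di, dj, , ], cin, cout))
  }
  gb <- colSums(matrix(gy, 4 * h * wd, cout))
  list(gx = array(gx, d), gw = gw, gb = gb)
}

# Backward pass: returns the gradient of a scalar loss w.r.t. every
# parameter, given the gradient w.r.t. the network output.
nnBackward <- function(model, fw, gout) {
  grads <- list()
  gs <- list()
  last <- model@graph[[length(model@graph)]]$id
  gs[[last]] <- asCube(gout)
  P <- model@params
  addG <- function(id, g) {
    gs[[id]] <<- if (is.null(gs[[id]])) g else gs[[id]] + g
  }
  addP <- function(nm, g) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  }
  for (node in rev(model@graph)) {
    g <- gs[[node$id]]
    if (is.null(g)) next
    a1 <- node$inputs[1]
    switch(node$op,
      conv = {
        r <- conv2d_bwd(fw$outs[[a1]], P[[node$w]], g, node$k)
        addP(node$w, r$gw); addP(node$bias, as.numeric(r$gb))
        addG(a1, r$gx)
      },
      relu = addG(a1, g * (fw$outs[[node$id]] > 0)),
      bn = {
        cc <- fw$cache[[node$id]]
        d <- dim(g); N <- d[1] * d[2]; C <- d[3]
        gm <- matrix(g, N, C)
        addP(node$g, colSums(gm * cc$xhat))
        addP(node$be, colSums(gm))
        dxh <- sweep(gm, 2, P[[node$g]], `*`)
        if (isTRUE(fw$training)) {
          # batch statistics depend on the input
          s1 <- colSums(dxh); s2 <- colSums(dxh * cc$xhat)
          gx <- sweep(dxh, 2, s1 / N) - sweep(cc$xhat, 2, s2 / N, `*`)
          gx <- sweep(gx, 2, cc$istd, `*`)
        } else {
          # running statistics are constants: BN is a fixed affine map
          gx <- sweep(dxh, 2, cc$istd, `*`)
        }
        addG(a1, array(gx, d))
      },
      pool = {
        d <- dim(fw$outs[[a1]])
        addG(a1, scatter_to(g, fw$cache[[node$id]], d[1], d[2]))
      },
      unpool = {
        idx <- fw$cache[[node$from]]
        addG(a1, array(as.vector(g)[idx + 1L], dim(fw$outs[[a1]])))
      },
      tconv = {
        r <- tconvBwd(fw$outs[[a1]], P[[node$w]], g)
        addP(node$w, r$gw); addP(node$bias, r$gb)
        addG(a1, r$gx)
      },
      concat = {
        c1 <- dim(fw$outs[[a1]])[3]
        addG(a1, g[, , seq_len(c1), drop = FALSE])
        addG(node$inputs[2], g[, , -seq_len(c1), drop = FALSE])
      },
      add = {
        addG(a1, g)
        addG(node$inputs[2], g)
      },
      dropout = {
        m <- fw$cache[[node$id]]
        addG(a1, if (is.null(m)) g else g * m)
      },
      stop("unknown op: ", node$op))
  }
  grads
}
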
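# Training: half mean-squared-error regression loss with an L2 weight
# penalty, Adam updates, a piecewise-constant learning-rate schedule
# (factor 0.3 every 10 epochs), validation checks every 50 iterations, and
# hyperparameter search (random or Gaussian-process-guided).

weightNormSq <- function(params) {
  nm <- grep("\\.w$", names(params), value = TRUE)
  sum(vapply(params[nm], function(p) sum(p * p), 0))
}

#' Half-MSE regression loss with L2 weight penalty
#'
#' \deqn{L = \frac{1}{K} \sum_{p=1}^{K} \frac12 \sum_{i,j}
#'   (y_p(i,j) - x_p(i,j))^2 + \lambda \|\theta\|^2}
#' where \eqn{\|\theta\|^2} is the sum of squared convolution and
#' transposed-convolution weights (biases and normalisation parameters are
#' not penalised).
#'
#' @param outputs network output image (matrix) or list of K images.
#' @param targets ground-truth image or list, matching shapes.
#' @param params named parameter list (e.g. \code{model@params}) used for
#'   the penalty; may be NULL when \code{lambda = 0}.
#' @param lambda regularisation weight.
#' @return Scalar loss.
#' @examples
#' halfMSELoss(matrix(0, 2, 2), matrix(c(1, -1, 2, 0), 2, 2))  # 3
#' @export
halfMSELoss <- function(outputs, targets, params = NULL, lambda = 0) {
  if (is.matrix(outputs)) outputs <- list(outputs)
  if (is.matrix(targets)) targets <- list(targets)
  if (length(outputs) != length(targets))
    stop("outputs and targets must have the same length")
  K <- length(outputs)
  data_term <- 0
  for (p in seq_len(K)) {
    checkSameShape(outputs[[p]], targets[[p]])
    data_term <- data_term + 0.5 * sum((targets[[p]] - outputs[[p]])^2)
  }
  pen <- if (lambda > 0) {
    if (is.null(params)) stop("params required when lambda > 0")
    lambda * weightNormSq(params)
  } else 0
  data_term / K + pen
}

#' Learning rate at a given epoch
#'
#' Piecewise-constant schedule:
#' \code{initialLr * lrDropFactor^floor(epoch / lrDropPeriod)} with the
#' default drop factor 0.3 and period 10 (epochs are 0-based).
#'
#' @param epoch 0-based epoch index.
#' @param cfg a \linkS4class{TrainConfig}.
#' @return The learning rate.
#' @export
lrAt <- function(epoch, cfg) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  cfg@initialLr * cfg@lrDropFactor^floor(epoch / cfg@lrDropPeriod)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

validationScores <- function(model, valPairs, lambda) {
  r <- vapply(valPairs, function(p) {
    out <- forwardDenoise(model, p$noisy)
    c(rmse(p$clean, out), halfMSELoss(out, p$clean, model@params, lambda))
  }, numeric(2))
  c(rmse = mean(r[1, ]), loss = mean(r[2, ]))
}

#' Train a network on paired noisy/clean B-scans
#'
#' Iterates singleton mini-batches in seeded shuffled order (optionally with
#' random paired translations per draw), updates weights with Adam against
#' the half-MSE + L2 loss, and evaluates validation RMSE and loss every
#' \code{valInterval} iterations. The returned model carries the weights of
#' the checkpoint with the lowest validation RMSE.
#'
#' @param model an untrained \linkS4class{NetworkModel}.
#' @param trainPairs,valPairs lists of \code{list(noisy =, clean =)} matrix
#'   pairs sized to the model input.
#' @param cfg a \linkS4class{TrainConfig}.
#' @param verbose print a line per validation check.
#' @return List with \code{model} (best-checkpoint weights) and
#'   \code{history}: \code{iterationLoss} (data.frame iteration, epoch, lr,
#'   loss) and \code{checkpoints} (data.frame iteration, valRMSE, valLoss,
#'   best).
#' @export
trainModel <- function(model, trainPairs, valPairs, cfg, verbose = FALSE) {
  stopifnot(is(model, "NetworkModel"), is(cfg, "TrainConfig"))
  if (length(trainPairs) == 0L || length(valPairs) == 0L)
    stop("training and validation sets must be nonempty")
  withSeed(cfg@seed, {
    opt <- adamInit(model@params)
    iter <- 0L
    losses <- numeric(0); lrs <- numeric(0); epochsRec <- integer(0)
    ckIter <- integer(0); ckRMSE <- numeric(0); ckLoss <- numeric(0)
    bestRMSE <- Inf; bestParams <- model@params; bestState <- model@state
    for (epoch in 0:(cfg@epochs - 1L)) {
      lr <- lrAt(epoch, cfg)
      order_ <- sample.int(length(trainPairs))
      for (i in order_) {
        pair <- trainPairs[[i]]
        if (cfg@augment) {
          a <- augmentTranslate(pair$noisy, pair$clean, cfg@maxShift)
          pair <- list(noisy = a$noisy, clean = a$clean)
        }
        fw <- nnForward(model, pair$noisy, training = TRUE)
        out <- fw$out[, , 1]
        li <- halfMSELoss(out, pair$clean, model@params, cfg@lambda)
        if (!is.finite(li))
          stop("non-finite loss at iteration ", iter + 1L,
               "; reduce the learning rate")
        grads <- nnBackward(model, fw, out - pair$clean)
        if (cfg@lambda > 0) {
          for (nm in grep("\\.w$", names(grads), value = TRUE))
            grads[[nm]] <- grads[[nm]] + 2 * cfg@lambda * model@params[[nm]]
        }
        st <- adamStep(model@params, grads, opt, lr)
        model@params <- st$params; opt <- st$opt
        if (length(fw$stateNew))
          model@state[names(fw$stateNew)] <- fw$stateNew
        iter <- iter + 1L
        losses[iter] <- li; lrs[iter] <- lr; epochsRec[iter] <- epoch
        if (iter %% cfg@valInterval == 0L) {
          vs <- validationScores(model, valPairs, cfg@lambda)
          ckIter <- c(ckIter, iter)
          ckRMSE <- c(ckRMSE, unname(vs["rmse"]))
          ckLoss <- c(ckLoss, unname(vs["loss"]))
          if (vs["rmse"] < bestRMSE) {
            bestRMSE <- unname(vs["rmse"])
            bestParams <- model@params; bestState <- model@state
          }
          if (verbose)
            message(sprintf("iter %d (epoch %d): loss %.4g, val RMSE %.4g",
                            iter, epoch, li, vs["rmse"]))
        }
      }
    }
    # Final check so short runs (< valInterval iterations) still checkpoint
    vs <- validationScores(model, valPairs, cfg@lambda)
    if (!length(ckIter) || ckIter[length(ckIter)] != iter) {
      ckIter <- c(ckIter, iter)
      ckRMSE <- c(ckRMSE, unname(vs["rmse"]))
      ckLoss <- c(ckLoss, unname(vs["loss"]))
    }
    if (vs["rmse"] < bestRMSE) {
      bestRMSE <- unname(vs["rmse"])
      bestParams <- model@params; bestState <- model@state
    }
    model@params <- bestParams; model@state <- bestState
    list(model = model,
         history = list(
           iterationLoss = data.frame(iteration = seq_len(iter),
                                      epoch = epochsRec, lr = lrs,
                                      loss = losses),
           checkpoints = data.frame(iteration = ckIter, valRMSE = ckRMSE,
                                    valLoss = ckLoss,
                                    best = ckRMSE == bestRMSE),
           bestValRMSE = bestRMSE))
  })
}

# Minimal GP surrogate (RBF kernel on unit-scaled coordinates) used by the
# Bayesian strategy; fitted on <= trials points, so a dense solve is cheap.
gpFit <- function(X, y, ls = 0.4, noise = 1e-6) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    exp(-pmax(d2, 0) / (2 * ls^2))
  }
  mu <- mean(y); sdv <- max(sd(y), 1e-12)
  ys <- (y - mu) / sdv
  K <- k(X, X) + diag(noise, nrow(X))
  Ki <- solve(K)
  list(predict = function(Xs) {
    ks <- k(Xs, X)
    m <- as.numeric(ks %*% Ki %*% ys)
    v <- pmax(1 - rowSums((ks %*% Ki) * ks), 1e-12)
    list(mean = m * sdv + mu, sd = sqrt(v) * sdv)
  })
}

expectedImprovement <- function(pred, best) {
  z <- (best - pred$mean) / pred$sd
  (best - pred$mean) * pnorm(z) + pred$sd * dnorm(z)
}

#' Hyperparameter search over learning rate, epochs and L2 penalty
#'
#' Evaluates \code{trials} configurations of \code{objective} and returns
#' the one with the lowest score (validation RMSE in the training use case).
#' The \code{"bayesian"} strategy fits a Gaussian-process surrogate on the
#' unit-scaled (log-lr, epochs, log-lambda) coordinates and picks each next
#' trial by expected improvement over random candidates; \code{"random"}
#' samples the space uniformly (log-uniform for lr and lambda).
#'
#' @param space a \linkS4class{SearchSpace}.
#' @param objective function(list(initialLr, epochs, lambda)) -> scalar score
#'   to minimise.
#' @param seed integer seed.
#' @return List with \code{best} (the winning configuration list, with its
#'   \code{score}) and \code{trials} (the full trial table).
#' @export
tuneHyperparameters <- function(space, objective, seed = NA_integer_) {
  stopifnot(is(space, "SearchSpace"))
  validObject(space)
  withSeed(seed, {
    lo <- c(log(space@lrRange[1]), space@epochsRange[1],
            log(max(space@lambdaRange[1], 1e-12)))
    hi <- c(log(space@lrRange[2]), space@epochsRange[2],
            log(max(space@lambdaRange[2], 1e-12)))
    toCfg <- function(u) {
      v <- lo + u * (hi - lo)
      list(initialLr = exp(v[1]), epochs = as.integer(round(v[2])),
           lambda = if (space@lambdaRange[2] == 0) 0 else exp(v[3]))
    }
    n <- space@trials
    U <- matrix(runif(3 * n), n, 3)
    scores <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (space@strategy == "bayesian" && i > 3) {
        done <- seq_len(i - 1)
        gp <- gpFit(U[done, , drop = FALSE], scores[done])
        cand <- matrix(runif(3 * 256), 256, 3)
        ei <- expectedImprovement(gp$predict(cand), min(scores[done]))
        U[i, ] <- cand[which.max(ei), ]
      }
      cfg <- toCfg(U[i, ])
      scores[i] <- objective(cfg)
    }
    if (all(!is.finite(scores))) {
      print(data.frame(U, score = scores))
      stop("all trials diverged")
    }
    besti <- which.min(scores)
    best <- toCfg(U[besti, ])
    best$score <- scores[besti]
    trialTab <- data.frame(
      trial = seq_len(n),
      initialLr = vapply(seq_len(n), function(i) toCfg(U[i, ])$initialLr, 0),
      epochs = vapply(seq_len(n), function(i) toCfg(U[i, ])$epochs, 0L),
      lambda = vapply(seq_len(n), function(i) toCfg(U[i, ])$lambda, 0),
      score = scores)
    list(best = best, trials = trialTab)
  })
}
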
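#' Hyperparameter configuration for one training run
#'
#' A single point of the search grid: architecture (hidden width), LIF decay
#' `beta`, surrogate slope, optimizer and its settings, gradient-clipping
#' flag and epoch count.
#'
#' @param nHidden hidden neurons.
#' @param beta membrane decay in (0, 1).
#' @param slope surrogate sigmoid steepness.
#' @param optimizer optimizer name (see [makeOptimizer()]).
#' @param lr learning rate.
#' @param wd weight decay.
#' @param gc logical; clip gradients to global norm 1 when `TRUE`.
#' @param epochs training epochs.
#' @return a `hyperParamPoint` (named list).
#' @examples
#' hyperParamPoint(nHidden = 1000, beta = 0.95, slope = 50,
#'                 optimizer = "Adamax", lr = 2e-3)
#' @export
hyperParamPoint <- function(nHidden = 1000, beta = 0.95, slope = 50,
                            optimizer = "Adam", lr = 1e-4, wd = 0,
                            gc = FALSE, epochs = 25) {
  stopifnot(nHidden >= 1, beta > 0, beta < 1, slope > 0, lr >= 0, wd >= 0,
            epochs >= 1)
  structure(list(nHidden = as.integer(nHidden), beta = beta, slope = slope,
                 optimizer = optimizer, lr = lr, wd = wd, gc = isTRUE(gc),
                 epochs = as.integer(epochs)),
            class = "hyperParamPoint")
}

#' @export
print.hyperParamPoint <- function(x, ...) {
  cat(sprintf(
    "<hyperparameters: %d hidden, beta %g, slope %g, %s lr %g wd %g gc %s, %d epochs>\n",
    x$nHidden, x$beta, x$slope, x$optimizer, x$lr, x$wd, x$gc, x$epochs))
  invisible(x)
}

# Clip a list of gradients to a global L2 norm.
.clipGlobalNorm <- function(grads, maxNorm = 1) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > maxNorm)
    grads <- lapply(grads, function(g) g * (maxNorm / nrm))
  grads
}

#' Train a spiking classifier by surrogate-gradient descent
#'
#' Mini-batch training: each epoch shuffles the samples and walks through
#' mini-batches of `batchSize` (64 by default — small batches avoid the
#' generalization gap of large-batch training), computing the rate-coded
#' cross-entropy gradient by backpropagation through time with the logistic
#' surrogate and applying one optimizer step per batch. When the point's
#' `gc` flag is set, gradients are clipped to global L2 norm 1 to protect
#' against exploding gradients. Fully reproducible from `seed` (weight
#' initialization and shuffles both derive from it).
#'
#' @param fpset a [FingerprintSet-class] with training samples.
#' @param point a [hyperParamPoint()].
#' @param seed master seed for init and batch shuffling.
#' @param nSteps simulation steps per forward pass (default 25).
#' @param threshold LIF firing threshold (default 1).
#' @param batchSize mini-batch size (default 64).
#' @param maxRestarts spike-count training has degenerate attractors: an
#'   output neuron that falls completely silent gets no surrogate gradient
#'   (its membrane potential sits far from threshold), can never win the
#'   spike-count vote, and pins every prediction to one class. When the
#'   trained network has an output neuron that never spiked over the
#'   training data it is discarded and training restarts from a fresh
#'   deterministically derived initialization, up to `maxRestarts` times
#'   (default 5); degenerate attempts are abandoned at the first epoch that
#'   exposes them, so only healthy training pays the full epoch budget.
#'   Results remain fully reproducible from `seed`.
#' @return the trained [SNNModel-class]; attribute `"lossHistory"` holds the
#'   mean batch loss per epoch (length `epochs`) and `"restarts"` the number
#'   of restarts taken.
#' @examples
#' fps <- syntheticFingerprints(nPerClass = c(40, 40), nBits = 32,
#'                              nInformative = 8, seed = 1)
#' net <- trainNetwork(fps, hyperParamPoint(nHidden = 16, epochs = 2,
#'                                          lr = 1e-3), seed = 1)
#' attr(net, "lossHistory")
#' @export
trainNetwork <- function(fpset, point, seed, nSteps = 25, threshold = 1,
                         batchSize = 64, maxRestarts = 5) {
  X <- fpMatrix(fpset); y <- fpLabels(fpset)
  if (nrow(X) == 0L) stop("empty dataset", call. = FALSE)
  spec <- networkSpec(nInputs = ncol(X), nHidden = point$nHidden,
                      nSteps = nSteps,
                      lif = lifParams(beta = point$beta,
                                      threshold = threshold),
                      surrogate = surrogateParams(slope = point$slope))
  n <- nrow(X)
  for (attempt in 0:maxRestarts) {
    initSeed <- if (attempt == 0) .deriveSeed(seed, "init")
                else .deriveSeed(seed, "restart", attempt)
    model <- initNetwork(spec, initSeed)
    opt <- makeOptimizer(point$optimizer, lr = point$lr, wd = point$wd)
    lossHistory <- numeric(point$epochs)
    for (ep in seq_len(point$epochs)) {
      ord <- .withSeed(.deriveSeed(seed, "shuffle", attempt, ep),
                       sample.int(n))
      starts <- seq(1L, n, by = batchSize)
      losses <- numeric(length(starts))
      for (b in seq_along(starts)) {
        idx <- ord[starts[b]:min(starts[b] + batchSize - 1L, n)]
        g <- snnGradient(model, X[idx, , drop = FALSE], y[idx])
        grads <- list(W1 = g$dW1, W2 = g$dW2)
        if (point$gc) grads <- .clipGlobalNorm(grads, 1)
        upd <- opt$step(list(W1 = model@W1, W2 = model@W2), grads)
        model@W1 <- upd$W1; model@W2 <- upd$W2
        losses[b] <- g$loss
      }
      lossHistory[ep] <- mean(losses)
      # abandon a degenerate attempt as soon as an epoch exposes it (but
      # let the final permitted attempt run its full budget)
      if (attempt < maxRestarts && ep < point$epochs &&
          .isSilent(model, X)) break
    }
    if (attempt == maxRestarts || !.isSilent(model, X)) break
  }
  attr(model, "lossHistory") <- lossHistory
  attr(model, "restarts") <- attempt
  model
}

# Degenerate-network probe: TRUE when either output neuron emits no spike
# at all over (a subsample of) the training fingerprints. A dead output
# neuron can never win the spike-count vote (ties go to class 0), so the
# network is pinned to one class and — with the surrogate gradient vanishing
# far from threshold — cannot recover by further training.
.isSilent <- function(model, X, maxSamples = 256L) {
  probe <- X[seq_len(min(nrow(X), maxSamples)), , drop = FALSE]
  min(colSums(.forwardBatch(model, probe)$outputCounts)) == 0
}
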
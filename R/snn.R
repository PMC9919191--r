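#' Construct a network architecture specification
#'
#' @param nInputs fingerprint length (166 for MACCS, 1024 for default ECFP).
#' @param nHidden hidden LIF neurons.
#' @param nSteps simulation steps `T` per forward pass (default 25: long
#'   enough for spike counts to separate classes, short enough to keep
#'   desk-scale runtime; configurable).
#' @param lif a [LIFParams-class] shared by hidden and output layers.
#' @param surrogate a [SurrogateParams-class].
#' @return a [NetworkSpec-class] (output layer is always 2 neurons).
#' @examples
#' networkSpec(nInputs = 166, nHidden = 1000)
#' @export
networkSpec <- function(nInputs = 166, nHidden = 1000, nSteps = 25,
                        lif = lifParams(), surrogate = surrogateParams()) {
  new("NetworkSpec", nInputs = as.integer(nInputs),
      nHidden = as.integer(nHidden), nOutputs = 2L,
      nSteps = as.integer(nSteps), lif = lif, surrogate = surrogate)
}

#' Spiking classifier with dense weights
#'
#' Weight container for the two-layer fully connected spiking network:
#' `W1` (`nInputs x nHidden`) carries the fingerprint bits into the hidden
#' LIF layer as input currents, `W2` (`nHidden x 2`) carries hidden spikes
#' into the two output neurons.
#'
#' @slot W1,W2 numeric weight matrices.
#' @slot spec the [NetworkSpec-class] the weights were built for.
#' @slot seed integer seed the initialization was drawn from.
#' @seealso [initNetwork()], [snnForward()], [trainNetwork()]
#' @name SNNModel-class
#' @rdname SNNModel-class
#' @exportClass SNNModel
setClass("SNNModel",
  representation(W1 = "matrix", W2 = "matrix", spec = "NetworkSpec",
                 seed = "integer"))

setMethod("show", "SNNModel", function(object) {
  s <- object@spec
  cat(sprintf("SNNModel: %d -> %d -> 2 LIF network, T = %d steps\n",
              s@nInputs, s@nHidden, s@nSteps))
  cat(sprintf("  beta = %g, threshold = %g, surrogate slope = %g, seed = %d\n",
              s@lif@beta, s@lif@threshold, s@surrogate@slope, object@seed))
  invisible(NULL)
})

#' Initialize network weights
#'
#' Dense scaled-uniform initialization, `U(-1/sqrt(fanIn), 1/sqrt(fanIn))`
#' per layer, fully reproducible from the seed.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer seed.
#' @return an [SNNModel-class].
#' @examples
#' net <- initNetwork(networkSpec(nInputs = 8, nHidden = 4), seed = 1)
#' dim(net@W1)
#' @export
initNetwork <- function(spec, seed) {
  validObject(spec)
  .withSeed(seed, {
    r1 <- 1 / sqrt(spec@nInputs)
    W1 <- matrix(stats::runif(spec@nInputs * spec@nHidden, -r1, r1),
                 spec@nInputs, spec@nHidden)
    r2 <- 1 / sqrt(spec@nHidden)
    W2 <- matrix(stats::runif(spec@nHidden * 2L, -r2, r2), spec@nHidden, 2L)
    new("SNNModel", W1 = W1, W2 = W2, spec = spec, seed = as.integer(seed))
  })
}

# Batched forward pass over T steps. X: n x nInputs matrix of 0/1 bits,
# injected as constant input current at every step through W1. With
# smoothed = TRUE the Heaviside spike is replaced by the logistic
# sigma(k (u - theta)) everywhere (a fully differentiable relaxation used
# by the gradient checks); counts are then real-valued.
# Returns counts and, if cache = TRUE, the per-step quantities the backward
# pass needs.
.forwardBatch <- function(model, X, smoothed = FALSE, cache = FALSE) {
  spec <- model@spec
  if (ncol(X) != spec@nInputs)
    stop("fingerprint length ", ncol(X), " does not match network inputs ",
         spec@nInputs, call. = FALSE)
  n <- nrow(X); nh <- spec@nHidden; Tt <- spec@nSteps
  beta <- spec@lif@beta; theta <- spec@lif@threshold
  k <- spec@surrogate@slope
  spk <- if (smoothed) function(u) stats::plogis(k * (u - theta))
         else          function(u) (u >= theta) + 0
  Ch <- X %*% model@W1                   # constant injection, reused each step
  Vh <- matrix(0, n, nh); Vo <- matrix(0, n, 2L)
  hiddenCounts <- matrix(0, n, nh); outputCounts <- matrix(0, n, 2L)
  Uh <- if (cache) vector("list", Tt)
  Sh <- if (cache) vector("list", Tt)
  Uo <- if (cache) vector("list", Tt)
  for (t in seq_len(Tt)) {
    uh <- beta * Vh + Ch
    sh <- spk(uh)
    Vh <- uh - theta * sh
    uo <- beta * Vo + sh %*% model@W2
    so <- spk(uo)
    Vo <- uo - theta * so
    hiddenCounts <- hiddenCounts + sh
    outputCounts <- outputCounts + so
    if (cache) { Uh[[t]] <- uh; Sh[[t]] <- sh; Uo[[t]] <- uo }
  }
  out <- list(outputCounts = outputCounts, hiddenCounts = hiddenCounts)
  if (cache) { out$Uh <- Uh; out$Sh <- Sh; out$Uo <- Uo; out$X <- X }
  out
}

.softmax2 <- function(counts) {
  ex <- exp(counts - apply(counts, 1L, max))
  ex / rowSums(ex)
}

# Backpropagation through time. Gradients of the mean rate-coded
# cross-entropy over the batch w.r.t. W1 and W2. The same recursion serves
# the training path (hard forward, surrogate derivative at the hard
# operating points) and the smoothed relaxation (where it is the exact
# chain rule).
#
# resetGrad: whether the spike's appearance in the reset-by-subtraction
# (V = U - theta * s(U)) contributes -theta * ds/dU to dV/dU. With the
# steep surrogate slopes used here that factor exceeds 1 in magnitude and
# compounds over time steps into exploding gradients, so the training path
# detaches it (the convention of surrogate-gradient SNN frameworks);
# resetGrad = TRUE gives the exact chain rule of the smoothed network and
# is what the finite-difference validation uses.
.backwardBatch <- function(model, fwd, y, resetGrad = FALSE) {
  spec <- model@spec
  n <- nrow(fwd$X); Tt <- spec@nSteps
  beta <- spec@lif@beta; theta <- spec@lif@threshold
  surrogate <- spec@surrogate
  p <- .softmax2(fwd$outputCounts)
  loss <- mean(-log(pmax(p[cbind(seq_len(n), y + 1L)], 1e-300)))
  dC <- p / n
  dC[cbind(seq_len(n), y + 1L)] <- dC[cbind(seq_len(n), y + 1L)] - 1 / n
  gVo <- matrix(0, n, 2L); gVh <- matrix(0, n, spec@nHidden)
  dW2 <- matrix(0, spec@nHidden, 2L)
  dChSum <- matrix(0, n, spec@nHidden)
  rg <- if (resetGrad) theta else 0
  for (t in rev(seq_len(Tt))) {
    dUo <- (dC - rg * gVo) * surrogateGrad(fwd$Uo[[t]] - theta,
                                           surrogate) + gVo
    gVo <- beta * dUo
    dW2 <- dW2 + crossprod(fwd$Sh[[t]], dUo)
    dSh <- dUo %*% t(model@W2)
    dUh <- (dSh - rg * gVh) * surrogateGrad(fwd$Uh[[t]] - theta,
                                            surrogate) + gVh
    gVh <- beta * dUh
    dChSum <- dChSum + dUh
  }
  list(dW1 = crossprod(fwd$X, dChSum), dW2 = dW2, loss = loss)
}

#' Run the spiking classifier on fingerprints
#'
#' Simulates the network for `T` steps with the fingerprint bits injected as
#' constant input currents at every step (fingerprints are already binary,
#' so no spike-train conversion is needed), and counts spikes per neuron.
#' The continuous class score is the positive output neuron's share of the
#' total output spikes.
#'
#' @param model an [SNNModel-class].
#' @param x a 0/1 fingerprint vector, or an `n x nInputs` matrix of them.
#' @return for a single fingerprint, a list with `outputCounts` (2 integers),
#'   `hiddenCounts` and `score`; for a matrix, `outputCounts` is `n x 2`,
#'   `hiddenCounts` `n x nHidden` and `score` length `n`. Predictions for a
#'   sample are identical whether it is run alone or inside a batch.
#' @examples
#' net <- initNetwork(networkSpec(nInputs = 8, nHidden = 4, nSteps = 10), 1)
#' snnForward(net, rep(1, 8))$outputCounts
#' @export
snnForward <- function(model, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1L) else as.matrix(x)
  .assertBinary(X, "fingerprint")
  fwd <- .forwardBatch(model, X)
  score <- fwd$outputCounts[, 2L] /
    pmax(1, fwd$outputCounts[, 1L] + fwd$outputCounts[, 2L])
  if (single)
    list(outputCounts = drop(fwd$outputCounts),
         hiddenCounts = drop(fwd$hiddenCounts), score = score)
  else
    list(outputCounts = fwd$outputCounts, hiddenCounts = fwd$hiddenCounts,
         score = score)
}

#' Spike-count class decision
#'
#' The sample is assigned to the output neuron that fired more spikes; an
#' exact tie (including total silence) goes deterministically to class 0.
#'
#' @param result the value of [snnForward()], or an `n x 2` matrix of output
#'   spike counts.
#' @return integer 0/1 vector of predicted classes.
#' @examples
#' snnPredict(rbind(c(3, 7), c(5, 5)))  # 1, 0
#' @export
snnPredict <- function(result) {
  counts <- if (is.list(result)) result$outputCounts else result
  if (is.null(dim(counts))) counts <- matrix(counts, 1L)
  as.integer(counts[, 2L] > counts[, 1L])
}

#' Rate-coded cross-entropy loss
#'
#' Cross-entropy of the softmax over time-summed output spike counts against
#' the 0/1 label — the differentiable counterpart of the "more spikes wins"
#' decision rule. Equal counts give `log(2)` regardless of label.
#'
#' @param outputCounts 2-vector or `n x 2` matrix of output spike counts.
#' @param labels 0/1 vector.
#' @return mean loss (non-negative scalar).
#' @examples
#' rateLoss(c(5, 5), 1)  # log(2)
#' @export
rateLoss <- function(outputCounts, labels) {
  counts <- if (is.null(dim(outputCounts))) matrix(outputCounts, 1L)
            else as.matrix(outputCounts)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  p <- .softmax2(counts)
  mean(-log(pmax(p[cbind(seq_len(nrow(counts)), labels + 1L)], 1e-300)))
}

#' Loss gradient through the spiking network
#'
#' Backpropagation through time of the mean rate-coded cross-entropy.
#' With `smoothed = FALSE` (the training path) the forward pass emits hard
#' Heaviside spikes and the backward pass substitutes the logistic surrogate
#' derivative at the hard operating points. With `smoothed = TRUE` every
#' spike is replaced by the logistic `sigma(k (u - theta))` in the forward
#' pass as well, making the whole network differentiable — in that mode the
#' returned gradient is the exact gradient of the smoothed loss and can be
#' validated against finite differences.
#'
#' @param model an [SNNModel-class].
#' @param X `n x nInputs` 0/1 matrix.
#' @param y length-`n` 0/1 label vector.
#' @param smoothed logical; see above.
#' @param resetGrad logical; propagate the gradient through the spike's
#'   appearance in the reset-by-subtraction term. Off by default for
#'   training (the steep surrogate makes that term compound into exploding
#'   gradients over time steps — detaching the reset is the usual
#'   surrogate-gradient convention); turned on together with `smoothed` it
#'   yields the exact gradient of the smoothed loss.
#' @return list with `dW1`, `dW2` and the forward `loss`.
#' @export
snnGradient <- function(model, X, y, smoothed = FALSE,
                        resetGrad = smoothed) {
  X <- as.matrix(X)
  fwd <- .forwardBatch(model, X, smoothed = smoothed, cache = TRUE)
  .backwardBatch(model, fwd, as.integer(y), resetGrad = resetGrad)
}

# Loss of the fully smoothed network (used by finite-difference checks).
.smoothedLoss <- function(model, X, y) {
  fwd <- .forwardBatch(model, as.matrix(X), smoothed = TRUE)
  rateLoss(fwd$outputCounts, y)
}
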
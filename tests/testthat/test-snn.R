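# Network construction, forward simulation, decision rule, loss, gradients.

test_that("initialization is seed-reproducible with the right shapes", {
  spec <- networkSpec(nInputs = 166, nHidden = 1000, nSteps = 5)
  a <- initNetwork(spec, 7); b <- initNetwork(spec, 7)
  expect_identical(a@W1, b@W1); expect_identical(a@W2, b@W2)
  expect_equal(dim(a@W1), c(166L, 1000L))
  expect_equal(dim(a@W2), c(1000L, 2L))
  c <- initNetwork(spec, 8)
  expect_false(identical(a@W1, c@W1))
  expect_error(networkSpec(nInputs = 0), "nInputs")
})

test_that("forward pass respects zero-input and count bounds", {
  net <- initNetwork(networkSpec(nInputs = 12, nHidden = 6, nSteps = 9), 3)
  z <- snnForward(net, rep(0, 12))
  expect_equal(z$outputCounts, c(0, 0))
  expect_equal(z$hiddenCounts, rep(0, 6))
  expect_equal(z$score, 0)
  set.seed(11)
  X <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12)
  f <- snnForward(net, X)
  expect_true(all(f$outputCounts >= 0 & f$outputCounts <= 9))
  expect_true(all(f$hiddenCounts >= 0 & f$hiddenCounts <= 9))
  expect_true(all(f$score >= 0 & f$score <= 1))
  expect_error(snnForward(net, rep(0, 13)), "does not match")
})

test_that("single hidden neuron with beta = 0 fires each step iff its drive reaches threshold", {
  mk <- function(w) {
    spec <- networkSpec(nInputs = 1, nHidden = 1, nSteps = 8,
                        lif = lifParams(beta = 1e-9, threshold = 1))
    net <- initNetwork(spec, 1)
    net@W1[1, 1] <- w; net@W2[, ] <- 0
    net
  }
  # beta ~ 0: no integration memory, so the neuron fires every step iff w >= 1
  expect_equal(snnForward(mk(1.0), 1)$hiddenCounts, 8)
  expect_equal(snnForward(mk(1.7), 1)$hiddenCounts, 8)
  expect_equal(snnForward(mk(0.99), 1)$hiddenCounts, 0)
})

test_that("inference is batch invariant", {
  net <- initNetwork(networkSpec(nInputs = 20, nHidden = 10, nSteps = 12), 5)
  set.seed(2)
  X <- matrix(rbinom(7 * 20, 1, 0.4), 7, 20)
  batch <- snnForward(net, X)
  for (i in seq_len(7)) {
    solo <- snnForward(net, X[i, ])
    expect_identical(solo$outputCounts, batch$outputCounts[i, ])
    expect_identical(solo$score, batch$score[i])
  }
})

test_that("prediction takes the neuron with more spikes, ties to class 0", {
  expect_equal(snnPredict(rbind(c(3, 7), c(5, 5), c(0, 0), c(9, 1))),
               c(1L, 0L, 0L, 0L))
  # consistency with the score up to the tie rule
  net <- initNetwork(networkSpec(nInputs = 20, nHidden = 10, nSteps = 12), 5)
  set.seed(3)
  f <- snnForward(net, matrix(rbinom(20 * 20, 1, 0.5), 20, 20))
  pred <- snnPredict(f)
  expect_true(all(pred[f$score > 0.5] == 1L))
  expect_true(all(pred[f$score < 0.5] == 0L))
  # all-zero weights silence the network
  net@W1[, ] <- 0; net@W2[, ] <- 0
  f0 <- snnForward(net, matrix(1, 3, 20))
  expect_true(all(f0$outputCounts == 0))
  expect_equal(snnPredict(f0), rep(0L, 3))
})

test_that("rate loss behaves like a softmax cross-entropy on counts", {
  expect_equal(rateLoss(c(4, 4), 0), log(2))
  expect_equal(rateLoss(c(4, 4), 1), log(2))
  # decreases as the true-class count grows, other count fixed
  losses <- vapply(0:10, function(k) rateLoss(c(5, k), 1), numeric(1))
  expect_true(all(diff(losses) < 0))
  # symmetric under label flip + count swap
  expect_equal(rateLoss(c(7, 2), 0), rateLoss(c(2, 7), 1))
  expect_error(rateLoss(c(1, 2), 2), "labels")
})

test_that("backprop through time matches finite differences of the smoothed network", {
  set.seed(9)
  X <- matrix(rbinom(4 * 5, 1, 0.5), 4, 5)
  y <- c(0, 1, 1, 0)
  for (k in c(25, 75)) {
    spec <- networkSpec(nInputs = 5, nHidden = 3, nSteps = 3,
                        lif = lifParams(beta = 0.8),
                        surrogate = surrogateParams(k))
    m <- initNetwork(spec, 13)
    # operating points near threshold keep the check well conditioned
    m@W1 <- m@W1 + 0.3; m@W2 <- m@W2 + 0.4
    g <- snnGradient(m, X, y, smoothed = TRUE)
    fd <- smoothedFiniteDiff(m, X, y, eps = 1e-5)
    expect_lt(gradRelErr(list(g$dW1, g$dW2), fd), 1e-4)
  }
})

test_that("training gradient agrees with the smoothed gradient when spikes saturate", {
  # with hidden drives far from threshold the hard and smoothed forwards
  # coincide, so the surrogate training gradient approaches the exact one
  spec <- networkSpec(nInputs = 2, nHidden = 2, nSteps = 1,
                      lif = lifParams(beta = 0.9),
                      surrogate = surrogateParams(50))
  m <- initNetwork(spec, 3)
  m@W1 <- matrix(c(2, -1, -1, 2), 2, 2)      # |U - theta| = 1 at the inputs
  m@W2 <- matrix(c(1.6, 0.4, 0.3, 1.7), 2, 2)
  X <- rbind(c(1, 0), c(0, 1)); y <- c(1, 0)
  gHard <- snnGradient(m, X, y)               # training path
  gSmooth <- snnGradient(m, X, y, smoothed = TRUE)
  expect_lt(gradRelErr(list(gHard$dW1, gHard$dW2),
                       list(gSmooth$dW1, gSmooth$dW2)), 1e-6)
})
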
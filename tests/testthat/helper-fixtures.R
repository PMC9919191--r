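# Shared fixtures: all data is generated in code at test time.

# A tiny SMILES/label CSV on disk; returns the path.
writeSmilesCSV <- function(smiles, label,
                           path = tempfile(fileext = ".csv")) {
  utils::write.csv(data.frame(smiles = smiles, label = label), path,
                   row.names = FALSE, quote = FALSE)
  path
}

# Small, quickly learnable synthetic task.
easyFingerprints <- function(nPerClass = c(80, 80), seed = 7) {
  syntheticFingerprints(nPerClass = nPerClass, nBits = 64,
                        nInformative = 16, pOnActive = 0.7,
                        pBackground = 0.1, seed = seed)
}

# Tiny hyperparameter settings that keep CV tests fast.
tinyPoint <- function(...) {
  args <- utils::modifyList(
    list(nHidden = 16, beta = 0.9, slope = 50, optimizer = "Adamax",
         lr = 2e-3, wd = 0, gc = FALSE, epochs = 2), list(...))
  do.call(hyperParamPoint, args)
}

tinyGrid <- function(...) {
  args <- utils::modifyList(
    list(nHidden = 16L, beta = 0.9, slope = 50, optimizer = "Adamax",
         lr = 2e-3, wd = 0, gc = FALSE, epochs = 2L), list(...))
  do.call(hyperGrid, args)
}

# Euclidean-norm relative error between two gradients (lists of matrices).
gradRelErr <- function(g, ref) {
  num <- sqrt(sum(mapply(function(a, b) sum((a - b)^2), g, ref)))
  den <- sqrt(sum(vapply(ref, function(b) sum(b^2), numeric(1))))
  num / max(den, 1e-300)
}

# Central finite difference of the fully smoothed network loss w.r.t. every
# weight — the independent oracle for the backprop implementation.
smoothedFiniteDiff <- function(model, X, y, eps = 1e-5) {
  lossAt <- function(m) SpikeScreen:::.smoothedLoss(m, X, y)
  fdMat <- function(slotName) {
    W <- slot(model, slotName)
    out <- W * 0
    for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
      m1 <- model; m2 <- model
      slot(m1, slotName)[i, j] <- W[i, j] + eps
      slot(m2, slotName)[i, j] <- W[i, j] - eps
      out[i, j] <- (lossAt(m1) - lossAt(m2)) / (2 * eps)
    }
    out
  }
  list(dW1 = fdMat("W1"), dW2 = fdMat("W2"))
}

# Brute-force AUC: fraction of positive/negative pairs ranked correctly,
# ties counting one half.
bruteForceAUC <- function(yTrue, scores) {
  pos <- scores[yTrue == 1]; neg <- scores[yTrue == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
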
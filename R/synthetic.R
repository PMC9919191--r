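#' Generate fingerprint-like binary data with known class structure
#'
#' Emulates sparse fixed-length binary molecular fingerprints with a planted
#' class signal: every bit is an independent Bernoulli draw whose activation
#' probability is `pBackground` everywhere except for the first
#' `nInformative` bits in class-1 samples, which activate with probability
#' `pOnActive`. Class imbalance is set directly through `nPerClass` (e.g.
#' `c(1366, 112)` to mimic a strongly imbalanced toxicity benchmark).
#' Defaults give the "easy" benchmark task used throughout the package's
#' self-tests: 500 samples per class, 166 bits of which 30 are informative,
#' `pOnActive = 0.6` against a 0.1 background.
#'
#' @param nPerClass integer 2-vector `c(nNegative, nPositive)`.
#' @param nBits fingerprint length (default 166).
#' @param nInformative number of class-discriminative bits (<= `nBits`).
#' @param pOnActive activation probability of informative bits in class 1.
#' @param pBackground baseline activation probability (all other bits and
#'   all class-0 bits); must not exceed `pOnActive`.
#' @param seed integer seed; generation is bit-exactly reproducible.
#' @return a [FingerprintSet-class] (`fpType = "synthetic"`), negatives
#'   first.
#' @examples
#' fps <- syntheticFingerprints(nPerClass = c(20, 20), nBits = 64,
#'                              nInformative = 8, seed = 1)
#' fps
#' @export
syntheticFingerprints <- function(nPerClass = c(500, 500), nBits = 166,
                                  nInformative = 30, pOnActive = 0.6,
                                  pBackground = 0.1, seed = 1) {
  if (length(nPerClass) != 2L || any(nPerClass < 1))
    stop("nPerClass must be two positive counts", call. = FALSE)
  if (pBackground < 0 || pOnActive > 1 || pBackground > pOnActive)
    stop("need 0 <= pBackground <= pOnActive <= 1", call. = FALSE)
  if (nInformative > nBits)
    stop("nInformative cannot exceed nBits", call. = FALSE)
  n0 <- nPerClass[1]; n1 <- nPerClass[2]
  .withSeed(seed, {
    neg <- matrix(stats::rbinom(n0 * nBits, 1L, pBackground), n0, nBits)
    p1 <- rep(pBackground, nBits)
    if (nInformative > 0) p1[seq_len(nInformative)] <- pOnActive
    pos <- matrix(stats::rbinom(n1 * nBits, 1L,
                                rep(p1, each = n1)), n1, nBits)
    FingerprintSet(rbind(neg, pos), labels = rep(c(0L, 1L), c(n0, n1)),
                   fpType = "synthetic")
  })
}

#' Per-bit empirical activation rates by class
#'
#' @param fpset a [FingerprintSet-class].
#' @return a `2 x nBits` matrix of activation frequencies with rows
#'   `"class0"` and `"class1"` (a row of `NaN` if a class is absent).
#' @examples
#' fps <- syntheticFingerprints(nPerClass = c(50, 50), nBits = 16,
#'                              nInformative = 4, seed = 1)
#' rowMeans(empiricalBitFrequency(fps))
#' @export
empiricalBitFrequency <- function(fpset) {
  X <- fpMatrix(fpset); y <- fpLabels(fpset)
  if (nrow(X) == 0L) stop("empty dataset", call. = FALSE)
  rbind(class0 = colMeans(X[y == 0L, , drop = FALSE]),
        class1 = colMeans(X[y == 1L, , drop = FALSE]))
}

#' Write a FingerprintSet as a SMILES-table-layout CSV
#'
#' Serializes the fingerprint bits as a compact bitstring column plus the
#' label, in the same comma-separated layout [loadSmilesTable()] reads (the
#' bitstring stands in the SMILES column, useful for exercising loaders and
#' pipelines without chemistry).
#'
#' @param fpset a [FingerprintSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFingerprintCSV <- function(fpset, path) {
  bits <- apply(fpMatrix(fpset), 1L, paste, collapse = "")
  utils::write.csv(data.frame(smiles = bits, label = fpLabels(fpset)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [writeFingerprintCSV()]
#'
#' @param path CSV path.
#' @param fpType fingerprint family label for the result.
#' @return a [FingerprintSet-class].
#' @export
readFingerprintCSV <- function(path, fpType = "synthetic") {
  d <- utils::read.csv(path, colClasses = c(smiles = "character"))
  bits <- do.call(rbind, lapply(strsplit(d$smiles, ""),
                                function(ch) as.integer(ch)))
  FingerprintSet(bits, labels = d$label, fpType = fpType)
}
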
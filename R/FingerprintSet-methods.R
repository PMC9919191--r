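#' Construct a FingerprintSet
#'
#' @param bits matrix with entries in \{0,1\}, one row per molecule.
#' @param labels vector coercible to integer 0/1, one entry per row.
#' @param fpType character scalar naming the fingerprint family.
#' @return a [FingerprintSet-class] object.
#' @examples
#' fps <- FingerprintSet(matrix(c(1,0,0,1), 2, 2), labels = c(0, 1),
#'                       fpType = "toy")
#' fps
#' @export
FingerprintSet <- function(bits, labels, fpType = "unknown") {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "double"
  new("FingerprintSet", bits = bits, labels = as.integer(labels),
      fpType = as.character(fpType))
}

#' @rdname FingerprintSet-class
#' @export
setMethod("fpMatrix", "FingerprintSet", function(x) x@bits)

#' @rdname FingerprintSet-class
#' @export
setMethod("fpLabels", "FingerprintSet", function(x) x@labels)

#' @rdname FingerprintSet-class
#' @export
setMethod("nBits", "FingerprintSet", function(x) ncol(x@bits))

#' @rdname FingerprintSet-class
#' @export
setMethod("fpType", "FingerprintSet", function(x) x@fpType)

#' @rdname FingerprintSet-class
#' @export
setMethod("length", "FingerprintSet", function(x) nrow(x@bits))

#' @describeIn FingerprintSet-class subset samples (rows); duplicated and
#'   reordered indices are allowed, which is how oversampling and CV folds
#'   are materialized.
#' @param i integer or logical row index
#' @param j,...,drop ignored
#' @export
setMethod("[", "FingerprintSet", function(x, i, j, ..., drop = FALSE) {
  new("FingerprintSet", bits = x@bits[i, , drop = FALSE],
      labels = x@labels[i], fpType = x@fpType)
})

setMethod("show", "FingerprintSet", function(object) {
  n <- nrow(object@bits)
  cat(sprintf("FingerprintSet: %d molecule%s x %d bits (%s)\n",
              n, if (n == 1) "" else "s", ncol(object@bits), object@fpType))
  if (n) {
    tab <- table(factor(object@labels, levels = c(0, 1)))
    cat(sprintf("  labels: %d negative / %d positive\n", tab[["0"]],
                tab[["1"]]))
    cat(sprintf("  bit density: %.3f\n", mean(object@bits)))
  }
  invisible(NULL)
})

#' @rdname CVSummary-class
#' @export
setMethod("cvResults", "CVSummary", function(x) x@results)

setMethod("show", "CVSummary", function(object) {
  cat("Repeated nested cross-validation summary\n")
  cfg <- object@config
  cat(sprintf("  %d repetition(s) x %d outer fold(s), %d inner fold(s), balance = %s\n",
              cfg$nRepeats, cfg$kOuter, cfg$kInner, cfg$balance))
  cat(sprintf("  balanced accuracy: %.3f %% (sd %.3f)\n",
              object@meanBA, object@stdBA))
  cat(sprintf("  ROC AUC:           %.3f (sd %.3f)\n",
              object@meanAUC, object@stdAUC))
  invisible(NULL)
})
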
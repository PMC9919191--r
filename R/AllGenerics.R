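#' @describeIn FingerprintSet-class fingerprint matrix accessor
#' @param x,object a `FingerprintSet`
#' @export
setGeneric("fpMatrix", function(x) standardGeneric("fpMatrix"))

#' @describeIn FingerprintSet-class label vector accessor
#' @export
setGeneric("fpLabels", function(x) standardGeneric("fpLabels"))

#' @describeIn FingerprintSet-class number of fingerprint bits
#' @export
setGeneric("nBits", function(x) standardGeneric("nBits"))

#' @describeIn FingerprintSet-class fingerprint family label
#' @export
setGeneric("fpType", function(x) standardGeneric("fpType"))

#' @describeIn CVSummary-class per-fold results table accessor
#' @param x a `CVSummary`
#' @export
setGeneric("cvResults", function(x) standardGeneric("cvResults"))

#' Mean pairwise Tanimoto similarity
#'
#' Arithmetic mean of the Jaccard–Tanimoto index over all unordered distinct
#' pairs of fingerprints. Used to gauge how structurally homogeneous a
#' compound collection is before classification (homogeneous sets make
#' generalization claims weaker).
#'
#' @param x a [FingerprintSet-class] or a 0/1 matrix with one fingerprint
#'   per row; at least 2 rows.
#' @return numeric scalar in \[0, 1\].
#' @examples
#' m <- rbind(c(1,1,0,0), c(0,1,1,0), c(1,1,1,0))
#' meanPairwiseTanimoto(m)  # mean of 1/3, 2/3, 2/3 = 5/9
#' @export
setGeneric("meanPairwiseTanimoto",
           function(x) standardGeneric("meanPairwiseTanimoto"))

#' Equalize class counts by oversampling the minority class
#'
#' Duplicates minority-class records, drawn uniformly with replacement under
#' an explicit seed, until both classes match the original majority count.
#' Balancing the two classes before training prevents the classifier from
#' being over-exposed to the majority class.
#'
#' @param x a [FingerprintSet-class] or a data.frame with a label column.
#' @param seed integer seed controlling the resampling draws.
#' @param labelColumn for the data.frame method, name of the 0/1 label
#'   column (default `"label"`).
#' @return an object of the same class as `x` with equal class counts; the
#'   appended rows are duplicates of minority rows. The attribute
#'   `"oversampleIdx"` holds the row indices of `x` that make up the result.
#' @examples
#' d <- data.frame(smiles = c("a","b","c","d"), label = c(0,0,0,1))
#' table(oversampleMinority(d, seed = 1)$label)
#' @export
setGeneric("oversampleMinority",
           function(x, seed, ...) standardGeneric("oversampleMinority"))
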
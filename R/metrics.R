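#' Balanced accuracy
#'
#' Mean of sensitivity (true-positive rate) and specificity (true-negative
#' rate), in percent. Robust to class imbalance: a constant predictor scores
#' 50 regardless of the class ratio.
#'
#' @param yTrue,yPred 0/1 vectors of equal length; `yTrue` must contain both
#'   classes.
#' @return percentage in \[0, 100\].
#' @examples
#' balancedAccuracy(c(rep(1,10), rep(0,10)),
#'                  c(rep(1,9), 0, rep(0,8), 1, 1))  # 85
#' @export
balancedAccuracy <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred lengths differ", call. = FALSE)
  .assertBinary(yTrue, "yTrue"); .assertBinary(yPred, "yPred")
  if (length(unique(yTrue)) < 2L)
    stop("yTrue must contain both classes", call. = FALSE)
  sens <- mean(yPred[yTrue == 1] == 1)
  spec <- mean(yPred[yTrue == 0] == 0)
  100 * (sens + spec) / 2
}

#' Area under the ROC curve
#'
#' Computed via the rank (Mann–Whitney) statistic with midranks for tied
#' scores: the probability that a randomly chosen positive outscores a
#' randomly chosen negative, ties counting one half.
#'
#' @param yTrue 0/1 vector containing both classes.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @examples
#' aucROC(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))  # 0.75
#' @export
aucROC <- function(yTrue, scores) {
  if (length(yTrue) != length(scores))
    stop("yTrue and scores lengths differ", call. = FALSE)
  .assertBinary(yTrue, "yTrue")
  n1 <- sum(yTrue == 1); n0 <- sum(yTrue == 0)
  if (n1 == 0L || n0 == 0L)
    stop("yTrue must contain both classes", call. = FALSE)
  r <- rank(scores)                      # midranks for ties
  (sum(r[yTrue == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
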
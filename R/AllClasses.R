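#' @import methods
NULL

#' FingerprintSet: a labelled binary fingerprint matrix
#'
#' Central data container of the package: an `n_samples x n_bits` matrix of
#' 0/1 fingerprint bits together with a binary activity label per sample
#' (1 = active/toxic, 0 = inactive). Rows are molecules, columns are
#' fingerprint bits — the row-per-molecule layout conventional for
#' cheminformatics fingerprint containers.
#'
#' @slot bits integer or numeric matrix with entries in \{0,1\}; one row per
#'   molecule, one column per fingerprint bit.
#' @slot labels integer vector of 0/1 class labels, one per row of `bits`.
#' @slot fpType character scalar describing the fingerprint family
#'   (e.g. `"MACCS"`, `"ECFP4"`, `"synthetic"`).
#'
#' @seealso [FingerprintSet()] for the user-facing constructor,
#'   [fpMatrix()], [fpLabels()], [nBits()], [fpType()].
#' @name FingerprintSet-class
#' @rdname FingerprintSet-class
#' @exportClass FingerprintSet
setClass("FingerprintSet",
  representation(bits = "matrix", labels = "integer", fpType = "character"),
  prototype(bits = matrix(integer(0), 0, 0), labels = integer(0),
            fpType = "unknown"))

setValidity("FingerprintSet", function(object) {
  msg <- character(0)
  b <- object@bits
  if (length(b) && !all(b %in% c(0, 1)))
    msg <- c(msg, "all fingerprint entries must be 0 or 1")
  if (length(object@labels) != nrow(b))
    msg <- c(msg, "length(labels) must equal nrow(bits)")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(object@fpType) != 1L)
    msg <- c(msg, "fpType must be a single string")
  if (length(msg)) msg else TRUE
})

#' LIF neuron parameters
#'
#' Discrete-time leaky integrate-and-fire parameters. The continuous membrane
#' equation (an RC low-pass filter driven by an input current) is discretized
#' by forward Euler into `U_t = beta * V_{t-1} + I_t`; `beta` in (0,1) is the
#' per-step membrane decay and `threshold` the firing threshold. After a
#' spike the threshold value is subtracted from the membrane potential
#' (reset by subtraction); reset to zero is deliberately not offered.
#'
#' @slot beta numeric in (0,1); per-step membrane potential decay.
#' @slot threshold positive numeric; firing threshold (membrane units).
#' @slot resetMode character; only `"subtract"` is implemented.
#' @seealso [lifParams()], [lifStep()], [simulateConstantInput()]
#' @name LIFParams-class
#' @rdname LIFParams-class
#' @exportClass LIFParams
setClass("LIFParams",
  representation(beta = "numeric", threshold = "numeric",
                 resetMode = "character"),
  prototype(beta = 0.95, threshold = 1, resetMode = "subtract"))

setValidity("LIFParams", function(object) {
  msg <- character(0)
  if (length(object@beta) != 1L || !is.finite(object@beta) ||
      object@beta <= 0 || object@beta >= 1)
    msg <- c(msg, "beta must be a single value in (0, 1)")
  if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
      object@threshold <= 0)
    msg <- c(msg, "threshold must be a single positive value")
  if (!identical(object@resetMode, "subtract"))
    msg <- c(msg, "only resetMode = \"subtract\" is implemented")
  if (length(msg)) msg else TRUE
})

#' Surrogate-gradient parameters
#'
#' The spike nonlinearity is the Heaviside step in the forward pass; in the
#' backward pass its non-existent derivative is replaced by the derivative of
#' a logistic sigmoid `sigma(k * u)` of finite slope `k`.
#'
#' @slot slope positive numeric; sigmoid steepness `k`.
#' @seealso [surrogateParams()], [spikeFunction()], [surrogateGrad()]
#' @name SurrogateParams-class
#' @rdname SurrogateParams-class
#' @exportClass SurrogateParams
setClass("SurrogateParams",
  representation(slope = "numeric"),
  prototype(slope = 50))

setValidity("SurrogateParams", function(object) {
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    "slope must be a single positive value" else TRUE
})

#' Network architecture specification
#'
#' Shape and dynamics of the fully connected spiking classifier: an input
#' layer with one unit per fingerprint bit, one hidden layer of LIF neurons
#' and an output layer of exactly two LIF neurons whose spike counts over
#' `nSteps` simulation steps decide the class.
#'
#' @slot nInputs integer; number of fingerprint bits (166 MACCS, 1024 ECFP).
#' @slot nHidden integer; hidden LIF neurons.
#' @slot nOutputs integer; fixed at 2.
#' @slot nSteps integer >= 1; simulation steps per forward pass.
#' @slot lif [LIFParams-class] shared by hidden and output layers.
#' @slot surrogate [SurrogateParams-class] for the backward pass.
#' @seealso [networkSpec()], [initNetwork()], [snnForward()]
#' @name NetworkSpec-class
#' @rdname NetworkSpec-class
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(nInputs = "integer", nHidden = "integer",
                 nOutputs = "integer", nSteps = "integer",
                 lif = "LIFParams", surrogate = "SurrogateParams"),
  prototype(nInputs = 166L, nHidden = 1000L, nOutputs = 2L, nSteps = 25L))

setValidity("NetworkSpec", function(object) {
  msg <- character(0)
  if (object@nOutputs != 2L)
    msg <- c(msg, "nOutputs is fixed at 2 (two-neuron spike-count readout)")
  if (object@nInputs < 1L) msg <- c(msg, "nInputs must be >= 1")
  if (object@nHidden < 1L) msg <- c(msg, "nHidden must be >= 1")
  if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Repeated nested cross-validation summary
#'
#' Result container for [nestedCV()]: one row of `results` per repetition and
#' outer fold (balanced accuracy in percent, ROC AUC, and the winning
#' hyperparameter configuration), plus index bookkeeping sufficient to audit
#' that no outer-test sample ever entered its own inner hyperparameter
#' search.
#'
#' @slot results data.frame with columns `rep`, `fold`, `ba`, `auc` and the
#'   chosen hyperparameters.
#' @slot meanBA,stdBA numeric; mean and sd over repetitions of the
#'   per-repetition mean outer-fold balanced accuracy (percent).
#' @slot meanAUC,stdAUC numeric; same aggregation for AUC.
#' @slot bookkeeping list; per repetition x fold: `outerTest` indices,
#'   `innerTrain` indices actually used by the hyperparameter search and
#'   `outerTrain` indices used for the final refit.
#' @slot config list; folds, repeats, balancing mode and seeds of the run.
#' @seealso [nestedCV()], [cvResults()]
#' @name CVSummary-class
#' @rdname CVSummary-class
#' @exportClass CVSummary
setClass("CVSummary",
  representation(results = "data.frame", meanBA = "numeric",
                 stdBA = "numeric", meanAUC = "numeric", stdAUC = "numeric",
                 bookkeeping = "list", config = "list"))
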
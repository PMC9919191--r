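#' Construct LIF neuron parameters
#'
#' @param beta per-step membrane decay in (0, 1). The forward-Euler
#'   discretization of the RC membrane equation reduces the continuous time
#'   constant and input resistance to this single decay factor
#'   (`U_t = beta * V_{t-1} + I_t`); the input scale is absorbed by the
#'   synaptic weights.
#' @param threshold firing threshold, membrane-potential units (default 1;
#'   weights and `beta` absorb any overall scale).
#' @return a [LIFParams-class] object.
#' @examples
#' lifParams(beta = 0.8)
#' @export
lifParams <- function(beta = 0.95, threshold = 1) {
  new("LIFParams", beta = beta, threshold = threshold,
      resetMode = "subtract")
}

#' Construct surrogate-gradient parameters
#'
#' @param slope steepness `k` of the logistic sigmoid `sigma(k * u)` whose
#'   derivative replaces the Heaviside step's in the backward pass.
#' @return a [SurrogateParams-class] object.
#' @export
surrogateParams <- function(slope = 50) new("SurrogateParams", slope = slope)

#' One discrete LIF time step
#'
#' Advances a layer of LIF neurons by one step: the membrane first decays
#' and integrates the input current, `U = beta * V + I`; neurons whose
#' potential reaches the threshold fire a spike; firing neurons have the
#' threshold subtracted from their potential (reset by subtraction), so any
#' over-threshold residual is retained for the next step.
#'
#' @param state numeric vector of membrane potentials `V` (one per neuron).
#' @param inputCurrent numeric vector of input currents, same length.
#' @param params a [LIFParams-class].
#' @return list with `spikes` (0/1 vector) and `state` (updated potentials).
#' @examples
#' s <- lifStep(state = 0, inputCurrent = 1.5,
#'              params = lifParams(beta = 0.9, threshold = 1))
#' s$spikes  # 1: U = 1.5 crossed the threshold
#' s$state   # 0.5: reset by subtraction keeps the residual
#' @export
lifStep <- function(state, inputCurrent, params = lifParams()) {
  if (length(state) != length(inputCurrent))
    stop("state and inputCurrent lengths differ", call. = FALSE)
  if (!all(is.finite(state)) || !all(is.finite(inputCurrent)))
    stop("non-finite membrane potential or input current", call. = FALSE)
  u <- params@beta * state + inputCurrent
  spikes <- as.numeric(u >= params@threshold)
  list(spikes = spikes, state = u - spikes * params@threshold)
}

#' Simulate a single LIF neuron under constant input current
#'
#' Runs `nSteps` LIF updates from a resting potential of 0 with the same
#' input current at every step — the standard demonstration of leaky
#' integration: sub-threshold currents charge the membrane along
#' `V_t = I (1 - beta^t) / (1 - beta)` towards the `I / (1 - beta)`
#' asymptote, while supra-threshold currents produce regular firing.
#'
#' @param params a [LIFParams-class].
#' @param inputCurrent scalar current injected at every step.
#' @param nSteps number of steps (>= 1).
#' @return data.frame with columns `step`, `V` (potential after the step)
#'   and `spike` (0/1), suitable for direct CSV export.
#' @examples
#' tr <- simulateConstantInput(lifParams(beta = 0.9), 0.05, 20)
#' tail(tr, 3)
#' @export
simulateConstantInput <- function(params, inputCurrent, nSteps) {
  if (nSteps < 1) stop("nSteps must be >= 1", call. = FALSE)
  V <- numeric(nSteps); S <- numeric(nSteps)
  st <- 0
  for (t in seq_len(nSteps)) {
    r <- lifStep(st, inputCurrent, params)
    V[t] <- r$state; S[t] <- r$spikes; st <- r$state
  }
  data.frame(step = seq_len(nSteps), V = V, spike = S)
}

#' Spike nonlinearity with its surrogate derivative
#'
#' Forward value is exactly the Heaviside step of the centred potential
#' (1 iff `U - threshold >= 0`). Because the step's true derivative (a Dirac
#' delta) is useless for backpropagation, training uses the finite-slope
#' logistic surrogate: `d/du sigma(k u) = k sigma(k u) (1 - sigma(k u))`.
#' Both are returned so the forward pass stays binary while gradients flow.
#'
#' @param uMinusTheta numeric vector `U - threshold`.
#' @param surrogate a [SurrogateParams-class].
#' @return list with `spikes` (0/1 forward values) and `grad` (surrogate
#'   derivative evaluated at the same points).
#' @examples
#' spikeFunction(0, surrogateParams(slope = 50))$grad  # k/4 = 12.5
#' @export
spikeFunction <- function(uMinusTheta, surrogate = surrogateParams()) {
  if (!all(is.finite(uMinusTheta)))
    stop("non-finite input to spike function", call. = FALSE)
  list(spikes = as.numeric(uMinusTheta >= 0),
       grad = surrogateGrad(uMinusTheta, surrogate))
}

#' @rdname spikeFunction
#' @param u numeric vector at which to evaluate the surrogate derivative.
#' @export
surrogateGrad <- function(u, surrogate = surrogateParams()) {
  k <- surrogate@slope
  sg <- stats::plogis(k * u)
  k * sg * (1 - sg)
}
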
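---
title: "Spiking neural network QSAR screening: models and methods"
author: "SpikeScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking neural network QSAR screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpikeScreen)
```

## The problem and the idea

Quantitative structure–activity relationship (QSAR) screening asks whether a
molecule's structure predicts a biological outcome — here, binary toxicity
labels of the kind distributed with MoleculeNet benchmarks (ClinTox, Tox21
tasks, ToxCast, BBBP, SIDER). The standard featurization is a *molecular
fingerprint*: a fixed-length binary vector marking the presence or absence of
substructures, either the 166 keyed SMARTS patterns of the public MACCS set
or hashed circular environments (ECFP).

Spiking neural networks (SNNs) communicate in binary events, so a binary
fingerprint needs no encoding step at all: each bit is injected, unchanged,
as an input current into a layer of leaky integrate-and-fire (LIF) neurons
at every simulation step. This package implements that pipeline end to end:
chemistry in, spike counts out, evaluated the way a careful QSAR study is —
repeated nested cross-validation, balanced accuracy and ROC AUC on held-out
folds.

## The LIF neuron

The membrane of a LIF neuron is an RC low-pass filter driven by an input
current. Discretized by forward Euler, the continuous time constant and
input resistance collapse into a single per-step decay factor
$\beta \in (0,1)$ and the synaptic weights, giving the update used
everywhere in this package:

$$U_t = \beta V_{t-1} + I_t, \qquad
  S_t = H(U_t - \theta), \qquad
  V_t = U_t - \theta\, S_t,$$

where $H$ is the Heaviside step, $\theta$ the firing threshold, $S_t$ the
emitted spike and the last expression is *reset by subtraction*: a firing
neuron keeps its over-threshold residual rather than being clamped to rest.
Reset to zero is deliberately not implemented. Two closed forms pin the
implementation down exactly and are asserted in the tests: free decay
$V_t = \beta^t V_0$, and charging under constant sub-threshold current
$V_t = I\,(1-\beta^t)/(1-\beta)$.

The threshold is $\theta = 1$ by default. Its scale is not identifiable
separately from the weights and $\beta$, so fixing it costs no generality.

## Architecture and readout

The classifier is fully connected: one input unit per fingerprint bit, one
hidden LIF layer (width is a search parameter), and exactly two output LIF
neurons. The fingerprint is injected identically at each of $T$ steps
($T = 25$ by default — long enough for spike counts to be informative,
small enough for desk-scale runs; it is a configurable argument, not a
tuned quantity). The class decision is rate-coded: the sample goes to the
output neuron that fired more spikes over the $T$ steps, with exact ties
(including total silence) resolved deterministically to class 0. The
continuous score used for ROC curves is the positive neuron's share of the
total output spikes.

## Surrogate-gradient training

The Heaviside step has a Dirac-delta derivative, so the hard forward pass is
kept while the backward pass substitutes the derivative of a logistic
sigmoid of finite slope $k$:

$$\frac{\partial S}{\partial U} \approx k\,\sigma(k(U-\theta))\bigl(1-\sigma(k(U-\theta))\bigr),$$

with $k$ searched over $\{25, 50, 75\}$. The training objective is the
cross-entropy of the softmax over time-summed output spike counts — the
differentiable counterpart of the "more spikes wins" rule. Training runs
over shuffled mini-batches of 64 samples, with the optimizer menu
Adam/Adamax/SGO/Adagrad/Adadelta/AdamW/RMSProp, optional weight decay, and
optional gradient clipping to global L2 norm 1.

Three numerical choices deserve explanation:

* **Reset detachment.** The reset term $-\theta S_t$ depends on the spike,
  so the full chain rule contributes a factor $1 - \theta\,\partial S/\partial U$
  to $\partial V_t / \partial U_t$. At $k = 50$ that factor reaches $-11.5$
  and compounds across time steps into astronomically exploding gradients.
  The training path therefore treats the reset as a constant in the backward
  pass (the convention of surrogate-gradient SNN frameworks); the exact
  chain rule remains available (`snnGradient(..., resetGrad = TRUE)`) and is
  what the finite-difference validation exercises.

* **Gradient validation.** Because the hard forward pass is discontinuous,
  gradients are checked against a *fully smoothed* reference network in
  which every Heaviside is replaced by $\sigma(k(U-\theta))$. In that mode
  the package's backward pass is the exact gradient and matches central
  finite differences to better than $10^{-4}$ relative error — the same
  code path that trains the hard network, evaluated on smooth activations.

* **Silent-collapse restarts.** The spike-count loss has degenerate
  attractors: an output neuron that falls silent receives essentially no
  surrogate gradient (its membrane potential sits far from threshold, where
  $\partial S/\partial U \approx k e^{-k|U-\theta|}$), can never win the
  spike-count vote against its live sibling, and therefore pins every
  prediction to a single class with no way back; if both outputs die the
  loss simply freezes at $\ln 2$. The opposite extreme is no better — an
  over-driven network saturates and also loses gradient — which is why
  simply scaling up the initialization makes matters worse, not better.
  Training therefore probes the finished network on its training
  fingerprints and, if either output neuron never spiked, restarts from a
  fresh initialization whose seed is derived deterministically from the
  master seed (up to five times by default, like `nstart` in k-means, with
  degenerate attempts abandoned at the first epoch that exposes them).
  Runs remain bit-reproducible.

Weight initialization is scaled-uniform per layer,
$U(-1/\sqrt{f}, 1/\sqrt{f})$ with $f$ the fan-in, drawn from the seed.

## Chemistry front end

SMILES tables are read in the MoleculeNet CSV layout (one SMILES column, one
binary label column). Each molecule is normalized and canonicalized through
the OpenBabel toolkit (via ChemmineOB); the operation is idempotent and
unparseable strings are dropped with a logged report rather than aborting a
load. MACCS fingerprints use OpenBabel's SMARTS implementation of the 166
public keys, whose key numbering matches the RDKit implementation (verified
bit-for-bit on reference molecules; rare single-key differences reflect
SMARTS dialect choices). ECFP fingerprints of radius $r$ come from
OpenBabel's hashed `ECFP2r` generator and are OR-folded from the native
4096 bits to the requested length (1024 by default) — the standard folding
construction, so bit positions are not comparable across toolkits even
though lengths and densities are.

Structural homogeneity of a dataset is measured by the mean Jaccard–Tanimoto
index $|a \wedge b|/|a \vee b|$ over all unordered pairs. Two all-zero
fingerprints have an indeterminate 0/0 index; the package defines it as 0
with a warning, since two featureless vectors share no substructure
evidence.

## Class balancing and the evaluation protocol

Toxicity benchmarks are imbalanced (e.g. 1366 negatives against 112
positives). Balance is restored by oversampling the minority class —
uniform draws with replacement under an explicit seed — until both classes
match the majority count.

Model quality is estimated by repeated nested cross-validation: an inner
random search (uniform draws from the hyperparameter grid, scored by mean
inner-fold balanced accuracy, ties to the earlier draw) selects a
configuration using only the outer-training portion; the winner is refit on
that whole portion and scored on the outer fold; the whole procedure is
repeated (10 times by default) with reshuffled folds. Defaults are 5 outer
and 3 inner folds — the protocol fixes the nesting, not the fold counts, and
these keep desk-scale runtime sensible. Reported summaries are the mean and
standard deviation over repetitions of the per-repetition mean.

Balancing interacts with cross-validation in a way worth being explicit
about. The historical protocol (`balance = "paper"`) equalizes counts once,
before folds are drawn, so duplicated minority molecules can land on both
sides of a fold boundary and leak information; the package reproduces that
mode faithfully and its bookkeeping lets the straddling be audited. The
recommended mode (`balance = "safe"`) oversamples inside each training
portion only, so no test fold ever contains a duplicate of a training
record. Both modes are asserted by index bookkeeping in the tests; in no
mode does an outer-test sample ever enter its own inner search.

The hyperparameter grid defaults follow the published search ranges for
this architecture: hidden width 500–2000 (including the intermediate levels
that appear in ranked result tables), six equally spaced decays on
$[0.6, 0.95]$, slopes $\{25,50,75\}$, fifteen learning-rate levels on
$[10^{-5}, 0.5]$ (the commonly selected values padded log-uniformly),
weight decay $\{0\}$ plus four log-spaced levels on $[10^{-4}, 0.05]$,
clipping on/off, and epochs $\{10, 25, 50, 100\}$. Every axis can be
overridden.

## The synthetic benchmark

Because the real benchmarks require downloads and multi-hour searches, the
package ships a generator of fingerprint-like data with a planted signal:
each bit is an independent Bernoulli draw at a background rate (0.1 by
default, giving sparse vectors of realistic density), except for a block of
informative bits that activate at a higher rate (0.6) in positive samples
only. Defaults — 500 molecules per class, 166 bits, 30 informative — define
the "easy" task used by the self-tests: under the best published
configuration for this architecture (1000 hidden neurons, $\beta = 0.95$,
slope 50, Adamax at $2\times10^{-3}$, 25 epochs) it is learned to ≥ 90%
held-out balanced accuracy, while the null variant (informative rate equal
to background) stays at chance.

What the generator does *not* emulate: correlated bits (real substructures
co-occur), key-specific marginal frequencies, and any notion of chemical
similarity structure beyond what independent Bernoulli bits induce. Passing
the synthetic checks therefore demonstrates that the learning machinery,
balancing and protocol bookkeeping are correct — not that any particular
accuracy will transfer to a real benchmark.

```{r example, eval = FALSE}
fps <- syntheticFingerprints()          # the easy task
cv <- nestedCV(fps, hyperGrid(nHidden = c(500L, 1000L), epochs = 25L),
               nRepeats = 2, nDraws = 5, seed = 1, balance = "safe")
cv
```

## Problem sizes used by the self-tests

The test-suite and the acceptance script run everything at sizes a single
CPU handles in minutes, chosen as the package's own benchmark conditions:
the learnability check trains the full 166–1000–2 network on 800 samples
for 25 epochs; the null control uses 5 seeds of a 400-sample task with a
100-neuron network; the nested-CV audit runs 2 repetitions of 3×2 folds on
200–220 samples with reduced widths and epoch counts. Fold counts, repeat
counts and widths in those runs are arguments, not changed defaults.

## Known limitations

* Only single-task binary classification; multi-label Tox21-style loading
  is out of scope (one task column at a time).
* Standardization is OpenBabel canonicalization; it does not reproduce
  every MolVS normalization rule (charge parenting, tautomer canonning).
* No scaffold splitting; random stratified folds only.
* The spike-count loss can collapse to silence on hard or tiny tasks; the
  restart guard recovers the common case but a network that predicts a
  single class while still spiking is left to the hyperparameter search to
  reject.
* No conductance-based (second-order) neurons, no refractory period beyond
  reset-by-subtraction, no temporal input codes, no neuromorphic backends.
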
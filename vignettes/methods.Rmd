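---
title: "Methods: model equations, conventions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model equations, conventions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drosdecide)
```

This vignette records the mathematical content of the simulator and, for
every constant that is not taken directly from the published parameter
set, how its default value was chosen and then frozen. Nothing here is a
tuning knob: the values below are fixed and all results in the test suite
and the acceptance script are produced with them.

## Neuron model

Every neuron is a leaky integrate-and-fire (LIF) point neuron,

$$\tau_m \frac{dv}{dt} = -v + R\,I(t),$$

with $\tau_m = 20$ ms, $R = 1$, threshold $v_{th} = 0.1$ and reset
$v_r = 0$, integrated with the forward Euler scheme. The published
description uses a 1 ms step; this implementation integrates at
$dt = 0.1$ ms because at 1 ms a constant suprathreshold current makes the
Euler trajectory overshoot the exact solution
$v(t) = R I\,(1 - e^{-t/\tau_m})$ by enough to shift first-spike
latencies by a full step, and first-spike order is the behavioural
readout. At $dt = 0.1$ ms the Euler latency for a constant input matches
the closed-form latency

$$t^\ast = \tau_m \ln \frac{I}{I - v_{th}}$$

to well under one step (asserted in the test suite). All protocol
durations are expressed in ms and are unchanged.

## Synapses and the charge convention

A spike arriving through a synapse of weight $w$ delivers a rectangular
current pulse such that the total charge deposited on the target is
$w/\tau_m$: a single spike through $w = 10$ (the weight ceiling) lifts a
resting neuron by $0.5$, five times threshold, while $w = 2$ lifts it by
exactly $v_{th}$. This convention makes the saturated memory weights
single-spike suprathreshold and the fixed relays exactly threshold-strong,
which is what the published circuit diagrams require qualitatively
(saturated memories decide in one volley; relays need temporal summation
or a strong input to fire the next layer).

Each synapse carries a 0/1 connectivity mask. Masked-out entries transmit
no charge and are invisible to plasticity: the visual-to-CC and
visual-to-KC relays are one-to-one (diagonal masks, with the colour
channels of each eye wired to their own relay), and the mutual-inhibition
pairs are off-diagonal.

## Plasticity

Spike-timing-dependent plasticity uses the standard exponential windows
with $A^+ = 0.925$, $A^- = 0.9$, $\tau^+ = \tau^- = 20$ ms, and
nearest-neighbour pair-once matching: each spike is paired with at most
one partner spike.

The update is applied to the synaptic **efficacy**, signed by the synapse
type: for an excitatory synapse a pre-before-post pairing increases the
weight, while for an inhibitory synapse the same pairing *releases* the
inhibition (drives the magnitude toward zero). This signed-efficacy
convention is what lets the dopamine window weaken the APL clamp on the
salient cue's Kenyon cells: a magnitude-increasing rule on inhibitory
synapses is homeostatic and inverts the gain-gating (the salient cue would
be suppressed hardest). Weights are clipped to $[0, 10]$.

Punishment is a phasic dopamine trace

$$DA(t) = DA_{peak}\, e^{-(t - t_{pun})/\tau_t}, \qquad DA_{peak} = 10,\ \tau_t = 2\ \mathrm{ms},$$

which, while above $1\%$ of its peak, depresses every memory weight from a
currently active input channel to the chosen behaviour by
$DA(t)\,dt/\tau_t$ per step, for a cumulative depression of
$\approx DA_{peak}$ independent of $dt$.

## Architecture

Populations, in order: visual input ($n$ channels), CC input layer ($n$),
CC output (2, mutual inhibition), Kenyon cells ($n$), MBONs (2, mutual
inhibition), APL (2), DA (1). Two plastic memory matrices — CC input
$\to$ CC output and KC $\to$ MBON — are kept identical during training
(the two pathways experience the same conditioning). The gating loop of
the choice phase adds fixed KC $\to$ APL, DA $\dashv$ APL and a fixed
DA $\to$ MBON synapse, plus plastic APL $\dashv$ KC and APL $\dashv$ DA
inhibition.

The first spike among the two output neurons (CC output for the linear
pathway, MBONs for the nonlinear one) is the behavioural choice. Mutual
inhibition plus the single-spike-suprathreshold memory convention makes
this a winner-take-all readout; exact ties are broken at random.

## Protocols

* **Training**: each pattern is presented for 1000 ms; wrong choices
  trigger the dopamine trace; STDP potentiates the correct pairing. An
  undecided episode is resolved by a uniformly random exploratory choice,
  realised as an output spike at episode end so that STDP and punishment
  apply to it as usual. A punished episode ends with the *avoidance
  response*: the agent performs the alternative behaviour, and STDP pairs
  that motor spike with the still-active inputs, potentiating the
  alternative memory column. This is the mechanism that bounds learning at
  one punished episode per pattern per contingency, including after
  contingency reversal.
* **Choice**: 2000 ms split into 20 sub-trials of 100 ms with full state
  reset in between; each sub-trial's first output spike is one choice;
  $PI = (t_1 - t_2)/(t_1 + t_2)$. Memory matrices are frozen; only the
  gating synapses remain plastic. Under the nonlinear pathway the DA
  neuron receives an external drive of 2 for the first 100 ms.
* **Conflict monitor**: with the active (nonzero) filtered channels
  $A$, the monitor computes $s_b = \sum_{i \in A} W_{ib}$ and routes to
  the linear pathway when $|s_1 - s_2| > 3$; otherwise to the nonlinear
  one. A stimulus with at most one live channel is never in conflict and
  always routes linear — a single cue cannot conflict with itself, and
  the fast pathway suffices whatever the memory sums are.

## Calibration (chosen once, then frozen)

* **`input_gain = 0.16`** converts saliency (colour channels scale as
  $10 \cdot CI$) into input current. It was calibrated — as the model
  description prescribes — so that the colour-discrimination turning
  point falls at $CI = 0.1$: below it the colour channels never drive the
  relays above threshold within an episode, so no colour memory forms;
  at and above it conditioning is perfect.
* **`relay = 2`, `mutual = 2`**: exactly threshold-strong relays and
  mutual inhibition strong enough that the loser of the first volley
  cannot recover within a sub-trial.
* **`kc_apl = 1.1`**: at 1.0 the KC $\to$ APL drive is too weak for the
  reciprocal loop to amplify a two-cue difference (the nonlinear count
  difference equals the linear pass-through); at 1.1 the iceberg effect
  emerges and the amplification holds across seeds. Frozen after that
  one verification.
* **`apl_kc = 1.5`, `da_apl = 3`, `apl_da = 1.5`**: APL inhibition strong
  enough to clamp sub-saturation KC drive, and DA drive strong enough to
  silence APL throughout its window.
* **`da_mbon = 2`, non-plastic**: while the DA neuron fires it injects a
  threshold-strong tie into both MBONs, so sub-trials inside an
  over-long dopamine window degenerate toward coin flips. This is the
  mechanism behind the dopamine-duration dependence: an intermediate
  window (around 70–100 ms) gives better multi-cue choice quality than a
  very long one.
* **Phase-jittered gain gating**: `gain_gate()` repeats each measurement
  (default 30 times) from random sub-threshold initial membrane
  potentials and sums the counts. A fully synchronised start phase-locks
  the Kenyon cells to the APL oscillation and produces resonance
  artefacts in which a weaker cue can outlast a stronger one; the jitter
  restores monotonicity of expected counts in saliency. The repetition
  count was raised from 10 to 30 after observing that at 10 the
  sampling noise of the four-cue tasks occasionally reordered adjacent
  variants.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from the installed package and a
single `--seed`, the conditioning, threshold, conflict-sweep and
pathway-comparison targets, and writes them as bare numbers with
`jsonlite::write_json(..., auto_unbox = TRUE, digits = NA)`. The
acceptance test file (`tests/testthat/test-acceptance.R`) asserts the
same claims as tolerated hypotheses over multiple seeds.
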
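---
title: "Hebbian learning of sensorimotor inverse models: methods and design"
author: "mirrorloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hebbian learning of sensorimotor inverse models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`mirrorloop` simulates a closed sensorimotor loop in which a motor area
(think HVC or LMAN in the songbird) drives behaviour, and delayed sensory
feedback returns to the motor area through learnable synapses.  The loop is
linear:

* **Feedback**: the sensory population response is `a(t) = Q m(t - tau)`,
  where `m(t)` is the motor rate vector, `Q` the (unknown, composite)
  motor-to-sensory map and `tau = tauM + tauA` the loop delay — the time
  from motor command to behaviour plus the time from behaviour to sensory
  response.  A single linear `Q` stands in for the highly nonlinear
  motor-to-sound-to-ear pathway; the justification is dimensional: cortical
  populations vastly outnumber the effective degrees of freedom of the
  periphery, so a high-dimensional linear map can approximate the composite
  low-dimensional nonlinear one.

* **Learning** (`learningUpdate`, `runLearning`): sensory-to-motor weights
  `V` change according to an eligibility-weighted Hebbian rule with
  equal-time heterosynaptic depression,

  `dV_ij = [ integral e(s) m_i(t - s) ds ] a_j(t)  -  mhat_i(t) a_j(t)`,

  where `mhat(t) = V a(t)` is the *silently postdicted* motor activity.
  The eligibility trace `e(s)` is a monotonically decaying postsynaptic
  gain that makes synapses onto a recently active motor neuron modifiable;
  it must bridge the loop delay (`e(tau)` well above zero).  During
  learning the gate is closed: `V` never drives motor firing (otherwise
  the loop would feed back on itself and bias the very correlations being
  learned — and produce cyclic, stutter-like output).  During playback /
  sleep the gate opens and the sensory-evoked motor response is
  `m^a(t) = V a(t)`.

* **Steady states**: for *variable* (uncorrelated, explorative) motor codes
  the learning fixed point is the **causal inverse**
  `V = e(tau) t0 Q^-1` — each sensory pattern maps back onto its motor
  cause (`predictedCausalInverse`).  For *stereotyped* traveling-pulse
  codes it is approximately the **predictive inverse**
  `V ~ e(0) t0 H^tau Q^-1`, the inverse composed with a shifter that
  advances motor activity by one loop delay
  (`predictedPredictiveInverse`, `shifterFromCode`).  `t0` is the width of
  the motor cross-correlation peak, realised here as the burst width.

The rule is exact gradient descent on the eligibility-weighted postdiction
error `E(t) = 1/2 sum_i int [m_i(t-s) - (V a(t))_i]^2 e(s) ds` **when the
trace has unit mass** (`traceMass(trace) == 1`).  For a general trace the
depression term of the gradient carries the factor `int e(s) ds` while the
rule as implemented uses weight 1; the tests assert both the exact
equivalence for unit-mass kernels and the mass factor for others.

## What the generators emulate

`generateVariableCode` realises the white-noise idealisation of an
explorative code (LMAN-like): every neuron emits one square burst of width
`t0 = 10` ms and unit amplitude at a uniformly random onset per rendition.
The default rendition is a long (8 s) babbling bout, and that choice is
load-bearing: the causal closed form assumes vanishing cross-correlations,
and with bursts of density `rho` per ms the learned weights acquire a
rank-one bias along the population-mean direction of relative size about
`N rho int e(s) ds / e(tau)` (~3% under the defaults).  Denser codes —
shorter bouts or more bursts — degrade the match to `e(tau) t0 Q^-1`
noticeably before anything else breaks.

`generateStereotypedCode` realises an HVC-like sequence: neuron i bursts at
onset `(i-1) * lag` in every rendition, optionally repeated cyclically
(`cycles > 1`) so the sequence wraps around as in continuously repeated
song.  Renditions are separated by silent gaps of at least
`tau + eligibility support` so that no correlations straddle rendition
boundaries.

What the generators do **not** emulate: spiking (everything is a rate),
trial-to-trial amplitude variability, multi-burst HVC-like patterns,
behavioural nonlinearity, or sensory noise.  Tests passing on these codes
therefore show that the learning dynamics follow the theory under its own
idealisations, not that real recordings would.

## The exact steady state is an eligibility comb

For a pure traveling pulse the exact fixed point of the rule (computable in
closed form from the data as
`V* = <F a'> <a a'>^+`, exposed as `steadyStateWeights`) is richer than the
single-shifter formula: writing `M = V* Q`,

`M_ij ~ t0 * e(tau - (i - j) lag)`

for every inter-burst diagonal with `tau - (i-j) lag >= -t0`, i.e. weight
mass sits on *all* sequence offsets the eligibility window reaches, not
only on the `tau`-shifter.  Two consequences matter throughout the
package:

1. **The zero-lag tooth is halved.**  The correlation triangle of a burst
   with itself straddles `s = 0`, but eligibility is one-sided
   (`e(s) = 0` for `s < 0`), so the tooth at zero lag integrates only half
   its mass (about `0.5 e(0) t0` for traces much slower than `t0`).
2. **The single-shifter form is a steep-trace approximation.**  It becomes
   accurate only when `e(lag) << e(0)` — the trace must decay substantially
   within one inter-burst interval.  With the package default
   (`decayTime = 2 tau = 80` ms, chosen so that `e(tau)/e(0) = 0.61` is
   comfortably "eligible at the loop delay") and `lag = 20` ms, the
   neighbouring teeth carry 0.78 and 0.61 of the dominant one, and the
   exact fixed point differs from `e(0) t0 H Q^-1` by more than 100%
   relative Frobenius norm.  The online learner is therefore verified
   against the exact comb (`steadyStateWeights`, agreement to <3%), while
   the single-shifter comparison is reported as what it is: an
   approximation whose error the acceptance suite measures honestly.

The same comb shapes the mirroring experiment.  The motor-vs-playback
cross-correlogram of a stereotyped code samples the eligibility at lags
`tau - d * lag`; with a shallow trace the `e(lag)` tooth beats the halved
`e(0)` tooth, so the measured mirroring offset sits at `+lag` (20 ms here)
rather than 0.  Offsets collapse to ~0 once `e(lag) < e(0)/2`, i.e.
`decayTime < lag / ln 2` (about 29 ms at `lag = 20`); the bundled
`predictive_demo.yaml` uses `decayTime = 20` ms to demonstrate that regime,
and a property test sweeps it explicitly.  Either way the offset dichotomy
against the causal case (offset `= tau` exactly) survives, which is the
experimentally decisive signature.

## Mirroring measurements

`mirroringOffset` reports, per neuron, the lag of peak Pearson correlation
between motor activity and playback response (`m^a = V a`, gate open,
stimulus = the sensory stream of the final learning epoch).  Ties break
towards the smallest |lag|, then the negative lag.  An optional shuffle
null (playback circularly shifted within renditions, default 100 draws,
peak must clear the 95th percentile) flags flat correlograms.

Peak *amplitudes* are compared through covariance gains — peak raw
cross-covariance divided by the motor auto-covariance peak — rather than
Pearson coefficients: a correlation coefficient is scale invariant, so the
eligibility amplitude cancels out of it, whereas the gain of a converged
variable-code run is `e(tau) t0` and of a stereotyped run about
`e(0) t0` (modulo the comb effects above).  `peakRatio` forms the
variable/stereotyped ratio of mean gains, which tracks `e(tau)/e(0)`:
steeper traces weaken variable-code mirroring.  The ratio is monotone in
trace steepness; its absolute agreement with `e(tau)/e(0)` is limited to
~20-35% by the half-tooth and smoothing effects, and the acceptance suite
reports the measured discrepancy rather than hiding it.

## Numerical choices

* Time is a uniform grid, `dt = 1` ms by default; all delays, lags and
  widths must be integer multiples of `dt` (validated up front).
* `discretizeTrace` uses the rectangle rule `kernel[k] = e(k dt) dt`,
  truncated at 5 decay times for the exponential (<1% mass lost).
* The learning step is online per bin, scaled by `learningRate * dt`.
  When no rate is given, a calibration pass sets
  `eta = rateScale / lambda_max(sum_t a a' dt)` over one epoch, i.e. the
  leading sensory-correlation mode contracts by `rateScale` per epoch
  (default 0.5; the recovery experiments use 1.0).  The slowest mode
  converges at a rate smaller by `cond(Q)^2`, which is why
  `randomInvertibleMap` caps the condition number at 5 by default and why
  recovery runs use ~150 epochs.
* Fresh-rendition learning is stochastic approximation; the returned
  weights are the average of per-epoch snapshots over the final `tailFrac`
  (default 0.3) of epochs, which suppresses the gradient noise without
  moving the fixed point.
* Convergence is declared when the net weight change of an epoch drops
  below `convergenceTol` relative to `||V||`; divergence (rate too large)
  raises an error when `||V||` exceeds 1000x the predicted causal
  inverse's norm.
* Non-square `Q` uses the Moore-Penrose pseudo-inverse; learning from
  `V0 = 0` keeps each weight row inside the image of `Q`, which is the
  model's account of selectivity for the bird's own song: sensory patterns
  orthogonal to everything the bird ever produced map to (numerically)
  nothing.
* `burst width vs trace`: closed forms assume `t0` small relative to the
  decay time; a warning is emitted when `t0 > 0.15 decayTime`.

## Problem sizes

The recovery experiments run 4 motor / 4 sensory neurons, `tau = 40` ms
(25 motor + 15 sensory), 150 epochs x 40 renditions (6000 renditions) for
the variable code and 600 deterministic epochs for the stereotyped code;
the mirroring dichotomy uses 10 seeded replicates at 40 x 20 renditions,
and the steepness sweep 4 trace decays (160/80/40/20 ms) under one fixed
`Q`.  These sizes put the stochastic recovery error near 4% — comfortably
inside the 10% band the closed forms are good for — and run in a couple of
minutes on one CPU.

## The imitation demo

`abcdDemo` realises the four-syllable repertoire A-D as one-hot motor
patterns.  Trained on variable exploration, the learned causal inverse
imitates any resequencing of the repertoire (`ABDB -> ABDB`, open loop).
Trained on the repeated cycle `ABCD` with inter-syllable lag equal to
`tau`, the predictive inverse maps each percept to its training successor;
seeded with the percept `A`, its own feedback then locks production into
repetitions of the shifted cycle `BCDA`, regardless of the intended target
— the open-loop slot-by-slot mapping of `ABDB` is `BCAC`, and both are
reported.  The demo uses a trace decay of 30 ms (< `tau / ln 2`): with a
shallower trace the halved successor tooth loses to the `e(tau)` self
tooth and the percept-to-successor mapping — the premise of the
demonstration — does not materialise.

## The binary mirroring model

`binaryMirrorChannel` is the two-state abstraction: binary motor state `M`
(prior 1/2) and binary detection `S` of one sensory feature, coupled by
`p(S=1|M=1)` and `p(S=1|M=0)`, with independent symmetric flip noise on
each variable.  Everything is computed by exact enumeration;
`monteCarloCorrelation` is the sampling cross-check.

* *Perfect tuning* is realised as an unbiased deterministic detector,
  `p(S=1|M=0) = 1 - p(S=1|M=1)`; then `corr(M, S)` equals the tuning
  difference exactly.  (For a biased detector the identity picks up a
  `sqrt(q(1-q))` marginal factor — the unbiased channel is the one for
  which the clean statement holds.)
* *Equal intrinsic noise*: a plain `corr(M, S)` under symmetric flips
  scales *linearly* with the tuning difference — noise multiplies in
  `(1-2nu)^2` but cannot change the exponent, because Pearson
  normalisation is scale invariant.  The squared-difference law emerges
  from the two-stage pathway that mirroring actually takes:
  `mirroringCoefficient` learns a Hebbian readout weight
  `w = Cov(M, S)` from the noisy joint and drives a stochastic binary
  response `R` with `p(R=1|S) = 1/2 + gain * w * (S - E S)` in a fresh
  episode.  The tuning difference then enters twice (once via `w`, once
  via the replayed correlation) while the response variance is pinned at
  1/4 by the intrinsic noise, giving
  `corr(M, R) = 4 gain w^2 ∝ (p1 - p0)^2` — exactly, so the log-log slope
  against the squared difference is 1.  Noise attenuates it by
  `(1-2nu)^4`.

## Known limitations

* Everything is linear and rate-based; the nonlinear and spiking
  extensions the framework hints at are out of scope.
* The single-shifter predictive closed form, the near-zero predictive
  mirroring offset and the `e(tau)/e(0)` peak-ratio value are steep-trace
  idealisations; under the package's default shallow trace the simulator
  reproduces the *structure* (comb fixed point, offset dichotomy, ratio
  monotonicity) but deviates quantitatively in the ways spelled out above,
  and the acceptance outputs report those deviations as measured.
* Heterosynaptic depression is the specific subtractive term of the rule;
  other competitive normalisations are not implemented.
* Gating is a boolean switch, not a mechanistic model of neuromodulatory
  or thalamic gating.
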
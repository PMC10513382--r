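---
title: "Belief states, TD learning, and recurrent value networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief states, TD learning, and recurrent value networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beliefrnn)
```

## The scientific problem

In Pavlovian trace conditioning, an animal learns that an odor cue predicts
a reward after a delay. When the delay is variable, or the reward is
sometimes withheld, the state of the world that matters for prediction —
"how long ago was the odor, and is a reward still coming?" — is *hidden*:
the animal observes only the cue and the reward. The normative solution is
to track a **belief state**, the Bayesian posterior over hidden states given
the observation history, and to learn values on top of it by temporal
difference (TD) learning. The alternative this package studies is a
**recurrent value network**: a gated recurrent unit (GRU) whose hidden state
feeds a linear value readout, trained end-to-end by TD learning from the raw
two-channel observation stream. The package provides the tasks, the exact
belief computation, the TD/LSTD machinery, the network training, and a
battery of analyses that quantify how belief-like a learned representation
is.

## The tasks

Time is discretised into 200-ms bins. Every trial is
`[ITI nulls][odor][ISI − 1 nulls][reward]`, with the intertrial interval
(ITI) equal to 10 bins plus a geometric draw with parameter 1/8 (mean 17).

* **Variable-delay tasks** (`starkweather1`, `starkweather2`): the
  interstimulus interval (ISI) is drawn from a Gaussian with mean 10 bins
  and sd 2.5, evaluated at the integer support 6–14 and renormalised. We
  read "discretised Gaussian" as density evaluation at the support points
  rather than bin integration; at this sd the two differ negligibly, but it
  is an assumption. In variant 2 the reward is omitted with probability
  0.1, i.i.d. across trials (the omission law is not further specified, so
  independent Bernoulli draws are assumed).
* **Reward-block task** (`babayan`): the ISI is uniform on {9, 10, 11} and
  the nonzero reward magnitude is 1 or 10 depending on a hidden block
  identity resampled uniformly every 5 trials. Probe sessions add blocks
  with intermediate magnitudes {2, 4, 6, 8} in the published proportions
  (39 + 39 standard blocks, 3 of each intermediate size, 90 blocks total,
  so standard rewards make up about 90% of trials).

The observation at each bin is `o_t = [c_t, r_t]`: a binary cue channel and
a reward channel carrying magnitude. The generator also emits the true
hidden microstate sequence (below), which the analyses use as ground truth.

## Microstates and exact beliefs

Each task is formalised as a Markov chain over time-indexed *microstates*,
which converts the semi-Markov trial structure (variable dwell times) into
a Markov one. For the variable-delay tasks, states 1–14 are ISI microstates
and 15–25 are ITI microstates (10 minimum-delay states plus one recurrent
geometric state): `K = 25`. The block task uses one 22-state copy per block
(11 ISI + 11 ITI), concatenated to a 44-dimensional representation.
Observations are emitted on transitions; the reward hazard at ISI step `t`
is `h_t = p_t / (1 − F_t)` from the delay distribution, so the last
possible reward time has hazard 1. Reward-omission trials route the odor
transition directly from the terminal ITI state to the first ITI
microstate — the hidden state never enters the ISI on those trials.

Beliefs follow the forward recursion
`b_t(k) ∝ Σ_j O_o(k, j) T(k, j) b_{t−1}(j)`, renormalised each step, with
the normaliser retained for diagnostics. Numerical choices:

* **Initial belief**: one-hot at the terminal ITI state, which is the
  null-input fixed point of the recursion. Sessions begin in an ITI, so
  this is the natural starting point; it is a convention, not a task fact.
* **Underflow**: in the no-omission task, a null observation more than 14
  steps after an odor has zero likelihood — the posterior is genuinely
  undefined. When the per-step normaliser falls below 1e-12 the belief is
  reset to the ITI fixed point and the step is flagged (`underflow =
  "hold"` keeps the previous belief instead). This choice matters only for
  counterfactual omission probes of the no-omission task.
* **Block posterior** (`babayan`): the probability of the small-reward
  block is a function of the most recent nonzero reward only,
  `f(r) = φ(r; 1, σ) / (φ(r; 1, σ) + φ(r; 10, σ))` with `σ = 0.001`,
  computed on the log scale so the near-degenerate likelihoods are exact
  (crossing point 5.5). It starts at 1/2 and is held between rewards; it is
  deliberately *not* a full Bayesian filter over block history, so belief
  performance on each block's first trial is not an upper bound and the
  decoding analysis excludes those trials.

## Value learning

Values are linear readouts `V_t = w' z_t + w0` of a representation `z_t`
(beliefs or GRU activity), with discount `γ = 0.93` per bin. Rewards ride
on observation rows, and observations occur on transitions, so the TD error
of the transition out of step `t` is `δ_t = r_{t+1} + γ V_{t+1} − V_t`.
This alignment is what makes the reward-step prediction error a genuine
surprise signal (the value at the reward step has already seen the reward).
LSTD solves for the weights in closed form; sums never cross episode or
session boundaries, and a constant feature carries the intercept. Beliefs
plus an intercept are exactly collinear (rows sum to one), so the LSTD
system is rank-deficient by construction there; a documented ridge of 1e-8
on the diagonal handles it, with a warning. For comparability, *every*
model's value weights are re-fit by LSTD at analysis time, including
networks that learned their own readout during training.

## The recurrent value models

The GRU follows the standard gated update (reset gate inside the
candidate's recurrent term; update gate interpolates old state and
candidate) — gate conventions differ across published variants, so the
compiled implementation is pinned against an independent R reference and a
finite-difference gradient check. Three model kinds share the class:

* **Value RNN** (`type = "trained"`): all parameters initialised uniform on
  `(−1/√H, 1/√H)` and trained by semi-gradient TD — the bootstrapped target
  `r_{t+1} + γ V_{t+1}` is treated as a constant, and the squared error is
  backpropagated through time over whole episodes (20 concatenated trials;
  50 for the block task), hidden state reset to zero at each episode start.
  Adam, learning rate 0.003, batches of 12 episodes in shuffled order, at
  most 150 epochs over a 10,000-trial session, stopping early after 4
  consecutive epoch-loss increases. The batch loss is the mean over all
  (step, episode) pairs; the protocol does not pin sum vs mean, and the
  choice only rescales the learning rate. No hyperparameter search was
  performed. Adam's secondary constants are the usual 0.9/0.999/1e-8.
* **Untrained RNN** (`type = "untrained"`): the same initialisation with no
  training — the reservoir baseline.
* **Value ESN** (`type = "esn"`): echo-state initialisation — each of the
  three H×H recurrent gate blocks an independent random orthogonal matrix
  scaled by a gain, zero biases, input weights uniform with bound
  `√(6/(2+H))` — with the cell frozen so only the readout is learned.
  Applying the orthogonal-gain scheme per gate block (rather than to the
  stacked 3H×H matrix) is an interpretation; it gives every block singular
  values exactly equal to the gain.

Training is deterministic given `(seed, config)`: the seed controls
initialisation, the training session, and batch shuffling, and the
compiled gradient is exact (it matches the per-episode path to machine
precision), so replicate runs are bit-identical.

## Quantifying belief-likeness

Because GRU activity is a deterministic function of its inputs, all
regression and decoding analyses first inject Gaussian noise scaled per
unit to a fixed signal-to-noise ratio, `SNR = −20·log10(g)` dB (26 dB at
the default `g = 0.05`). Noise is applied to network representations only
— never to beliefs — and only for regression/decoding, not for value
fitting.

* **Belief regression**: multivariate linear regression of beliefs on
  activity, fit on one 1,000-trial session, scored on another as the
  *pooled* variance explained (one scalar across all belief dimensions,
  not per-dimension averages). The statistic can be negative for bad fits.
* **State decoding**: multinomial logistic regression of true microstates
  from standardised activity (statistics from the fit split only), with a
  quadratic penalty at inverse strength 1 applied to the summed loss
  (`nnet::multinom` with `decay = 1/2` stands behind this surface; its
  penalty also covers the intercepts, which is immaterial at these sample
  sizes). Beliefs themselves, scored as probabilities, are the ceiling on
  held-out log-likelihood.
* **Dynamics**: null-input fixed points are found by iterating the map
  from states sampled just after odor/reward observations until the
  consecutive-step squared change falls below 1e-5, merging points within
  distance 1e-3. Trained GRUs can contract very slowly, so once the
  detection criterion fires each candidate is *polished* — null iterations
  continue until the step change falls below 1e-12 — before merging;
  without this, one slow attractor masquerades as several nearby "fixed
  points" and return-time probes against the unpolished point never
  terminate. The *odor (reward) memory* is the step at which activity,
  probed at the fixed point with a single odor (reward), first returns
  within squared distance 1e-3. With the probe at step 1, the Task 2
  beliefs' odor memory is 15 and the reward memory 11 — one step after the
  minimum ITI; the alternative time origin would report 14/10, and only
  differences of memories are compared across models. A reward observation
  has zero likelihood at the belief ITI fixed point, so the belief reward
  probe conditions a uniform prior on the reward instead (every
  reward-emitting transition lands in the first ITI microstate, so the
  result is exact whenever defined).

## A worked example

```{r example, eval = FALSE}
task <- cond_task("starkweather2")
rnn  <- value_rnn(task, H = 50, seed = 1)          # TD-trained Value RNN
untr <- value_rnn(task, H = 50, type = "untrained", seed = 1)
model_belief_r2(rnn,  task, session_seed = 100, noise_seed = 200)
model_belief_r2(untr, task, session_seed = 100, noise_seed = 200)
session <- simulate(task, nsim = 500, seed = 9)
memory_difference(rnn, session, seed = 1)
```

## What the generator does and does not emulate

The synthetic tasks reproduce the statistical structure the analyses
assume: geometric ITIs with a hard minimum, the stated delay laws, i.i.d.
omissions, hidden block identities, and magnitude-coded rewards. They do
not model scalar timing noise, licking or other behaviour, slow
motivational drifts, or inter-animal variability — so passing tests show
that the algorithms behave as specified under the generative model, not
that they fit any particular animal's data.

## Problem sizes and reproducibility

Analyses use two sessions of 1,000 trials (fit/evaluation). Network
training uses the full protocol above; summary experiments in the test
suite train 3 replicate networks per task (rather than 12) with a
60-epoch cap, and the capacity/gain sweeps in `run_grid()` default to 12
replicates per cell at the full protocol.
Every stochastic step takes an explicit integer seed, and derived per-cell
seeds make any single grid cell reproducible in isolation.

## Known limitations

* The belief recursion assumes the exact generative matrices; there is no
  model learning, no action dependence, and no continuous-time variant.
* Degenerate delay distributions (all mass at one step) make late ISI
  microstates unreachable; those states exit with hazard 1 by convention
  to keep the chain stochastic.
* The trained-network analyses are stochastic in the training seed; medians
  over replicates are the stable summaries, and single-seed numbers should
  be read with the replicate spread in mind.
* TD training here is plain semi-gradient TD(0); eligibility traces,
  distributional critics, and discount fitting are out of scope.
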
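# beliefrnn

Belief states and TD-trained recurrent value networks for partially
observable Pavlovian conditioning tasks.

## What this is for

In trace conditioning with variable reward delays, probabilistic reward
omission, or hidden reward-size blocks, the state that matters for reward
prediction is not observable. The normative account tracks a **belief
state** — the posterior *b_t* over hidden microstates given the observation
history — and learns a value function on top of it by temporal-difference
(TD) learning, with TD error

    δ_t = r_{t+1} + γ V̂_{t+1} − V̂_t,     V̂_t = w' z_t + w0,  γ = 0.93

(the model counterpart of phasic dopamine). This package implements that
Belief model exactly, and the learned alternative: a **Value RNN**, a GRU
whose hidden state feeds a linear value readout, trained end-to-end by
semi-gradient TD with backpropagation through time from the raw 2-channel
observation stream (odor cue, reward magnitude, 200-ms bins). It then asks
how belief-like the learned representation is, three ways:

* **regression** — held-out pooled R² of a linear map from activity to
  beliefs, `R² = 1 − Var(B − ZŴ)/Var(B)`;
* **decoding** — held-out log-likelihood of a multinomial decoder of the
  true hidden microstate, against the belief ceiling;
* **dynamics** — null-input fixed points and the *odor/reward memory*
  (steps for activity to return within squared distance 1e-3 of its fixed
  point after a single probe observation).

It is intended for computational-neuroscience researchers studying
reward-prediction-error signatures and state representations under partial
observability.

Tasks provided: the two variable-delay tasks (discretised-Gaussian delay
over 6–14 bins; 10% reward omission in variant 2; 25 hidden microstates)
and the hidden reward-block task (delays uniform on {9,10,11}, reward 1 or
10 in hidden 5-trial blocks, 22 microstates per block copy, 44-dimensional
block belief), plus probe sessions with intermediate reward sizes.

## A worked example

```r
library(beliefrnn)
task <- cond_task("starkweather2")   # 10% omission task
print(task)
#> Conditioning task: starkweather2
#>   ITI: 10 + Geom(0.125) bins of 200 ms
#>   ISI support: {6, 7, 8, 9, 10, 11, 12, 13, 14}
#>   reward omission prob: 0.1

# exact beliefs and their dynamics
bm <- belief_model(task)
session <- simulate(task, nsim = 500, seed = 9)
md <- memory_difference(bm, session, seed = 1)
str(md[1:4])
#> List of 4
#>  $ odor_memory   : int 15
#>  $ reward_memory : int 11
#>  $ difference    : int 4
#>  $ n_fixed_points: int 1

# an untrained 50-unit GRU still supports a partial linear readout of
# beliefs (held-out pooled R-squared, noise gain 0.05):
untr <- value_rnn(task, H = 50, type = "untrained", seed = 1)
model_belief_r2(untr, task, session_seed = 100, noise_seed = 200)
#> [1] 0.405252

# TD-training the same architecture makes the representation much more
# belief-like (a few minutes on one core):
rnn <- value_rnn(task, H = 50, seed = 1)   # early-stops after 77 epochs
model_belief_r2(rnn, task, session_seed = 100, noise_seed = 200)
#> [1] 0.7965799
```

The belief model's odor memory of 15 steps reflects the last possible
reward time (14 bins after the odor): one step later, a missing reward has
fully resolved the omission ambiguity and the posterior collapses back to
the intertrial-interval fixed point. The reward memory of 11 reflects the
minimum 10-bin intertrial delay. Trained networks reproduce this
asymmetry; untrained ones do not.

`run_grid()` orchestrates replicate sweeps (capacity, ESN gain, noise) and
`summary()` on its report reproduces the per-cell medians.

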
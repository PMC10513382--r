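Package: beliefrnn
Title: Belief States and Value RNNs for Partially Observable Conditioning Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates Pavlovian trace-conditioning tasks with hidden states
    (the Starkweather variable-reward-time tasks and the Babayan reward-block
    task), computes exact POMDP belief states over time-indexed microstates,
    estimates value functions by least-squares temporal difference (LSTD)
    learning, and trains gated recurrent (GRU) value networks by semi-gradient
    TD learning with backpropagation through time. Provides analyses that
    quantify how belief-like a recurrent representation is: linear belief
    regression (held-out pooled R-squared), multinomial state decoding against
    the belief ceiling, reward-prediction-error comparison, and
    dynamical-systems characterisation (null-input fixed points and
    odor/reward memory durations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    nnet,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
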
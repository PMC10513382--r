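# Independent oracles used across test files.

# Brute-force POMDP filtering: posterior over the current state by
# enumerating every state path consistent with the observation sequence.
# M[[obs]][to, from] = T[to, from] * O_obs[to, from]; start distribution b0.
path_sum_posterior <- function(M, b0, obs_seq) {
  K <- length(b0)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), length(obs_seq) + 1L)))
  w <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    p <- b0[paths[i, 1L]]
    for (t in seq_along(obs_seq)) {
      p <- p * M[[obs_seq[t]]][paths[i, t + 1L], paths[i, t]]
    }
    w[i] <- p
  }
  post <- tapply(w, paths[, ncol(paths)], sum)
  out <- numeric(K)
  out[as.integer(names(post))] <- post
  out / sum(out)
}

# Random small POMDP (random stochastic transition matrix, random
# assignment of each possible transition to one of the three observations).
random_pomdp_matrices <- function(K) {
  Tm <- matrix(stats::rexp(K * K), K, K)
  Tm <- sweep(Tm, 2L, colSums(Tm), `/`)
  lab <- matrix(sample(1:3, K * K, replace = TRUE), K, K)
  M <- lapply(1:3, function(o) Tm * (lab == o))
  names(M) <- c("null", "odor", "reward")
  M
}

# Closed-form value of a Markov reward process: V = (I - gamma P)^-1 R,
# with P[i, j] = P(j -> i) column-stochastic and R the expected reward
# received on leaving each state.
mrp_value <- function(P, R, gamma) {
  solve(diag(nrow(P)) - gamma * t(P), R)
}
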
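#' Exact belief-state model of a task
#'
#' Constructs the Bayes-optimal "Belief model": the representation at each
#' time bin is the exact posterior over the task's hidden microstates given
#' the observation history, computed by the forward recursion of the
#' microstate POMDP. Its value estimate is a linear readout of the belief,
#' fit by LSTD (see [lstd()]). For the Babayan task the representation is
#' the 44-dimensional concatenation `[p_t * b1_t, (1 - p_t) * b2_t]`, where
#' `p_t` is the posterior probability of being in the small-reward block
#' given the most recently observed nonzero reward, and `b1`, `b2` are
#' per-block-copy microstate beliefs.
#'
#' @param task a [cond_task] object.
#' @param sigma_r reward-likelihood sd for the Babayan block posterior.
#' @return object of class `belief_model` with elements `spec` (the
#'   [pomdp_spec()]), `task`, `D` (representation dimension).
#' @export
belief_model <- function(task, sigma_r = 0.001) {
  stopifnot(inherits(task, "cond_task"))
  spec <- pomdp_spec(task)
  D <- if (task$task_id == "babayan") 2L * spec$K else spec$K
  structure(list(spec = spec, task = task, D = D,
                 mu = if (task$task_id == "babayan") task$reward_sizes else NULL,
                 sigma_r = sigma_r),
            class = "belief_model")
}

#' @export
print.belief_model <- function(x, ...) {
  cat("Belief model for ", x$task$task_id, " (representation dimension ",
      x$D, ")\n", sep = "")
  invisible(x)
}

#' Model representation over a session
#'
#' Runs a model forward over a session's observations and returns its
#' time-by-dimension representation matrix: exact beliefs for a
#' [belief_model], hidden-unit activity for a [value_rnn].
#'
#' @param model a `belief_model` or `value_rnn`.
#' @param session a `cond_session`.
#' @param ... passed to methods.
#' @return T x D numeric matrix.
#' @export
representation <- function(model, session, ...) UseMethod("representation")

#' @export
representation.belief_model <- function(model, session, ...) {
  stopifnot(inherits(session, "cond_session"))
  if (model$task$task_id == "babayan") {
    compute_babayan_beliefs(model$spec, session, mu = model$mu,
                            sigma_r = model$sigma_r)
  } else {
    compute_beliefs(model$spec, session, ...)
  }
}

## precompute the three per-observation propagation matrices
obs_matrices <- function(spec) {
  lapply(spec$O, function(Oo) spec$T_mat * Oo)
}

#' Belief trajectory over a session
#'
#' Iterates the belief recursion over every bin of a session, starting from
#' the null-input fixed point `b0`. Rows sum to 1; per-step normalisers are
#' retained for underflow diagnostics and steps where the recursion
#' underflowed (observation impossible under the model) are flagged and
#' reset per [update_belief()].
#'
#' @param spec a `pomdp`.
#' @param session a `cond_session` (its observations are classified into
#'   null/odor/reward).
#' @inheritParams update_belief
#' @return T x K matrix with attributes `normalizers` (length T) and
#'   `underflow` (logical length T).
#' @export
compute_beliefs <- function(spec, session, underflow = "reset", floor = 1e-12) {
  obs <- session$obs
  Tn <- nrow(obs)
  M <- obs_matrices(spec)
  cls <- ifelse(obs[, 1L] > 0, "odor", ifelse(obs[, 2L] > 0, "reward", "null"))
  if (any(obs[, 1L] > 0 & obs[, 2L] > 0)) {
    stop("simultaneous cue and reward observation")
  }
  B <- matrix(0, Tn, spec$K)
  norms <- numeric(Tn)
  uf <- logical(Tn)
  b <- spec$b0
  for (t in seq_len(Tn)) {
    b_new <- as.numeric(M[[cls[t]]] %*% b)
    z <- sum(b_new)
    if (!is.finite(z) || z < floor) {
      b <- if (underflow == "reset") spec$b0 else b
      uf[t] <- TRUE
    } else {
      b <- b_new / z
    }
    norms[t] <- z
    B[t, ] <- b
  }
  attr(B, "normalizers") <- norms
  attr(B, "underflow") <- uf
  B
}

#' Babayan block posterior from a reward observation
#'
#' Posterior probability of the small-reward block given a single nonzero
#' reward `r`, under equal-variance Gaussian likelihoods centred at the two
#' block reward sizes: `f(r) = phi(r; mu1, s) / (phi(r; mu1, s) + phi(r;
#' mu2, s))`. Computed on the log scale, so it is exact even for the
#' near-degenerate default `sigma_r = 0.001` (crossing point at
#' `(mu1 + mu2) / 2`).
#'
#' @param r nonzero reward magnitude(s).
#' @param mu the two block reward sizes (default `c(1, 10)`).
#' @param sigma_r likelihood sd.
#' @return probability (vectorised over `r`).
#' @export
block_posterior <- function(r, mu = c(1, 10), sigma_r = 0.001) {
  stats::plogis(((r - mu[2L])^2 - (r - mu[1L])^2) / (2 * sigma_r^2))
}

#' Babayan concatenated block beliefs
#'
#' Computes the 44-dimensional Babayan belief `[p_t * b1_t, (1 - p_t) *
#' b2_t]`. The two per-block sub-beliefs are propagated independently
#' through the single-block POMDP (reward magnitude enters only through the
#' block posterior `p_t`, which updates via [block_posterior()] at nonzero
#' rewards and is held otherwise; it starts at 1/2).
#'
#' @param spec the single-block `pomdp` (`K = 22`).
#' @inheritParams compute_beliefs
#' @inheritParams block_posterior
#' @return T x 2K matrix with attribute `p_block1` (length T).
#' @export
compute_babayan_beliefs <- function(spec, session, mu = c(1, 10),
                                    sigma_r = 0.001, underflow = "reset",
                                    floor = 1e-12) {
  obs <- session$obs
  Tn <- nrow(obs)
  M <- obs_matrices(spec)
  cls <- ifelse(obs[, 1L] > 0, "odor", ifelse(obs[, 2L] > 0, "reward", "null"))
  B <- matrix(0, Tn, 2L * spec$K)
  pb <- numeric(Tn)
  b1 <- spec$b0; b2 <- spec$b0
  p <- 0.5
  for (t in seq_len(Tn)) {
    Mt <- M[[cls[t]]]
    for (side in 1:2) {
      b <- if (side == 1) b1 else b2
      b_new <- as.numeric(Mt %*% b)
      z <- sum(b_new)
      b <- if (!is.finite(z) || z < floor) {
        if (underflow == "reset") spec$b0 else b
      } else b_new / z
      if (side == 1) b1 <- b else b2 <- b
    }
    if (obs[t, 2L] > 0) p <- block_posterior(obs[t, 2L], mu, sigma_r)
    pb[t] <- p
    B[t, ] <- c(p * b1, (1 - p) * b2)
  }
  attr(B, "p_block1") <- pb
  B
}

#' Null-input step map of a model
#'
#' Returns the one-step state-update function `function(state, obs)` of a
#' model's recurrent dynamics, used by the fixed-point and memory analyses:
#' the belief recursion for a `belief_model` (operating on the full
#' concatenated belief for the Babayan task), the GRU map for a
#' `value_rnn`. `obs` is a 2-channel observation vector.
#'
#' @param model a `belief_model` or `value_rnn`.
#' @return function of `(state, obs)` returning the next state.
#' @export
step_fun <- function(model) UseMethod("step_fun")

#' @export
step_fun.belief_model <- function(model) {
  spec <- model$spec
  M <- obs_matrices(spec)
  babayan <- model$task$task_id == "babayan"
  mu <- model$mu; sigma_r <- model$sigma_r
  function(b, o) {
    cls <- classify_obs(o)
    Mt <- M[[cls]]
    stepb <- function(b, prior_fallback = TRUE) {
      b_new <- as.numeric(Mt %*% b)
      z <- sum(b_new)
      if (!is.finite(z) || z < 1e-12) {
        if (prior_fallback && cls != "null") {
          ## observation impossible from this belief (e.g. a reward probe at
          ## the ITI fixed point): condition a uniform prior on it instead
          b_new <- as.numeric(Mt %*% rep(1 / nrow(Mt), nrow(Mt)))
          z <- sum(b_new)
        }
        if (z < 1e-12) return(spec$b0)
      }
      b_new / z
    }
    if (!babayan) return(stepb(b))
    K <- spec$K
    p <- sum(b[seq_len(K)])
    b1 <- if (p > 0) b[seq_len(K)] / p else spec$b0
    b2 <- if (p < 1) b[K + seq_len(K)] / (1 - p) else spec$b0
    b1 <- stepb(b1); b2 <- stepb(b2)
    if (o[2L] > 0) p <- block_posterior(o[2L], mu, sigma_r)
    c(p * b1, (1 - p) * b2)
  }
}
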
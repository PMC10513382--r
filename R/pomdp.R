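#' Microstate POMDP of a conditioning task
#'
#' Builds the hidden-Markov (microstate) formulation of a task: each 200-ms
#' bin is a discrete state, with ISI microstates `1..max(isi_support)`
#' followed by ITI microstates for the minimum delay plus one recurrent
#' geometric state. Observations (null / odor / reward) are emitted on state
#' transitions; `O[[o]][to, from]` indicates that the transition
#' `from -> to` emits observation `o`. The reward hazard at ISI step t is
#' `h_t = p_t / (1 - F_t)` with `p` the delay distribution and `F` its
#' cumulative mass up to the previous step.
#'
#' For the Babayan task this returns the single-block copy (`K = 22`); the
#' full 44-dimensional block belief is handled by [compute_beliefs()] via
#' the block posterior (see [block_posterior()]).
#'
#' @param task a [cond_task] object.
#' @return an object of class `pomdp`: list with `K`, `T_mat` (K x K,
#'   columns sum to 1, `T_mat[to, from]`), `O` (list of three 0/1 matrices
#'   `null`, `odor`, `reward`), `hazard`, `state_labels`, and `b0` (one-hot
#'   at the terminal ITI state, the null-observation fixed point).
#' @examples
#' spec <- pomdp_spec(cond_task("starkweather2"))
#' spec$K   # 25
#' @export
pomdp_spec <- function(task) {
  stopifnot(inherits(task, "cond_task"))
  n_isi <- n_isi_states(task)
  K <- n_states_per_block(task)
  p_om <- if (task$task_id == "babayan") 0 else task$p_omission

  p <- numeric(n_isi)
  p[task$isi_support] <- isi_distribution(task)
  Fcum <- cumsum(p)
  hazard <- numeric(n_isi)
  for (t in seq_len(n_isi)) {
    surv <- 1 - (if (t > 1) Fcum[t - 1] else 0)
    if (p[t] > 0 && surv <= 0) stop("hazard undefined at ISI step ", t)
    ## unreachable ISI states (all delay mass already spent) exit with
    ## hazard 1 so the chain stays stochastic; they are never visited
    hazard[t] <- if (surv > 0) p[t] / surv else 1
  }
  hazard[n_isi] <- 1

  Tm <- matrix(0, K, K)
  O_null <- matrix(0, K, K); O_odor <- matrix(0, K, K); O_rew <- matrix(0, K, K)
  iti1 <- n_isi + 1L  # first ITI microstate (post-reward state)

  ## ISI microstates
  for (t in seq_len(n_isi)) {
    h <- hazard[t]
    if (t < n_isi) Tm[t + 1L, t] <- 1 - h
    Tm[iti1, t] <- Tm[iti1, t] + h          # reward transition
    if (t < n_isi) O_null[t + 1L, t] <- 1
    if (h > 0) O_rew[iti1, t] <- 1
  }
  ## ITI microstates advance deterministically to the terminal state
  for (m in iti1:(K - 1L)) {
    Tm[m + 1L, m] <- 1
    O_null[m + 1L, m] <- 1
  }
  ## terminal ITI state: stay, or emit the odor of the next trial
  Tm[K, K] <- 1 - task$p_iti
  O_null[K, K] <- 1
  Tm[1L, K] <- task$p_iti * (1 - p_om)
  O_odor[1L, K] <- 1
  if (p_om > 0) {
    Tm[iti1, K] <- task$p_iti * p_om        # omission: odor, straight to ITI
    O_odor[iti1, K] <- 1
  }

  b0 <- numeric(K); b0[K] <- 1
  structure(list(
    K = K,
    T_mat = Tm,
    O = list(null = O_null, odor = O_odor, reward = O_rew),
    hazard = hazard,
    state_labels = c(paste0("ISI_", seq_len(n_isi)),
                     paste0("ITI_", seq_len(K - n_isi))),
    b0 = b0,
    task = task
  ), class = "pomdp")
}

#' @rdname pomdp_spec
#' @param variant 1 or 2 (omission probability 0 or 0.1).
#' @param ... passed to [cond_task()].
#' @export
build_starkweather_pomdp <- function(variant = 1, ...) {
  pomdp_spec(cond_task(paste0("starkweather", variant), ...))
}

#' @rdname pomdp_spec
#' @export
build_babayan_block_pomdp <- function(...) {
  pomdp_spec(cond_task("babayan", ...))
}

#' @export
print.pomdp <- function(x, ...) {
  n_isi <- sum(startsWith(x$state_labels, "ISI"))
  cat("Microstate POMDP (", x$task$task_id, "): K = ", x$K, " states (",
      n_isi, " ISI + ", x$K - n_isi, " ITI)\n", sep = "")
  invisible(x)
}

#' Classify an observation vector
#'
#' Maps a 2-channel observation `[cue, reward]` to one of `null`, `odor`,
#' `reward`. Simultaneous cue and reward cannot occur in these tasks and is
#' rejected.
#' @param o numeric length-2 observation.
#' @return character scalar.
#' @export
classify_obs <- function(o) {
  if (o[1L] > 0 && o[2L] > 0) stop("simultaneous cue and reward observation")
  if (o[1L] > 0) "odor" else if (o[2L] > 0) "reward" else "null"
}

#' One Bayesian belief update
#'
#' Propagates a belief through one observed time step:
#' `b_new(k) propto sum_j O_o(k, j) T(k, j) b(j)`, renormalised. If the
#' observation has (numerically) zero likelihood under the prior predictive
#' -- e.g. a null observation beyond the last possible reward time in a task
#' with no omissions -- the belief is reset to the null-input fixed point
#' `b0` (`underflow = "reset"`) or held (`underflow = "hold"`), and flagged.
#'
#' @param spec a `pomdp`.
#' @param b_prev belief vector on the simplex.
#' @param obs `"null"`, `"odor"`, `"reward"`, or a 2-channel observation.
#' @param underflow what to do when the normaliser falls below `floor`.
#' @param floor normaliser floor (default 1e-12).
#' @return belief vector with attributes `normalizer` and `underflow`.
#' @export
update_belief <- function(spec, b_prev, obs,
                          underflow = c("reset", "hold"), floor = 1e-12) {
  underflow <- match.arg(underflow)
  if (is.numeric(obs)) obs <- classify_obs(obs)
  M <- spec$T_mat * spec$O[[obs]]
  b <- as.numeric(M %*% b_prev)
  z <- sum(b)
  if (!is.finite(z) || z < floor) {
    b <- if (underflow == "reset") spec$b0 else b_prev
    attr(b, "normalizer") <- z
    attr(b, "underflow") <- TRUE
    return(b)
  }
  b <- b / z
  attr(b, "normalizer") <- z
  attr(b, "underflow") <- FALSE
  b
}
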
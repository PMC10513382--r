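#' Least-squares temporal-difference value weights
#'
#' Closed-form linear value weights minimising the TD error over a sample
#' path: `w = D^-1 d` with `D = sum_t z_t (z_t - gamma z_{t+1})'` and
#' `d = sum_t r_{t+1} z_t`, sums running over within-episode transition
#' pairs only (rewards are observed on transitions, so the reward paired
#' with the transition out of step t is the one carried by observation row
#' t + 1). A constant-1 feature is appended internally to carry the
#' intercept `w0`. If the system is (numerically) singular -- as it always
#' is for beliefs plus an intercept, since belief rows sum to 1 -- a ridge
#' of 1e-8 is added to the diagonal with a warning.
#'
#' @param Z T x D representation matrix.
#' @param r length-T reward sequence aligned with the rows of `Z`.
#' @param gamma discount factor per 200-ms bin (default 0.93).
#' @param episode optional length-T episode/session labels; transition
#'   pairs spanning a boundary are excluded.
#' @return object of class `value_weights`: list with `w` (length D),
#'   `w0`, `gamma`.
#' @export
lstd <- function(Z, r, gamma = 0.93, episode = NULL) {
  Z <- as.matrix(Z)
  Tn <- nrow(Z)
  stopifnot(length(r) == Tn, gamma >= 0, gamma < 1)
  if (Tn < ncol(Z) + 2L) stop("need T >= D + 2 samples")
  if (is.null(episode)) episode <- rep(1L, Tn)
  idx <- which(episode[-Tn] == episode[-1L])
  Za <- cbind(Z[idx, , drop = FALSE], 1)
  Zb <- cbind(Z[idx + 1L, , drop = FALSE], 1)
  D_hat <- crossprod(Za, Za - gamma * Zb)
  d_hat <- crossprod(Za, r[idx + 1L])
  sol <- tryCatch({
    if (rcond(D_hat) < 1e-12) stop("singular")
    solve(D_hat, d_hat)
  }, error = function(e) {
    warning("LSTD system is singular; solving with ridge 1e-8 on the diagonal",
            call. = FALSE)
    solve(D_hat + diag(1e-8, nrow(D_hat)), d_hat)
  })
  w <- as.numeric(sol)
  structure(list(w = w[-length(w)], w0 = w[length(w)], gamma = gamma),
            class = "value_weights")
}

#' @export
print.value_weights <- function(x, ...) {
  cat("LSTD value weights: D =", length(x$w), " gamma =", x$gamma,
      " w0 =", signif(x$w0, 4), "\n")
  invisible(x)
}

#' Linear value estimate from a representation
#'
#' @param Z T x D representation matrix (or length-D vector).
#' @param weights a [lstd()] `value_weights` object.
#' @return numeric length-T value sequence `Z w + w0`.
#' @export
value_estimate <- function(Z, weights) {
  stopifnot(inherits(weights, "value_weights"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  if (ncol(Z) != length(weights$w)) stop("representation/weight shape mismatch")
  as.numeric(Z %*% weights$w + weights$w0)
}

#' Temporal-difference errors along a session
#'
#' TD error for the transition out of step t:
#' `delta_t = r_{t+1} + gamma * V_{t+1} - V_t`, for t = 1..T-1; pairs that
#' span an episode boundary are `NA` (no bootstrapping across resets, and
#' no value beyond the final step).
#'
#' @param values length-T value sequence.
#' @param r length-T reward sequence (rewards ride on observation rows).
#' @param gamma discount factor.
#' @param episode optional episode labels as in [lstd()].
#' @return numeric vector of length T-1.
#' @export
td_errors <- function(values, r, gamma = 0.93, episode = NULL) {
  Tn <- length(values)
  stopifnot(length(r) == Tn)
  if (Tn < 2L) return(numeric(0))
  delta <- r[-1L] + gamma * values[-1L] - values[-Tn]
  if (!is.null(episode)) delta[episode[-Tn] != episode[-1L]] <- NA_real_
  delta
}

#' Reward-prediction-error trace of a model on a session
#'
#' Runs a model over a session, fits (or applies) LSTD value weights, and
#' returns the per-step TD errors together with the per-trial RPE at the
#' reward-delivery step -- the model counterpart of phasic dopamine
#' responses. The reward-step RPE of a trial rewarded at bin `t_r` is
#' `delta_{t_r - 1}` (the error of the transition on which the reward
#' arrives); omission trials carry `NA`.
#'
#' @param model a `belief_model` or `value_rnn`.
#' @param session a `cond_session`.
#' @param weights optional pre-fit `value_weights`; by default LSTD is fit
#'   on this session's representation (all model classes are re-fit by
#'   LSTD for analysis, including trained RNNs).
#' @param gamma discount factor.
#' @param Z optional precomputed representation (to reuse across calls).
#' @return object of class `rpe_trace`: list with `delta` (length T-1),
#'   `reward_step_delta` (length n_trials, `NA` on omissions), `isi`
#'   (per-trial reward times in bins after the cue), `block`, and
#'   `weights`.
#' @export
rpe_trace <- function(model, session, weights = NULL, gamma = 0.93, Z = NULL) {
  stopifnot(inherits(session, "cond_session"))
  if (is.null(Z)) Z <- representation(model, session)
  r <- session$obs[, 2L]
  if (is.null(weights)) weights <- suppressWarnings(lstd(Z, r, gamma))
  v <- value_estimate(Z, weights)
  delta <- td_errors(v, r, gamma = weights$gamma)
  rs <- ifelse(is.na(session$reward_time), NA_integer_, session$reward_time - 1L)
  rsd <- rep(NA_real_, session$n_trials)
  ok <- !is.na(rs) & rs >= 1L
  rsd[ok] <- delta[rs[ok]]
  structure(list(delta = delta, reward_step_delta = rsd,
                 isi = session$isi, block = session$block_of_trial,
                 weights = weights),
            class = "rpe_trace")
}

#' @export
print.rpe_trace <- function(x, ...) {
  cat("RPE trace:", length(x$delta), "steps,",
      sum(!is.na(x$reward_step_delta)), "rewarded trials\n")
  invisible(x)
}

#' Mean squared difference between reward-step RPEs
#'
#' Compares two models' RPE traces on the same session, restricted to the
#' reward-delivery step of rewarded trials.
#'
#' @param model_rpe,reference_rpe `rpe_trace` objects from the same session.
#' @return scalar mean squared error.
#' @export
rpe_mse <- function(model_rpe, reference_rpe) {
  stopifnot(inherits(model_rpe, "rpe_trace"), inherits(reference_rpe, "rpe_trace"))
  a <- model_rpe$reward_step_delta
  b <- reference_rpe$reward_step_delta
  if (length(a) != length(b)) stop("traces come from different sessions")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no rewarded trials in common")
  mean((a[ok] - b[ok])^2)
}
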
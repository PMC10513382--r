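#' Null-input fixed points of a recurrent map
#'
#' Iterates a state-update map under the null observation from a set of
#' seed states until the consecutive-step squared distance falls below
#' `fp_tol` (or `max_steps` is hit), then merges converged points that lie
#' within Euclidean distance `merge_dist` of one another and re-verifies
#' each survivor's one-step residual against `fp_tol`.
#'
#' @param step a step function `function(state, obs)` (see [step_fun()]),
#'   or a model with a [step_fun()] method.
#' @param seeds matrix of seed states (one per row), typically states
#'   observed just after an odor or reward; see [fp_seeds()].
#' @param fp_tol consecutive-step squared-distance convergence tolerance.
#' @param merge_dist merge radius (a distance, not squared).
#' @param max_steps iteration cap per seed.
#' @param polish_tol once a trajectory satisfies `fp_tol`, iteration
#'   continues until the consecutive-step squared distance falls below
#'   this much tighter tolerance (or `max_steps` more iterations elapse),
#'   so that slowly contracting systems are reported at their actual
#'   attractor rather than wherever the loose criterion first fired. Set
#'   equal to `fp_tol` to disable.
#' @param null_obs the null observation vector (beliefs classify it as
#'   `"null"`).
#' @return object of class `fixed_point_set`: list with `points` (rows),
#'   `residuals` (one-step squared residuals), `basin_seed_counts`,
#'   `n_unconverged`.
#' @export
find_fixed_points <- function(step, seeds, fp_tol = 1e-5, merge_dist = 1e-3,
                              max_steps = 1000, polish_tol = 1e-12,
                              null_obs = c(0, 0)) {
  if (!is.function(step)) step <- step_fun(step)
  seeds <- as.matrix(seeds)
  converged <- list()
  n_unconverged <- 0L
  for (i in seq_len(nrow(seeds))) {
    z <- seeds[i, ]
    ok <- FALSE
    for (k in seq_len(max_steps)) {
      z_new <- step(z, null_obs)
      if (sum((z_new - z)^2) < fp_tol) { z <- z_new; ok <- TRUE; break }
      z <- z_new
    }
    if (ok && polish_tol < fp_tol) {
      for (k in seq_len(max_steps)) {
        z_new <- step(z, null_obs)
        d2 <- sum((z_new - z)^2)
        z <- z_new
        if (d2 < polish_tol) break
      }
    }
    if (ok) converged[[length(converged) + 1L]] <- z
    else n_unconverged <- n_unconverged + 1L
  }
  if (length(converged) == 0L) {
    warning("no seed converged to a fixed point")
    return(structure(list(points = matrix(numeric(0), 0, ncol(seeds)),
                          residuals = numeric(0),
                          basin_seed_counts = integer(0),
                          n_unconverged = n_unconverged),
                     class = "fixed_point_set"))
  }
  P <- do.call(rbind, converged)
  ## greedy merge: assign each converged point to the first representative
  ## within merge_dist (order-independent for well-separated clusters)
  reps <- list(); counts <- integer(0)
  for (i in seq_len(nrow(P))) {
    assigned <- FALSE
    for (j in seq_along(reps)) {
      if (sqrt(sum((P[i, ] - reps[[j]])^2)) < merge_dist) {
        counts[j] <- counts[j] + 1L
        assigned <- TRUE
        break
      }
    }
    if (!assigned) { reps[[length(reps) + 1L]] <- P[i, ]; counts <- c(counts, 1L) }
  }
  pts <- do.call(rbind, reps)
  res <- apply(pts, 1L, function(z) sum((step(z, null_obs) - z)^2))
  keep <- res < fp_tol
  structure(list(points = pts[keep, , drop = FALSE],
                 residuals = res[keep],
                 basin_seed_counts = counts[keep],
                 n_unconverged = n_unconverged),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat("Fixed-point set:", nrow(x$points), "point(s); residuals",
      paste(signif(x$residuals, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Fixed-point search seeds from session data
#'
#' Selects model states observed just after odor or reward observations in
#' a session, the natural starting points for the null-input fixed-point
#' search.
#'
#' @param model a `belief_model` or `value_rnn`.
#' @param session a `cond_session`.
#' @param n number of seeds (default 20).
#' @param seed integer seed for the random selection.
#' @param Z optional precomputed representation.
#' @return matrix of seed states (one per row).
#' @export
fp_seeds <- function(model, session, n = 20, seed = NULL, Z = NULL) {
  if (is.null(Z)) Z <- representation(model, session)
  cand <- which(session$obs[, 1L] > 0 | session$obs[, 2L] > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pick <- sample(cand, min(n, length(cand)))
  as.matrix(Z[pick, , drop = FALSE])
}

#' Memory duration for a probe observation
#'
#' Initialises the system at a null-input fixed point, applies a single
#' observation at step `t = 1`, then iterates under null input; the memory
#' is the first step `t` at which the squared distance back to the fixed
#' point falls below `return_tol`. A system that never leaves its fixed
#' point has memory 1; a system that does not return within `max_steps`
#' returns `NA` with a flag.
#'
#' @param step a step function or model (see [find_fixed_points()]).
#' @param fixed_point the fixed point state.
#' @param obs_vector the 2-channel probe observation (e.g. `c(1, 0)` for
#'   odor, `c(0, 1)` for a unit reward).
#' @param return_tol squared-distance return threshold (default 1e-3).
#' @param max_steps cap on probe duration.
#' @param null_obs the null observation.
#' @return integer number of steps (or `NA` if capped), with attribute
#'   `trace` holding the per-step squared distances.
#' @export
memory_duration <- function(step, fixed_point, obs_vector,
                            return_tol = 1e-3, max_steps = 1000,
                            null_obs = c(0, 0)) {
  if (!is.function(step)) step <- step_fun(step)
  z <- step(fixed_point, obs_vector)
  dist2 <- numeric(0)
  for (t in seq_len(max_steps)) {
    d <- sum((z - fixed_point)^2)
    dist2 <- c(dist2, d)
    if (d < return_tol) {
      return(structure(t, trace = dist2))
    }
    z <- step(z, null_obs)
  }
  structure(NA_integer_, trace = dist2, capped = TRUE)
}

#' Odor memory minus reward memory of a model
#'
#' Finds the model's null-input fixed point(s) from session data, probes
#' the fixed point with a single odor (`[1, 0]`) and a single reward
#' (`[0, r]` with the task's reward magnitude), and returns the signed
#' difference of the two memory durations. For beliefs this difference is
#' positive: the odor memory tracks the maximum reward delay while the
#' reward memory tracks the minimum ITI. Multi-fixed-point models are
#' probed at the fixed point with the largest seed basin (flagged).
#'
#' @param model a `belief_model` or `value_rnn`.
#' @param session an evaluation `cond_session` from the model's task.
#' @param reward_magnitude reward size of the probe (defaults to the
#'   task's first reward size).
#' @param n_seeds seeds for the fixed-point search.
#' @param seed RNG seed for seed selection.
#' @param ... further arguments to [find_fixed_points()] /
#'   [memory_duration()].
#' @return list with `odor_memory`, `reward_memory`, `difference`,
#'   `n_fixed_points`, `fixed_points`.
#' @export
memory_difference <- function(model, session, reward_magnitude = NULL,
                              n_seeds = 20, seed = NULL, ...) {
  task <- model$task
  if (is.null(reward_magnitude)) reward_magnitude <- task$reward_sizes[1L]
  stp <- step_fun(model)
  fps <- find_fixed_points(stp, fp_seeds(model, session, n = n_seeds,
                                         seed = seed), ...)
  if (nrow(fps$points) == 0L) stop("no fixed point found")
  main <- which.max(fps$basin_seed_counts)
  fp <- fps$points[main, ]
  om <- memory_duration(stp, fp, c(1, 0))
  rm_ <- memory_duration(stp, fp, c(0, reward_magnitude))
  list(odor_memory = as.integer(om),
       reward_memory = as.integer(rm_),
       difference = as.integer(om) - as.integer(rm_),
       n_fixed_points = nrow(fps$points),
       fixed_points = fps)
}
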
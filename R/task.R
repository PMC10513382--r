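#' Define a partially observable conditioning task
#'
#' Constructs the configuration of one of the three trace-conditioning tasks
#' used throughout the package. Time is discretised into 200-ms bins. In the
#' Starkweather tasks a single odor cue predicts a unit reward after a
#' variable delay drawn from a discretised Gaussian over 6--14 bins; in task
#' variant 2 the reward is omitted on a fraction of trials, making the
#' post-odor state partially observable. In the Babayan task the reward
#' magnitude (1 or 10) is set by a hidden block identity that is resampled
#' every 5 trials, and the delay is uniform over \{9, 10, 11\} bins. In every
#' task the intertrial interval is a minimum of 10 bins plus a geometric
#' draw with parameter 1/8.
#'
#' @param task one of `"starkweather1"`, `"starkweather2"`, `"babayan"`.
#' @param p_iti geometric ITI parameter (default 1/8).
#' @param min_iti minimum ITI duration in bins (default 10).
#' @param p_omission reward-omission probability. Defaults to 0.1 for
#'   `"starkweather2"` and 0 otherwise.
#' @param isi_mean,isi_sd mean and sd of the discretised Gaussian delay
#'   distribution (Starkweather tasks only).
#' @param block_length trials per hidden block (Babayan task).
#' @return An object of class `cond_task`.
#' @examples
#' task <- cond_task("starkweather2")
#' isi_distribution(task)
#' @export
cond_task <- function(task = c("starkweather1", "starkweather2", "babayan"),
                      p_iti = 1 / 8, min_iti = 10L, p_omission = NULL,
                      isi_mean = 10, isi_sd = 2.5, block_length = 5L) {
  task <- match.arg(task)
  if (is.null(p_omission)) {
    p_omission <- if (task == "starkweather2") 0.1 else 0
  }
  stopifnot(p_iti > 0, p_iti < 1, min_iti >= 0,
            p_omission >= 0, p_omission < 1)
  cfg <- list(
    task_id = task,
    time_bin_ms = 200,
    p_iti = p_iti,
    min_iti = as.integer(min_iti),
    isi_support = if (task == "babayan") 9:11 else 6:14,
    isi_mean = isi_mean,
    isi_sd = isi_sd,
    p_omission = p_omission,
    reward_sizes = if (task == "babayan") c(1, 10) else 1,
    block_length = as.integer(block_length)
  )
  if (length(cfg$isi_support) == 0L || any(diff(cfg$isi_support) <= 0) ||
      min(cfg$isi_support) < 1L) {
    stop("isi_support must be a nonempty strictly increasing set of steps >= 1")
  }
  structure(cfg, class = "cond_task")
}

#' @export
print.cond_task <- function(x, ...) {
  cat("Conditioning task: ", x$task_id, "\n", sep = "")
  cat("  ITI: ", x$min_iti, " + Geom(", format(x$p_iti), ") bins of ",
      x$time_bin_ms, " ms\n", sep = "")
  cat("  ISI support: {", paste(x$isi_support, collapse = ", "), "}\n", sep = "")
  if (x$p_omission > 0) cat("  reward omission prob:", x$p_omission, "\n")
  if (x$task_id == "babayan") {
    cat("  reward sizes ", paste(x$reward_sizes, collapse = "/"),
        " in hidden blocks of ", x$block_length, " trials\n", sep = "")
  }
  invisible(x)
}

#' Delay (ISI) distribution of a task
#'
#' Probability of each odor-to-reward delay on the task's support. The
#' Starkweather tasks use a Gaussian density (mean 10, sd 2.5) evaluated at
#' the integer support points 6..14 and renormalised; the Babayan task is
#' uniform over \{9, 10, 11\}.
#'
#' @param task a [cond_task] object.
#' @return named numeric vector of probabilities over the ISI support.
#' @export
isi_distribution <- function(task) {
  stopifnot(inherits(task, "cond_task"))
  s <- task$isi_support
  p <- if (task$task_id == "babayan") {
    rep(1 / length(s), length(s))
  } else {
    d <- stats::dnorm(s, mean = task$isi_mean, sd = task$isi_sd)
    d / sum(d)
  }
  names(p) <- s
  p
}

## Microstate counts: ISI microstates 1..max(isi_support), ITI microstates
## max+1 .. max+min_iti+1 (one per minimum-delay step plus one recurrent
## geometric state).
n_isi_states <- function(task) max(task$isi_support)
n_iti_states <- function(task) task$min_iti + 1L
n_states_per_block <- function(task) n_isi_states(task) + n_iti_states(task)

#' Simulate a session of a conditioning task
#'
#' Samples `nsim` trials of the task. Each trial is laid out as
#' `[ITI null bins][odor bin][ISI-1 null bins][reward bin]`; on omission
#' trials the reward bin carries no reward. Observations are two channels:
#' a binary odor cue and a reward magnitude. Hidden microstates follow the
#' generative Markov chain convention of [pomdp_spec()]: odor sends the
#' state to the first ISI microstate on rewarded trials and directly to the
#' first ITI microstate on omission trials; reward sends it to the first
#' ITI microstate; null observations advance it by one step, saturating at
#' the recurrent terminal ITI state.
#'
#' @param object a [cond_task] object.
#' @param nsim number of trials.
#' @param seed integer seed (optional).
#' @param block_rewards optional vector of per-block nonzero reward sizes
#'   (Babayan only); defaults to uniform draws from `object$reward_sizes`.
#' @param ... unused.
#' @return an object of class `cond_session`: a list with elements
#'   `obs` (T x 2 matrix, columns `cue`, `reward`), `state` (length-T
#'   integer microstates), `trial`, `block` (length-T), `reward_time`
#'   (per-trial bin of reward delivery, `NA` on omission), `isi`, `iti`
#'   (per-trial realised intervals), `block_of_trial`, and the task config.
#' @export
simulate.cond_task <- function(object, nsim = 1000, seed = NULL,
                               block_rewards = NULL, ...) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  n_trials <- as.integer(nsim)
  if (is.na(n_trials) || n_trials < 1L) stop("nsim must be a positive count")
  task <- object

  iti <- task$min_iti + stats::rgeom(n_trials, task$p_iti)
  pisi <- isi_distribution(task)
  isi <- task$isi_support[
    sample.int(length(task$isi_support), n_trials, replace = TRUE, prob = pisi)]
  omitted <- stats::runif(n_trials) < task$p_omission

  if (task$task_id == "babayan") {
    n_blocks <- ceiling(n_trials / task$block_length)
    if (is.null(block_rewards)) {
      block_rewards <- sample(task$reward_sizes, n_blocks, replace = TRUE)
    }
    stopifnot(length(block_rewards) >= n_blocks, all(block_rewards > 0))
    block_of_trial <- rep(seq_len(n_blocks), each = task$block_length)[seq_len(n_trials)]
    trial_reward <- block_rewards[block_of_trial]
    ## block identity index (1 or 2) for state offsets: reward <= midpoint -> 1
    block_kind <- ifelse(trial_reward <= mean(range(task$reward_sizes)), 1L, 2L)
  } else {
    block_of_trial <- rep(1L, n_trials)
    trial_reward <- rep(task$reward_sizes[1L], n_trials)
    block_kind <- rep(1L, n_trials)
  }

  n_isi <- n_isi_states(task)
  Kb <- n_states_per_block(task)       # states per block copy
  K <- if (task$task_id == "babayan") 2L * Kb else Kb

  trial_len <- iti + 1L + isi
  total <- sum(trial_len)
  cue <- numeric(total); rew <- numeric(total)
  state <- integer(total); trial_id <- integer(total); block_id <- integer(total)
  reward_time <- rep(NA_integer_, n_trials)

  pos <- 0L
  cur_state <- K                       # session starts at the terminal ITI state
  for (i in seq_len(n_trials)) {
    off <- (block_kind[i] - 1L) * Kb
    len <- trial_len[i]
    idx <- pos + seq_len(len)
    trial_id[idx] <- i
    block_id[idx] <- block_of_trial[i]
    ## ITI nulls: advance, saturating at the terminal state of the current copy
    for (j in seq_len(iti[i])) {
      cur_state <- advance_state(cur_state, Kb)
      state[pos + j] <- cur_state
    }
    ## odor bin
    cue[pos + iti[i] + 1L] <- 1
    cur_state <- if (omitted[i]) off + n_isi + 1L else off + 1L
    state[pos + iti[i] + 1L] <- cur_state
    ## ISI nulls and reward bin
    for (j in seq_len(isi[i])) {
      at_reward <- (j == isi[i]) && !omitted[i]
      cur_state <- if (at_reward) off + n_isi + 1L else advance_state(cur_state, Kb)
      state[pos + iti[i] + 1L + j] <- cur_state
    }
    if (!omitted[i]) {
      reward_time[i] <- pos + len
      rew[pos + len] <- trial_reward[i]
    }
    pos <- pos + len
  }

  structure(list(
    obs = cbind(cue = cue, reward = rew),
    state = state,
    trial = trial_id,
    block = block_id,
    reward_time = reward_time,
    isi = isi, iti = iti,
    omitted = omitted,
    block_of_trial = block_of_trial,
    trial_reward = trial_reward,
    n_trials = n_trials,
    task = task
  ), class = "cond_session")
}

## advance one null step within a block copy of Kb states, saturating at the
## terminal ITI state of that copy
advance_state <- function(s, Kb) {
  off <- ((s - 1L) %/% Kb) * Kb
  local <- s - off
  off + min(local + 1L, Kb)
}

#' @rdname simulate.cond_task
#' @param task a [cond_task] object.
#' @param n_trials number of trials.
#' @export
sample_session <- function(task, n_trials, seed = NULL) {
  simulate.cond_task(task, nsim = n_trials, seed = seed)
}

#' @export
print.cond_session <- function(x, ...) {
  cat("cond_session: ", x$n_trials, " trials, ", nrow(x$obs), " bins (",
      x$task$task_id, ")\n", sep = "")
  cat("  rewarded trials: ", sum(!is.na(x$reward_time)),
      "; mean ITI ", round(mean(x$iti), 2),
      "; mean ISI ", round(mean(x$isi), 2), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cond_session <- function(x, ...) {
  data.frame(t = seq_len(nrow(x$obs)), trial = x$trial, block = x$block,
             cue = x$obs[, 1L], reward = x$obs[, 2L], state = x$state)
}

#' Babayan probe session with intermediate reward sizes
#'
#' Generates a Babayan-task session whose blocks include intermediate reward
#' magnitudes. The default preset mirrors the published probe-session
#' proportions: 39 blocks each of reward 1 and 10 plus 3 blocks each of
#' rewards 2, 4, 6, 8 (84 blocks, 420 trials), with block order shuffled, so
#' that standard-size blocks make up roughly 90% of trials.
#'
#' @param task a Babayan [cond_task] object.
#' @param seed integer seed.
#' @param n_standard number of blocks at each of the standard rewards (1, 10).
#' @param n_intermediate number of blocks at each intermediate reward.
#' @param intermediate_rewards the intermediate magnitudes.
#' @return a `cond_session`.
#' @export
make_probe_session <- function(task, seed = NULL, n_standard = 39L,
                               n_intermediate = 3L,
                               intermediate_rewards = c(2, 4, 6, 8)) {
  stopifnot(inherits(task, "cond_task"))
  if (task$task_id != "babayan") {
    stop("probe sessions are defined only for the babayan task")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  blocks <- c(rep(task$reward_sizes, each = n_standard),
              rep(intermediate_rewards, each = n_intermediate))
  blocks <- sample(blocks)
  simulate.cond_task(task, nsim = length(blocks) * task$block_length,
                     block_rewards = blocks)
}

#' Split a session into fixed-length episodes
#'
#' Cuts a session into contiguous episodes of `episode_len_trials` trials
#' (the unit over which recurrent value networks are trained and their
#' hidden state reset). Trailing trials that do not fill an episode are
#' dropped.
#'
#' @param session a `cond_session`.
#' @param episode_len_trials trials per episode (20 for Starkweather
#'   training, 50 for Babayan).
#' @return list of episodes, each a list with `obs` and `state` slices;
#'   concatenating them reproduces the truncated session.
#' @export
to_episodes <- function(session, episode_len_trials) {
  stopifnot(inherits(session, "cond_session"))
  len <- as.integer(episode_len_trials)
  if (is.na(len) || len < 1L) stop("episode_len_trials must be a positive count")
  if (len > session$n_trials) stop("episode longer than session")
  n_ep <- session$n_trials %/% len
  lapply(seq_len(n_ep), function(e) {
    trials <- ((e - 1L) * len + 1L):(e * len)
    idx <- which(session$trial %in% trials)
    list(obs = session$obs[idx, , drop = FALSE],
         state = session$state[idx],
         trial = session$trial[idx])
  })
}
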
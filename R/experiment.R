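#' Full belief-likeness analysis of one model
#'
#' Runs the complete analysis battery on a fitted model: two fresh
#' analysis sessions (fit + evaluation), LSTD-refit RPEs compared with the
#' Belief model ([rpe_mse()]), held-out belief regression ([belief_r2()]),
#' optional state decoding with the belief ceiling, and the fixed-point /
#' memory characterisation.
#'
#' @param model a `value_rnn` (or `belief_model`).
#' @param seed integer seed controlling the analysis sessions and noise.
#' @param n_trials trials per analysis session (default 1000).
#' @param g representation noise gain (default 0.05; noise is applied to
#'   RNN representations only, not to beliefs).
#' @param include_decoding fit the multinomial state decoder (slower).
#' @param include_dynamics run the fixed-point/memory analysis.
#' @return one-row `data.frame` of metrics.
#' @export
analyze_model <- function(model, seed = 1, n_trials = 1000, g = 0.05,
                          include_decoding = FALSE, include_dynamics = TRUE) {
  task <- model$task
  set.seed(as.integer(seed))
  fit_s <- simulate.cond_task(task, nsim = n_trials)
  eval_s <- simulate.cond_task(task, nsim = n_trials)
  bm <- belief_model(task)
  Bf <- representation(bm, fit_s)
  Be <- representation(bm, eval_s)
  is_belief <- inherits(model, "belief_model")
  Zf <- representation(model, fit_s)
  Ze <- representation(model, eval_s)
  ## noise is injected for regression/decoding only; value fitting uses the
  ## deterministic representation
  if (!is_belief && g > 0) {
    Zf_n <- add_representation_noise(Zf, g)
    Ze_n <- add_representation_noise(Ze, g)
  } else {
    Zf_n <- Zf; Ze_n <- Ze
  }

  ## RPE error vs the Belief model (value weights LSTD-refit on the fit
  ## session, evaluated on the eval session)
  r_fit <- fit_s$obs[, 2L]
  wb <- suppressWarnings(lstd(Bf, r_fit, model$gamma %||% 0.93))
  wz <- suppressWarnings(lstd(Zf, r_fit, model$gamma %||% 0.93))
  rpe_b <- rpe_trace(bm, eval_s, weights = wb, Z = Be)
  rpe_z <- rpe_trace(model, eval_s, weights = wz, Z = Ze)
  mse <- rpe_mse(rpe_z, rpe_b)

  r2 <- if (is_belief) 1 else belief_r2(Zf_n, Bf, Ze_n, Be)

  dec_ll <- NA_real_; bel_ll <- NA_real_
  if (include_decoding) {
    keep <- decoding_mask(eval_s)
    bel_ll <- as.numeric(decoder_loglik(probs = Be, states_eval = eval_s$state,
                                        keep = keep))
    dec <- fit_state_decoder(Zf_n, fit_s$state, K = ncol(Bf))
    dec_ll <- as.numeric(decoder_loglik(dec, Ze_n, eval_s$state, keep = keep))
  }

  om <- NA_integer_; rm_ <- NA_integer_; md <- NA_integer_; nfp <- NA_integer_
  if (include_dynamics) {
    dyn <- memory_difference(model, eval_s, seed = seed)
    om <- dyn$odor_memory; rm_ <- dyn$reward_memory
    md <- dyn$difference; nfp <- dyn$n_fixed_points
  }

  data.frame(task = task$task_id,
             kind = if (is_belief) "belief" else model$type,
             H = if (is_belief) ncol(Bf) else model$H,
             gain = if (is_belief) NA_real_ else (model$gain %||% NA_real_),
             rpe_mse = mse, belief_r2 = r2,
             decoder_ll = dec_ll, belief_ll = bel_ll,
             odor_memory = om, reward_memory = rm_, memory_diff = md,
             n_fixed_points = nfp,
             epochs = if (is_belief) NA_integer_ else model$epochs_run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## evaluation mask: Babayan decoding excludes each block's first trial
decoding_mask <- function(session) {
  if (session$task$task_id != "babayan") return(NULL)
  first_of_block <- which(c(TRUE, diff(session$block_of_trial) != 0))
  !(session$trial %in% first_of_block)
}

#' Run a replicate grid of models and analyses
#'
#' Executes the simulate-(train)-analyze pipeline over a grid of cells:
#' tasks x model kinds x sizes (or gains) x replicates, with one derived
#' seed per cell so any single cell can be regenerated in isolation.
#' Failures in individual cells are recorded and the grid continues.
#'
#' @param tasks character vector of task ids.
#' @param kinds model kinds among `"value_rnn"`, `"untrained"`, `"esn"`.
#' @param H hidden sizes to sweep.
#' @param gains ESN gains to sweep (ignored for other kinds).
#' @param n_replicates replicates per cell (default 12).
#' @param base_seed base integer seed.
#' @param n_train_trials training-session trials for trained cells.
#' @param max_epochs training epoch cap.
#' @param n_analysis_trials trials per analysis session.
#' @param g analysis noise gain.
#' @param include_decoding fit state decoders (slower).
#' @param verbose log each cell.
#' @return `data.frame` of class `analysis_report`, one row per replicate
#'   per cell, with full provenance columns (`seed`, `replicate`, `error`).
#' @export
run_grid <- function(tasks = "starkweather2", kinds = c("value_rnn", "untrained"),
                     H = 50, gains = NULL, n_replicates = 12, base_seed = 1,
                     n_train_trials = 10000, max_epochs = 150,
                     n_analysis_trials = 1000, g = 0.05,
                     include_decoding = FALSE, verbose = FALSE) {
  cells <- expand.grid(task = tasks, kind = kinds, H = H,
                       replicate = seq_len(n_replicates),
                       stringsAsFactors = FALSE)
  cells$gain <- NA_real_
  if (!is.null(gains) && "esn" %in% kinds) {
    esn <- cells$kind == "esn"
    swept <- merge(cells[esn, setdiff(names(cells), "gain"), drop = FALSE],
                   data.frame(gain = gains))
    cells <- rbind(cells[!esn, , drop = FALSE], swept[, names(cells)])
  }
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    seed <- derive_seed(base_seed, cl$task, cl$kind, cl$H, cl$gain,
                        cl$replicate)
    if (verbose) {
      message(sprintf("cell %d/%d: %s %s H=%d gain=%s rep=%d (seed %d)",
                      i, nrow(cells), cl$task, cl$kind, cl$H,
                      format(cl$gain), cl$replicate, seed))
    }
    rows[[i]] <- tryCatch({
      task <- cond_task(cl$task)
      type <- switch(cl$kind, value_rnn = "trained", untrained = "untrained",
                     esn = "esn")
      model <- value_rnn(task, H = cl$H, type = type,
                         gain = if (is.na(cl$gain)) NULL else cl$gain,
                         seed = seed, n_trials = n_train_trials,
                         max_epochs = max_epochs)
      out <- analyze_model(model, seed = seed + 1L,
                           n_trials = n_analysis_trials, g = g,
                           include_decoding = include_decoding)
      out$replicate <- cl$replicate
      out$seed <- seed
      out$error <- NA_character_
      out
    }, error = function(e) {
      data.frame(task = cl$task, kind = cl$kind, H = cl$H, gain = cl$gain,
                 rpe_mse = NA_real_, belief_r2 = NA_real_,
                 decoder_ll = NA_real_, belief_ll = NA_real_,
                 odor_memory = NA_integer_, reward_memory = NA_integer_,
                 memory_diff = NA_integer_, n_fixed_points = NA_integer_,
                 epochs = NA_integer_, replicate = cl$replicate, seed = seed,
                 error = conditionMessage(e))
    })
  }
  report <- do.call(rbind, rows)
  class(report) <- c("analysis_report", "data.frame")
  report
}

## deterministic small-integer seed per grid cell
derive_seed <- function(base_seed, ...) {
  key <- paste(c(base_seed, ...), collapse = "|")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

#' Summarise an analysis report
#'
#' Per-cell medians and means over successfully analysed replicates, with
#' replicate counts; metric columns that are entirely missing are dropped
#' with a warning.
#'
#' @param object an `analysis_report`.
#' @param ... unused.
#' @return `data.frame`, one row per (task, kind, H, gain) cell.
#' @export
summary.analysis_report <- function(object, ...) {
  metrics <- c("rpe_mse", "belief_r2", "decoder_ll", "belief_ll",
               "odor_memory", "reward_memory", "memory_diff",
               "n_fixed_points")
  empty <- metrics[vapply(metrics, function(m) all(is.na(object[[m]])),
                          logical(1))]
  if (length(empty)) {
    warning("dropping empty metric columns: ", paste(empty, collapse = ", "))
    metrics <- setdiff(metrics, empty)
  }
  key <- paste(object$task, object$kind, object$H,
               ifelse(is.na(object$gain), "-", object$gain))
  out <- do.call(rbind, lapply(split(object, key), function(d) {
    row <- d[1L, c("task", "kind", "H", "gain")]
    row$n_ok <- sum(is.na(d$error))
    for (m in metrics) {
      row[[paste0(m, "_median")]] <- stats::median(d[[m]], na.rm = TRUE)
      row[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
    }
    row
  }))
  rownames(out) <- NULL
  out
}
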
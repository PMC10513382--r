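#' Fit (or initialise) a recurrent value network on a conditioning task
#'
#' The central model of the package: a GRU whose hidden state feeds a
#' linear value readout, trained end-to-end by semi-gradient TD(0) with
#' backpropagation through time. The network sees only the raw 2-channel
#' observation stream (odor cue, reward magnitude) and is trained to
#' minimise the squared TD error `(r_{t+1} + gamma V_{t+1} - V_t)^2` with
#' the bootstrapped target held constant. Training runs over episodes of
#' concatenated trials (hidden state reset to zero at each episode start),
#' in shuffled batches, with Adam, and stops early after `patience`
#' consecutive epoch-loss increases.
#'
#' Three model kinds are supported: `"trained"` (the Value RNN: default
#' uniform initialisation, all parameters learned), `"untrained"` (same
#' initialisation, no training -- the reservoir baseline), and `"esn"`
#' (orthogonal-gain echo-state initialisation via [init_gru_esn()], with
#' the recurrent cell frozen so only the value readout is learned).
#'
#' @param task a [cond_task] object.
#' @param H number of hidden units (default 50).
#' @param type `"trained"`, `"untrained"` or `"esn"`.
#' @param gain orthogonal-init gain (ESN only).
#' @param seed integer seed controlling initialisation and, unless a
#'   `session` is supplied, the training session.
#' @param n_trials training-session length in trials (default 10000).
#' @param session optional pre-generated training `cond_session`.
#' @param episode_len trials per training episode; defaults to 20 for
#'   Starkweather tasks and 50 for Babayan.
#' @param gamma discount factor per bin.
#' @param lr Adam learning rate (default 0.003).
#' @param max_epochs maximum training epochs (default 150).
#' @param batch_size episodes per gradient step (default 12).
#' @param patience consecutive epoch-loss increases tolerated before
#'   stopping (default 4).
#' @param init optional `gru_params` to start from (overrides `type`'s
#'   initialiser).
#' @param verbose print per-epoch loss.
#' @return object of class `value_rnn`: list with `cell` (`gru_params`),
#'   `readout` (`value_weights`), `type`, `H`, `gain`, `train_log`
#'   (per-epoch mean TD loss), `epochs_run`, `task`, `gamma`, `seed`.
#' @examples
#' task <- cond_task("starkweather2")
#' m <- value_rnn(task, H = 8, type = "untrained", seed = 1)
#' s <- simulate(task, nsim = 20, seed = 2)
#' head(predict(m, s))
#' @export
value_rnn <- function(task, H = 50, type = c("trained", "untrained", "esn"),
                      gain = NULL, seed = NULL, n_trials = 10000,
                      session = NULL, episode_len = NULL, gamma = 0.93,
                      lr = 0.003, max_epochs = 150, batch_size = 12,
                      patience = 4, init = NULL, verbose = FALSE) {
  stopifnot(inherits(task, "cond_task"))
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(episode_len)) {
    episode_len <- if (task$task_id == "babayan") 50L else 20L
  }
  if (type == "esn") {
    if (is.null(gain)) stop("esn models need a gain")
    cell <- if (is.null(init)) init_gru_esn(H, gain) else init
  } else {
    cell <- if (is.null(init)) init_gru_default(H) else init
  }
  H <- cell$H
  ## readout initialised like the cell: uniform with bound 1/sqrt(H)
  a <- 1 / sqrt(H)
  readout <- structure(list(w = stats::runif(H, -a, a),
                            w0 = stats::runif(1, -a, a), gamma = gamma),
                       class = "value_weights")
  model <- structure(list(cell = cell, readout = readout, type = type,
                          H = H, gain = gain, train_log = numeric(0),
                          epochs_run = 0L, task = task, gamma = gamma,
                          episode_len = episode_len, seed = seed),
                     class = "value_rnn")
  if (type == "untrained") return(model)

  if (is.null(session)) session <- simulate.cond_task(task, nsim = n_trials)
  episodes <- to_episodes(session, episode_len)
  eps <- lapply(episodes, function(e) list(obs = e$obs, rew = e$obs[, 2L]))
  n_ep <- length(eps)
  if (n_ep < 1L) stop("training session too short for one episode")

  freeze_cell <- type == "esn"
  par <- list(Wi = cell$Wi, Wh = cell$Wh, bi = cell$bi, bh = cell$bh,
              w = readout$w, w0 = readout$w0)
  learned <- if (freeze_cell) c("w", "w0") else names(par)
  m1 <- lapply(par, function(p) p * 0)
  m2 <- m1
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  step <- 0L
  epoch_loss <- numeric(0)
  n_increase <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n_ep)
    tot_loss <- 0; tot_n <- 0
    for (b0 in seq(1L, n_ep, by = batch_size)) {
      batch <- ord[b0:min(b0 + batch_size - 1L, n_ep)]
      gr <- cpp_gru_batch_grad(par$Wi, par$Wh, par$bi, par$bh,
                               par$w, par$w0,
                               lapply(eps[batch], `[[`, "obs"),
                               lapply(eps[batch], `[[`, "rew"), gamma)
      if (!is.finite(gr$loss)) stop("training diverged (non-finite loss)")
      bl <- gr$loss; bn <- gr$n
      g <- list(Wi = gr$dWi, Wh = gr$dWh, bi = as.numeric(gr$dbi),
                bh = as.numeric(gr$dbh), w = as.numeric(gr$dw), w0 = gr$dw0)
      g <- lapply(g, function(x) x / bn)   # mean TD loss over the batch
      step <- step + 1L
      for (nm in learned) {
        m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * g[[nm]]
        m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m1[[nm]] / (1 - beta1^step)
        vhat <- m2[[nm]] / (1 - beta2^step)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps_adam)
      }
      tot_loss <- tot_loss + bl; tot_n <- tot_n + bn
    }
    epoch_loss <- c(epoch_loss, tot_loss / tot_n)
    if (verbose) {
      message(sprintf("epoch %3d  mean TD loss %.6f", epoch,
                      epoch_loss[epoch]))
    }
    if (epoch > 1L && epoch_loss[epoch] > epoch_loss[epoch - 1L]) {
      n_increase <- n_increase + 1L
    } else {
      n_increase <- 0L
    }
    if (n_increase >= patience) break
  }
  model$cell <- structure(list(Wi = par$Wi, Wh = par$Wh, bi = par$bi,
                               bh = par$bh, H = H), class = "gru_params")
  model$readout <- structure(list(w = par$w, w0 = par$w0, gamma = gamma),
                             class = "value_weights")
  model$train_log <- epoch_loss
  model$epochs_run <- length(epoch_loss)
  model
}

#' @export
print.value_rnn <- function(x, ...) {
  kind <- switch(x$type, trained = "Value RNN (TD-trained)",
                 untrained = "Untrained RNN", esn = "Value ESN")
  cat(kind, ": H = ", x$H, ", task ", x$task$task_id, sep = "")
  if (!is.null(x$gain)) cat(", gain ", x$gain, sep = "")
  if (x$epochs_run > 0L) {
    cat(sprintf(", %d epochs, final TD loss %.4g", x$epochs_run,
                utils::tail(x$train_log, 1)))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.value_rnn <- function(object, ...) {
  print(object)
  if (object$epochs_run > 0L) {
    cat("training loss: start ", signif(object$train_log[1], 4),
        " -> final ", signif(utils::tail(object$train_log, 1), 4), "\n",
        sep = "")
  }
  cat("readout |w| range: ", paste(signif(range(object$readout$w), 3),
                                   collapse = " .. "), "\n", sep = "")
  invisible(object)
}

#' @export
coef.value_rnn <- function(object, ...) {
  c(object$readout$w, w0 = object$readout$w0)
}

#' @export
representation.value_rnn <- function(model, session, z0 = NULL, ...) {
  stopifnot(inherits(session, "cond_session"))
  gru_rollout(model$cell, session$obs, z0)
}

#' Value estimates of a recurrent value model on a session
#'
#' Rolls the GRU over the session and applies the value readout. By
#' default the model's own (trained or initial) readout is used; pass
#' `weights` to apply LSTD-refit weights instead.
#'
#' @param object a `value_rnn`.
#' @param session a `cond_session`.
#' @param weights optional `value_weights` replacing the model's readout.
#' @param ... unused.
#' @return numeric value sequence, one per bin.
#' @export
predict.value_rnn <- function(object, session, weights = NULL, ...) {
  Z <- representation(object, session)
  value_estimate(Z, if (is.null(weights)) object$readout else weights)
}

#' TD-error residuals of a recurrent value model
#'
#' Returns the per-step TD errors of the model on a session. For analysis
#' comparability the value weights are re-fit by LSTD on the session's
#' representation (`refit = TRUE`, the default); with `refit = FALSE` the
#' model's own readout is used.
#'
#' @param object a `value_rnn`.
#' @param session a `cond_session`.
#' @param refit refit value weights by LSTD before computing TD errors.
#' @param ... unused.
#' @return numeric vector of TD errors (length T - 1).
#' @export
residuals.value_rnn <- function(object, session, refit = TRUE, ...) {
  Z <- representation(object, session)
  w <- if (refit) {
    suppressWarnings(lstd(Z, session$obs[, 2L], object$gamma))
  } else object$readout
  td_errors(value_estimate(Z, w), session$obs[, 2L], gamma = object$gamma)
}

#' @export
plot.value_rnn <- function(x, ...) {
  if (x$epochs_run == 0L) stop("model has no training log")
  plot(seq_along(x$train_log), x$train_log, type = "b", pch = 16,
       xlab = "epoch", ylab = "mean TD loss",
       main = paste0("Value ", toupper(substr(x$type, 1, 1)),
                     substr(x$type, 2, nchar(x$type)), " training (",
                     x$task$task_id, ")"), ...)
  invisible(x)
}

#' @export
step_fun.value_rnn <- function(model) {
  cell <- model$cell
  function(z, o) gru_step(cell, z, o)
}
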
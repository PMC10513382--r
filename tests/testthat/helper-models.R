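# Shared model cache for the acceptance tests. Training a 50-unit value
# network takes minutes, so the replicate networks are trained once per
# test run and reused across test blocks. The suite trains 3 replicates
# per task with a 60-epoch cap (the full protocol allows 150); analysis
# sessions are 1,000 trials as in the analyses proper.

.acc_cache <- new.env(parent = emptyenv())

acc_sessions <- function(task_id) {
  key <- paste0("sess_", task_id)
  if (is.null(.acc_cache[[key]])) {
    task <- cond_task(task_id)
    set.seed(901)
    fit_s <- simulate(task, nsim = 1000)
    eval_s <- simulate(task, nsim = 1000)
    bm <- belief_model(task)
    .acc_cache[[key]] <- list(
      task = task, bm = bm, fit = fit_s, eval = eval_s,
      B_fit = representation(bm, fit_s),
      B_eval = representation(bm, eval_s))
  }
  .acc_cache[[key]]
}

acc_models <- function(task_id, n_seeds = 3) {
  key <- paste0("mod_", task_id)
  if (is.null(.acc_cache[[key]])) {
    task <- cond_task(task_id)
    .acc_cache[[key]] <- lapply(seq_len(n_seeds), function(k) {
      list(trained = value_rnn(task, H = 50, seed = k, n_trials = 10000,
                               max_epochs = 60),
           untrained = value_rnn(task, H = 50, type = "untrained", seed = k),
           seed = k)
    })
  }
  .acc_cache[[key]]
}

# noise-injected held-out belief R2 against the cached sessions
acc_belief_r2 <- function(model, sess, noise_seed) {
  set.seed(noise_seed)
  Zf <- add_representation_noise(representation(model, sess$fit), 0.05)
  Ze <- add_representation_noise(representation(model, sess$eval), 0.05)
  belief_r2(Zf, sess$B_fit, Ze, sess$B_eval)
}
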
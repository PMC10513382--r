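#' Add fixed-SNR Gaussian noise to a representation
#'
#' RNN activity is a deterministic function of its inputs, so before
#' regression/decoding analyses each unit receives zero-mean Gaussian noise
#' with standard deviation `g * sigma_i`, where `sigma_i` is that unit's
#' sample sd over the session. Every unit then has the same signal-to-noise
#' ratio, `SNR = -20 log10(g)` dB (about 26 dB at the default `g = 0.05`).
#' Zero-variance units receive no noise (with a warning).
#'
#' @param Z T x H representation matrix.
#' @param g noise gain (`g = 0` returns `Z` unchanged).
#' @param seed optional integer seed for the noise draw.
#' @return matrix of the same shape, with attribute `noise_sd` (per-unit sd
#'   of the added noise).
#' @export
add_representation_noise <- function(Z, g = 0.05, seed = NULL) {
  stopifnot(g >= 0)
  Z <- as.matrix(Z)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sds <- apply(Z, 2L, stats::sd)
  if (any(sds == 0)) warning("zero-variance units receive no noise")
  if (g > 0) {
    E <- matrix(stats::rnorm(length(Z)), nrow(Z), ncol(Z))
    Z <- Z + sweep(E, 2L, g * sds, `*`)
  }
  attr(Z, "noise_sd") <- g * sds
  Z
}

#' Signal-to-noise ratio of a noise gain
#'
#' @param g noise gain.
#' @return SNR in dB: `-20 log10(g)`.
#' @export
noise_snr_db <- function(g) -20 * log10(g)

#' Held-out pooled variance of beliefs explained by a representation
#'
#' Multivariate linear regression of beliefs on a representation:
#' `W = (Z'Z)^-1 Z'B` with `Z` augmented by a constant-1 column, fit on
#' one session and evaluated on another. The returned statistic is the
#' total (pooled across belief dimensions) variance explained,
#' `R2 = 1 - Var(B - ZW) / Var(B)`, where `Var(X)` is the mean squared
#' row-distance from the row-mean; it can be negative for poor fits.
#' Rank-deficient designs are handled by the least-squares pseudoinverse
#' solution (with a warning).
#'
#' @param Z_fit,B_fit fit-session representation and beliefs.
#' @param Z_eval,B_eval evaluation-session representation and beliefs.
#' @return scalar held-out pooled R-squared.
#' @export
belief_r2 <- function(Z_fit, B_fit, Z_eval, B_eval) {
  Zf <- cbind(as.matrix(Z_fit), 1)
  Ze <- cbind(as.matrix(Z_eval), 1)
  Bf <- as.matrix(B_fit); Be <- as.matrix(B_eval)
  stopifnot(nrow(Zf) == nrow(Bf), nrow(Ze) == nrow(Be),
            ncol(Zf) == ncol(Ze), ncol(Bf) == ncol(Be))
  G <- crossprod(Zf)
  W <- tryCatch({
    if (rcond(G) < 1e-14) stop("rank-deficient")
    solve(G, crossprod(Zf, Bf))
  }, error = function(e) {
    warning("rank-deficient design; using the pseudoinverse solution",
            call. = FALSE)
    fit <- lm.fit(Zf, Bf)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    cf
  })
  resid <- Be - Ze %*% W
  1 - pooled_var(resid) / pooled_var(Be)
}

pooled_var <- function(X) {
  mu <- colMeans(X)
  mean(rowSums(sweep(X, 2L, mu)^2))
}

#' Multinomial decoder of hidden states from a representation
#'
#' Fits a linear (softmax) decoder of the task's hidden microstates from a
#' representation: each dimension is standardised to zero mean and unit
#' variance (statistics from the fit split only), then a multinomial
#' logistic regression with a quadratic penalty of `1/(2C)` on the weights
#' (inverse regularisation strength `C`, applied to the summed
#' cross-entropy) is fit by BFGS via `nnet::multinom`.
#'
#' @param Z_fit T x H fit-split representation (typically noise-injected).
#' @param states_fit length-T integer states in `1..K`.
#' @param C inverse penalty strength (default 1).
#' @param K total number of states (defaults to `max(states_fit)`);
#'   classes absent from the fit split receive near-zero probability.
#' @param maxit optimiser iteration cap.
#' @return object of class `state_decoder` with the standardisation
#'   statistics and the (H+1) x K weight matrix (intercept first row).
#' @export
fit_state_decoder <- function(Z_fit, states_fit, C = 1, K = NULL,
                              maxit = 1e4) {
  Z_fit <- as.matrix(Z_fit)
  Tn <- nrow(Z_fit)
  stopifnot(length(states_fit) == Tn, all(states_fit >= 1))
  if (is.null(K)) K <- max(states_fit)
  seen <- sort(unique(states_fit))
  if (length(seen) < K) warning("some states unseen in the fit split")
  mu <- colMeans(Z_fit)
  sds <- apply(Z_fit, 2L, stats::sd)
  sds[sds == 0] <- 1
  Zs <- sweep(sweep(Z_fit, 2L, mu), 2L, sds, `/`)
  colnames(Zs) <- paste0("z", seq_len(ncol(Zs)))
  fit <- nnet::multinom(y ~ ., data = data.frame(y = factor(states_fit,
                                                            levels = seen),
                                                 Zs),
                        decay = 1 / (2 * C), maxit = maxit,
                        MaxNWts = 1e5, trace = FALSE)
  ## weights relative to the first seen class (its column is zero)
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1L)
  W <- matrix(-50, nrow = ncol(Z_fit) + 1L, ncol = K)  # unseen classes sunk
  W[, seen[1L]] <- 0
  for (j in seq_len(nrow(co))) W[, seen[j + 1L]] <- co[j, ]
  structure(list(mean = mu, sd = sds, W = W, K = K, C = C),
            class = "state_decoder")
}

#' @export
print.state_decoder <- function(x, ...) {
  cat("Multinomial state decoder:", length(x$mean), "features ->", x$K,
      "states (C =", x$C, ")\n")
  invisible(x)
}

#' Decoder state probabilities
#'
#' @param object a `state_decoder`.
#' @param Z T x H representation (raw scale; standardisation from the fit
#'   split is applied internally).
#' @param ... unused.
#' @return T x K matrix of softmax state probabilities.
#' @export
predict.state_decoder <- function(object, Z, ...) {
  Z <- as.matrix(Z)
  Zs <- sweep(sweep(Z, 2L, object$mean), 2L, object$sd, `/`)
  A <- cbind(1, Zs) %*% object$W
  A <- A - apply(A, 1L, max)
  P <- exp(A)
  P / rowSums(P)
}

#' Mean held-out log-likelihood of decoded states
#'
#' `(1/T) sum_t log pi_t(s_t)` for a decoder's probabilities on an
#' evaluation split. Pass `probs` directly (e.g. the beliefs themselves)
#' to evaluate the belief ceiling without any trained decoder. Zero
#' probabilities are floored at the machine log floor and flagged.
#'
#' @param model a `state_decoder`, or `NULL` when `probs` is given.
#' @param Z_eval evaluation representation (ignored when `probs` given).
#' @param states_eval length-T true states.
#' @param probs optional T x K probability matrix to score directly.
#' @param keep optional logical mask of evaluation steps (e.g. to exclude
#'   each block's first trial in the Babayan task).
#' @return scalar mean log-likelihood (nats), with attribute `floored`
#'   counting floored steps.
#' @export
decoder_loglik <- function(model = NULL, Z_eval = NULL, states_eval,
                           probs = NULL, keep = NULL) {
  if (is.null(probs)) {
    stopifnot(inherits(model, "state_decoder"))
    probs <- predict(model, Z_eval)
  }
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == length(states_eval))
  if (!is.null(keep)) {
    probs <- probs[keep, , drop = FALSE]
    states_eval <- states_eval[keep]
  }
  p <- probs[cbind(seq_along(states_eval), states_eval)]
  floored <- p < .Machine$double.xmin
  p[floored] <- .Machine$double.xmin
  ll <- mean(log(p))
  attr(ll, "floored") <- sum(floored)
  ll
}

#' Principal-component projection of a representation
#'
#' Centred PCA of the time-by-unit activity matrix, for visualising
#' recurrent trajectories in their dominant subspace.
#'
#' @param Z T x H representation.
#' @param n_components number of components to keep (default 2).
#' @return list with `scores` (T x n_components), `rotation`,
#'   `explained` (variance fractions of the kept components), `center`.
#' @export
pca_project <- function(Z, n_components = 2) {
  Z <- as.matrix(Z)
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       center = pc$center)
}

#' Held-out belief R-squared of a model on a task
#'
#' Convenience pipeline for the belief-regression analysis: simulate a fit
#' and an evaluation session, run the model and the exact Belief model over
#' both, inject fixed-SNR noise into the model representation, and return
#' the held-out pooled [belief_r2()].
#'
#' @param model a `value_rnn` (or any object with a [representation()]
#'   method whose output is not itself the belief).
#' @param task the [cond_task].
#' @param n_trials trials per session (default 1000).
#' @param g noise gain (default 0.05).
#' @param session_seed integer seed for the two analysis sessions.
#' @param noise_seed integer seed for the noise draw.
#' @param sessions optional list of two pre-generated sessions, overriding
#'   `n_trials`/`session_seed` (their beliefs are recomputed).
#' @return scalar held-out R-squared.
#' @export
model_belief_r2 <- function(model, task, n_trials = 1000, g = 0.05,
                            session_seed = NULL, noise_seed = NULL,
                            sessions = NULL) {
  if (is.null(sessions)) {
    if (!is.null(session_seed)) set.seed(as.integer(session_seed))
    sessions <- list(simulate.cond_task(task, nsim = n_trials),
                     simulate.cond_task(task, nsim = n_trials))
  }
  bm <- belief_model(task)
  Bf <- representation(bm, sessions[[1L]])
  Be <- representation(bm, sessions[[2L]])
  if (!is.null(noise_seed)) set.seed(as.integer(noise_seed))
  Zf <- add_representation_noise(representation(model, sessions[[1L]]), g)
  Ze <- add_representation_noise(representation(model, sessions[[2L]]), g)
  belief_r2(Zf, Bf, Ze, Be)
}
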
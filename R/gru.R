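#' GRU parameter initialisers
#'
#' `init_gru_default()` draws every weight and bias i.i.d. uniform on
#' `(-1/sqrt(H), 1/sqrt(H))` -- the conventional default for gated
#' recurrent cells. `init_gru_esn()` builds an echo-state-style cell: all
#' biases zero, each of the three H x H recurrent gate blocks an
#' independent random orthogonal matrix scaled by `gain` (so every singular
#' value equals `gain`), and input weights uniform on `(-a, a)` with
#' `a = sqrt(6 / (2 + H))`.
#'
#' Parameters are stored with rows grouped by gate (reset, update,
#' candidate), each block of `H` rows: `Wi` (3H x 2), `Wh` (3H x H),
#' `bi`, `bh` (3H).
#'
#' @param H number of hidden units.
#' @param seed optional integer seed.
#' @param gain scalar gain on the orthogonal recurrent blocks.
#' @return object of class `gru_params`.
#' @export
init_gru_default <- function(H, seed = NULL) {
  H <- as.integer(H)
  if (is.na(H) || H < 1L) stop("H must be a positive count")
  if (!is.null(seed)) set.seed(as.integer(seed))
  a <- 1 / sqrt(H)
  structure(list(
    Wi = matrix(stats::runif(3L * H * 2L, -a, a), 3L * H, 2L),
    Wh = matrix(stats::runif(3L * H * H, -a, a), 3L * H, H),
    bi = stats::runif(3L * H, -a, a),
    bh = stats::runif(3L * H, -a, a),
    H = H), class = "gru_params")
}

## random orthogonal H x H matrix, Haar-distributed (QR with sign fix)
random_orthogonal <- function(H) {
  qrdec <- qr(matrix(stats::rnorm(H * H), H, H))
  Q <- qr.Q(qrdec)
  Q %*% diag(sign(diag(qr.R(qrdec))), H)
}

#' @rdname init_gru_default
#' @export
init_gru_esn <- function(H, gain, seed = NULL) {
  H <- as.integer(H)
  if (is.na(H) || H < 1L) stop("H must be a positive count")
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0) {
    stop("gain must be a positive scalar")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  a <- sqrt(6 / (2 + H))
  Wh <- do.call(rbind, lapply(1:3, function(i) gain * random_orthogonal(H)))
  structure(list(
    Wi = matrix(stats::runif(3L * H * 2L, -a, a), 3L * H, 2L),
    Wh = Wh,
    bi = numeric(3L * H),
    bh = numeric(3L * H),
    H = H), class = "gru_params")
}

#' One GRU step (reference implementation)
#'
#' Pure-R single-step GRU update, used as the step map for dynamics
#' analyses and as an independent cross-check of the compiled rollout.
#' Gate convention: reset gate applied inside the candidate's recurrent
#' term; update gate interpolates between the candidate and the previous
#' state.
#'
#' @param params a `gru_params` object.
#' @param z_prev length-H previous hidden state.
#' @param o length-2 observation `[cue, reward]`.
#' @return length-H new hidden state.
#' @export
gru_step <- function(params, z_prev, o) {
  H <- params$H
  stopifnot(length(z_prev) == H, length(o) == 2L,
            all(is.finite(z_prev)), all(is.finite(o)))
  ai <- as.numeric(params$Wi %*% o + params$bi)
  ah <- as.numeric(params$Wh %*% z_prev + params$bh)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1
  r <- stats::plogis(ai[i1] + ah[i1])
  u <- stats::plogis(ai[i2] + ah[i2])
  n <- tanh(ai[i3] + r * ah[i3])
  (1 - u) * n + u * z_prev
}

#' Roll a GRU over a sequence of observations
#'
#' @param params a `gru_params` object.
#' @param obs T x 2 observation matrix.
#' @param z0 initial hidden state (default zero).
#' @return T x H matrix of hidden states.
#' @export
gru_rollout <- function(params, obs, z0 = NULL) {
  if (is.null(z0)) z0 <- numeric(params$H)
  stopifnot(ncol(obs) == 2L, length(z0) == params$H)
  cpp_gru_forward(params$Wi, params$Wh, params$bi, params$bh,
                  as.matrix(obs), z0)
}
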
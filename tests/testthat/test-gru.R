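test_that("default initialisation is uniform with bound 1/sqrt(H)", {
  p <- init_gru_default(4, seed = 1)
  all_par <- c(p$Wi, p$Wh, p$bi, p$bh)
  expect_true(all(abs(all_par) < 0.5))
  ## moments over many draws: mean 0, variance a^2/3
  big <- init_gru_default(64, seed = 2)
  v <- c(big$Wh)
  a <- 1 / 8
  expect_lt(abs(mean(v)), 4 * a / sqrt(3 * length(v)))
  expect_lt(abs(var(v) - a^2 / 3), 5e-5)
  ## bit-identical under the same seed
  expect_identical(init_gru_default(4, seed = 1), p)
  expect_false(identical(init_gru_default(4, seed = 3)$Wh, p$Wh))
})

test_that("echo-state initialisation is orthogonal-gain with zero biases", {
  H <- 12; gain <- 1.9
  p <- init_gru_esn(H, gain, seed = 4)
  for (blk in 1:3) {
    W <- p$Wh[((blk - 1) * H + 1):(blk * H), ]
    expect_equal(crossprod(W), gain^2 * diag(H), tolerance = 1e-8)
  }
  expect_equal(p$bi, rep(0, 3 * H))
  expect_equal(p$bh, rep(0, 3 * H))
  expect_true(all(abs(p$Wi) <= sqrt(6 / (2 + H))))
  expect_error(init_gru_esn(H, gain = -1), "gain")
})

test_that("the GRU step obeys its closed-form limits", {
  H <- 5
  zero <- structure(list(Wi = matrix(0, 3 * H, 2), Wh = matrix(0, 3 * H, H),
                         bi = rep(0, 3 * H), bh = rep(0, 3 * H), H = H),
                    class = "gru_params")
  z <- runif(H)
  ## all-zero parameters: u = 1/2, n = 0, so the state halves each step
  expect_equal(gru_step(zero, z, c(1, 0)), z / 2)
  ## a large update-gate bias forces u -> 1: perfect memory
  mem <- zero
  mem$bi[(H + 1):(2 * H)] <- 50
  expect_equal(gru_step(mem, z, c(0, 1)), z, tolerance = 1e-12)
})

test_that("compiled rollout matches the R reference step exactly", {
  set.seed(6)
  p <- init_gru_default(9)
  obs <- cbind(rbinom(40, 1, 0.2), rexp(40) * rbinom(40, 1, 0.3))
  Z <- gru_rollout(p, obs)
  z <- numeric(9)
  for (t in 1:40) {
    z <- gru_step(p, z, obs[t, ])
    expect_equal(Z[t, ], z, tolerance = 1e-12)
  }
  ## determinism and zero-parameter decay
  expect_identical(gru_rollout(p, obs), Z)
  zero <- list(Wi = p$Wi * 0, Wh = p$Wh * 0, bi = p$bi * 0, bh = p$bh * 0,
               H = 9L)
  Zd <- gru_rollout(structure(zero, class = "gru_params"), obs * 0,
                    z0 = rep(1, 9))
  expect_equal(Zd[40, ], rep(2^-40, 9), tolerance = 1e-9)
})

test_that("BPTT gradients match finite differences of the frozen-target loss", {
  set.seed(13)
  H <- 4
  p <- init_gru_default(H)
  w <- runif(H, -0.5, 0.5); w0 <- 0.2
  obs <- cbind(rbinom(25, 1, 0.25), rbinom(25, 1, 0.15))
  rew <- obs[, 2]
  gamma <- 0.93
  g <- beliefrnn:::cpp_gru_episode_grad(p$Wi, p$Wh, p$bi, p$bh, w, w0,
                                        obs, rew, gamma)
  ## semi-gradient = gradient of sum_t (y_t - V_t)^2 with targets y frozen
  ## at the base parameters
  value_seq <- function(par) {
    Z <- beliefrnn:::cpp_gru_forward(par$Wi, par$Wh, par$bi, par$bh, obs,
                                     rep(0, H))
    as.numeric(Z %*% par$w + par$w0)
  }
  base <- c(p, list(w = w, w0 = w0))
  V0 <- value_seq(base)
  y <- rew[-1] + gamma * V0[-1]
  loss_frozen <- function(par) {
    V <- value_seq(par)
    sum((y - V[-length(V)])^2)
  }
  eps <- 1e-6
  for (nm in c("Wi", "Wh", "bi", "bh", "w", "w0")) {
    target <- base[[nm]]
    picks <- sample(seq_along(target), min(6, length(target)))
    for (i in picks) {
      up <- base; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- base; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_frozen(up) - loss_frozen(dn)) / (2 * eps)
      ana <- if (nm == "w0") g$dw0 else g[[paste0("d", nm)]][i]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("untrained networks respond transiently to observations", {
  task <- cond_task("starkweather2")
  m <- value_rnn(task, H = 50, type = "untrained", seed = 5)
  s <- simulate(task, nsim = 50, seed = 6)
  Z <- representation(m, s)
  ## activity right after an odor deviates from the pre-odor baseline,
  ## then decays back toward it over the following null steps
  cues <- which(s$obs[, 1] > 0)
  cues <- cues[cues > 20 & cues < nrow(Z) - 15]
  jump <- mean(sqrt(rowSums((Z[cues + 1, ] - Z[cues - 1, ])^2)))
  settle <- mean(sqrt(rowSums((Z[cues + 6, ] - Z[cues + 5, ])^2)))
  expect_gt(jump, 3 * settle)
})
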
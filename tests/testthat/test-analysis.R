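test_that("representation noise has the stated per-unit scale and SNR", {
  expect_equal(noise_snr_db(0.05), -20 * log10(0.05))
  expect_equal(noise_snr_db(0.05), 26.02, tolerance = 1e-3)
  set.seed(3)
  Z <- matrix(rnorm(4000, sd = rep(c(1, 5), each = 2000)), 2000, 2)
  expect_equal(add_representation_noise(Z, g = 0), Z, ignore_attr = TRUE)
  Zn <- add_representation_noise(Z, g = 0.05, seed = 4)
  noise <- Zn - Z
  sds <- apply(Z, 2, sd)
  expect_equal(apply(noise, 2, sd), 0.05 * sds, tolerance = 0.1)
  ## zero-variance unit: no noise, with a warning
  Zc <- cbind(Z[, 1], 1)
  expect_warning(Zc_n <- add_representation_noise(Zc, g = 0.05), "zero-variance")
  expect_equal(Zc_n[, 2], rep(1, 2000), ignore_attr = TRUE)
})

test_that("belief regression attains its identity and null limits", {
  task <- cond_task("starkweather2")
  bm <- belief_model(task)
  s1 <- simulate(task, nsim = 60, seed = 1)
  s2 <- simulate(task, nsim = 60, seed = 2)
  B1 <- representation(bm, s1); B2 <- representation(bm, s2)
  ## beliefs regressed on themselves explain everything
  expect_equal(suppressWarnings(belief_r2(B1, B1, B2, B2)), 1,
               tolerance = 1e-8)
  ## pure noise explains (essentially) nothing held-out
  set.seed(5)
  N1 <- matrix(rnorm(nrow(B1) * 10), ncol = 10)
  N2 <- matrix(rnorm(nrow(B2) * 10), ncol = 10)
  expect_lt(belief_r2(N1, B1, N2, B2), 0.05)
  ## invariance to invertible affine reparameterisation of the features
  set.seed(6)
  A <- matrix(rnorm(100), 10, 10) + 5 * diag(10)
  r2_raw <- belief_r2(N1, B1, N2, B2)
  r2_aff <- belief_r2(N1 %*% A + 2, B1, N2 %*% A + 2, B2)
  expect_equal(r2_raw, r2_aff, tolerance = 1e-6)
})

test_that("the state decoder saturates on separable features and is chance on permuted labels", {
  set.seed(11)
  states <- sample(1:4, 3000, replace = TRUE)
  Z <- diag(4)[states, ] + matrix(rnorm(12000, sd = 0.01), ncol = 4)
  dec <- fit_state_decoder(Z[1:2000, ], states[1:2000])
  ll <- as.numeric(decoder_loglik(dec, Z[2001:3000, ], states[2001:3000]))
  expect_gt(ll, -0.1)   # near-perfect, bounded below 0 by the penalty
  expect_lte(ll, 0)
  ## permuted labels: held-out log-likelihood falls to chance, log(1/K)
  perm <- sample(states[1:2000])
  dec0 <- fit_state_decoder(Z[1:2000, ], perm)
  ll0 <- as.numeric(decoder_loglik(dec0, Z[2001:3000, ], states[2001:3000]))
  expect_equal(ll0, log(1 / 4), tolerance = 0.05)
})

test_that("uniform probabilities score log(1/K) and beliefs cap the decoder", {
  K <- 25
  states <- sample(1:K, 500, replace = TRUE)
  unif <- matrix(1 / K, 500, K)
  expect_equal(as.numeric(decoder_loglik(probs = unif, states_eval = states)),
               log(1 / K))
  ## belief ceiling on a Starkweather session: a decoder fit on the beliefs
  ## themselves cannot beat scoring the beliefs directly
  task <- cond_task("starkweather2")
  bm <- belief_model(task)
  s1 <- simulate(task, nsim = 150, seed = 3)
  s2 <- simulate(task, nsim = 150, seed = 4)
  B1 <- representation(bm, s1); B2 <- representation(bm, s2)
  ceiling_ll <- as.numeric(decoder_loglik(probs = B2, states_eval = s2$state))
  dec <- fit_state_decoder(B1, s1$state, K = K)
  dec_ll <- as.numeric(decoder_loglik(dec, B2, s2$state))
  expect_lte(dec_ll, ceiling_ll + 0.01)
})

test_that("PCA projection matches the SVD oracle and its invariances", {
  set.seed(21)
  ## rank-2 data: two components explain everything
  basis <- matrix(rnorm(20), 10, 2)
  Z <- matrix(rnorm(400), 200, 2) %*% t(basis)
  pr <- pca_project(Z, 2)
  expect_equal(sum(pr$explained), 1, tolerance = 1e-10)
  ## orthogonal rotation leaves explained fractions unchanged
  Q <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  pr_rot <- pca_project(Z %*% Q, 2)
  expect_equal(pr$explained, pr_rot$explained, tolerance = 1e-10)
  ## scores equal the eigendecomposition oracle up to sign
  Zf <- matrix(rnorm(600), 100, 6)
  pr2 <- pca_project(Zf, 3)
  Zc <- scale(Zf, center = TRUE, scale = FALSE)
  sv <- svd(Zc)
  oracle <- Zc %*% sv$v[, 1:3]
  for (j in 1:3) {
    expect_equal(abs(pr2$scores[, j]), abs(oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("untrained-RNN belief R2 is reproducible and in the reported range", {
  task <- cond_task("starkweather2")
  m <- value_rnn(task, H = 50, type = "untrained", seed = 1)
  r2a <- model_belief_r2(m, task, session_seed = 100, noise_seed = 200)
  r2b <- model_belief_r2(m, task, session_seed = 100, noise_seed = 200)
  expect_equal(r2a, r2b)
  expect_gt(r2a, 0.2); expect_lt(r2a, 0.6)
})
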
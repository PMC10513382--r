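test_that("LSTD recovers trivial and closed-form values", {
  set.seed(1)
  Z <- matrix(rnorm(600), 200, 3)
  ## zero rewards give exactly zero weights
  w <- lstd(Z, rep(0, 200), gamma = 0.9)
  expect_equal(w$w, rep(0, 3))
  expect_equal(w$w0, 0)
  ## one-hot features select the corresponding weight
  expect_equal(value_estimate(diag(3), w), rep(0, 3))
})

test_that("LSTD matches the closed-form value of a 2-state MRP", {
  ## column-stochastic P; reward R(s) received on leaving state s
  P <- matrix(c(0.7, 0.3,
                0.4, 0.6), 2, 2)  # P[to, from]
  R <- c(1, 0)
  gamma <- 0.9
  V_true <- mrp_value(P, R, gamma)
  set.seed(7)
  Tn <- 1e5
  s <- integer(Tn); s[1] <- 1L
  for (t in 2:Tn) s[t] <- sample(1:2, 1, prob = P[, s[t - 1]])
  ## reward on the transition out of s_t rides on observation row t+1
  r <- c(0, R[s[-Tn]])
  Z <- diag(2)[s, ]
  w <- suppressWarnings(lstd(Z, r, gamma))
  V_hat <- value_estimate(diag(2), w)
  expect_equal(V_hat, as.numeric(V_true), tolerance = 0.02)
  ## error shrinks with sample size (halves as T quadruples, within noise)
  w_small <- suppressWarnings(lstd(Z[1:6250, ], r[1:6250], gamma))
  err_small <- max(abs(value_estimate(diag(2), w_small) - V_true))
  err_big <- max(abs(V_hat - V_true))
  expect_lt(err_big, err_small)
})

test_that("batch TD(0) iteration on fixed features converges to LSTD", {
  P <- matrix(c(0.5, 0.5,
                0.2, 0.8), 2, 2)
  R <- c(0, 1); gamma <- 0.8
  set.seed(8)
  Tn <- 2000
  s <- integer(Tn); s[1] <- 1L
  for (t in 2:Tn) s[t] <- sample(1:2, 1, prob = P[, s[t - 1]])
  r <- c(0, R[s[-Tn]])
  Z <- cbind(diag(2)[s, ], 1)  # explicit intercept feature
  w_lstd <- suppressWarnings(lstd(Z[, 1:2], r, gamma))
  wv <- c(w_lstd$w, w_lstd$w0)
  ## batch semi-gradient TD(0) iteration with a fixed step size converges
  ## to the same fixed point as the closed-form LSTD solve
  w <- rep(0, 3)
  for (it in 1:20000) {
    v <- as.numeric(Z %*% w)
    delta <- r[-1] + gamma * v[-1] - v[-Tn]
    w <- w + 0.05 * crossprod(Z[-Tn, , drop = FALSE], delta)[, 1] / Tn
    if (sqrt(sum((w - wv)^2)) < 5e-4) break
  }
  expect_lt(sqrt(sum((w - wv)^2)), 1e-3)
})

test_that("TD errors behave in the myopic and perfect-value limits", {
  v <- c(1, 2, 3, 4)
  r <- c(0, 1, 0, 2)
  ## gamma = 0: delta_t = r_{t+1} - V_t
  expect_equal(td_errors(v, r, gamma = 0), r[-1] - v[-4])
  ## perfect values on a deterministic chain have zero TD error
  gamma <- 0.9
  rr <- c(0, 0, 0, 1)         # reward observed entering the final step
  vv <- c(gamma^2, gamma, 1, 0)  # value of the upcoming reward
  expect_equal(td_errors(vv, rr, gamma), rep(0, 3), tolerance = 1e-12)
  ## episode boundaries produce NA, not cross-episode bootstrap
  d <- td_errors(v, r, gamma = 0.5, episode = c(1, 1, 2, 2))
  expect_true(is.na(d[2]))
  expect_false(anyNA(d[-2]))
})

test_that("LSTD value weights on beliefs drive mean TD error to zero", {
  task <- cond_task("starkweather1")
  bm <- belief_model(task)
  s <- simulate(task, nsim = 2000, seed = 12)
  B <- representation(bm, s)
  tr <- rpe_trace(bm, s, Z = B)
  m <- mean(tr$delta, na.rm = TRUE)
  se <- sd(tr$delta, na.rm = TRUE) / sqrt(sum(!is.na(tr$delta)))
  expect_lt(abs(m), 3 * se + 1e-10)
})

test_that("belief-model reward-step RPEs trend oppositely across tasks", {
  ## RPE at the reward decreases with reward time in Task 1 (hazard grows)
  ## and increases in Task 2 (omission uncertainty resolves)
  for (tid in c("starkweather1", "starkweather2")) {
    task <- cond_task(tid)
    bm <- belief_model(task)
    s <- simulate(task, nsim = 4000, seed = 33)
    tr <- rpe_trace(bm, s, Z = representation(bm, s))
    ok <- !is.na(tr$reward_step_delta)
    mean_by_isi <- tapply(tr$reward_step_delta[ok], tr$isi[ok], mean)
    expect_length(mean_by_isi, 9)
    rho <- cor(as.numeric(names(mean_by_isi)), mean_by_isi,
               method = "spearman")
    if (tid == "starkweather1") expect_lt(rho, 0) else expect_gt(rho, 0)
  }
})

test_that("rpe_mse is a proper squared discrepancy on rewarded trials", {
  task <- cond_task("starkweather2")
  bm <- belief_model(task)
  s <- simulate(task, nsim = 200, seed = 9)
  tr <- rpe_trace(bm, s, Z = representation(bm, s))
  expect_equal(rpe_mse(tr, tr), 0)
  ## constant shift on rewarded trials gives c^2
  tr2 <- tr
  tr2$reward_step_delta <- tr$reward_step_delta + 0.3
  expect_equal(rpe_mse(tr, tr2), 0.09, tolerance = 1e-12)
  expect_equal(rpe_mse(tr2, tr), 0.09, tolerance = 1e-12)  # symmetric
})
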
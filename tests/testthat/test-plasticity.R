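test_that("log-likelihood of a target pattern behaves as a logistic model", {
  p <- snn_params(N = 1, T = 2, v_th = 0, dv = 0.5)
  # at threshold every outcome has probability 1/2
  expect_equal(log_likelihood(matrix(c(0, 1), 1), matrix(0, 1, 2), p),
               log(0.5))
  expect_equal(log_likelihood(matrix(c(0, 0), 1), matrix(0, 1, 2), p),
               log(0.5))
  # a comfortably satisfied pattern has likelihood ~ 1
  p2 <- snn_params(N = 2, T = 6, v_th = 0, dv = 0.1)
  s <- rbind(rep(1, 6), rep(0, 6))
  v <- rbind(rep(10 * 0.1, 6), rep(-10 * 0.1, 6))
  expect_gt(log_likelihood(s, v, p2), -2 * 5 * 1e-4 * 10)
  expect_lt(log_likelihood(s, v, p2), 0)
  # definitional decomposition into per-slot spike probabilities
  set.seed(2)
  s <- matrix(rbinom(12, 1, 0.5), 2, 6)
  v <- matrix(rnorm(12), 2, 6)
  manual <- 0
  for (t in 1:5) manual <- manual +
    sum(log(spike_probability(v[, t], s[, t + 1], p2)))
  expect_equal(log_likelihood(s, v, p2), manual)
  expect_error(log_likelihood(s, v, p2, dv = 0), "dv")
})

test_that("cuBa eligibility trace equals the finite-difference membrane derivative", {
  expect_equal(eligibility_step(0, 0, snn_params(N = 1, T = 2, tau_m = 2)), 0)
  expect_equal(eligibility_step(0, 1, snn_params(N = 1, T = 2, tau_m = 2)),
               0.5)
  p <- snn_params(N = 3, T = 10, tau_m = 4, tau_s = 2, v_rest = -1,
                  v0 = -0.5, J_res = 2)
  set.seed(21)
  J <- matrix(rnorm(9, 0, 0.5), 3, 3)
  s_targ <- matrix(rbinom(30, 1, 0.4), 3, 10)
  I <- matrix(rnorm(30), 3, 10)
  run_v <- function(J) run_trial(J, I, mode = "clamped", s_clamp = s_targ,
                                 params = p)$v
  tr <- numeric(3)
  shat <- s_targ[, 1]
  eps <- 1e-6
  for (tau in 1:9) {
    tr <- eligibility_step(tr, shat, p)        # dv^{tau+1}/dJ_{.k}
    shat <- filter_spikes(shat, s_targ[, tau + 1], p$tau_s, p$dt)
    for (i in 1:3) for (k in 1:3) {
      Jp <- J; Jp[i, k] <- Jp[i, k] + eps
      Jm <- J; Jm[i, k] <- Jm[i, k] - eps
      fd <- (run_v(Jp)[i, tau + 1] - run_v(Jm)[i, tau + 1]) / (2 * eps)
      expect_equal(tr[k], fd, tolerance = 1e-4)
    }
  }
})

test_that("coBa eligibility: zero driving force and pure decay limits", {
  p <- snn_params(N = 2, T = 5, tau_m = 4, model = "coba", E_exc = 5,
                  E_inh = -8, exc = c(TRUE, FALSE))
  P0 <- matrix(0.4, 2, 2)
  # at v = E_exc the excitatory increment vanishes (zero driving force)
  up <- eligibility_step_coba(P0, P0, c(1, 0), c(0, 0), rep(5, 2),
                              matrix(0, 2, 2), p)
  expect_equal(up$p_exc, P0 * (1 - 0.25))
  # all filtered spikes zero: pure decay by (1 - dt/tau_m)
  up0 <- eligibility_step_coba(P0, P0, c(0, 0), c(0, 0), rep(0, 2),
                               matrix(0.5, 2, 2), p)
  expect_equal(up0$p_exc, P0 * 0.75)
  expect_equal(up0$p_inh, P0 * 0.75)
})

test_that("error signal: ternary spike form, graded voltage form", {
  p <- snn_params(N = 3, T = 5, v_th = 0, dv = 0.2)
  expect_equal(error_signal("spike", c(1, 0, 1), c(1, 0, 0), params = p),
               c(0, 0, 1))
  expect_equal(error_signal("voltage", 1, v = 0, params = p), 0.5)
  e <- error_signal("voltage", 0, v = 5, params = p)
  expect_lt(e, -0.99)
  expect_gt(e, -1)
  # spike error from thresholding the membrane directly
  expect_equal(error_signal("spike", c(1, 1, 0), v = c(1, -1, 1), params = p),
               c(0, 1, -1))
  expect_error(error_signal("voltage", 1, v = 0, params = p, dv = 0), "dv")
})

test_that("exact replay is a fixed point of the spike rule", {
  p <- snn_params(N = 30, T = 40, tau_m = 4, tau_s = 2, v_rest = -1,
                  v0 = -0.5, J_res = 5)
  sc <- self_consistent_bundle(31, p)
  ctl <- learn_control("spike", "batch", "plain", eta0 = 1)
  dJ <- weight_update_batch(sc$s_targ, sc$I, sc$J, ctl, p)
  expect_equal(max(abs(dJ)), 0)
  # online updates also leave the weights unchanged
  res <- weight_update_online(sc$s_targ, sc$I, sc$J, ctl, p)
  expect_equal(res$J, sc$J)
  expect_equal(res$delta_s, 0)
  # and generation from the trial's initial frame replays exactly
  gen <- run_trial(sc$J, sc$I, mode = "generation", params = p,
                   s_init = sc$s_targ[, 1])
  expect_equal(spike_mismatch(sc$s_targ, gen$raster), 0)
})

test_that("batch update rows carry the Kronecker-delta locality structure", {
  p <- snn_params(N = 4, T = 12, tau_m = 4, tau_s = 2, v_rest = -1,
                  v0 = -0.5, J_res = 2, dv = 0.4)
  set.seed(41)
  J <- matrix(rnorm(16, 0, 0.4), 4, 4)
  s_targ <- matrix(rbinom(48, 1, 0.4), 4, 12)
  I <- matrix(rnorm(48), 4, 12)
  ctl <- learn_control("voltage", "batch", "plain", eta0 = 1, dv = 0.4)
  dJ <- weight_update_batch(s_targ, I, J, ctl, p)
  # independent reconstruction: err_i^t (x) p^t summed over the trial
  tr <- run_trial(J, I, mode = "clamped", s_clamp = s_targ, params = p)
  pvec <- numeric(4); shat <- s_targ[, 1]
  want <- matrix(0, 4, 4)
  for (tau in 1:11) {
    err <- error_signal("voltage", s_targ[, tau + 1], v = tr$v[, tau],
                        params = p, dv = 0.4)
    want <- want + err %o% pvec        # p^tau pairs with the error at tau
    pvec <- eligibility_step(pvec, shat, p)
    shat <- filter_spikes(shat, s_targ[, tau + 1], p$tau_s, p$dt)
  }
  expect_equal(dJ, want, tolerance = 1e-10)
})

test_that("summed online updates approach the batch update as the step shrinks", {
  p <- snn_params(N = 8, T = 25, tau_m = 4, tau_s = 2, v_rest = -1,
                  v0 = -0.5, J_res = 3, dv = 0.3)
  set.seed(51)
  J <- matrix(rnorm(64, 0, 0.4), 8, 8)
  s_targ <- matrix(rbinom(200, 1, 0.3), 8, 25)
  I <- matrix(rnorm(200), 8, 25)
  batch_dir <- weight_update_batch(s_targ, I, J,
    learn_control("voltage", "batch", "plain", eta0 = 1, dv = 0.3), p)
  dev <- sapply(c(1e-3, 1e-4, 1e-5), function(e0) {
    ctl <- learn_control("voltage", "online", "plain", eta0 = e0, dv = 0.3)
    res <- weight_update_online(s_targ, I, J, ctl, p)
    total <- (res$J - J) / e0
    sqrt(sum((total - batch_dir)^2)) / sqrt(sum(batch_dir^2))
  })
  expect_true(all(diff(dev) < 0))
})

test_that("Adam steps: first step, sign limit, zero gradient", {
  opt <- adam_init(c(2, 2))
  st <- adam_step(opt, matrix(0, 2, 2), eta0 = 0.1)
  expect_equal(st$update, matrix(0, 2, 2))
  g <- matrix(c(0.3, -2, 5e-3, 1), 2, 2)
  st <- adam_step(adam_init(c(2, 2)), g, eta0 = 0.1)
  expect_equal(st$update, 0.1 * g / (abs(g) + 1e-8), tolerance = 1e-6)
  # constant gradient: step magnitude converges to eta0 * sign(g)
  opt2 <- adam_init(c(2, 2))
  for (i in 1:3000) { tmp <- adam_step(opt2, g, eta0 = 0.1); opt2 <- tmp$opt }
  expect_equal(tmp$update, 0.1 * sign(g), tolerance = 1e-3)
})

test_that("Dale projection conserves synapse signs through an update", {
  p <- snn_params(N = 6, T = 10, model = "coba",
                  exc = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  set.seed(61)
  J <- matrix(rnorm(36), 6, 6)
  Jd <- apply_dale(J, p)
  expect_true(all(Jd[, 1:3] >= 0))
  expect_true(all(Jd[, 4:6] <= 0))
  # training a coBa net keeps the constraint after every presentation
  p2 <- snn_params(N = 6, T = 15, tau_m = 3, tau_s = 2, v_rest = -1,
                   v0 = -0.5, J_res = 2, model = "coba", E_exc = 5,
                   E_inh = -8, exc = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                   eta0 = 0.1)
  s_targ <- matrix(rbinom(90, 1, 0.3), 6, 15)
  I <- matrix(rnorm(90), 6, 15)
  ctl <- learn_control("spike", "online", "plain", eta0 = 0.1)
  J <- apply_dale(matrix(rnorm(36, 0, 0.3), 6, 6), p2)
  for (it in 1:5) {
    J <- weight_update_online(s_targ, I, J, ctl, p2)$J
    expect_true(all(J[, 1:3] >= 0) && all(J[, 4:6] <= 0))
  }
})
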
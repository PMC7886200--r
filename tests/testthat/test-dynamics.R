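test_that("synaptic filter has the right fixed points and step response", {
  expect_equal(filter_spikes(0, 0, tau = 2, dt = 1), 0)
  expect_equal(filter_spikes(1, 1, tau = 5, dt = 1), 1)
  expect_equal(filter_spikes(0, 1, tau = 2, dt = 1), 0.5)
  # vectorized, stays in [0, 1] for binary input over long runs
  sh <- rep(0.3, 4)
  set.seed(1)
  for (t in 1:200) {
    sh <- filter_spikes(sh, rbinom(4, 1, 0.5), tau = 3, dt = 1)
    expect_true(all(sh >= 0 & sh <= 1))
  }
  expect_error(filter_spikes(0, 1, tau = 0.5, dt = 1), "tau")
})

test_that("cuBa membrane step: rest fixed point, reset, geometric charging", {
  p <- snn_params(N = 3, T = 10, tau_m = 5, tau_s = 2, v_rest = -4,
                  J_res = 20)
  st <- snn_state(rep(-4, 3), rep(0, 3))
  expect_equal(membrane_step_cuba(st, rep(0, 3), matrix(0, 3, 3), p),
               rep(-4, 3))
  # subtractive reset dominates after a spike
  p0 <- snn_params(N = 1, T = 10, tau_m = 5, tau_s = 2, v_rest = 0,
                   J_res = 20)
  st <- snn_state(0, 1, 0)
  expect_equal(membrane_step_cuba(st, 0, matrix(0, 1, 1), p0), -20)
  # leaky integrator converges to a constant input
  v <- 0
  for (t in 1:400) {
    st <- snn_state(v, 0, 0)
    v <- membrane_step_cuba(st, 3, matrix(0, 1, 1), p0)
  }
  expect_equal(v, 3, tolerance = 1e-10)
  expect_error(membrane_step_cuba(snn_state(0, 0), rep(0, 2),
                                  matrix(0, 1, 1), p0), "length")
})

test_that("coBa membrane step: driving-force structure", {
  p <- snn_params(N = 2, T = 10, tau_m = 2, tau_s = 2, v_rest = 0,
                  v_th = 0, J_res = 20, model = "coba", E_exc = 5,
                  E_inh = -8, exc = c(TRUE, FALSE))
  # at the excitatory reversal potential the excitatory drive vanishes
  st <- snn_state(rep(5, 2), rep(0, 2), c(1, 0))
  J_exc <- matrix(c(0, 1, 0, 0), 2, 2)  # synapse 2 <- 1
  v1 <- membrane_step_coba(st, rep(0, 2), J_exc, matrix(0, 2, 2), p)
  v_leak <- (1 - 0.5) * 5 + 0.5 * 0   # pure leak toward v_rest = 0
  expect_equal(v1, rep(v_leak, 2))
  # with all filtered spikes zero it reduces to the cuBa leak
  st0 <- snn_state(c(2, -3), rep(0, 2), rep(0, 2))
  expect_equal(membrane_step_coba(st0, rep(0, 2), J_exc, matrix(0, 2, 2), p),
               (1 - 0.5) * c(2, -3))
  # single excitatory synapse, hand evaluation: v' = 2.5 w
  w <- 0.7
  st <- snn_state(rep(0, 2), rep(0, 2), c(1, 0))
  Jw <- matrix(c(0, w, 0, 0), 2, 2)
  v2 <- membrane_step_coba(st, rep(0, 2), Jw, matrix(0, 2, 2), p)
  expect_equal(v2[2], 2.5 * w)
})

test_that("spike probability is a logistic law with its symmetries", {
  p <- snn_params(N = 1, T = 10, v_th = 0, dv = 0.5)
  expect_equal(spike_probability(0, 1, p), 0.5)
  expect_equal(spike_probability(0, 0, p), 0.5)
  expect_equal(spike_probability(0.5 * log(3), 1, p), 0.75)
  v <- seq(-3, 3, length.out = 11)
  expect_equal(spike_probability(v, rep(1, 11), p) +
                 spike_probability(v, rep(0, 11), p), rep(1, 11))
  p0 <- snn_params(N = 1, T = 10, dv = 0)
  expect_error(spike_probability(0, 1, p0), "deterministic")
})

test_that("deterministic spiking is the small-noise limit of the logistic law", {
  p <- snn_params(N = 1, T = 10, v_th = 0.3)
  expect_equal(generate_spikes_deterministic(-0.7, p), 0)
  expect_equal(generate_spikes_deterministic(1.3, p), 1)
  expect_equal(generate_spikes_deterministic(0.3, p), 0)  # tie: no spike
  ptiny <- snn_params(N = 1, T = 10, v_th = 0.3, dv = 1e-6)
  vg <- setdiff(seq(-1, 1, by = 0.05), 0.3)
  for (v in vg) {
    map <- as.numeric(spike_probability(v, 1, ptiny) >
                        spike_probability(v, 0, ptiny))
    expect_equal(map, generate_spikes_deterministic(v, p))
  }
})

test_that("run_trial matches a hand-unrolled oracle in every mode", {
  p <- snn_params(N = 5, T = 30, tau_m = 4, tau_s = 2, v_rest = -2,
                  v0 = -0.5, J_res = 6)
  set.seed(7)
  J <- matrix(rnorm(25, 0, 0.8), 5, 5)
  I <- matrix(rnorm(5 * 30, 0, 2.5), 5, 30)
  s_clamp <- matrix(rbinom(5 * 30, 1, 0.3), 5, 30)

  for (mode in c("clamped", "generation", "open_loop")) {
    got <- run_trial(J, I, mode = mode, params = p,
                     s_clamp = if (mode == "clamped") s_clamp else NULL,
                     s_init = s_clamp[, 1])
    want <- oracle_trial_cuba(J, I, p, mode = mode,
                              s_clamp = if (mode == "clamped") s_clamp,
                              s_init = s_clamp[, 1])
    expect_equal(got$raster, want$raster, info = mode)
    expect_equal(got$v, want$v, tolerance = 1e-12, info = mode)
  }
  # tiny N = 2, T = 5 clamped case, fully explicit
  p2 <- snn_params(N = 2, T = 5, tau_m = 2, tau_s = 2, v_rest = 0,
                   v0 = 0, J_res = 1)
  J2 <- matrix(c(0, 1, -1, 0), 2, 2)
  I2 <- matrix(0, 2, 5)
  sc <- rbind(c(1, 0, 1, 0, 0), c(0, 1, 0, 0, 1))
  got <- run_trial(J2, I2, mode = "clamped", s_clamp = sc, params = p2)
  want <- oracle_trial_cuba(J2, I2, p2, mode = "clamped", s_clamp = sc)
  expect_equal(got$v, want$v, tolerance = 1e-14)

  expect_error(run_trial(J, I, mode = "clamped", params = p), "s_clamp")
})

test_that("coBa trial agrees with the conductance oracle", {
  p <- snn_params(N = 4, T = 20, tau_m = 4, tau_s = 2, v_rest = -1,
                  v0 = -0.5, J_res = 3, model = "coba", E_exc = 5,
                  E_inh = -8, exc = c(TRUE, TRUE, FALSE, FALSE))
  set.seed(11)
  mag <- matrix(abs(rnorm(16, 0, 0.5)), 4, 4)
  J <- mag * rep(c(1, 1, -1, -1), each = 4)
  I <- matrix(rnorm(4 * 20, 0, 2), 4, 20)
  tr <- run_trial(J, I, mode = "generation", params = p)
  # independent recomputation, explicit driving-force loop
  a <- p$dt / p$tau_m; b <- p$dt / p$tau_s
  v <- rep(p$v0, 4); s <- rep(0, 4); sh <- rep(0, 4)
  for (t in 2:20) {
    s_next <- as.numeric(v > p$v_th)
    vn <- numeric(4)
    for (i in 1:4) {
      ge <- sum(pmax(J[i, ], 0) * sh * p$exc)
      gi <- sum(pmax(-J[i, ], 0) * sh * !p$exc)
      vn[i] <- (1 - a) * v[i] + a * (I[i, t] + p$v_rest) +
        a * ((p$E_exc - v[i]) * ge + (p$E_inh - v[i]) * gi) -
        p$J_res * s[i]
    }
    s <- s_next; sh <- (1 - b) * sh + b * s; v <- vn
    expect_equal(tr$v[, t], v, tolerance = 1e-12)
    expect_equal(tr$raster[, t], s)
  }
})

test_that("with zero input the membrane relaxes monotonically to rest", {
  p <- snn_params(N = 1, T = 200, tau_m = 6, tau_s = 2, v_rest = -4,
                  v0 = -0.5)
  tr <- run_trial(matrix(0, 1, 1), NULL, mode = "generation", params = p)
  expect_equal(sum(tr$raster), 0)
  dv <- diff(tr$v[1, ])
  expect_true(all(dv <= 1e-12))
  expect_equal(tr$v[1, 200], -4, tolerance = 1e-9)
})
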
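test_that("few-presentations experiment: online beats batch, no learning at eta0 = 0", {
  p <- task_params("few_presentations", N = 250)
  ex <- run_few_presentations_experiment(n_realizations = 3,
                                         max_presentations = 25, seed = 7,
                                         params = p)
  expect_s3_class(ex, "few_presentations_experiment")
  expect_equal(nrow(ex$counts), 6)
  on <- ex$counts$presentations[ex$counts$schedule == "online"]
  ba <- ex$counts$presentations[ex$counts$schedule == "batch"]
  expect_true(all(is.finite(on)))
  # the online approximation needs fewer presentations on average
  expect_lt(mean(on), mean(ifelse(is.na(ba), 25, ba)))
  # with a zero learning rate the criterion is never reached
  p0 <- task_params("few_presentations", N = 250, eta0 = 0)
  ex0 <- run_few_presentations_experiment(n_realizations = 1,
                                          max_presentations = 5, seed = 7,
                                          params = p0, schedules = "online")
  expect_true(is.na(ex0$counts$presentations))
})

test_that("noise robustness: zero noise recovers training-time retrieval, degradation is monotone", {
  p <- task_params("trajectory3d", N = 250, T = 400)
  y <- sample_trajectory(seed = 95, T = p$T, dt = p$dt)
  fit <- fit_snn(y, p, learn_control("voltage", "online", "plain", dv = 0.05,
                                     readout = "adam"),
                 iterations = 150, seed = 95, eval_every = 150)
  ex <- run_noise_experiment(fit, noise_ratios = c(0, 0.02, 0.5),
                             n_realizations = 6, seed = 2)
  # grid point 0 reproduces the final training evaluation bit-for-bit
  expect_equal(ex$mse_mean[1], tail(fit$history$mse, 1))
  expect_equal(ex$mse_sd[1], 0)
  expect_equal(ex$ds_mean[1], tail(fit$history$delta_s_gen, 1))
  # paired noise draws: mean raster corruption grows with the noise ratio
  expect_true(all(diff(ex$ds_mean) > 0))
  expect_gt(ex$mse_mean[3], ex$mse_mean[1])
})

test_that("voltage-rule margins confer noise robustness the spike rule lacks", {
  # full published network size: the margin effect needs a well-trained net
  p <- task_params("trajectory3d")
  y <- sample_trajectory(seed = 96, T = p$T, dt = p$dt)
  fit_v <- fit_snn(y, p, learn_control("voltage", "online", "plain",
                                       dv = 0.05, readout = "adam"),
                   iterations = 300, seed = 96, eval_every = 300)
  fit_s <- fit_snn(y, p, learn_control("spike", "online", "plain",
                                       readout = "adam"),
                   iterations = 300, seed = 96, eval_every = 300)
  rv <- run_noise_experiment(fit_v, noise_ratios = c(0.01, 0.1),
                             n_realizations = 6, seed = 3)
  rs <- run_noise_experiment(fit_s, noise_ratios = c(0.01, 0.1),
                             n_realizations = 6, seed = 3)
  # at a 1% variance ratio the voltage-trained network still completes the
  # task while the spike-trained one has already failed
  expect_lt(rv$mse_mean[1], 0.01)
  expect_gt(rs$mse_mean[1], 10 * rv$mse_mean[1])
  expect_lt(rv$ds_mean[1], rs$ds_mean[1])
  # and it remains no worse at a 10% ratio
  expect_lt(rv$mse_mean[2], rs$mse_mean[2])
})

test_that("temporal XOR: targets encode the answer and replay covers the supported slots", {
  p <- task_params("xor")
  ex <- run_xor_experiment(iterations = 200, seed = 23)
  expect_s3_class(ex, "xor_experiment")
  expect_equal(ex$true_sign, c(-1, 1, 1, -1))
  expect_length(ex$outputs, 4)
  # the converged readout classifies every TARGET raster correctly
  set.seed(23)
  task <- make_xor_task(T = p$T)
  J_in <- make_projection(p$N, 1, p$sigma_in)
  J_teach <- make_projection(p$N, 1, p$sigma_teach)
  bundles <- lapply(task$conditions, function(cc)
    build_target(list(J_in = J_in, J_teach = J_teach), cc$x, cc$y_targ, p))
  win <- task$response_window[1]:task$response_window[2]
  targ_amp <- sapply(bundles, function(b)
    mean((ex$J_out %*% filter_raster(b$s_targ, p$tau_rout, p$dt))[, win]))
  expect_equal(sign(targ_amp), ex$true_sign)
  expect_true(all(abs(targ_amp) > 0.25))
  # the trained network replays all causally supported target slots
  # (residual mismatch = the teacher-driven response spikes whose silent
  # pre-window gap leaves them without presynaptic support; see vignette)
  expect_true(all(ex$delta_s < 0.01))
  # readout-only ablation: with recurrence-free targets the input current
  # already reproduces the input-driven slots, so the ablation matches the
  # trained network everywhere except recurrent-context slots -- recurrent
  # training is never worse (the decisive response slots are unsupported
  # for both; see vignette)
  exa <- run_xor_experiment(iterations = 200, seed = 23,
                            train_recurrent = FALSE)
  expect_gte(mean(exa$delta_s), mean(ex$delta_s) - 1e-9)
})

test_that("trajectory experiment aggregates realizations reproducibly", {
  p <- task_params("trajectory3d", N = 150, T = 300)
  ex <- run_trajectory_experiment(iterations = 30, n_realizations = 2,
                                  seed = 4, params = p, eval_every = 10)
  expect_s3_class(ex, "trajectory_experiment")
  expect_length(ex$final_mse, 2)
  expect_equal(unique(ex$curves$realization), 1:2)
  ex2 <- run_trajectory_experiment(iterations = 30, n_realizations = 2,
                                   seed = 4, params = p, eval_every = 10)
  expect_identical(ex$final_mse, ex2$final_mse)
})
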
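#' Trajectory-generation experiment
#'
#' Full pipeline for the multidimensional trajectory task: sample a random
#' target trajectory, build its internal target spike pattern, train the
#' recurrent weights and the readout, and track generation-mode MSE over
#' presentations. Defaults reproduce the published 3D setup (N = 500,
#' T = 1000 steps, voltage-dependent rule at `dv = 0.2`, plain per-timestep
#' updates at step `eta0 = 0.5`, readout trained through Adam).
#'
#' @param iterations Training presentations per realization.
#' @param n_realizations Independent target/projection realizations.
#' @param seed Base seed; realization `r` uses `seed * 1000 + r`.
#' @param params An [snn_params()] object.
#' @param control A [learn_control()] object; the default is the headline
#'   voltage-rule plain-online configuration with the Adam-trained readout.
#' @param eval_every Evaluation cadence (forwarded to [fit_snn()]).
#' @param clock_channels Clock channels.
#' @param verbose Progress output.
#' @return A list of class `trajectory_experiment`: `fits` (one `snn_fit`
#'   per realization), `curves` (stacked history data frame with a
#'   `realization` column), and `final_mse` (vector).
#' @export
run_trajectory_experiment <- function(iterations = 1000, n_realizations = 1,
                                      seed = 1,
                                      params = task_params("trajectory3d"),
                                      control = NULL, eval_every = 1,
                                      clock_channels = 10, verbose = FALSE) {
  if (is.null(control))
    control <- learn_control("voltage", "online", "plain", dv = 0.2,
                             readout = "adam")
  fits <- vector("list", n_realizations)
  curves <- list()
  for (r in seq_len(n_realizations)) {
    sr <- (seed %% 2000000) * 1000 + r
    y <- sample_trajectory(seed = sr, T = params$T, dt = params$dt)
    fits[[r]] <- fit_snn(y, params, control, iterations = iterations,
                         clock_channels = clock_channels, seed = sr,
                         eval_every = eval_every, verbose = verbose)
    h <- fits[[r]]$history
    h$realization <- r
    curves[[r]] <- h
    if (any(!is.finite(h$mse)))
      warning(sprintf("realization %d: non-finite MSE (divergence)", r))
  }
  curves <- do.call(rbind, curves)
  structure(list(fits = fits, curves = curves,
                 final_mse = vapply(fits, function(f)
                   utils::tail(f$history$mse, 1), numeric(1)),
                 seed = seed),
            class = "trajectory_experiment")
}

#' @export
print.trajectory_experiment <- function(x, ...) {
  cat(sprintf("Trajectory experiment: %d realization(s)\n", length(x$fits)))
  cat(sprintf("  final generation MSE: %s (mean %.5f)\n",
              paste(sprintf("%.5f", x$final_mse), collapse = ", "),
              mean(x$final_mse)))
  invisible(x)
}

#' Few-presentations experiment (batch vs online)
#'
#' Short-trajectory task: a 50-step target is learned with the
#' spike-dependent rule and plain gradient steps, comparing the standard
#' batch gradient ascent against its per-timestep online approximation. For
#' each realization the generation MSE is tracked per presentation and the
#' number of presentations needed to fall below the criterion is recorded.
#' The readout is the converged least-squares decoder of the frozen target
#' raster, so the measured quantity is recurrent-learning speed.
#'
#' @param n_realizations Number of independent realizations.
#' @param max_presentations Presentations to run per schedule.
#' @param criterion MSE threshold defining success.
#' @param seed Base seed.
#' @param params An [snn_params()] object (the published short-trial column
#'   by default: T = 50, tau_m = 2 ms, tau_s = 1.25 ms, eta0 = 1, no Adam).
#' @param schedules Character vector among `"online"`, `"batch"`.
#' @param clock_channels Clock channels.
#' @return A list of class `few_presentations_experiment`: `counts` (data
#'   frame with `realization`, `schedule`, `presentations`; `NA` when the
#'   criterion was never reached), and `curves` (per-presentation MSE).
#' @export
run_few_presentations_experiment <- function(n_realizations = 10,
                                             max_presentations = 30,
                                             criterion = 0.01, seed = 1,
                                             params = task_params("few_presentations"),
                                             schedules = c("online", "batch"),
                                             clock_channels = 10) {
  counts <- list(); curves <- list()
  for (r in seq_len(n_realizations)) {
    sr <- (seed %% 2000000) * 1000 + r
    set.seed(sr)
    y <- sample_trajectory(T = params$T, dt = params$dt, duration = 1)
    clock <- make_clock(clock_channels, params$T)
    J_in <- make_projection(params$N, clock_channels, params$sigma_in)
    J_teach <- make_projection(params$N, nrow(y), params$sigma_teach)
    bundle <- build_target(list(J_in = J_in, J_teach = J_teach), clock, y,
                           params)
    for (sch in schedules) {
      ctl <- learn_control("spike", sch, "plain", readout = "lsq")
      fit <- train_snn_core(bundle, y, params, ctl,
                            iterations = max_presentations)
      h <- fit$history
      hit <- which(h$mse < criterion)
      counts[[length(counts) + 1]] <-
        data.frame(realization = r, schedule = sch,
                   presentations = if (length(hit)) h$iteration[hit[1]]
                                   else NA_integer_)
      h$realization <- r; h$schedule <- sch
      curves[[length(curves) + 1]] <- h
    }
  }
  structure(list(counts = do.call(rbind, counts),
                 curves = do.call(rbind, curves),
                 criterion = criterion, seed = seed),
            class = "few_presentations_experiment")
}

#' @export
print.few_presentations_experiment <- function(x, ...) {
  cat(sprintf("Few-presentations experiment (criterion MSE < %g)\n",
              x$criterion))
  agg <- stats::aggregate(presentations ~ schedule, data = x$counts,
                          FUN = function(z) mean(z, na.rm = TRUE),
                          na.action = stats::na.pass)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-7s mean presentations to criterion: %.2f\n",
                agg$schedule[i], agg$presentations[i]))
  invisible(x)
}

#' Noise-robustness experiment
#'
#' Evaluates a trained network under Gaussian perturbation of the clock
#' signal, `I_clock = J_in (x + sigma_noise * xi)`, across a grid of
#' variance ratios `sigma^2_noise / sigma^2_clock`. Noise draws are paired
#' across grid points (same seeds), so expected MSE and raster mismatch are
#' non-decreasing along the grid.
#'
#' @param fit A trained `snn_fit`.
#' @param noise_ratios Grid of variance ratios (include 0 to recover the
#'   noise-free retrieval).
#' @param n_realizations Noise draws per grid point.
#' @param seed Base seed.
#' @return A data frame of class `noise_experiment` with one row per grid
#'   point: mean and sd of MSE and of the spike mismatch `delta_s`.
#' @export
run_noise_experiment <- function(fit, noise_ratios = c(0, 0.01, 0.1),
                                 n_realizations = 25, seed = 1) {
  rows <- lapply(noise_ratios, function(rho) {
    m <- numeric(n_realizations); d <- numeric(n_realizations)
    for (j in seq_len(n_realizations)) {
      ev <- predict(fit, noise_ratio = rho, type = "both",
                    seed = (seed %% 200000) * 10000 + j)
      m[j] <- ev$mse; d[j] <- ev$delta_s
    }
    data.frame(noise_ratio = rho, mse_mean = mean(m), mse_sd = stats::sd(m),
               ds_mean = mean(d), ds_sd = stats::sd(d),
               n = n_realizations)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("noise_experiment", "data.frame")
  out
}

#' Temporal XOR experiment
#'
#' Trains one network on the four input conditions of the temporal XOR task,
#' processing one sequence at a time in random order. Each condition has its
#' own frozen internal target raster (built from the condition's input pulses
#' plus the projected target response); the readout is trained across all
#' four. At retrieval the decoded output inside the response window is
#' classified by its sign.
#'
#' @param iterations Training sweeps (each sweep presents the 4 conditions
#'   once, in random order).
#' @param seed Integer seed.
#' @param params An [snn_params()] object (published XOR column by default).
#' @param control A [learn_control()] object; defaults to the spike rule
#'   with plain per-timestep updates and the converged least-squares
#'   readout of the four target rasters (the limit of the delta rule).
#' @param task An [make_xor_task()] definition.
#' @param train_recurrent Set `FALSE` for the readout-only ablation.
#' @return A list of class `xor_experiment`: per-condition decoded outputs,
#'   predicted and expected signs, window amplitudes, `accuracy`, and
#'   `success` (all four correct).
#' @details A structural caveat documented in the methods vignette: with
#'   targets built recurrence-free, the teacher-driven response spikes sit
#'   after a silent gap longer than the membrane memory, so the replayed
#'   raster typically omits them and the decoded window amplitude is
#'   near zero -- inspect `amplitude` before trusting `accuracy`.
#' @export
run_xor_experiment <- function(iterations = 400, seed = 1,
                               params = task_params("xor"), control = NULL,
                               task = NULL, train_recurrent = TRUE) {
  if (is.null(control))
    control <- learn_control("spike", "online", "plain", readout = "lsq")
  control <- resolve_control(control, params)
  if (control$rule == "voltage" && control$dv <= 0) control$dv <- 0.2
  if (is.null(task)) task <- make_xor_task(T = params$T)
  set.seed(seed)
  N <- params$N; D <- 1L
  J_in <- make_projection(N, 1, params$sigma_in)
  J_teach <- make_projection(N, D, params$sigma_teach)
  bundles <- lapply(task$conditions, function(cc)
    build_target(list(J_in = J_in, J_teach = J_teach), cc$x, cc$y_targ,
                 params))
  J <- matrix(0, N, N); J_out <- matrix(0, D, N)
  st <- list(mJ = matrix(0, N, N), vJ = matrix(0, N, N), tJ = 0,
             mO = matrix(0, D, N), vO = matrix(0, D, N), tO = 0)
  if (control$readout == "lsq") {
    SH <- do.call(cbind, lapply(bundles, function(b)
      filter_raster(b$s_targ, params$tau_rout, params$dt)))
    Y <- do.call(cbind, lapply(task$conditions, function(cc) cc$y_targ))
    J_out <- readout_lsq(Y, SH)
  }
  for (it in seq_len(iterations)) {
    for (mu in sample.int(4)) {
      if (!train_recurrent) {
        # readout-only ablation: keep J frozen, still train the decoder
        stp <- train_snn_step(J, J_out, bundles[[mu]]$I_clock,
                              bundles[[mu]]$s_targ,
                              task$conditions[[mu]]$y_targ, params,
                              within_control(control, eta0 = 0), st)
      } else {
        stp <- train_snn_step(J, J_out, bundles[[mu]]$I_clock,
                              bundles[[mu]]$s_targ,
                              task$conditions[[mu]]$y_targ, params,
                              control, st)
        J <- stp$J
      }
      J_out <- stp$Jout; st <- stp$state
    }
  }
  win <- max(1, task$response_window[1]):min(params$T, task$response_window[2])
  outputs <- list(); pred_sign <- integer(4); true_sign <- integer(4)
  ds <- numeric(4); amp <- numeric(4)
  for (mu in 1:4) {
    ev <- eval_generation(J, J_out, bundles[[mu]],
                          task$conditions[[mu]]$y_targ, params)
    outputs[[mu]] <- ev$y
    amp[mu] <- mean(ev$y[, win])
    pred_sign[mu] <- sign(amp[mu])
    true_sign[mu] <- task$conditions[[mu]]$sign
    ds[mu] <- ev$delta_s
  }
  structure(list(outputs = outputs, pred_sign = pred_sign,
                 true_sign = true_sign, delta_s = ds, amplitude = amp,
                 accuracy = mean(pred_sign == true_sign),
                 success = all(pred_sign == true_sign),
                 J = J, J_out = J_out, task = task, params = params,
                 seed = seed),
            class = "xor_experiment")
}

within_control <- function(control, ...) {
  over <- list(...)
  control[names(over)] <- over
  control
}

#' @export
print.xor_experiment <- function(x, ...) {
  cat("Temporal XOR experiment\n")
  for (mu in 1:4)
    cat(sprintf("  bits (%d,%d): expected %+d, decoded %+d (amplitude %+.4f), dS = %.4f\n",
                x$task$conditions[[mu]]$bits[1],
                x$task$conditions[[mu]]$bits[2],
                x$true_sign[mu], x$pred_sign[mu], x$amplitude[mu],
                x$delta_s[mu]))
  cat(sprintf("  accuracy %d/4 -> %s\n", round(4 * x$accuracy),
              if (x$success) "success" else "failure"))
  invisible(x)
}
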
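#' Fit a recurrent spiking network to replay a target output signal
#'
#' The central modelling function. Given a desired output signal, it (i)
#' draws the static Gaussian clock and teacher projections, (ii) builds the
#' internal target spike pattern by driving the recurrence-free network with
#' clock + teacher currents, and (iii) trains the recurrent weights by the
#' maximum-likelihood plasticity rule (spike- or voltage-dependent, batch or
#' per-timestep online, plain or Adam) while the linear readout learns to
#' decode the target raster. Generation-mode performance (autonomous replay
#' decoded by the readout, clock input only) is evaluated along the way.
#'
#' @param y Target output signal: `D x T` matrix (or a length-`T` vector for
#'   `D = 1`). With `normalize = TRUE` each channel is divided by its
#'   maximum absolute value, so the reported MSE is on normalized
#'   trajectories.
#' @param params An [snn_params()] object (see [task_params()] for presets).
#' @param control A [learn_control()] object.
#' @param iterations Number of training presentations of the full trial.
#' @param clock_channels Number of box-code clock channels.
#' @param seed Optional integer seed controlling projections and any
#'   randomness, for end-to-end reproducibility.
#' @param eval_every Evaluate generation-mode MSE and raster mismatch every
#'   this many presentations (always at the final one). Use larger values to
#'   cut evaluation cost on long runs.
#' @param normalize Normalize each output channel to unit maximum absolute
#'   value before building the teacher current and the readout target.
#' @param verbose Print progress every evaluation.
#' @return An object of class `snn_fit`; see Details.
#' @details The returned object carries the fitted weights (`J`, `J_out`),
#'   the frozen teacher bundle (`s_targ`, currents, projections), the
#'   resolved `params`/`control`, and `history`, a data frame with one row
#'   per evaluated presentation (`iteration`, `loglik`, `delta_s_train`,
#'   `mse`, `delta_s_gen`). Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `simulate`, `plot`, `logLik`.
#' @examples
#' \donttest{
#' p <- task_params("few_presentations", N = 120)
#' y <- sample_trajectory(seed = 1, T = p$T, dt = p$dt)
#' fit <- fit_snn(y, p, learn_control("spike", "online", "plain",
#'                                    readout = "lsq"),
#'                iterations = 8, seed = 1)
#' fit
#' }
#' @export
fit_snn <- function(y, params = task_params("trajectory3d"),
                    control = learn_control(), iterations = 100,
                    clock_channels = 10, seed = NULL,
                    eval_every = 1, normalize = TRUE, verbose = FALSE) {
  cl <- match.call()
  control <- resolve_control(control, params)
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(y) && is.null(dim(y))) y <- matrix(y, 1)
  if (ncol(y) != params$T) stop("y must have T columns")
  if (normalize) y <- normalize_trajectory(y)
  D <- nrow(y); N <- params$N; T <- params$T

  clock <- make_clock(clock_channels, T)
  J_in <- make_projection(N, clock_channels, params$sigma_in)
  J_teach <- make_projection(N, D, params$sigma_teach)
  bundle <- build_target(list(J_in = J_in, J_teach = J_teach), clock, y,
                         params)
  fit <- train_snn_core(bundle, y, params, control, iterations,
                        eval_every = eval_every, verbose = verbose)
  fit$call <- cl
  fit$seed <- seed
  fit$weights <- snn_weights(fit$J, J_in, J_teach, fit$J_out)
  fit
}

# Shared training engine over one frozen teacher bundle. Also used by the
# experiment drivers (the XOR driver interleaves several bundles and calls
# train_snn_step directly).
train_snn_core <- function(bundle, y, params, control, iterations,
                           eval_every = 1, verbose = FALSE) {
  control <- resolve_control(control, params)
  N <- params$N; T <- params$T; D <- nrow(y)
  J <- matrix(0, N, N)                      # weights start at zero
  J_out <- matrix(0, D, N)
  st <- list(mJ = matrix(0, N, N), vJ = matrix(0, N, N), tJ = 0,
             mO = matrix(0, D, N), vO = matrix(0, D, N), tO = 0)
  if (control$readout == "lsq")
    J_out <- readout_lsq(y, filter_raster(bundle$s_targ, params$tau_rout,
                                          params$dt))
  hist <- list()
  for (it in seq_len(iterations)) {
    step <- train_snn_step(J, J_out, bundle$I_clock, bundle$s_targ, y,
                           params, control, st)
    J <- step$J; J_out <- step$Jout; st <- step$state
    if (it %% eval_every == 0 || it == iterations) {
      ev <- eval_generation(J, J_out, bundle, y, params)
      hist[[length(hist) + 1]] <-
        data.frame(iteration = it, loglik = step$loglik,
                   delta_s_train = step$delta_s,
                   mse = ev$mse, delta_s_gen = ev$delta_s)
      if (verbose)
        message(sprintf("iter %4d  mse %.5f  dS(train) %.4f  dS(gen) %.4f",
                        it, ev$mse, step$delta_s, ev$delta_s))
    }
  }
  out <- list(J = J, J_out = J_out, params = params, control = control,
              bundle = bundle, y = y, iterations = iterations,
              history = do.call(rbind, hist), opt_state = st)
  class(out) <- "snn_fit"
  out
}

# one presentation: recurrent + readout updates in the compiled core (cuBa)
# or the R reference path (coBa)
train_snn_step <- function(J, J_out, I, s_targ, y, params, control, st) {
  if (params$model == "coba") {
    res <- train_presentation_coba(J, I, s_targ, control, params)
    # readout trained on the frozen target raster via Adam (R path)
    sh <- filter_raster(s_targ, params$tau_rout, params$dt)
    optO <- list(m = st$mO, v = st$vO, t = st$tO)
    for (tt in seq_len(ncol(sh))) {
      g <- readout_update(J_out, y[, tt], sh[, tt], mode = "online")
      stp <- adam_step(optO, g, control$readout_lr, control$beta1,
                       control$beta2, control$eps)
      J_out <- J_out + stp$update; optO <- stp$opt
    }
    st$mO <- optO$m; st$vO <- optO$v; st$tO <- optO$t
    return(list(J = res$J, Jout = J_out, state = st,
                loglik = res$loglik, delta_s = res$delta_s))
  }
  out <- cpp_train_presentation(
    J, J_out, I, s_targ, y,
    params$dt, params$tau_m, params$tau_s, params$tau_rout,
    params$v_th, params$v_rest, params$J_res, params$v0,
    rule = if (control$rule == "voltage") 1L else 0L,
    dv = if (control$dv > 0) control$dv else 1,
    schedule = if (control$schedule == "online") 1L else 0L,
    optimizer = if (control$optimizer == "adam") 1L else 0L,
    eta0 = control$eta0,
    mJ = st$mJ, vJ = st$vJ, tJ = st$tJ,
    beta1 = control$beta1, beta2 = control$beta2, adam_eps = control$eps,
    train_readout = control$readout %in% c("adam", "plain"),
    r_optimizer = if (control$readout == "adam") 1L else 0L,
    r_lr = control$readout_lr,
    mO = st$mO, vO = st$vO, tO = st$tO,
    update_J = TRUE)
  if (control$dv <= 0) out$loglik <- NA_real_
  list(J = out$J, Jout = out$Jout,
       state = list(mJ = out$mJ, vJ = out$vJ, tJ = out$tJ,
                    mO = out$mO, vO = out$vO, tO = out$tO),
       loglik = out$loglik, delta_s = out$delta_s)
}

# generation-mode evaluation: autonomous replay under the clock current
eval_generation <- function(J, J_out, bundle, y, params, input = NULL) {
  if (is.null(input)) input <- bundle$I_clock
  trial <- run_trial(J, input, mode = "generation", params = params,
                     s_init = bundle$s_targ[, 1])
  sh <- filter_raster(trial$raster, params$tau_rout, params$dt)
  yhat <- decode(J_out, sh)
  list(mse = mse(yhat, y), delta_s = spike_mismatch(bundle$s_targ,
                                                    trial$raster),
       y = yhat, raster = trial$raster)
}

# --- S3 methods -----------------------------------------------------------

#' @export
print.snn_fit <- function(x, ...) {
  h <- x$history
  cat("Recurrent spiking network fit (target-based maximum likelihood)\n")
  cat(sprintf("  %d neurons, %d steps, %d-channel output, %s model\n",
              x$params$N, x$params$T, nrow(x$y), x$params$model))
  cat(sprintf("  rule: %s (dv = %g), schedule: %s, optimizer: %s, %d presentations\n",
              x$control$rule, x$control$dv, x$control$schedule,
              x$control$optimizer, x$iterations))
  if (!is.null(h) && nrow(h))
    cat(sprintf("  final generation MSE %.5f, raster mismatch %.5f\n",
                h$mse[nrow(h)], h$delta_s_gen[nrow(h)]))
  invisible(x)
}

#' Summary of a fitted spiking network
#'
#' @param object An `snn_fit` object.
#' @param ... Unused.
#' @return A `summary.snn_fit` list (printed with its own method).
#' @export
summary.snn_fit <- function(object, ...) {
  h <- object$history
  s <- list(params = object$params, control = object$control,
            iterations = object$iterations,
            final = h[nrow(h), , drop = FALSE],
            best_mse = min(h$mse, na.rm = TRUE),
            spikes_target = sum(object$bundle$s_targ),
            rate_target = mean(object$bundle$s_targ),
            J_norm = sqrt(mean(object$J^2)),
            history = h)
  class(s) <- "summary.snn_fit"
  s
}

#' @export
print.summary.snn_fit <- function(x, ...) {
  cat("Target-based spiking network fit\n")
  print(x$params)
  print(x$control)
  cat(sprintf("Target raster: %d spikes (rate %.3f)\n", x$spikes_target,
              x$rate_target))
  cat(sprintf("After %d presentations: MSE %.5f (best %.5f), dS(gen) %.5f, RMS(J) %.4f\n",
              x$iterations, x$final$mse, x$best_mse, x$final$delta_s_gen,
              x$J_norm))
  invisible(x)
}

#' @export
coef.snn_fit <- function(object,
                         which = c("recurrent", "readout", "all"), ...) {
  which <- match.arg(which)
  switch(which, recurrent = object$J, readout = object$J_out,
         all = list(J = object$J, J_out = object$J_out))
}

#' Predict (retrieve) from a fitted spiking network
#'
#' Runs the trained network in generation mode -- plasticity off,
#' deterministic spiking, clock input only -- and decodes the output,
#' optionally perturbing the clock signal with Gaussian noise.
#'
#' @param object An `snn_fit` object.
#' @param noise_ratio Variance ratio of the clock perturbation,
#'   `sigma^2_noise / sigma^2_clock` (0 = noise-free retrieval).
#' @param type `"output"` (decoded `D x T` trajectory), `"raster"`, or
#'   `"both"`.
#' @param seed Optional seed for the noise draw.
#' @param ... Unused.
#' @return The decoded output matrix, the raster, or a list with both plus
#'   `mse` and `delta_s`.
#' @export
predict.snn_fit <- function(object, noise_ratio = 0,
                            type = c("output", "raster", "both"),
                            seed = NULL, ...) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  input <- noisy_clock_current(object, noise_ratio)
  ev <- eval_generation(object$J, object$J_out, object$bundle, object$y,
                        object$params, input = input)
  switch(type, output = ev$y, raster = ev$raster, both = ev)
}

noisy_clock_current <- function(object, noise_ratio) {
  if (noise_ratio == 0) return(object$bundle$I_clock)
  x <- unclass(object$bundle$clock)
  sigma_clock2 <- stats::var(as.vector(x))
  sn <- sqrt(noise_ratio * sigma_clock2)
  xi <- matrix(stats::rnorm(length(x), 0, sn), nrow(x), ncol(x))
  object$weights$J_in %*% (x + xi)
}

#' @export
fitted.snn_fit <- function(object, ...) predict(object)

#' @export
residuals.snn_fit <- function(object, ...) object$y - fitted(object)

#' Simulate noisy retrievals from a fitted spiking network
#'
#' @param object An `snn_fit` object.
#' @param nsim Number of retrieval runs.
#' @param seed Optional seed.
#' @param noise_ratio Clock-noise variance ratio applied to every run.
#' @param ... Unused.
#' @return A data frame with one row per run (`sim`, `mse`, `delta_s`);
#'   the decoded outputs are attached as attribute `"outputs"`.
#' @export
simulate.snn_fit <- function(object, nsim = 1, seed = NULL,
                             noise_ratio = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  outs <- vector("list", nsim)
  res <- data.frame(sim = seq_len(nsim), mse = NA_real_, delta_s = NA_real_)
  for (i in seq_len(nsim)) {
    ev <- predict(object, noise_ratio = noise_ratio, type = "both")
    res$mse[i] <- ev$mse; res$delta_s[i] <- ev$delta_s
    outs[[i]] <- ev$y
  }
  attr(res, "outputs") <- outs
  res
}

#' @export
logLik.snn_fit <- function(object, dv = NULL, ...) {
  p <- object$params; ctl <- object$control
  if (is.null(dv)) dv <- if (ctl$dv > 0) ctl$dv else 0.2
  tr <- run_trial(object$J, object$bundle$I_clock, mode = "clamped",
                  s_clamp = object$bundle$s_targ, params = p)
  ll <- log_likelihood(object$bundle$s_targ, tr$v, p, dv = dv)
  structure(ll, df = p$N^2, nobs = p$N * (p$T - 1), class = "logLik")
}

#' Plot a fitted spiking network
#'
#' @param x An `snn_fit` object.
#' @param which Subset of panels: 1 = generation MSE over presentations
#'   (log scale), 2 = decoded output vs target, 3 = spike raster in
#'   generation mode.
#' @param ... Passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.snn_fit <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ev <- if (any(which >= 2)) predict(x, type = "both") else NULL
  for (w in which) {
    if (w == 1) {
      h <- x$history
      graphics::plot(h$iteration, pmax(h$mse, 1e-6), type = "l", log = "y",
                     xlab = "presentation", ylab = "generation MSE",
                     main = "Training progress", ...)
    } else if (w == 2) {
      tt <- seq_len(ncol(x$y)) * x$params$dt
      graphics::matplot(tt, t(x$y), type = "l", lty = 2, col = seq_len(nrow(x$y)),
                        xlab = "time (ms)", ylab = "output",
                        main = "Target (dashed) vs retrieved (solid)", ...)
      graphics::matlines(tt, t(ev$y), lty = 1, col = seq_len(nrow(x$y)))
    } else if (w == 3) {
      sp <- which(ev$raster == 1, arr.ind = TRUE)
      graphics::plot(sp[, 2] * x$params$dt, sp[, 1], pch = ".",
                     xlab = "time (ms)", ylab = "neuron",
                     main = "Generation-mode raster", ...)
    }
  }
  invisible(x)
}
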
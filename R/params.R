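#' Network and simulation parameters
#'
#' Constructor for the parameter set of a discrete-time recurrent network of
#' leaky integrate-and-fire neurons. All potentials are in dimensionless model
#' units; time constants and the integration step are in milliseconds.
#'
#' @param N Number of neurons.
#' @param T Trial length in integration steps.
#' @param dt Integration step (ms).
#' @param tau_m Membrane time constant (ms); must satisfy `tau_m >= dt`.
#' @param tau_s Synaptic filter time constant (ms); must satisfy `tau_s >= dt`.
#' @param tau_rout Readout filter time constant (ms).
#' @param v_th Firing threshold.
#' @param v_rest Rest potential (asymptotic value with no input).
#' @param v0 Initial membrane potential (applied to all neurons at `t = 1`).
#' @param J_res Reset magnitude: after a spike the membrane is lowered by
#'   `J_res` (soft, subtractive reset).
#' @param dv Spike-generation noise scale \eqn{\delta v}. Spike generation is
#'   always performed in the deterministic limit; `dv` parametrises the
#'   voltage-dependent learning rule and the likelihood. `dv = 0` encodes the
#'   deterministic limit (spike-dependent rule).
#' @param eta0 Learning rate \eqn{\eta_0 = \eta/\delta v} (also used as the
#'   Adam step size when the Adam optimizer is selected).
#' @param sigma_teach,sigma_in Standard deviation of the Gaussian teacher and
#'   input (clock) projection matrices.
#' @param model `"cuba"` (current-based) or `"coba"` (conductance-based)
#'   synaptic integration.
#' @param E_exc,E_inh Reversal potentials for excitatory and inhibitory
#'   conductances (coBa only).
#' @param exc Logical vector of length `N` flagging excitatory neurons (coBa
#'   only); defaults to the first `round(0.8 N)` neurons.
#'
#' @return An object of class `snn_params` (a validated named list).
#' @seealso [task_params()] for the per-task parameter presets.
#' @examples
#' p <- snn_params(N = 10, T = 100)
#' p$tau_m
#' @export
snn_params <- function(N = 500, T = 1000, dt = 1, tau_m = 8, tau_s = 2,
                       tau_rout = 20, v_th = 0, v_rest = -4, v0 = -0.5,
                       J_res = 20, dv = 0, eta0 = 0.5,
                       sigma_teach = 10, sigma_in = 2,
                       model = c("cuba", "coba"),
                       E_exc = 5, E_inh = -8, exc = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(N), length(N) == 1, N >= 1, N == round(N))
  stopifnot(is.numeric(T), length(T) == 1, T >= 2, T == round(T))
  if (dt <= 0) stop("dt must be positive")
  if (tau_m < dt) stop("tau_m must be >= dt (leak factor 1 - dt/tau_m would be negative)")
  if (tau_s < dt) stop("tau_s must be >= dt (leak factor 1 - dt/tau_s would be negative)")
  if (tau_rout < dt) stop("tau_rout must be >= dt")
  if (dv < 0) stop("dv must be >= 0")
  if (sigma_teach < 0 || sigma_in < 0) stop("projection stds must be >= 0")
  if (model == "coba") {
    if (is.null(exc)) exc <- seq_len(N) <= round(0.8 * N)
    if (!is.logical(exc) || length(exc) != N)
      stop("exc must be a logical vector of length N for the coBa model")
    if (E_exc <= v_th) warning("E_exc at or below threshold: excitatory drive cannot elicit spikes")
  }
  p <- list(N = as.integer(N), T = as.integer(T), dt = dt, tau_m = tau_m,
            tau_s = tau_s, tau_rout = tau_rout, v_th = v_th, v_rest = v_rest,
            v0 = v0, J_res = J_res, dv = dv, eta0 = eta0,
            sigma_teach = sigma_teach, sigma_in = sigma_in, model = model,
            E_exc = E_exc, E_inh = E_inh, exc = exc)
  class(p) <- "snn_params"
  p
}

#' @export
print.snn_params <- function(x, ...) {
  cat(sprintf("Spiking network parameters (%s model)\n", x$model))
  cat(sprintf("  N = %d neurons, T = %d steps, dt = %g ms\n", x$N, x$T, x$dt))
  cat(sprintf("  tau_m = %g ms, tau_s = %g ms, tau_rout = %g ms\n",
              x$tau_m, x$tau_s, x$tau_rout))
  cat(sprintf("  v_th = %g, v_rest = %g, v0 = %g, J_res = %g\n",
              x$v_th, x$v_rest, x$v0, x$J_res))
  cat(sprintf("  dv = %g, eta0 = %g, sigma_teach = %g, sigma_in = %g\n",
              x$dv, x$eta0, x$sigma_teach, x$sigma_in))
  if (x$model == "coba")
    cat(sprintf("  E_exc = %g, E_inh = %g, %d excitatory / %d inhibitory\n",
                x$E_exc, x$E_inh, sum(x$exc), sum(!x$exc)))
  invisible(x)
}

#' Per-task parameter presets
#'
#' Returns the published parameter column for one of the benchmark tasks:
#' 3D trajectory generation, temporal XOR, and learning from few
#' presentations of a short (50-step) trajectory.
#'
#' @param task One of `"trajectory3d"`, `"xor"`, `"few_presentations"`.
#' @param ... Overrides forwarded to [snn_params()].
#' @return An `snn_params` object.
#' @examples
#' task_params("few_presentations")$T
#' @export
task_params <- function(task = c("trajectory3d", "xor", "few_presentations"),
                        ...) {
  task <- match.arg(task)
  base <- switch(task,
    trajectory3d = list(N = 500, T = 1000, dt = 1, tau_m = 8, tau_s = 2,
                        tau_rout = 20, v_th = 0, v_rest = -4, v0 = -0.5,
                        J_res = 20, dv = 0.2, eta0 = 0.5,
                        sigma_teach = 10, sigma_in = 2),
    xor = list(N = 500, T = 130, dt = 1, tau_m = 8, tau_s = 2,
               tau_rout = 2, v_th = 0, v_rest = -4, v0 = -0.5,
               J_res = 20, dv = 0, eta0 = 0.5,
               sigma_teach = 5, sigma_in = 3),
    few_presentations = list(N = 500, T = 50, dt = 1, tau_m = 2, tau_s = 1.25,
                             tau_rout = 20, v_th = 0, v_rest = -1, v0 = -0.5,
                             J_res = 20, dv = 0, eta0 = 1.0,
                             sigma_teach = 10, sigma_in = 2))
  over <- list(...)
  base[names(over)] <- over
  do.call(snn_params, base)
}

#' Learning configuration
#'
#' Bundles the choices that define the plasticity rule and its optimisation
#' schedule: spike- vs voltage-dependent error, batch gradient ascent vs the
#' per-timestep online approximation, plain steps vs Adam, and how the linear
#' readout is trained.
#'
#' @param rule `"spike"` (error `s_targ - s_pred`, the deterministic
#'   \eqn{\delta v \to 0} limit) or `"voltage"` (graded error
#'   `s_targ - f(v)` at finite `dv`; requires `dv > 0`).
#' @param schedule `"batch"` (accumulate the gradient over the trial, apply
#'   once at trial end) or `"online"` (apply at every timestep with the
#'   currently available quantities).
#' @param optimizer `"plain"` gradient ascent or `"adam"` adaptive moments.
#' @param eta0 Learning rate / Adam step size; `NULL` inherits from the
#'   network parameters.
#' @param dv Noise scale for the voltage rule; `NULL` inherits from the
#'   network parameters.
#' @param beta1,beta2,eps Adam moment-decay and regularisation constants.
#' @param readout How the linear readout is trained: `"adam"` (per-timestep
#'   delta rule through Adam), `"plain"` (per-timestep delta rule with step
#'   `readout_lr`), `"lsq"` (minimum-norm least squares on the frozen
#'   filtered target raster, the converged limit of the delta rule from zero
#'   initialisation), or `"none"`.
#' @param readout_lr Step size for the readout optimizer (default 1e-4: small
#'   relative to the typical readout weight scale, keeping the stochastic
#'   per-timestep Adam floor near the least-squares optimum).
#' @return An object of class `learn_control`.
#' @examples
#' learn_control(rule = "voltage", dv = 0.2)
#' @export
learn_control <- function(rule = c("spike", "voltage"),
                          schedule = c("online", "batch"),
                          optimizer = c("plain", "adam"),
                          eta0 = NULL, dv = NULL,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          readout = c("adam", "plain", "lsq", "none"),
                          readout_lr = 1e-4) {
  ctl <- list(rule = match.arg(rule), schedule = match.arg(schedule),
              optimizer = match.arg(optimizer), eta0 = eta0, dv = dv,
              beta1 = beta1, beta2 = beta2, eps = eps,
              readout = match.arg(readout), readout_lr = readout_lr)
  if (!is.null(ctl$dv) && ctl$rule == "voltage" && ctl$dv <= 0)
    stop("the voltage-dependent rule requires dv > 0")
  class(ctl) <- "learn_control"
  ctl
}

#' @export
print.learn_control <- function(x, ...) {
  cat(sprintf("Learning control: %s rule, %s schedule, %s optimizer\n",
              x$rule, x$schedule, x$optimizer))
  cat(sprintf("  eta0 = %s, dv = %s, readout = %s (lr = %g)\n",
              if (is.null(x$eta0)) "<from params>" else format(x$eta0),
              if (is.null(x$dv)) "<from params>" else format(x$dv),
              x$readout, x$readout_lr))
  invisible(x)
}

# resolve NULL entries of a learn_control against the network parameters
resolve_control <- function(control, params) {
  if (is.null(control$eta0)) control$eta0 <- params$eta0
  if (is.null(control$dv)) control$dv <- params$dv
  if (control$rule == "voltage" && control$dv <= 0)
    stop("the voltage-dependent rule requires dv > 0")
  control
}
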
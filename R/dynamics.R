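#' Exponential synaptic filtering of a spike vector
#'
#' One step of the first-order low-pass filter applied to spikes,
#' `s_hat' = (1 - dt/tau) s_hat + (dt/tau) s`.
#'
#' @param s_hat_prev Filtered spike vector at the previous step.
#' @param s Binary spike vector at the current step.
#' @param tau Filter time constant (ms); must be `>= dt`.
#' @param dt Integration step (ms).
#' @return The updated filtered spike vector (stays in `[0, 1]` for binary
#'   input when initialised in `[0, 1]`).
#' @examples
#' filter_spikes(0, 1, tau = 2, dt = 1)  # 0.5
#' @export
filter_spikes <- function(s_hat_prev, s, tau, dt) {
  if (tau < dt) stop("tau must be >= dt (leak factor would be negative)")
  (1 - dt / tau) * s_hat_prev + (dt / tau) * s
}

#' Network state at one time step
#'
#' @param v Membrane potentials (length `N`).
#' @param s Binary spike vector (length `N`).
#' @param s_hat Filtered spikes (length `N`, in `[0, 1]`).
#' @return An object of class `snn_state`.
#' @export
snn_state <- function(v, s, s_hat = s) {
  stopifnot(length(v) == length(s), length(s) == length(s_hat))
  if (!all(s %in% c(0, 1))) stop("s entries must be 0 or 1")
  structure(list(v = as.numeric(v), s = as.numeric(s),
                 s_hat = as.numeric(s_hat)), class = "snn_state")
}

#' Membrane update for current-based (cuBa) neurons
#'
#' One synchronous update of the leaky-integrator membrane, using the
#' previous step's spikes and filtered spikes (causal convention):
#' `v' = (1 - dt/tau_m) v + (dt/tau_m) (J s_hat + I_ext + v_rest) - J_res s`.
#' The reset is subtractive (soft): a spike lowers the membrane by `J_res`
#' with no clamping to a floor.
#'
#' @param state An [snn_state()] holding `v`, `s`, `s_hat` of the previous step.
#' @param I_ext External input current (length `N`).
#' @param J Recurrent weight matrix (`N x N`).
#' @param params An [snn_params()] object.
#' @return The updated membrane potential vector.
#' @export
membrane_step_cuba <- function(state, I_ext, J, params) {
  N <- length(state$v)
  if (length(I_ext) != N) stop("I_ext length does not match the state")
  if (!is.matrix(J) || nrow(J) != N || ncol(J) != N)
    stop("J must be an N x N matrix")
  a <- params$dt / params$tau_m
  (1 - a) * state$v + a * (drop(J %*% state$s_hat) + I_ext + params$v_rest) -
    params$J_res * state$s
}

#' Membrane update for conductance-based (coBa) neurons
#'
#' As [membrane_step_cuba()], but synaptic drive is multiplied by the driving
#' force towards the excitatory/inhibitory reversal potentials:
#' `v' = (1-a) v + a (I_ext + v_rest) + a [(E_exc - v) J_exc s_hat_exc +
#' (E_inh - v) J_inh s_hat_inh] - J_res s` with `a = dt/tau_m`. Conductance
#' weights are stored as magnitudes (`>= 0`); the sign of the drive is
#' carried entirely by the driving-force factors.
#'
#' @inheritParams membrane_step_cuba
#' @param J_exc,J_inh Non-negative `N x N` conductance matrices; only columns
#'   belonging to excitatory (resp. inhibitory) presynaptic neurons are read.
#' @return The updated membrane potential vector.
#' @export
membrane_step_coba <- function(state, I_ext, J_exc, J_inh, params) {
  if (is.null(params$exc)) stop("coBa model requires an excitatory/inhibitory partition")
  N <- length(state$v)
  a <- params$dt / params$tau_m
  sh_exc <- state$s_hat * params$exc
  sh_inh <- state$s_hat * !params$exc
  drive <- (params$E_exc - state$v) * drop(J_exc %*% sh_exc) +
           (params$E_inh - state$v) * drop(J_inh %*% sh_inh)
  (1 - a) * state$v + a * (I_ext + params$v_rest) + a * drive -
    params$J_res * state$s
}

#' Probability of an observed spike outcome
#'
#' Logistic spike model: the probability of observing `s_next` given the
#' membrane potential is `sigma((v - v_th)/dv)` for `s_next = 1` and its
#' complement for `s_next = 0`.
#'
#' @param v Membrane potential vector.
#' @param s_next Observed binary spike vector at the next step.
#' @param params An [snn_params()] object with `dv > 0`.
#' @return A vector of probabilities in `(0, 1)`.
#' @export
spike_probability <- function(v, s_next, params) {
  if (params$dv <= 0)
    stop("dv = 0 is the deterministic limit: use generate_spikes_deterministic()")
  q <- stats::plogis((v - params$v_th) / params$dv)
  ifelse(s_next == 1, q, 1 - q)
}

#' Deterministic spike generation
#'
#' The deterministic limit of the logistic spike model: a neuron spikes iff
#' its membrane potential strictly exceeds the threshold (a tie at
#' `v == v_th` produces no spike).
#'
#' @param v Membrane potential vector.
#' @param params An [snn_params()] object.
#' @return A binary vector.
#' @export
generate_spikes_deterministic <- function(v, params) {
  as.numeric(v > params$v_th)
}

#' Network weights
#'
#' Container for the recurrent matrix and the static projections.
#'
#' @param J Recurrent matrix (`N x N`).
#' @param J_in Clock/input projection (`N x K`), or `NULL`.
#' @param J_teach Teacher projection (`N x D`), or `NULL`.
#' @param J_out Readout matrix (`D_out x N`), or `NULL`.
#' @return An object of class `snn_weights`.
#' @export
snn_weights <- function(J, J_in = NULL, J_teach = NULL, J_out = NULL) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J))
  w <- list(J = J, J_in = J_in, J_teach = J_teach, J_out = J_out)
  class(w) <- "snn_weights"
  w
}

#' Simulate one trial of the network
#'
#' Runs the discrete-time dynamics for a full trial in one of three modes:
#' `"open_loop"` (recurrence off, spikes generated deterministically from the
#' externally driven membrane -- used to build target patterns),
#' `"clamped"` (the spike history is clamped to a given raster while the
#' membrane evolves underneath -- the configuration used by learning), and
#' `"generation"` (autonomous retrieval: the network's own deterministic
#' spikes feed back through the recurrence).
#'
#' @param weights An [snn_weights()] object or a bare `N x N` matrix. For the
#'   coBa model, `weights$J` carries signed weights; magnitudes are split by
#'   the presynaptic excitatory/inhibitory label.
#' @param input External input current, `N x T` matrix (or `NULL` for none).
#' @param mode One of `"generation"`, `"clamped"`, `"open_loop"`.
#' @param s_clamp `N x T` binary raster required in clamped mode.
#' @param params An [snn_params()] object.
#' @param s_init Initial spike vector `s^1`; defaults to the first clamped
#'   frame in clamped mode and to all-zero otherwise.
#' @return A list of class `snn_trial` with elements `raster` (`N x T`
#'   binary) and `v` (`N x T` membrane trace), plus `dt`.
#' @examples
#' p <- snn_params(N = 3, T = 20, v0 = -0.5)
#' tr <- run_trial(matrix(0, 3, 3), NULL, mode = "open_loop", params = p)
#' sum(tr$raster)  # subthreshold, never spikes
#' @export
run_trial <- function(weights, input = NULL,
                      mode = c("generation", "clamped", "open_loop"),
                      s_clamp = NULL, params, s_init = NULL) {
  mode <- match.arg(mode)
  if (inherits(weights, "snn_weights")) weights <- weights$J
  N <- params$N; T <- params$T
  if (is.null(input)) input <- matrix(0, N, T)
  if (!is.matrix(input) || nrow(input) != N || ncol(input) != T)
    stop("input must be an N x T matrix")
  if (mode == "clamped") {
    if (is.null(s_clamp)) stop("clamped mode requires s_clamp")
    if (!all(dim(s_clamp) == c(N, T))) stop("s_clamp must be N x T")
  }
  if (is.null(s_init))
    s_init <- if (mode == "clamped") s_clamp[, 1] else numeric(N)
  use_rec <- mode != "open_loop"
  if (params$model == "coba") {
    out <- run_trial_coba_r(weights, input, params, use_rec,
                            if (mode == "clamped") s_clamp else NULL, s_init)
  } else {
    out <- cpp_run_trial(weights, input, params$v0, s_init,
                         params$dt, params$tau_m, params$tau_s,
                         params$v_th, params$v_rest, params$J_res,
                         use_rec,
                         if (mode == "clamped") s_clamp else NULL)
  }
  structure(list(raster = out$raster, v = out$v, dt = params$dt, mode = mode),
            class = "snn_trial")
}

# conductance-based trial loop; small-scale use only, stays in R
run_trial_coba_r <- function(J, input, params, use_rec, s_clamp, s_init) {
  N <- params$N; T <- params$T
  J_exc <- pmax(J, 0); J_exc[, !params$exc] <- 0
  J_inh <- pmax(-J, 0); J_inh[, params$exc] <- 0
  S <- matrix(0, N, T); V <- matrix(0, N, T)
  st <- snn_state(rep(params$v0, N), s_init, s_init)
  V[, 1] <- st$v; S[, 1] <- st$s
  for (t in 2:T) {
    s_next <- if (!is.null(s_clamp)) s_clamp[, t]
              else generate_spikes_deterministic(st$v, params)
    v_new <- if (use_rec)
      membrane_step_coba(st, input[, t], J_exc, J_inh, params)
    else
      (1 - params$dt / params$tau_m) * st$v +
        (params$dt / params$tau_m) * (input[, t] + params$v_rest) -
        params$J_res * st$s
    sh <- filter_spikes(st$s_hat, s_next, params$tau_s, params$dt)
    st <- snn_state(v_new, s_next, sh)
    V[, t] <- st$v; S[, t] <- st$s
  }
  list(raster = S, v = V)
}

#' @export
print.snn_trial <- function(x, ...) {
  cat(sprintf("Spiking trial (%s mode): %d neurons x %d steps, %d spikes (rate %.3f)\n",
              x$mode, nrow(x$raster), ncol(x$raster), sum(x$raster),
              mean(x$raster)))
  invisible(x)
}
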
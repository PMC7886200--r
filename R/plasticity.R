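#' Log-likelihood of a target spike pattern
#'
#' Sum over neurons and `t = 1 .. T-1` of the log-probability of the target
#' spikes at `t + 1` given the membrane trace at `t`, under the logistic
#' spike model at noise scale `dv`. The membrane trace must come from
#' clamped-mode dynamics under the same target raster.
#'
#' @param s_targ `N x T` binary target raster.
#' @param v_trace `N x T` membrane trace (clamped mode).
#' @param params An [snn_params()] object.
#' @param dv Noise scale; must be `> 0`. Defaults to `params$dv`.
#' @return A scalar `<= 0`.
#' @export
log_likelihood <- function(s_targ, v_trace, params, dv = params$dv) {
  if (is.null(dv) || dv <= 0)
    stop("log-likelihood is undefined at dv = 0 (0/1 probabilities)")
  stopifnot(all(dim(s_targ) == dim(v_trace)))
  T <- ncol(s_targ)
  x <- (v_trace[, 1:(T - 1), drop = FALSE] - params$v_th) / dv
  s1 <- s_targ[, 2:T, drop = FALSE]
  # log p = s*x - log(1 + e^x), stable via plogis on the log scale
  sum(s1 * stats::plogis(x, log.p = TRUE) +
        (1 - s1) * stats::plogis(-x, log.p = TRUE))
}

#' Eligibility-trace recursion (cuBa)
#'
#' The presynaptic trace realising `dv_i^t/dJ_ik`: because of the Kronecker
#' delta structure the derivative is non-zero only for the postsynaptic index
#' and its value depends only on the presynaptic neuron, so one length-`N`
#' vector is shared across all postsynaptic rows. The recursion is
#' `p' = (1 - dt/tau_m) p + (dt/tau_m) s_hat_targ`, with `p = 0` at `t = 1`.
#' The presynaptic term uses the filtered TARGET spikes, a consequence of
#' likelihood maximisation under clamped dynamics.
#'
#' @param p Current trace (length `N`).
#' @param s_hat_targ Filtered target spikes at the current step.
#' @param params An [snn_params()] object.
#' @return The updated trace.
#' @export
eligibility_step <- function(p, s_hat_targ, params) {
  a <- params$dt / params$tau_m
  (1 - a) * p + a * s_hat_targ
}

#' Eligibility-trace recursion (coBa)
#'
#' Conductance-based spike response functions: the decay factor includes the
#' total conductance load `|J| s_hat` and the presynaptic term is multiplied
#' by the driving force `(E - v)`. Because both depend on the postsynaptic
#' neuron, the traces are full `N x N` matrices.
#'
#' @param p_exc,p_inh Current `N x N` traces for excitatory and inhibitory
#'   conductances.
#' @param s_hat_exc,s_hat_inh Filtered target spikes masked to the
#'   excitatory / inhibitory populations (zeros elsewhere); their sum is the
#'   full filtered spike vector.
#' @param v_prev Membrane potential at the previous step.
#' @param J Signed recurrent matrix (only `|J|` is used for the load term).
#' @param params An [snn_params()] object (coBa).
#' @return A list with updated `p_exc` and `p_inh`.
#' @export
eligibility_step_coba <- function(p_exc, p_inh, s_hat_exc, s_hat_inh,
                                  v_prev, J, params) {
  a <- params$dt / params$tau_m
  load <- drop(abs(J) %*% (s_hat_exc + s_hat_inh))
  d <- 1 - a - a * load
  list(p_exc = p_exc * d + a * outer(params$E_exc - v_prev, s_hat_exc),
       p_inh = p_inh * d + a * outer(params$E_inh - v_prev, s_hat_inh))
}

#' Per-neuron error signal
#'
#' The first factor of the three-factor update. Spike-dependent form:
#' `s_targ - s_pred` (ternary, zero exactly when the prediction matches, so
#' learning halts at satisfaction). Voltage-dependent form: `s_targ - f(v)`
#' with `f` the logistic sigmoid at scale `dv`; never exactly zero, which
#' keeps pushing the membrane away from threshold past satisfaction and
#' creates the safety margin behind noise robustness.
#'
#' @param rule `"spike"` or `"voltage"`.
#' @param s_targ_next Binary target spikes at `t + 1`.
#' @param s_pred_next Binary predicted spikes at `t + 1` (spike rule); if
#'   `NULL`, computed by thresholding `v`.
#' @param v Membrane potentials at `t` (required for the voltage rule and to
#'   derive `s_pred_next`).
#' @param params An [snn_params()] object.
#' @param dv Noise scale for the voltage rule; defaults to `params$dv`.
#' @return A numeric vector: entries in `{-1, 0, 1}` (spike rule) or
#'   `(-1, 1)` (voltage rule).
#' @export
error_signal <- function(rule = c("spike", "voltage"), s_targ_next,
                         s_pred_next = NULL, v = NULL, params,
                         dv = params$dv) {
  rule <- match.arg(rule)
  if (rule == "voltage") {
    if (is.null(dv) || dv <= 0) stop("the voltage rule requires dv > 0")
    if (is.null(v)) stop("the voltage rule requires the membrane potential v")
    s_targ_next - stats::plogis((v - params$v_th) / dv)
  } else {
    if (is.null(s_pred_next)) {
      if (is.null(v)) stop("supply s_pred_next or v for the spike rule")
      s_pred_next <- generate_spikes_deterministic(v, params)
    }
    s_targ_next - s_pred_next
  }
}

#' Batch weight update (gradient of the likelihood over one trial)
#'
#' Runs the clamped dynamics under the target raster, accumulates the
#' three-factor update `eta0 * sum_t error^t (x) p^t` over the whole trial,
#' and returns it WITHOUT applying it. At finite `dv` (voltage rule) this is
#' exactly `eta * dL/dJ` with `eta = eta0 * dv`.
#'
#' @param s_targ `N x T` target raster.
#' @param input `N x T` external current during training (clock only).
#' @param J Current recurrent matrix.
#' @param control A [learn_control()] object.
#' @param params An [snn_params()] object.
#' @return The `N x N` update matrix `Delta J`.
#' @export
weight_update_batch <- function(s_targ, input, J, control, params) {
  control <- resolve_control(control, params)
  if (params$model == "coba") {
    out <- train_presentation_coba(J, input, s_targ, control, params,
                                   schedule = "batch", apply = FALSE)
    return(out$dJ)
  }
  N <- params$N
  z <- matrix(0, N, N)
  out <- cpp_train_presentation(
    J, matrix(0, 1, N), input, s_targ, matrix(0, 1, params$T),
    params$dt, params$tau_m, params$tau_s, params$tau_rout,
    params$v_th, params$v_rest, params$J_res, params$v0,
    rule = if (control$rule == "voltage") 1L else 0L, dv = control$dv,
    schedule = 0L, optimizer = 0L, eta0 = control$eta0,
    mJ = z, vJ = z, tJ = 0, beta1 = control$beta1, beta2 = control$beta2,
    adam_eps = control$eps, train_readout = FALSE, r_optimizer = 0L,
    r_lr = 0, mO = matrix(0, 1, N), vO = matrix(0, 1, N), tO = 0,
    update_J = FALSE)
  control$eta0 * out$grad_sum
}

#' Online weight update (one presentation, per-timestep)
#'
#' Runs one target-clamped presentation applying the rank-1 update at every
#' timestep with the currently available quantities; the prediction at each
#' step uses the weights as already updated within the trial. Returns the
#' updated weights together with per-trial diagnostics.
#'
#' @inheritParams weight_update_batch
#' @param opt Optional Adam state (as returned) to carry across
#'   presentations; created on first use.
#' @return A list: `J` (updated matrix), `opt` (optimizer state),
#'   `delta_s` (training-time spike mismatch), `loglik` (at `dv`, or `NA`).
#' @export
weight_update_online <- function(s_targ, input, J, control, params,
                                 opt = NULL) {
  control <- resolve_control(control, params)
  if (params$model == "coba") {
    out <- train_presentation_coba(J, input, s_targ, control, params,
                                   schedule = "online", apply = TRUE)
    return(list(J = out$J, opt = NULL, delta_s = out$delta_s,
                loglik = out$loglik))
  }
  N <- params$N
  if (is.null(opt)) opt <- adam_init(c(N, N))
  out <- cpp_train_presentation(
    J, matrix(0, 1, N), input, s_targ, matrix(0, 1, params$T),
    params$dt, params$tau_m, params$tau_s, params$tau_rout,
    params$v_th, params$v_rest, params$J_res, params$v0,
    rule = if (control$rule == "voltage") 1L else 0L, dv = control$dv,
    schedule = 1L,
    optimizer = if (control$optimizer == "adam") 1L else 0L,
    eta0 = control$eta0,
    mJ = opt$m, vJ = opt$v, tJ = opt$t,
    beta1 = control$beta1, beta2 = control$beta2, adam_eps = control$eps,
    train_readout = FALSE, r_optimizer = 0L, r_lr = 0,
    mO = matrix(0, 1, N), vO = matrix(0, 1, N), tO = 0,
    update_J = TRUE)
  list(J = out$J, opt = list(m = out$mJ, v = out$vJ, t = out$tJ),
       delta_s = out$delta_s, loglik = out$loglik)
}

#' Adam optimizer state
#'
#' @param dim Dimensions of the parameter array.
#' @return A list with zero first/second moments `m`, `v` and step count `t`.
#' @export
adam_init <- function(dim) {
  list(m = array(0, dim), v = array(0, dim), t = 0)
}

#' One Adam step
#'
#' Standard adaptive-moment update with bias correction. Gradient-ascent
#' convention: the returned update is ADDED to the parameters.
#'
#' @param opt State from [adam_init()] (or a previous call).
#' @param grad Gradient array (same shape as the state).
#' @param eta0 Step size.
#' @param beta1,beta2,eps Adam constants.
#' @return A list: `update` (to add to the parameters) and the new `opt`.
#' @export
adam_step <- function(opt, grad, eta0, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  list(update = eta0 * mhat / (sqrt(vhat) + eps), opt = opt)
}

#' Project a coBa weight matrix onto the Dale constraint
#'
#' Columns of excitatory presynaptic neurons are clipped to `>= 0`,
#' inhibitory columns to `<= 0`, so the sign of every synapse is conserved
#' through learning.
#'
#' @param J Signed recurrent matrix.
#' @param params A coBa [snn_params()] object (provides the partition).
#' @return The projected matrix.
#' @export
apply_dale <- function(J, params) {
  if (is.null(params$exc)) stop("Dale projection requires an exc/inh partition")
  J[, params$exc] <- pmax(J[, params$exc], 0)
  J[, !params$exc] <- pmin(J[, !params$exc], 0)
  J
}

# One training presentation for the conductance-based model (R reference
# path; used at small N). Signed J; conductance magnitudes carry the
# gradient, the Dale projection is applied after every update.
train_presentation_coba <- function(J, input, s_targ, control, params,
                                    schedule = control$schedule,
                                    apply = TRUE) {
  N <- params$N; T <- params$T
  a <- params$dt / params$tau_m
  exc <- params$exc
  v <- rep(params$v0, N)
  shat <- s_targ[, 1]
  p_exc <- matrix(0, N, N); p_inh <- matrix(0, N, N)
  G <- matrix(0, N, N)
  mism <- 0; loglik <- if (control$dv > 0) 0 else NA_real_
  for (tau in 1:(T - 1)) {
    err <- error_signal(control$rule, s_targ[, tau + 1], v = v,
                        params = params, dv = control$dv)
    pred <- generate_spikes_deterministic(v, params)
    mism <- mism + sum(abs(s_targ[, tau + 1] - pred))
    if (control$dv > 0)
      loglik <- loglik + sum(log(spike_probability(v, s_targ[, tau + 1],
        within_params_dv(params, control$dv))))
    # signed gradient: conductance magnitude grows with err * trace;
    # inhibitory signed weights move opposite to their magnitude
    P <- p_exc; P[, !exc] <- -p_inh[, !exc]
    g <- err %o% rep(1, N) * P
    if (schedule == "online" && apply) {
      J <- apply_dale(J + control$eta0 * g, params)
    } else {
      G <- G + g
    }
    # advance clamped state
    sh_exc <- shat * exc; sh_inh <- shat * !exc
    st <- snn_state(v, s_targ[, tau], shat)
    J_exc <- pmax(J, 0); J_exc[, !exc] <- 0
    J_inh <- pmax(-J, 0); J_inh[, exc] <- 0
    v_new <- membrane_step_coba(st, input[, tau + 1], J_exc, J_inh, params)
    tr <- eligibility_step_coba(p_exc, p_inh, sh_exc, sh_inh, v, J, params)
    p_exc <- tr$p_exc; p_inh <- tr$p_inh
    v <- v_new
    shat <- filter_spikes(shat, s_targ[, tau + 1], params$tau_s, params$dt)
  }
  dJ <- control$eta0 * G
  if (schedule == "batch" && apply) J <- apply_dale(J + dJ, params)
  list(J = J, dJ = dJ, delta_s = mism / (N * (T - 1)), loglik = loglik)
}

within_params_dv <- function(params, dv) { params$dv <- dv; params }
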
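#' Exponentially filter a raster for the readout
#'
#' Applies the first-order low-pass filter with the readout time constant to
#' every neuron's spike train: `s_hat^t = (1 - dt/tau) s_hat^{t-1} +
#' (dt/tau) s^t`, with `s_hat^0 = init` (0 by default).
#'
#' @param raster `N x T` binary raster.
#' @param tau Filter time constant (ms).
#' @param dt Integration step (ms).
#' @param init Initial filter value.
#' @return An `N x T` matrix of filtered traces.
#' @export
filter_raster <- function(raster, tau, dt, init = 0) {
  if (tau < dt) stop("tau must be >= dt")
  cpp_filter_raster(raster, tau, dt, init)
}

#' Linear decoding of filtered spikes
#'
#' @param J_out Readout matrix (`D x N`).
#' @param s_hat_out Filtered spikes: a length-`N` vector (one step) or an
#'   `N x T` matrix (whole trial).
#' @return The decoded output: length-`D` vector or `D x T` matrix.
#' @export
decode <- function(J_out, s_hat_out) {
  if (is.matrix(s_hat_out)) J_out %*% s_hat_out else drop(J_out %*% s_hat_out)
}

#' Delta-rule readout update
#'
#' The gradient of the squared decoding error with respect to the readout
#' weights: `Delta J_out = (y_targ - J_out s_hat) s_hat^T`, either from the
#' full-trial matrices (`batch`) or from the instantaneous vectors
#' (`online`). No learning rate is applied; feed the result through an
#' optimizer step.
#'
#' @param J_out Current readout matrix (`D x N`).
#' @param y_targ Target output: `D x T` matrix (batch) or length-`D` vector
#'   (online).
#' @param s_hat_out Filtered spikes: `N x T` matrix (batch) or length-`N`
#'   vector (online).
#' @param mode `"batch"` or `"online"`.
#' @return The raw update matrix (`D x N`).
#' @export
readout_update <- function(J_out, y_targ, s_hat_out,
                           mode = c("batch", "online")) {
  mode <- match.arg(mode)
  if (mode == "batch") {
    (y_targ - J_out %*% s_hat_out) %*% t(s_hat_out)
  } else {
    (y_targ - drop(J_out %*% s_hat_out)) %o% s_hat_out
  }
}

#' Least-squares readout on a frozen raster
#'
#' The converged limit of the delta rule iterated from zero initialisation:
#' the minimum-norm least-squares solution of `J_out S = Y`, computed from
#' the SVD pseudoinverse of the filtered raster. Exact interpolation when
#' the trial is shorter than the network size.
#'
#' @param y_targ Target output (`D x T`).
#' @param s_hat_out Filtered raster (`N x T`).
#' @param tol Relative singular-value cutoff.
#' @return The readout matrix (`D x N`).
#' @export
readout_lsq <- function(y_targ, s_hat_out, tol = 1e-10) {
  sv <- svd(s_hat_out)
  keep <- sv$d > tol * sv$d[1]
  # pinv(S) = V diag(1/d) U^T (T x N) ; J_out = Y pinv(S)
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  y_targ %*% pinv
}
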
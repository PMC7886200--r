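#' Clock signal (box code)
#'
#' A low-dimensional temporally structured input providing a time scaffold:
#' `K` channels tile the trial in consecutive equal windows, each channel
#' equal to 1 inside its window and 0 outside.
#'
#' @param K Number of channels (`1 <= K <= T`).
#' @param T Trial length in steps.
#' @return A `K x T` matrix with entries in `{0, 1}`; class `clock_signal`.
#' @examples
#' make_clock(2, 10)  # channel 1 on for t in 1..5, channel 2 for 6..10
#' @export
make_clock <- function(K, T) {
  stopifnot(K >= 1, T >= 1)
  if (K > T) stop("K must not exceed T")
  edges <- floor(seq(0, T, length.out = K + 1))
  x <- matrix(0, K, T)
  for (k in seq_len(K)) x[k, (edges[k] + 1):edges[k + 1]] <- 1
  structure(x, class = c("clock_signal", "matrix", "array"))
}

#' Random Gaussian projection matrix
#'
#' Static projection with i.i.d. zero-mean Gaussian entries of standard
#' deviation `sigma`, reproducible under a seed.
#'
#' @param rows,cols Dimensions.
#' @param sigma Entry standard deviation (`>= 0`).
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return A `rows x cols` numeric matrix.
#' @export
make_projection <- function(rows, cols, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  matrix(stats::rnorm(rows * cols, 0, sigma), rows, cols)
}

#' Build the internal target spike pattern
#'
#' Drives the recurrence-free network with the clock current plus a random
#' projection of the desired output signal and records its deterministic
#' spiking activity. The resulting raster is the internal target the
#' recurrent weights are subsequently trained to replay, and is frozen for
#' the whole training process.
#'
#' @param weights An [snn_weights()] carrying `J_in` (`N x K`) and `J_teach`
#'   (`N x D`), or a list with those elements.
#' @param clock A `K x T` clock signal (see [make_clock()]).
#' @param y_targ Desired output signal, `D x T` matrix.
#' @param params An [snn_params()] object.
#' @param warmup Teacher-driven warm-up steps prepended before recording
#'   (clock and signal wrap around cyclically) and discarded. This makes the
#'   first recorded frame carry ongoing teacher-driven activity, so that the
#'   trial's initial spike frame (handed to the network as its initial
#'   condition) causally precedes every later target spike; without it, the
#'   very first teacher-driven spikes would have an empty presynaptic
#'   history and could never be credited to any recurrent synapse. Set to 0
#'   for a cold start.
#' @return A list of class `teacher_bundle`: `s_targ` (`N x T` raster),
#'   `I_clock`, `I_teach` (`N x T` currents), `v` (open-loop membrane trace),
#'   `clock`, and `y_targ`.
#' @export
build_target <- function(weights, clock, y_targ, params, warmup = 50) {
  if (is.numeric(y_targ) && is.null(dim(y_targ))) y_targ <- matrix(y_targ, 1)
  N <- params$N; T <- params$T
  J_in <- weights$J_in; J_teach <- weights$J_teach
  if (is.null(J_in) || is.null(J_teach)) stop("weights must carry J_in and J_teach")
  if (ncol(J_in) != nrow(clock)) stop("J_in columns must match clock channels")
  if (ncol(J_teach) != nrow(y_targ)) stop("J_teach columns must match output dimension")
  if (ncol(clock) != T || ncol(y_targ) != T) stop("clock and y_targ must span T steps")
  x <- unclass(clock)
  I_clock <- J_in %*% x
  I_teach <- J_teach %*% y_targ
  L <- min(warmup, T)
  s_init <- NULL
  if (L > 0) {
    # teacher-driven warm-up over the cyclically wrapped tail of the
    # signals; only its final spike frame is kept, as the engaged initial
    # condition of the recorded trial
    wrap <- (T - L + 1):T
    I_warm <- J_in %*% x[, wrap, drop = FALSE] +
      J_teach %*% y_targ[, wrap, drop = FALSE]
    pw <- params; pw$T <- as.integer(L)
    warm <- run_trial(matrix(0, N, N), I_warm, mode = "open_loop",
                      params = pw)
    s_init <- warm$raster[, L]
  }
  # the recorded run starts from the trial's own initial conditions
  # (v = v0, s = warm frame), so the raster is exactly the trajectory the
  # clamped/generation recursion can reproduce
  trial <- run_trial(matrix(0, N, N), I_clock + I_teach,
                     mode = "open_loop", params = params, s_init = s_init)
  s_targ <- trial$raster
  v <- trial$v
  structure(list(s_targ = s_targ, I_clock = I_clock, I_teach = I_teach,
                 v = v, clock = clock, y_targ = y_targ, warmup = L),
            class = "teacher_bundle")
}

#' @export
print.teacher_bundle <- function(x, ...) {
  cat(sprintf("Teacher bundle: %d x %d target raster, %d spikes (rate %.3f)\n",
              nrow(x$s_targ), ncol(x$s_targ), sum(x$s_targ), mean(x$s_targ)))
  cat(sprintf("  current std: teacher %.2f, clock %.2f\n",
              stats::sd(x$I_teach), stats::sd(x$I_clock)))
  invisible(x)
}
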
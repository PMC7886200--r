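#' Sample a random multi-sinusoid target trajectory
#'
#' Each channel is the superposition of four sinusoids at frequencies
#' 1, 2, 3 and 5 Hz, with amplitudes drawn uniformly from `[0.5, 2]` and
#' phases from `[0, 2*pi]`. Channels are normalized to unit maximum absolute
#' value, which fixes the scale on which MSEs are reported.
#'
#' @param seed Optional integer seed.
#' @param T Trial length in steps.
#' @param dt Step size in ms (time is `t * dt / 1000` seconds).
#' @param duration Signal duration in seconds spanned by the `T` bins;
#'   defaults to `T * dt / 1000` (real-time sampling). Set `duration = 1`
#'   to compress the full one-second waveform into `T` bins, as in the
#'   short-trial (few-presentations) task.
#' @param D Number of channels.
#' @param freqs Component frequencies in Hz.
#' @param amp_range Range of the uniform amplitude draw.
#' @param normalize Divide each channel by its maximum absolute value.
#' @return A `D x T` matrix with attributes `amplitudes` and `phases`
#'   (`D x length(freqs)` matrices).
#' @examples
#' y <- sample_trajectory(seed = 1, T = 1000, dt = 1)
#' dim(y)
#' @export
sample_trajectory <- function(seed = NULL, T = 1000, dt = 1, D = 3,
                              freqs = c(1, 2, 3, 5),
                              amp_range = c(0.5, 2), normalize = TRUE,
                              duration = T * dt / 1000) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::runif(D * length(freqs), amp_range[1], amp_range[2]),
              D, length(freqs))
  phi <- matrix(stats::runif(D * length(freqs), 0, 2 * pi), D,
                length(freqs))
  tt <- seq_len(T) / T * duration  # seconds
  y <- matrix(0, D, T)
  for (d in seq_len(D))
    for (j in seq_along(freqs))
      y[d, ] <- y[d, ] + A[d, j] * sin(2 * pi * freqs[j] * tt + phi[d, j])
  if (normalize) y <- normalize_trajectory(y)
  attr(y, "amplitudes") <- A
  attr(y, "phases") <- phi
  y
}

# channel-wise normalization to unit maximum absolute value
normalize_trajectory <- function(y) {
  m <- apply(abs(y), 1, max)
  m[m == 0] <- 1
  y / m
}

#' Mean squared error between trajectories
#'
#' Mean over all channels and timesteps of the squared difference.
#'
#' @param y,y_targ Equal-shaped numeric arrays.
#' @return A scalar.
#' @export
mse <- function(y, y_targ) {
  if (length(y) != length(y_targ)) stop("shapes differ")
  mean((y - y_targ)^2)
}

#' Normalized spike mismatch between two rasters
#'
#' The fraction of spike slots on which two rasters disagree (normalized
#' Hamming distance, in `[0, 1]`).
#'
#' @param s_targ,s_gen Equal-shaped binary matrices.
#' @return A scalar in `[0, 1]`.
#' @export
spike_mismatch <- function(s_targ, s_gen) {
  if (!all(dim(s_targ) == dim(s_gen))) stop("shapes differ")
  mean(abs(s_targ - s_gen))
}

#' Temporal XOR task definition
#'
#' Two bits are presented sequentially as single-pulse square waves whose
#' duty cycle encodes the bit (50% of the pulse window for 0, 25% for 1);
#' the desired response is a smooth bump at a later time whose sign encodes
#' the XOR of the two bits (`A_out = 2 (b1 xor b2) - 1`).
#'
#' @param T Trial length in steps.
#' @param pulse1,pulse2 Start step of the two pulse windows.
#' @param pulse_len Pulse window length in steps.
#' @param response_center Center of the response bump.
#' @param response_width Gaussian width (sd) of the bump in steps.
#' @return A list of class `xor_task` with one element per condition
#'   (`mu = 0..3`), each carrying `bits`, `x` (`1 x T` input signal),
#'   `y_targ` (`1 x T` response), and the expected `sign`.
#' @examples
#' task <- make_xor_task()
#' sapply(task$conditions, function(cc) cc$sign)
#' @export
make_xor_task <- function(T = 130, pulse1 = 1, pulse2 = 41, pulse_len = 30,
                          response_center = 110, response_width = 10) {
  pulse <- function(start, bit) {
    x <- numeric(T)
    on <- if (bit == 1) floor(0.25 * pulse_len) else floor(0.5 * pulse_len)
    x[start:min(start + on - 1, T)] <- 1
    x
  }
  tt <- seq_len(T)
  bump <- exp(-0.5 * ((tt - response_center) / response_width)^2)
  conds <- list()
  for (b1 in 0:1) for (b2 in 0:1) {
    a_out <- 2 * (xor(b1 == 1, b2 == 1) - 0.5)
    conds[[length(conds) + 1]] <-
      list(bits = c(b1, b2),
           x = matrix(pulse(pulse1, b1) + pulse(pulse2, b2), 1),
           y_targ = matrix(a_out * bump, 1),
           sign = a_out)
  }
  structure(list(conditions = conds, T = T,
                 response_window = c(response_center - 2 * response_width,
                                     min(response_center + 2 * response_width,
                                         T))),
            class = "xor_task")
}
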
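# Independent step-by-step oracle for the discrete-time LIF recurrence.
# Deliberately written as explicit per-neuron loops, independent of the
# package's vectorized / compiled paths.
oracle_trial_cuba <- function(J, I, params, mode = "generation",
                              s_clamp = NULL, s_init = NULL) {
  N <- params$N; T <- params$T
  a <- params$dt / params$tau_m
  b <- params$dt / params$tau_s
  if (is.null(s_init))
    s_init <- if (mode == "clamped") s_clamp[, 1] else numeric(N)
  S <- matrix(0, N, T); V <- matrix(0, N, T)
  v <- rep(params$v0, N); s <- s_init; sh <- s_init
  V[, 1] <- v; S[, 1] <- s
  for (t in 2:T) {
    s_next <- numeric(N)
    for (i in 1:N) {
      s_next[i] <- if (mode == "clamped") s_clamp[i, t]
                   else as.numeric(v[i] > params$v_th)
    }
    v_new <- numeric(N)
    for (i in 1:N) {
      rec <- 0
      if (mode != "open_loop") for (k in 1:N) rec <- rec + J[i, k] * sh[k]
      v_new[i] <- (1 - a) * v[i] + a * (rec + I[i, t] + params$v_rest) -
        params$J_res * s[i]
    }
    sh_new <- numeric(N)
    for (i in 1:N) sh_new[i] <- (1 - b) * sh[i] + b * s_next[i]
    v <- v_new; s <- s_next; sh <- sh_new
    V[, t] <- v; S[, t] <- s
  }
  list(raster = S, v = V)
}

# small teacher bundle for unit tests
tiny_bundle <- function(seed, params, K = 4, D = 2, warmup = 20) {
  set.seed(seed)
  y <- sample_trajectory(T = params$T, dt = params$dt, D = D, duration = 1)
  clock <- make_clock(K, params$T)
  J_in <- make_projection(params$N, K, params$sigma_in)
  J_teach <- make_projection(params$N, D, params$sigma_teach)
  b <- build_target(list(J_in = J_in, J_teach = J_teach), clock, y, params,
                    warmup = warmup)
  b$y <- y
  b
}

# a raster that is an exact fixed point of the dynamics: generate it from
# the network itself, then use it as its own target
self_consistent_bundle <- function(seed, params, K = 4) {
  set.seed(seed)
  J <- matrix(rnorm(params$N^2, 0, 1.5 / sqrt(params$N)), params$N, params$N)
  clock <- make_clock(K, params$T)
  J_in <- make_projection(params$N, K, 2)
  I <- J_in %*% unclass(clock)
  s1 <- as.numeric(runif(params$N) < 0.3)
  tr <- run_trial(J, I, mode = "generation", params = params, s_init = s1)
  list(J = J, I = I, s_targ = tr$raster, v = tr$v)
}
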
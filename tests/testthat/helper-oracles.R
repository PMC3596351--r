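# Independent oracles used by the tests; deliberately naive implementations
# that share no code with the package internals.

# Direct time-domain Morlet CWT at one scale: W(s, b_n) for every b on the
# sample grid, L2-normalized as sqrt(dt/s) * sum_m x_m psi0*((m-n) dt / s).
oracle_cwt_scale <- function(x, dt, s, omega0 = 6) {
  n <- length(x)
  idx <- seq_len(n)
  vapply(idx, function(b) {
    eta <- ((idx - b) * dt) / s
    psi <- pi^(-1 / 4) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
    sqrt(dt / s) * sum(x * Conj(psi))
  }, complex(1))
}

# Hill estimator of the cumulative tail exponent of a Pareto-type sample
# with known lower cutoff x_min.
oracle_hill <- function(x, x_min) {
  tail_x <- x[x > x_min]
  length(tail_x) / sum(log(tail_x / x_min))
}

# Deterministic highest-priority queue: same protocol as simulate_queue but
# always executes the current maximum; consumes the RNG stream in the same
# order (one dummy selection draw, one arrival draw per step) so that a
# run with the same seed is step-aligned with simulate_queue.
oracle_queue_argmax <- function(L, steps, floor_ = 1e-3) {
  x <- floor_ + (1 - floor_) * runif(L)
  arrival <- integer(L)
  taus <- integer(steps)
  for (t in seq_len(steps)) {
    runif(1)  # stands in for the selection draw
    sel <- which.max(x)
    taus[t] <- t - arrival[sel]
    x[sel] <- floor_ + (1 - floor_) * runif(1)
    arrival[sel] <- t
  }
  taus
}

# Generator scenario parameters shared across tests.
preset_truth <- list(
  wt    = list(gamma = 0.95, beta = 0.59, period = 24.0),
  per2  = list(gamma = 0.84, beta = 0.55, period = 23.1),
  clock = list(gamma = 0.99, beta = 0.62, period = 27.7),
  bmal1 = list(gamma = 0.97, beta = 0.65, period = NA_real_))

# Spectral pipeline for a single series exactly as the cohort runner
# applies it (aggregate to 60 s, grid extended 4 voices below the band,
# density normalized on the nominal band).
spectrum_of <- function(series, window = 60) {
  if (series$dt < window) series <- aggregate_series(series, window)
  fmax <- 1 / (2 * series$dt)
  normalized_spectrum(
    cwt_modulus(series, f_min = 1e-5 / 2^(4 / 16), f_max = fmax),
    norm_band = c(1e-5, fmax))
}
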
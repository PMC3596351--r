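test_that("resting-duration sampler follows the truncated power law", {
  set.seed(1701)
  # gamma = 1, scale = 1: median 2 (P(>= 2) = 0.5)
  d <- sample_resting_durations(1e5, 1, scale = 1, cap = 1e6, dt = 0)
  expect_equal(median(d), 2, tolerance = 0.02)
  # tight truncation: only two representable values survive
  d2 <- sample_resting_durations(500, 0.9, scale = 1, cap = 1.1, dt = 0.1)
  expect_true(all(d2 %in% c(1.0, 1.1)))
  # empirical survival within 3 SEM of the analytic truncated curve
  n <- 1e4
  d3 <- sample_resting_durations(n, 0.95, scale = 1, cap = 1e4, dt = 0)
  xs <- 10^seq(0.05, 3, by = 0.15)
  trunc_surv <- function(x) (x^-0.95 - 1e4^-0.95) / (1 - 1e4^-0.95)
  for (x in xs) {
    p <- trunc_surv(x)
    expect_lt(abs(mean(d3 >= x) - p), 3 * sqrt(p * (1 - p) / n) + 2 / n)
  }
  expect_error(sample_resting_durations(10, -1, 1, 10), "positive")
  expect_error(sample_resting_durations(10, 1, 1, 0.5), "cap")
})

test_that("active-duration sampler follows the stretched exponential", {
  set.seed(1702)
  d <- sample_active_durations(1e5, 1, scale = 2.5, dt = 0)
  expect_equal(mean(d), 2.5, tolerance = 0.02)          # beta = 1: exponential
  expect_equal(mean(d >= 2.5), exp(-1), tolerance = 0.02)
  d2 <- sample_active_durations(1e5, 0.59, scale = 1, dt = 0)
  expect_equal(mean(d2), gamma(1 + 1 / 0.59), tolerance = 0.02)
  expect_equal(mean(d2 >= 1), exp(-1), tolerance = 0.02)
  dq <- sample_active_durations(1000, 0.59, scale = 1, dt = 0.1)
  expect_true(all(abs(dq / 0.1 - round(dq / 0.1)) < 1e-9))
  expect_true(all(dq >= 0.1))
  expect_error(sample_active_durations(10, 0, 1), "positive")
})

test_that("zero-noise telegraph generation round-trips through extraction", {
  spec <- synth_spec(days = 0.05, dt = 0.1, circadian_period_h = NA,
                     circadian_depth = 0, ultradian_periods_h = numeric(0),
                     ultradian_amps = numeric(0), noise_sd = 0,
                     burst_sdlog = 0, seed = 1703)
  ser <- generate_series(spec)
  tr <- attr(ser, "truth")$epochs
  ds <- extract_durations(ser, threshold = 0.5)
  inner <- tr[2:(nrow(tr) - 1L), ]
  expect_identical(ds$resting, inner$duration_s[!inner$state])
  expect_identical(ds$active, inner$duration_s[inner$state])
  # rests carry exactly zero, bursts the constant magnitude
  expect_true(all(ser$values %in% c(0, exp(spec$burst_meanlog))))
})

test_that("generation is deterministic under a fixed seed", {
  s1 <- generate_series(locomotor_preset("wt", days = 0.1, seed = 1704))
  s2 <- generate_series(locomotor_preset("wt", days = 0.1, seed = 1704))
  expect_identical(s1$values, s2$values)
  s3 <- generate_series(locomotor_preset("wt", days = 0.1, seed = 1705))
  expect_false(identical(s1$values, s3$values))
})

test_that("generated series carry the prescribed bout-duration laws", {
  ser <- generate_series(locomotor_preset("wt", days = 1, dt = 0.1,
                                          seed = 1706))
  ds <- extract_durations(ser, multiplier = 1)
  gam <- fit_power_law(rescaled_cumulative(ds$resting))$gamma
  bet <- fit_stretched_exp(rescaled_cumulative(ds$active))$beta
  expect_lt(abs(gam - 0.95), 0.1)
  expect_lt(abs(bet - 0.59), 0.08)
})

test_that("injected oscillations surface as spectral maxima", {
  ser <- generate_series(locomotor_preset("bmal1", dt = 60, seed = 1707))
  sp <- spectrum_of(ser)
  pk <- spectral_peaks(sp, min_prominence = 0.05)
  f0 <- 1 / (8.6 * 3600)
  expect_true(any(abs(log(pk$freq_Hz / f0)) <= log(2^(1 / 16)) * 1.5))
  # the dominant ultradian component is the global spectral maximum
  expect_lt(abs(log(sp$freqs[which.max(sp$density)] / f0)), log(2^(2 / 16)))
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(synth_spec(days = -1), "positive")
  expect_error(synth_spec(gamma_true = 0), "positive")
  expect_error(synth_spec(circadian_depth = 1.4), "\\[0, 1\\]")
  expect_error(synth_spec(ultradian_periods_h = c(8, 6),
                          ultradian_amps = 0.1), "equal length")
  expect_error(synth_spec(rest_cap = 0.1), "rest_cap")
  expect_error(generate_series(synth_spec(dt = 60, rest_scale = 0.2,
                                          act_scale = 0.01)),
               "coarser")
})
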
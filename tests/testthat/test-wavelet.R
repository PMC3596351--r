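test_that("Morlet scale-frequency relation is the stated closed form", {
  # omega0 = 6: f * s = (6 + sqrt(38)) / (4 pi) ~ 0.9681
  expect_equal(scale_to_frequency(1) * 1, (6 + sqrt(38)) / (4 * pi))
  expect_equal(scale_to_frequency(1), 0.9681, tolerance = 1e-4)
  s <- c(10, 250, 9.7e4)
  expect_equal(scale_to_frequency(s[1]) / scale_to_frequency(s[2]),
               s[2] / s[1])
  expect_equal(frequency_to_scale(scale_to_frequency(s)), s,
               tolerance = 1e-12)
  expect_error(scale_to_frequency(-1), "positive")
  expect_error(frequency_to_scale(0), "positive")
})

test_that("period conversions reproduce the reported band landmarks", {
  expect_equal(frequency_to_period(3.24e-5, "hours", digits = 1), 8.6)
  expect_equal(frequency_to_period(4.53e-5, "hours", digits = 1), 6.1)
  expect_equal(frequency_to_period(1.88e-5, "hours", digits = 1), 14.8)
  expect_equal(frequency_to_period(1e-2, "seconds"), 100)
})

test_that("FFT-based CWT equals direct time-domain convolution", {
  set.seed(1401)
  n <- 256; dt <- 60
  x <- cos(2 * pi * (1:n) * dt / 7000) + 0.3 * rnorm(n)
  x <- x - mean(x)  # the transform demeans internally; align the oracle
  ser <- activity_series(x - min(x), dt = dt)  # nonneg container
  ser$values <- x  # bypass: compare on the exact zero-mean input
  m <- cwt_modulus(ser, f_min = 5e-4, f_max = 5e-3, voices = 8)
  for (i in c(3, 10, 17)) {
    w_direct <- oracle_cwt_scale(x, dt, m$scales[i])
    expect_lt(max(Mod(m$modulus[i, ] - Mod(w_direct))) /
                max(Mod(w_direct)), 1e-8)
  }
})

test_that("modulus is linear and vanishes for a zero signal", {
  set.seed(1402)
  z <- activity_series(rep(0, 512), dt = 60)
  expect_true(all(cwt_modulus(z, f_max = 1 / 120)$modulus == 0))
  x <- abs(rnorm(512)) + 0.2
  s1 <- activity_series(x, dt = 60)
  s2 <- activity_series(3 * x, dt = 60)
  m1 <- cwt_modulus(s1, f_max = 1 / 120)
  m2 <- cwt_modulus(s2, f_max = 1 / 120)
  expect_equal(m2$modulus, 3 * m1$modulus, tolerance = 1e-10)
})

test_that("pure tones are recovered at their own frequency", {
  dt <- 60
  tt <- (0:(3 * 1440 - 1)) * dt
  for (f0 in c(2e-5, 2.3e-4, 4.8e-3)) {
    ser <- activity_series(1 + 0.9 * sin(2 * pi * f0 * tt), dt = dt)
    m <- cwt_modulus(ser, f_max = 1 / 120)
    fhat <- m$freqs[which.max(rowMeans(m$modulus))]
    step <- 2^(1 / 16)
    expect_lt(abs(log(fhat / f0)), log(step) * 1.0001)
  }
})

test_that("a two-tone mixture yields two local spectral maxima", {
  dt <- 60
  tt <- (0:(3 * 1440 - 1)) * dt
  ser <- activity_series(2 + sin(2 * pi * tt / 86400) +
                           sin(2 * pi * tt / (8 * 3600)), dt = dt)
  sp <- normalized_spectrum(cwt_modulus(ser, f_max = 1 / 120))
  pk <- spectral_peaks(sp, min_prominence = 0.05)
  expect_gte(nrow(pk), 2L)
  step <- 2^(2 / 16)  # within one grid step (edge bias allows one more)
  expect_true(any(abs(log(pk$freq_Hz * 86400)) < log(step)))
  expect_true(any(abs(log(pk$freq_Hz * 8 * 3600)) < log(step)))
})

test_that("normalized spectrum has unit area and is scale free", {
  set.seed(1403)
  ser <- activity_series(abs(rnorm(2048)) + 0.1, dt = 60)
  m <- cwt_modulus(ser, f_max = 1 / 120)
  sp <- normalized_spectrum(m)
  expect_equal(pracma::trapz(sp$freqs, sp$density), 1, tolerance = 1e-6)
  m2 <- m; m2$modulus <- 7 * m$modulus
  expect_equal(normalized_spectrum(m2)$density, sp$density,
               tolerance = 1e-12)
  mz <- m; mz$modulus[] <- 0
  expect_error(normalized_spectrum(mz), "all-zero")
})

test_that("single tone gives a unimodal spectrum around its frequency", {
  dt <- 60
  tt <- (0:(3 * 1440 - 1)) * dt
  ser <- activity_series(1 + 0.9 * sin(2 * pi * tt / (6 * 3600)), dt = dt)
  sp <- normalized_spectrum(cwt_modulus(ser, f_max = 1 / 120))
  fmax_hat <- sp$freqs[which.max(sp$density)]
  pk <- spectral_peaks(sp, min_prominence = 0)
  other <- pk[abs(log2(pk$freq_Hz / fmax_hat)) > 2 / 16, ]
  if (nrow(other)) expect_true(all(other$density < 0.1 * max(sp$density)))
})

test_that("nyquist and frequency-range preconditions are enforced", {
  ser <- activity_series(abs(rnorm(600)) + 0.1, dt = 60)
  expect_error(cwt_modulus(ser, f_max = 1e-2), "Nyquist")
  expect_error(cwt_modulus(ser, f_min = 2e-3, f_max = 1e-3), "f_min")
  short <- activity_series(abs(rnorm(600)) + 0.1, dt = 0.1)
  m <- cwt_modulus(short, f_min = 1e-3, f_max = 1)
  expect_true(length(m$warnings) > 0)  # record shorter than one f_min cycle
})

test_that("circadian period finds the dominant in-band peak or reports extinction", {
  dt <- 60
  tt <- (0:(3 * 1440 - 1)) * dt
  set.seed(1404)
  for (Th in c(24, 23.1, 27.7)) {
    x <- pmax(1 + 0.9 * cos(2 * pi * tt / (Th * 3600)) +
                rnorm(length(tt), sd = 0.05), 0)
    sp <- spectrum_of(activity_series(x, dt = dt))
    p <- circadian_period(sp)
    expect_false(is.na(p))
    expect_lt(abs(p - Th) / Th, 0.05)
  }
  # ultradian-only record: no circadian peak
  x <- pmax(1 + 0.6 * cos(2 * pi * tt / (8.6 * 3600)) +
              rnorm(length(tt), sd = 0.05), 0)
  expect_true(is.na(circadian_period(spectrum_of(activity_series(x, dt)))))
})

test_that("band areas integrate the two bands and form their ratio", {
  # synthetic density: a Gaussian bump centered in the circadian band only
  f <- 10^seq(-5, log10(1 / 120), by = 1 / 16)
  d <- exp(-((f - 1.4e-5) / 1.5e-6)^2)
  d <- d / pracma::trapz(f, d)
  sp <- structure(list(freqs = f, density = d), class = "spectrum_density")
  ba <- band_areas(sp)
  expect_gt(ba$A_cir, 0.95)
  expect_lt(ba$A_ult / ba$A_cir, 1e-4)
  # equal-amplitude 24 h and 8.6 h tones: R near 1, checked against a
  # direct integration of the same density restricted to each band
  tt <- (0:(3 * 1440 - 1)) * 60
  ser <- activity_series(2 + sin(2 * pi * tt / 86400) +
                           sin(2 * pi * tt / (8.6 * 3600)), dt = 60)
  sp2 <- normalized_spectrum(cwt_modulus(ser, f_max = 1 / 120))
  ba2 <- band_areas(sp2)
  cir <- sp2$freqs >= 1e-5 & sp2$freqs <= 2e-5
  ult <- sp2$freqs >= 2e-5 & sp2$freqs <= 1.1e-4
  r_direct <- pracma::trapz(sp2$freqs[ult], sp2$density[ult]) /
    pracma::trapz(sp2$freqs[cir], sp2$density[cir])
  expect_equal(ba2$R, r_direct, tolerance = 0.05)
  expect_gt(ba2$R, 1 / 3); expect_lt(ba2$R, 3)
})
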
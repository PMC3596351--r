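test_that("duration extraction enumerates interior runs at the threshold", {
  s <- activity_series(c(0, 0, 1, 1, 1, 0, 1, 0, 0), dt = 0.1)
  ds <- extract_durations(s, threshold = 0.5)
  expect_equal(ds$resting, 0.1)
  expect_equal(ds$active, c(0.3, 0.1), tolerance = 1e-12)
  expect_equal(ds$mean_rest, 0.1)
  expect_equal(ds$mean_act, 0.2)
  # classification at exact equality: value == theta is resting
  s2 <- activity_series(c(0, 1, 0.5, 1, 0), dt = 0.1)
  ds2 <- extract_durations(s2, threshold = 0.5)
  expect_equal(ds2$resting, 0.1)
  expect_error(extract_durations(activity_series(c(0, 1), dt = 0.1),
                                 threshold = 0.5), "fewer than 3 runs")
})

test_that("run accounting and threshold monotonicity hold", {
  set.seed(1501)
  v <- abs(rnorm(5000)) * rbinom(5000, 1, 0.4)
  s <- activity_series(v, dt = 0.1)
  theta1 <- mean_nonzero(s) * 0.8
  theta2 <- mean_nonzero(s) * 1.4
  r1 <- rle(v > theta1)
  expect_equal(sum(r1$lengths), length(v))     # untruncated runs tile record
  expect_true(all(abs(diff(as.integer(r1$values))) == 1))  # strict alternation
  # every active sample at the higher threshold was active at the lower
  expect_true(all(v[v > theta2] > theta1))
  ds1 <- extract_durations(s, threshold = theta1)
  ds2 <- extract_durations(s, threshold = theta2)
  expect_lte(sum(ds2$active), sum(ds1$active) + 2 * 0.1)
  expect_lte(abs(length(ds1$resting) - length(ds1$active)), 1L)
})

test_that("extracted duration laws match the generating laws (telegraph oracle)", {
  set.seed(1502)
  n <- 1e4
  rest <- sample_resting_durations(n, 0.95, scale = 0.3, cap = 3600, dt = 0.1)
  act <- sample_active_durations(n, 0.6, scale = 0.4, dt = 0.1)
  lens <- as.vector(rbind(round(rest / 0.1), round(act / 0.1)))
  v <- rep(rep(c(0, 1), n), lens)
  ds <- extract_durations(activity_series(v, dt = 0.1), threshold = 0.5)
  # two-sample KS distance between extracted and freshly drawn durations
  ks_r <- suppressWarnings(stats::ks.test(
    ds$resting, sample_resting_durations(n, 0.95, 0.3, 3600, dt = 0.1)))
  ks_a <- suppressWarnings(stats::ks.test(
    ds$active, sample_active_durations(n, 0.6, 0.4, dt = 0.1)))
  expect_lt(unname(ks_r$statistic), 1.95 / sqrt(n / 2))
  expect_lt(unname(ks_a$statistic), 1.95 / sqrt(n / 2))
})

test_that("rescaled cumulative distribution is a proper survival curve", {
  set.seed(1503)
  d <- rexp(500, rate = 2)
  cd <- rescaled_cumulative(d)
  expect_equal(mean(d / mean(d)), 1, tolerance = 1e-12)
  expect_true(all(diff(cd$P) <= 1e-12))
  expect_true(all(cd$P >= 0 & cd$P <= 1))
  expect_equal(cum_prob(cd, min(cd$x)), 1)
  # sample {1,1,1}: survival 1 up to 1, 0 beyond the containing bin
  cd3 <- rescaled_cumulative(c(1, 1, 1), mean_duration = 1, bin_width = 0.1)
  expect_equal(cum_prob(cd3, 0.85), 1)
  expect_equal(cum_prob(cd3, 1.2), 0)
  expect_true(rescaled_cumulative(d[1:10])$low_confidence)
  expect_error(rescaled_cumulative(numeric(0)), "empty")
})

test_that("empirical survival of Pareto draws tracks the analytic curve", {
  set.seed(1504)
  n <- 1e4
  d <- sample_resting_durations(n, 1, scale = 1, cap = 1e6, dt = 0)
  cd <- rescaled_cumulative(d, mean_duration = 1)  # already on the x scale
  sel <- cd$x >= 1.5 & cd$x <= 50
  p_true <- cd$x[sel]^-1
  sem <- sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(cd$P[sel] - p_true) < 3 * sem + 0.1 / n))
})

test_that("fitters recover their own noiseless curves to high precision", {
  x <- log_grid(0.05, 50, 20)
  pl <- structure(list(x = x, P = x^-0.84, bin_width = 0.01,
                       n = 1e6, low_confidence = FALSE), class = "cumdist")
  f1 <- fit_power_law(pl)
  expect_equal(f1$gamma, 0.84, tolerance = 1e-6)
  pl2 <- pl; pl2$P <- x^-1
  expect_equal(fit_power_law(pl2)$gamma, 1, tolerance = 1e-6)

  se <- structure(list(x = x, P = exp(-x^0.59), bin_width = 0.01,
                       n = 1e6, low_confidence = FALSE), class = "cumdist")
  f2 <- fit_stretched_exp(se)
  expect_equal(f2$beta, 0.59, tolerance = 1e-6)
  expect_equal(f2$x0, 1, tolerance = 1e-5)
  se2 <- se; se2$P <- exp(-se2$x)
  f3 <- fit_stretched_exp(se2)
  expect_equal(f3$beta, 1, tolerance = 1e-6)
  expect_equal(f3$x0, 1, tolerance = 1e-6)
  # predict methods reproduce the fitted law
  expect_equal(predict(f2, 2), exp(-2^f2$beta * f2$x0^-f2$beta),
               tolerance = 1e-8)
  expect_equal(unname(coef(f1)["gamma"]), f1$gamma)
})

test_that("fit preconditions reject unsupported ranges", {
  x <- log_grid(0.05, 50, 20)
  pl <- structure(list(x = x, P = pmin(1, x^-1), bin_width = 0.01,
                       n = 100, low_confidence = FALSE), class = "cumdist")
  expect_error(fit_power_law(pl, range = c(40, 50)), "at least 10")
})

test_that("power-law estimator agrees with the Hill oracle on average", {
  set.seed(1505)
  reps <- 25; n <- 5000
  fits <- hills <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- sample_resting_durations(n, 0.95, scale = 1, cap = 18000, dt = 0)
    fits[i] <- fit_power_law(rescaled_cumulative(d))$gamma
    hills[i] <- oracle_hill(d, x_min = 2)
  }
  expect_lt(abs(mean(fits) - 0.95), 0.05)
  expect_lt(abs(mean(hills) - 0.95), 0.05)
  expect_lt(abs(mean(fits) - mean(hills)), 0.07)
})

test_that("stretched-exponential estimator agrees with the Weibull MLE oracle", {
  skip_if_not_installed("MASS")
  set.seed(1506)
  reps <- 20; n <- 5000
  fits <- mles <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- sample_active_durations(n, 0.6, scale = 1, dt = 0)
    fits[i] <- fit_stretched_exp(rescaled_cumulative(d))$beta
    mles[i] <- unname(suppressWarnings(
      MASS::fitdistr(d, "weibull"))$estimate["shape"])
  }
  expect_lt(abs(mean(fits) - 0.6), 0.05)
  expect_lt(abs(mean(mles) - 0.6), 0.02)
})

test_that("threshold sweep reproduces the default pipeline and degrades gracefully", {
  ser <- generate_series(locomotor_preset("wt", days = 0.5, dt = 0.1,
                                          seed = 1507))
  sw <- threshold_sweep(ser, multipliers = 1.0)
  ds <- extract_durations(ser, multiplier = 1)
  expect_equal(sw$gamma, fit_power_law(rescaled_cumulative(ds$resting))$gamma)
  expect_equal(sw$mean_rest, ds$mean_rest)
  # an impossible multiplier is recorded per-row, the sweep continues
  sw2 <- threshold_sweep(ser, multipliers = c(1e9, 1.0))
  expect_false(is.na(sw2$error[1]))
  expect_true(is.na(sw2$error[2]))
  expect_false(is.na(sw2$gamma[2]))
})

test_that("mean bout durations respond monotonically to the threshold", {
  ser <- generate_series(locomotor_preset("wt", days = 1, dt = 0.1,
                                          seed = 1508))
  sw <- threshold_sweep(ser, multipliers = seq(0.6, 1.8, 0.3))
  expect_true(all(diff(sw$mean_rest) > 0))
  expect_true(all(diff(sw$mean_act) < 0.01))
})

test_that("group averaging combines individuals pointwise", {
  set.seed(1509)
  mk <- function(n) rescaled_cumulative(rexp(n) + 0.1)
  d1 <- mk(400); d2 <- mk(400)
  g <- group_average(list(d1, d1))
  expect_true(all(g$sem == 0))
  g2 <- group_average(list(d1, d2))
  expect_equal(g2$mean_P, (d1$P + d2$P) / 2)
  expect_equal(g2$k, 2L)
  bad <- d2; bad$x <- bad$x * 2
  expect_error(group_average(list(d1, bad)), "mismatched")
  expect_error(group_average(list(d1)), "at least 2")
})

test_that("cohort group mean stays near the analytic survival curve", {
  set.seed(1510)
  dists <- lapply(1:12, function(i)
    rescaled_cumulative(sample_active_durations(2000, 0.59, 1, dt = 0)))
  g <- group_average(dists)
  sel <- g$x >= 0.2 & g$x <= 5
  truth <- exp(-(g$x[sel] * gamma(1 + 1 / 0.59))^0.59)
  dev <- abs(g$mean_P[sel] - truth)
  expect_true(all(dev < 2 * pmax(g$sem[sel], 0.004)))
})
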
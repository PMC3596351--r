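#' Extract resting and active bout durations by threshold crossing
#'
#' Classifies every sample of an activity series as active (value strictly
#' above the threshold) or resting (value at or below it), and converts
#' maximal runs of each state into durations (run length times the sampling
#' interval). The first and last runs are truncated by the recording
#' boundaries (their true length is unknowable) and are discarded. The
#' threshold defaults to `multiplier` times the mean of the non-zero
#' activity levels of the record.
#'
#' @param series An [activity_series()], typically at 0.1 s resolution.
#' @param multiplier Threshold multiplier `m` (default 1; the robustness
#'   sweep uses 0.6--1.8).
#' @param threshold Optional explicit threshold, overriding `multiplier *`
#'   [mean_nonzero()].
#' @return An object of class `duration_sample`: lists `resting` and
#'   `active` of durations in seconds, their means `mean_rest` / `mean_act`,
#'   the `threshold` and `multiplier` used, and the series `dt`.
#' @examples
#' s <- activity_series(c(0, 0, 1, 1, 1, 0, 1, 0, 0), dt = 0.1)
#' extract_durations(s, threshold = 0.5)
#' @export
extract_durations <- function(series, multiplier = 1, threshold = NULL) {
  stopifnot(inherits(series, "activity_series"))
  if (is.null(threshold)) {
    if (multiplier <= 0) stop("threshold multiplier must be positive")
    threshold <- multiplier * mean_nonzero(series)
  } else multiplier <- NA_real_
  act <- series$values > threshold
  r <- rle(act)
  if (length(r$lengths) < 3L)
    stop("fewer than 3 runs: no interior bouts after discarding boundary runs")
  keep <- 2:(length(r$lengths) - 1L)
  lens <- r$lengths[keep]
  states <- r$values[keep]
  resting <- lens[!states] * series$dt
  active <- lens[states] * series$dt
  structure(list(resting = resting, active = active,
                 mean_rest = if (length(resting)) mean(resting) else NA_real_,
                 mean_act = if (length(active)) mean(active) else NA_real_,
                 threshold = threshold, multiplier = multiplier,
                 dt = series$dt),
            class = "duration_sample")
}

#' @export
print.duration_sample <- function(x, ...) {
  cat(sprintf("<duration_sample> threshold %.4g (m = %s)\n", x$threshold,
              if (is.na(x$multiplier)) "explicit" else format(x$multiplier)))
  cat(sprintf("  resting: n = %d, mean <a_r> = %.3f s\n",
              length(x$resting), x$mean_rest))
  cat(sprintf("  active : n = %d, mean <a_a> = %.3f s\n",
              length(x$active), x$mean_act))
  invisible(x)
}

#' Logarithmic evaluation grid
#'
#' Shared grid on which rescaled cumulative distributions are evaluated so
#' that individuals can be averaged and compared pointwise.
#'
#' @param from,to Grid limits (rescaled duration units).
#' @param per_decade Points per decade (default 20).
#' @return Increasing numeric vector.
#' @export
log_grid <- function(from = 1e-2, to = 1e2, per_decade = 20) {
  10^seq(log10(from), log10(to), by = 1 / per_decade)
}

#' Mean-rescaled cumulative distribution of bout durations
#'
#' Durations are divided by the individual mean, a probability density is
#' estimated on bins of width `bin_width` (the rescaled equivalent of the
#' 0.1 s recording bins), and the density is integrated from above to give
#' the cumulative distribution `P(>= x)`, evaluated on a shared logarithmic
#' grid. Because the binned density is piecewise constant, its integral is
#' evaluated exactly (piecewise linear in x).
#'
#' @param durations Numeric vector of bout durations (seconds), or a column
#'   of a [extract_durations()] result.
#' @param mean_duration Individual mean used for rescaling (default: the
#'   sample mean).
#' @param bin_width Bin width on the rescaled axis (default `0.1 /
#'   mean_duration`, i.e. 0.1 s before rescaling).
#' @param grid Evaluation grid (default [log_grid()]).
#' @return An object of class `cumdist`: `x` (grid), `P` (cumulative
#'   probability, non-increasing), `bin_width`, `n`, and a `low_confidence`
#'   flag when fewer than 50 durations are available.
#' @export
rescaled_cumulative <- function(durations, mean_duration = mean(durations),
                                bin_width = 0.1 / mean_duration,
                                grid = log_grid()) {
  durations <- as.numeric(durations)
  if (length(durations) == 0L) stop("empty duration sample")
  if (!is.finite(mean_duration) || mean_duration <= 0)
    stop("mean duration must be positive")
  x <- durations / mean_duration
  n <- length(x)
  nb <- ceiling(max(x) / bin_width)
  counts <- tabulate(pmin(nb, ceiling(x / bin_width)), nbins = nb)
  # CDF at bin edges 0, bw, 2bw, ...; linear within bins (uniform density)
  edges <- bin_width * (0:nb)
  cdf <- c(0, cumsum(counts)) / n
  P <- 1 - approx(edges, cdf, xout = grid, rule = 2)$y
  P[grid <= 0] <- 1
  structure(list(x = grid, P = P, bin_width = bin_width, n = n,
                 low_confidence = n < 50L),
            class = "cumdist")
}

#' Empirical cumulative distribution on arbitrary support
#'
#' Survival function `P(>= x)` of a sample evaluated at its own unique
#' values (used for the integer waiting times of the queue model).
#'
#' @param values Numeric sample.
#' @return A `cumdist` whose `x` are the sorted unique values.
#' @export
empirical_cumulative <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty sample")
  tab <- table(values)
  x <- as.numeric(names(tab))
  P <- rev(cumsum(rev(as.numeric(tab)))) / length(values)
  structure(list(x = x, P = P, bin_width = NA_real_, n = length(values),
                 low_confidence = length(values) < 50L),
            class = "cumdist")
}

#' Evaluate a cumulative distribution at given points
#' @param dist A `cumdist`.
#' @param q Query points.
#' @return `P(>= q)`, by right-continuous step lookup on the stored grid.
#' @export
cum_prob <- function(dist, q) {
  stopifnot(inherits(dist, "cumdist"))
  vapply(q, function(qi) {
    if (qi <= dist$x[1]) return(1)
    i <- findInterval(qi, dist$x)
    if (dist$x[i] < qi) { if (i == length(dist$x)) 0 else dist$P[i + 1L] }
    else dist$P[i]
  }, numeric(1))
}

#' @export
print.cumdist <- function(x, ...) {
  pos <- x$P > 0
  cat(sprintf("<cumdist> n = %d, support x in [%.3g, %.3g]%s\n", x$n,
              min(x$x[pos]), max(x$x[pos]),
              if (isTRUE(x$low_confidence)) " (low confidence: n < 50)" else ""))
  invisible(x)
}

#' @export
plot.cumdist <- function(x, ...) {
  pos <- x$P > 0
  graphics::plot(x$x[pos], x$P[pos], log = "xy", type = "s",
                 xlab = "rescaled duration x", ylab = "P(>= x)", ...)
  invisible(x)
}

#' Fit a power law to a cumulative distribution
#'
#' Fits `P(>= x) = A * x^(-gamma)` to the grid points with `P > 0` inside
#' `range`, as a straight line in (log10 x, log10 P) by orthogonal distance
#' regression (errors in both coordinates, unit weights) with
#' Levenberg--Marquardt minimization of the chi-square statistic; five
#' starting slopes are tried and the best local minimum kept. This is the
#' estimator for the resting-bout scaling exponent: smaller `gamma` means a
#' fatter tail and more intermittent behavior.
#'
#' @param dist A [rescaled_cumulative()] (or [empirical_cumulative()])
#'   result.
#' @param range Fit range on the rescaled axis, default `c(0.2, 20)` (the
#'   resting law holds over more than two decades up to x = 20).
#' @param n_starts Number of multi-start perturbations (default 5).
#' @return Object of class `powerlaw_fit`: `gamma`, `amplitude`, `chi2`,
#'   `range`, `n_points`.
#' @export
fit_power_law <- function(dist, range = c(0.2, 20), n_starts = 5) {
  stopifnot(inherits(dist, "cumdist"))
  sel <- dist$x >= range[1] & dist$x <= range[2] & dist$P > 0
  if (sum(sel) < 10L)
    stop("need at least 10 grid points with P > 0 inside the fit range")
  lx <- log10(dist$x[sel]); ly <- log10(dist$P[sel])
  sl <- unname(coef(lm(ly ~ lx)))          # OLS seed: (intercept, slope)
  fac <- c(1, 0.5, 0.75, 1.5, 2)[seq_len(n_starts)]
  starts <- lapply(fac, function(f) c(sl[1], sl[2] * f))
  fit <- .odr_fit(lx, ly, function(x, th) th[1] + th[2] * x, starts,
                  dtheta = function(x, th) cbind(1, x),
                  dx = function(x, th) rep(th[2], length(x)))
  structure(list(gamma = -fit$theta[2], amplitude = 10^fit$theta[1],
                 chi2 = fit$chi2, range = range, n_points = sum(sel)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> P(>=x) = %.4g * x^-%.4f   (chi2 = %.3g, %d pts on [%g, %g])\n",
    x$amplitude, x$gamma, x$chi2, x$n_points, x$range[1], x$range[2]))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(gamma = object$gamma, amplitude = object$amplitude)
}

#' @export
predict.powerlaw_fit <- function(object, x, ...) {
  object$amplitude * x^(-object$gamma)
}

#' Fit a stretched exponential to a cumulative distribution
#'
#' Fits `P(>= x) = exp(-(x/x0)^beta)` to the grid points with `P > 0`
#' inside `range`, by orthogonal distance regression on (x, log P) with the
#' same Levenberg--Marquardt multi-start procedure as [fit_power_law()].
#' This is the estimator for the active-bout stretching exponent.
#'
#' @inheritParams fit_power_law
#' @param range Fit range, default `c(0.1, 10)`.
#' @return Object of class `stretchexp_fit`: `beta`, `x0`, `chi2`, `range`,
#'   `n_points`.
#' @export
fit_stretched_exp <- function(dist, range = c(0.1, 10), n_starts = 5) {
  stopifnot(inherits(dist, "cumdist"))
  sel <- dist$x >= range[1] & dist$x <= range[2] & dist$P > 0
  if (sum(sel) < 10L)
    stop("need at least 10 grid points with P > 0 inside the fit range")
  xx <- dist$x[sel]; ly <- log(dist$P[sel])
  ok <- ly < 0
  seed <- if (sum(ok) >= 2L) {
    cf <- unname(coef(lm(log(-ly[ok]) ~ log(xx[ok]))))  # log(-logP)=b*logx - b*logx0
    b0 <- max(cf[2], 0.05)
    c(log(b0), -cf[1] / b0)                              # (log beta, log x0)
  } else c(0, 0)
  starts <- lapply(list(c(0, 0), c(log(0.5), 0), c(log(2), 0),
                        c(0, log(2)), c(0, -log(2))),
                   function(d) seed + d)[seq_len(n_starts)]
  fn <- function(x, th) -(pmax(x, 1e-300) / exp(th[2]))^exp(th[1])
  dtheta <- function(x, th) {
    b <- exp(th[1]); u <- pmax(x, 1e-300) / exp(th[2])
    cbind(-u^b * log(u) * b, b * u^b)
  }
  dx <- function(x, th) {
    b <- exp(th[1]); u <- pmax(x, 1e-300) / exp(th[2])
    -b * u^(b - 1) / exp(th[2])
  }
  fit <- .odr_fit(xx, ly, fn, starts, dtheta = dtheta, dx = dx)
  structure(list(beta = exp(fit$theta[1]), x0 = exp(fit$theta[2]),
                 chi2 = fit$chi2, range = range, n_points = sum(sel)),
            class = "stretchexp_fit")
}

#' @export
print.stretchexp_fit <- function(x, ...) {
  cat(sprintf(
    "<stretchexp_fit> P(>=x) = exp(-(x/%.4f)^%.4f)   (chi2 = %.3g, %d pts on [%g, %g])\n",
    x$x0, x$beta, x$chi2, x$n_points, x$range[1], x$range[2]))
  invisible(x)
}

#' @export
coef.stretchexp_fit <- function(object, ...) {
  c(beta = object$beta, x0 = object$x0)
}

#' @export
predict.stretchexp_fit <- function(object, x, ...) {
  exp(-(x / object$x0)^object$beta)
}

#' Threshold-robustness sweep
#'
#' Re-runs the whole bout pipeline (threshold, duration extraction,
#' rescaling, both fits) for a set of threshold multipliers and tabulates
#' the parameters against the multiplier, mirroring the robustness analysis
#' in which conclusions must hold at every threshold between 0.6 and 1.8
#' times the mean non-zero activity.
#'
#' @param series An `activity_series` (0.1 s resolution).
#' @param multipliers Threshold multipliers (default `seq(0.6, 1.8, 0.1)`).
#' @param rest_range,act_range Fit ranges passed to the two fitters.
#' @return Data frame with one row per multiplier: `m`, `gamma`, `beta`,
#'   `mean_rest`, `mean_act`, `n_rest`, `n_act`, `error` (NA when the row
#'   succeeded; failures do not abort the sweep).
#' @export
threshold_sweep <- function(series, multipliers = seq(0.6, 1.8, by = 0.1),
                            rest_range = c(0.2, 20), act_range = c(0.1, 10)) {
  rows <- lapply(multipliers, function(m) {
    out <- data.frame(m = m, gamma = NA_real_, beta = NA_real_,
                      mean_rest = NA_real_, mean_act = NA_real_,
                      n_rest = NA_integer_, n_act = NA_integer_,
                      error = NA_character_)
    tryCatch({
      ds <- extract_durations(series, multiplier = m)
      pf <- fit_power_law(rescaled_cumulative(ds$resting), range = rest_range)
      sf <- fit_stretched_exp(rescaled_cumulative(ds$active), range = act_range)
      out$gamma <- pf$gamma; out$beta <- sf$beta
      out$mean_rest <- ds$mean_rest; out$mean_act <- ds$mean_act
      out$n_rest <- length(ds$resting); out$n_act <- length(ds$active)
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  do.call(rbind, rows)
}

#' Group-averaged cumulative distribution
#'
#' Pointwise mean and standard error of the mean across individual
#' cumulative distributions evaluated on the same grid. An optional
#' reference point aligns the curves vertically (multiplicatively) so they
#' take the same value there; alignment is for display only and is never
#' applied before fitting.
#'
#' @param dists List of `cumdist` objects sharing one grid.
#' @param align_at Optional reference x at which curves are aligned.
#' @return Object of class `group_distribution`: `x`, `mean_P`, `sem`, `k`
#'   (number of individuals).
#' @export
group_average <- function(dists, align_at = NULL) {
  if (length(dists) < 2L) stop("need at least 2 individuals")
  stopifnot(all(vapply(dists, inherits, logical(1), "cumdist")))
  x <- dists[[1]]$x
  for (d in dists)
    if (length(d$x) != length(x) || any(abs(d$x - x) > 1e-10 * pmax(x, 1)))
      stop("mismatched grids across individuals")
  M <- vapply(dists, function(d) {
    P <- d$P
    if (!is.null(align_at)) {
      ref <- cum_prob(d, align_at)
      if (ref <= 0) stop("alignment point outside the support of a curve")
      P <- P / ref
    }
    P
  }, numeric(length(x)))
  structure(list(x = x, mean_P = rowMeans(M),
                 sem = apply(M, 1, sd) / sqrt(ncol(M)), k = ncol(M)),
            class = "group_distribution")
}

#' @export
print.group_distribution <- function(x, ...) {
  cat(sprintf("<group_distribution> k = %d individuals, %d grid points\n",
              x$k, length(x$x)))
  invisible(x)
}

#' Write bout durations / distributions / fits to disk
#'
#' Durations go to one-column text, distributions to `(x, P[, sem])`
#' delimited text, and fits to flat JSON records.
#'
#' @param x Object to write.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_durations <- function(x, path) {
  v <- if (inherits(x, "duration_sample")) c(x$resting, x$active) else
    as.numeric(x)
  writeLines(format(v, digits = 17, trim = TRUE), path)
  invisible(path)
}

#' @rdname write_durations
#' @export
write_cumdist <- function(x, path) {
  d <- if (inherits(x, "group_distribution"))
    data.frame(x = x$x, P = x$mean_P, sem = x$sem)
  else data.frame(x = x$x, P = x$P)
  write.table(format(d, digits = 17, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_durations
#' @export
write_fit_json <- function(x, path) {
  stopifnot(inherits(x, "powerlaw_fit") || inherits(x, "stretchexp_fit") ||
            is.data.frame(x))
  jsonlite::write_json(if (is.data.frame(x)) x else unclass(x), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
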
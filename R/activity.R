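#' Raw sensor signal
#'
#' Container for a uniformly sampled raw sensor record (e.g. the voltage of a
#' piezoelectric sheet under a cage, sampled at 100 Hz). This is the input to
#' [local_variance()], which converts it into the activity series analyzed by
#' the rest of the package.
#'
#' @param values Numeric vector of finite samples (arbitrary units).
#' @param dt Sampling interval in seconds (e.g. `0.01` for 100 Hz).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `raw_signal`.
#' @export
raw_signal <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)")
  if (length(values) < 2L) stop("a raw signal needs at least 2 samples")
  if (any(!is.finite(values))) stop("raw signal values must be finite")
  structure(list(values = values, dt = as.numeric(dt), t0 = as.numeric(t0)),
            class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %d samples @ %g s (%.1f s total)\n",
              length(x$values), x$dt, length(x$values) * x$dt))
  invisible(x)
}

#' Activity series
#'
#' A uniformly sampled nonnegative activity series: each value is the local
#' variance of the detrended sensor signal over one window ("nVar" when
#' normalized by the record mean). Two window sizes are typical: 60 s for
#' spectral (circadian/ultradian) work and 0.1 s for bout-duration statistics.
#'
#' @param values Nonnegative numeric vector.
#' @param dt Window size / sampling interval in seconds.
#' @param normalized Logical; `TRUE` if the values have been divided by the
#'   record mean so that `mean(values) == 1`.
#' @param t0 Start time in seconds.
#' @return An object of class `activity_series` with fields `values`, `dt`,
#'   `normalized`, `t0`.
#' @seealso [local_variance()], [normalize_series()], [mean_nonzero()]
#' @export
activity_series <- function(values, dt, normalized = FALSE, t0 = 0) {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)")
  if (length(values) < 1L) stop("empty activity series")
  if (any(!is.finite(values))) stop("activity values must be finite")
  if (any(values < 0)) stop("activity values must be nonnegative")
  structure(list(values = values, dt = as.numeric(dt),
                 normalized = isTRUE(normalized), t0 = as.numeric(t0)),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %d windows @ %g s (%.2f h)%s\n",
              length(x$values), x$dt,
              length(x$values) * x$dt / 3600,
              if (x$normalized) ", normalized (nVar)" else ""))
  cat(sprintf("  mean %.4g | mean of non-zero values %.4g | %.1f%% zero\n",
              mean(x$values),
              if (any(x$values > 0)) mean(x$values[x$values > 0]) else NA,
              100 * mean(x$values == 0)))
  invisible(x)
}

#' Sample times of an activity series
#' @param series An `activity_series`.
#' @return Numeric vector of window-start times in seconds.
#' @export
series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1L) * series$dt
}

#' Windowed detrended local variance of a raw signal
#'
#' Partitions the raw signal into consecutive non-overlapping windows of
#' length `window` seconds, fits and subtracts an ordinary least-squares line
#' within each window (the local trend), and returns the population variance
#' of the residuals per window. This "energy" of the detrended signal is the
#' locomotor activity measure; a trailing partial window is discarded.
#'
#' @param raw A [raw_signal()] (or a plain numeric vector, in which case
#'   `dt_raw` must be given).
#' @param window Window length in seconds; must be a positive multiple of the
#'   raw sampling interval and span at least 2 samples.
#' @param dt_raw Sampling interval when `raw` is a plain vector.
#' @return An [activity_series()] with `dt = window`.
#' @details The variance uses the population denominator (divide by the
#'   number of samples in the window); only relative levels matter downstream
#'   because series are normalized by their record mean.
#' @examples
#' r <- raw_signal(sin(2 * pi * (0:999) / 50) + rnorm(1000, sd = 0.1), dt = 0.01)
#' local_variance(r, window = 1)
#' @export
local_variance <- function(raw, window, dt_raw = NULL) {
  if (!inherits(raw, "raw_signal")) {
    if (is.null(dt_raw)) stop("give a raw_signal, or a vector plus 'dt_raw'")
    raw <- raw_signal(raw, dt_raw)
  }
  dt <- raw$dt
  k <- window / dt
  if (abs(k - round(k)) > 1e-8 * max(1, k))
    stop("'window' must be an integer multiple of the raw sampling interval")
  k <- as.integer(round(k))
  if (k < 2L) stop("window must contain at least 2 raw samples")
  n <- length(raw$values)
  m <- n %/% k
  if (m < 1L) stop("signal shorter than one window")
  y <- matrix(raw$values[seq_len(m * k)], nrow = k, ncol = m)
  # OLS residual variance per window, population form:
  #   var(y) - cov(t, y)^2 / var(t), with t the centered within-window index
  tc <- seq_len(k) - (k + 1) / 2
  st2 <- sum(tc^2) / k
  my <- colMeans(y)
  my2 <- colMeans(y^2)
  sty <- colSums(tc * y) / k
  v <- (my2 - my^2) - sty^2 / st2
  v[v < 0] <- 0  # guard against roundoff on exactly-linear windows
  activity_series(v, dt = window, t0 = raw$t0)
}

#' Normalize an activity series by its record mean
#'
#' Divides every value by the mean of the record so that the output has mean
#' 1 ("nVar" units). Normalization makes records comparable across
#' individuals of different body weight.
#'
#' @param series An `activity_series` with positive mean.
#' @return The normalized `activity_series`.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  m <- mean(series$values)
  if (m <= 0) stop("cannot normalize an all-zero activity series")
  activity_series(series$values / m, dt = series$dt, normalized = TRUE,
                  t0 = series$t0)
}

#' Mean of the non-zero activity levels
#'
#' The overall average of the strictly positive activity values; the
#' bout-extraction threshold is a multiple of this quantity.
#'
#' @param series An `activity_series` (or numeric vector).
#' @return A single number.
#' @export
mean_nonzero <- function(series) {
  v <- if (inherits(series, "activity_series")) series$values else
    as.numeric(series)
  pos <- v[v > 0]
  if (length(pos) == 0L) stop("no strictly positive activity values")
  mean(pos)
}

#' Aggregate an activity series to a coarser window
#'
#' Averages consecutive blocks of samples so that, e.g., a 0.1 s-resolution
#' series can be reduced to the 60 s resolution used for spectral analysis.
#' A trailing partial block is discarded.
#'
#' @param series An `activity_series`.
#' @param window Target window in seconds (integer multiple of `series$dt`).
#' @return An `activity_series` at resolution `window`.
#' @export
aggregate_series <- function(series, window) {
  stopifnot(inherits(series, "activity_series"))
  k <- window / series$dt
  if (abs(k - round(k)) > 1e-8 * max(1, k))
    stop("'window' must be an integer multiple of the series interval")
  k <- as.integer(round(k))
  if (k < 1L) stop("window smaller than the series interval")
  if (k == 1L) return(series)
  m <- length(series$values) %/% k
  if (m < 1L) stop("series shorter than one aggregation window")
  v <- colMeans(matrix(series$values[seq_len(m * k)], nrow = k))
  activity_series(v, dt = window, normalized = FALSE, t0 = series$t0)
}

#' Read / write two-column (time, value) delimited text
#'
#' The on-disk exchange format for both raw signals and activity series: one
#' row per sample, first column time in seconds, second column the value,
#' whitespace- or comma-delimited, with an optional header line. Sampling
#' must be uniform. `write_activity()` emits full precision.
#'
#' @param path File path.
#' @param as Return type: an `"activity"` series or a `"raw"` signal.
#' @return `read_activity()`: an `activity_series` or `raw_signal`;
#'   `write_activity()`: the path, invisibly.
#' @export
read_activity <- function(path, as = c("activity", "raw")) {
  as <- match.arg(as)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), if (sep == ",") "," else "[ \t]+")[[1]][1])))
  d <- read.table(path, header = header, sep = sep)
  if (ncol(d) < 2L) stop("expected two columns: time_s, value")
  tt <- as.numeric(d[[1]]); vv <- as.numeric(d[[2]])
  if (length(tt) < 2L) stop("need at least 2 rows")
  dts <- diff(tt)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * max(dt, 1)))
    stop("non-uniform sampling in ", path)
  if (as == "raw") raw_signal(vv, dt = dt, t0 = tt[1])
  else activity_series(vv, dt = dt, t0 = tt[1])
}

#' @rdname read_activity
#' @param x A `raw_signal` or `activity_series`.
#' @export
write_activity <- function(x, path) {
  stopifnot(inherits(x, "raw_signal") || inherits(x, "activity_series"))
  tt <- x$t0 + (seq_along(x$values) - 1L) * x$dt
  d <- data.frame(time_s = format(tt, digits = 17, scientific = FALSE,
                                  trim = TRUE),
                  value = format(x$values, digits = 17, trim = TRUE))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
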
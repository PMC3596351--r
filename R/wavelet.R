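#' Morlet scale--frequency conversion
#'
#' For the Morlet wavelet with non-dimensional center frequency `omega0`, the
#' Fourier-equivalent frequency of scale `s` is
#' `f = (omega0 + sqrt(2 + omega0^2)) / (4 * pi * s)` (Torrence & Compo
#' convention). The relation is bijective; `frequency_to_scale()` is its
#' inverse and is used to build the scale grid from a frequency grid.
#'
#' @param s Scale(s) in seconds; must be positive.
#' @param f Frequency(ies) in Hz; must be positive.
#' @param omega0 Non-dimensional Morlet center frequency (default 6).
#' @return Frequencies in Hz, or scales in seconds.
#' @export
scale_to_frequency <- function(s, omega0 = 6) {
  if (any(s <= 0)) stop("scale must be positive")
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * s)
}

#' @rdname scale_to_frequency
#' @export
frequency_to_scale <- function(f, omega0 = 6) {
  if (any(f <= 0)) stop("frequency must be positive")
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * f)
}

#' Convert a frequency to a period
#'
#' Plain reciprocal `1/f`, expressed in seconds or hours, optionally rounded
#' for reporting. All period figures quoted by the package use this
#' convention (e.g. `3.24e-5` Hz is 8.6 h at one decimal).
#'
#' @param f Frequency in Hz (positive).
#' @param unit `"seconds"` or `"hours"`.
#' @param digits Optional number of decimal places for reporting.
#' @return Period(s) in the requested unit.
#' @export
frequency_to_period <- function(f, unit = c("seconds", "hours"),
                                digits = NULL) {
  unit <- match.arg(unit)
  if (any(f <= 0)) stop("frequency must be positive")
  p <- 1 / f
  if (unit == "hours") p <- p / 3600
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Morlet continuous wavelet transform modulus
#'
#' Computes the L2-normalized Morlet CWT of an activity series by
#' frequency-domain convolution over the zero-padded record and returns the
#' modulus `|W| = sqrt(Re^2 + Im^2)` on a logarithmic frequency grid. The
#' intermittent, non-stationary character of locomotor activity makes the
#' wavelet modulus a more robust basis for rhythm quantification than a
#' single global periodogram.
#'
#' @param series An [activity_series()], uniformly sampled (typically 60 s
#'   windows for circadian/ultradian work).
#' @param omega0 Morlet non-dimensional frequency (default 6).
#' @param f_min,f_max Frequency range in Hz (defaults `1e-5` to `1e-2`,
#'   i.e. roughly 100 s to 27 h periods). `f_max` must not exceed the
#'   Nyquist frequency `1/(2 dt)`.
#' @param voices Scale-grid density: voices per octave (default 16).
#' @return An object of class `wavelet_modulus` with fields `freqs` (Hz,
#'   increasing), `scales` (s), `times` (s), `modulus` (frequency x time
#'   matrix), `dt`, `omega0`, `coi` (cone-of-influence e-folding time per
#'   time point, reported as metadata only), and `warnings`.
#' @details Scales are placed at `voices` per octave spanning
#'   `[f_min, f_max]` via [frequency_to_scale()]; the series is zero-padded
#'   to the next power of two before the FFT and the padding removed
#'   afterwards. The cone of influence is computed but deliberately not
#'   excluded from later time-integration, which runs over the entire
#'   record.
#' @export
cwt_modulus <- function(series, omega0 = 6, f_min = 1e-5, f_max = 1e-2,
                        voices = 16) {
  stopifnot(inherits(series, "activity_series"))
  dt <- series$dt
  nyq <- 1 / (2 * dt)
  if (f_max > nyq + 1e-12)
    stop(sprintf("f_max = %g Hz exceeds the Nyquist frequency %g Hz",
                 f_max, nyq))
  if (f_min <= 0 || f_min >= f_max) stop("need 0 < f_min < f_max")
  warns <- character(0)
  x <- series$values
  n <- length(x)
  if (n * dt < 1 / f_min)
    warns <- c(warns, sprintf(
      "record (%.3g s) shorter than one oscillation at f_min (%.3g s)",
      n * dt, 1 / f_min))

  noct <- log2(f_max / f_min)
  expo <- seq(0, noct, by = 1 / voices)
  if (tail(expo, 1L) < noct - 1e-12) expo <- c(expo, noct)
  freqs <- f_min * 2^expo
  scales <- frequency_to_scale(freqs, omega0)

  # remove the record mean before zero padding (standard CWT practice):
  # the DC offset of an activity series otherwise turns the pad edges into
  # a large step whose broadband response tilts the low-frequency spectrum
  if (any(x != 0)) x <- x - mean(x)
  # pad to at least twice the record length so the frequency-domain product
  # realizes a linear (not circular) convolution for all but the very
  # largest scales
  npad <- 2^ceiling(log2(2 * n))
  xhat <- fft(c(x, numeric(npad - n)))
  k <- c(seq(0, floor(npad / 2)), seq(floor(npad / 2) + 1 - npad, -1))
  w <- 2 * pi * k / (npad * dt)

  mod <- matrix(0, nrow = length(scales), ncol = n)
  norm0 <- pi^(-1 / 4)
  for (i in seq_along(scales)) {
    s <- scales[i]
    # daughter wavelet in frequency space, L2-normalized (Torrence & Compo)
    psi <- numeric(npad)
    pos <- w > 0
    psi[pos] <- sqrt(2 * pi * s / dt) * norm0 * exp(-(s * w[pos] - omega0)^2 / 2)
    W <- fft(xhat * psi, inverse = TRUE) / npad
    mod[i, ] <- Mod(W[seq_len(n)])
  }
  structure(list(freqs = freqs, scales = scales,
                 times = series_times(series), modulus = mod, dt = dt,
                 omega0 = omega0,
                 coi = sqrt(2) * pmin(seq_len(n) - 1, n - seq_len(n)) * dt,
                 warnings = warns),
            class = "wavelet_modulus")
}

#' @export
print.wavelet_modulus <- function(x, ...) {
  cat(sprintf("<wavelet_modulus> %d scales (%.3g-%.3g Hz) x %d times, omega0 = %g\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$modulus), x$omega0))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Normalized wavelet spectrum
#'
#' Integrates the wavelet modulus over the whole record at each frequency and
#' divides by the trapezoidal integral over the frequency grid, so that the
#' resulting spectral density has unit area on the analyzed band.
#'
#' @param mod A [cwt_modulus()] result.
#' @param norm_band Optional frequency band (Hz) over which the area is
#'   normalized to 1; by default the full analyzed grid. Useful when the
#'   transform was computed on a grid extended slightly beyond the nominal
#'   band so that band-edge peaks can be resolved as local maxima.
#' @return An object of class `spectrum_density` with fields `freqs` (Hz)
#'   and `density` (unit-area values).
#' @export
normalized_spectrum <- function(mod, norm_band = NULL) {
  stopifnot(inherits(mod, "wavelet_modulus"))
  tint <- rowSums(mod$modulus) * mod$dt
  area <- if (is.null(norm_band)) pracma::trapz(mod$freqs, tint) else
    .band_integral(mod$freqs, tint, norm_band[1], norm_band[2])
  if (area <= 0) stop("all-zero modulus: spectrum normalization undefined")
  structure(list(freqs = mod$freqs, density = tint / area),
            class = "spectrum_density")
}

#' @export
print.spectrum_density <- function(x, ...) {
  cat(sprintf("<spectrum_density> %d frequencies, %.3g-%.3g Hz, area = %.6f\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              pracma::trapz(x$freqs, x$density)))
  invisible(x)
}

#' @export
plot.spectrum_density <- function(x, ...) {
  graphics::plot(x$freqs, x$density, type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "normalized density", ...)
  abline(v = c(1e-5, 2e-5, 1.1e-4), lty = 3, col = "grey50")
  invisible(x)
}

# prominence of a (possibly boundary) peak at index i: height above the
# higher of the two minima separating it from the nearest higher points
# (boundary peaks are judged by their single inner flank)
.peak_prominence <- function(y, i) {
  n <- length(y)
  lmin <- if (i == 1L) -Inf else {
    hl <- which(y[seq_len(i - 1L)] > y[i])
    min(y[(if (length(hl)) max(hl) else 1L):i])
  }
  rmin <- if (i == n) -Inf else {
    hr <- which(y[(i + 1L):n] > y[i])
    min(y[i:(if (length(hr)) i + min(hr) else n)])
  }
  y[i] - max(lmin, rmin, -Inf)
}

# indices of interior local maxima of y, with optional prominence filter
# (prominence relative to the global maximum)
.local_maxima <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (min_prominence > 0 && length(idx)) {
    gmax <- max(y)
    keep <- vapply(idx, function(i)
      .peak_prominence(y, i) >= min_prominence * gmax, logical(1))
    idx <- idx[keep]
  }
  idx
}

#' Circadian period from the normalized spectrum
#'
#' Returns the period (hours) of the most dominant spectral peak inside the
#' circadian band: among local maxima of the density with frequency in
#' `band`, the one with the greatest density. Arrhythmic records whose
#' spectrum has no in-band local maximum (an extinct circadian peak) return
#' `NA`.
#'
#' @param spec A [normalized_spectrum()] result.
#' @param band Circadian frequency band in Hz (default
#'   `c(1.0e-5, 2.0e-5)`, about 14--28 h).
#' @param min_prominence Significance criterion for a peak: its prominence
#'   (height above the higher flanking minimum) must reach this fraction of
#'   the global spectral maximum (default 0.05, the same criterion used for
#'   ultradian peaks); filters noise ripples in arrhythmic records.
#' @param min_dominance A circadian peak must be a dominant spectral
#'   feature, not merely a locally prominent ripple: its height must reach
#'   this fraction of the global spectral maximum (default 0.5). In
#'   rhythmic records the circadian peak essentially is the global maximum,
#'   while the in-band ripples of arrhythmic, ultradian-dominated records
#'   stay far below it, so the rule separates the two regimes with a wide
#'   margin.
#' @return Period in hours, or `NA_real_` when no circadian peak exists.
#' @export
circadian_period <- function(spec, band = c(1.0e-5, 2.0e-5),
                             min_prominence = 0.05, min_dominance = 0.5) {
  stopifnot(inherits(spec, "spectrum_density"))
  idx <- .local_maxima(spec$density, min_prominence = min_prominence)
  # when the analyzed grid starts at the band's lower edge, a peak whose
  # center lies at or just below the edge shows up as a maximum pinned to
  # the first grid point; admit it if the density falls away from the edge
  # with the same prominence requirement as an interior peak
  if (length(spec$density) >= 2L && spec$freqs[1] >= band[1] - 1e-12 &&
      spec$density[1] > spec$density[2] &&
      .peak_prominence(spec$density, 1L) >=
        min_prominence * max(spec$density))
    idx <- c(1L, idx)
  idx <- idx[spec$freqs[idx] >= band[1] & spec$freqs[idx] <= band[2]]
  idx <- idx[spec$density[idx] >= min_dominance * max(spec$density)]
  if (length(idx) == 0L) return(NA_real_)
  best <- idx[which.max(spec$density[idx])]
  frequency_to_period(spec$freqs[best], unit = "hours")
}

#' Significant spectral peaks
#'
#' Local maxima of the normalized spectrum whose prominence (height above the
#' higher flanking minimum) is at least `min_prominence` times the global
#' maximum. Used to report ultradian peaks.
#'
#' @param spec A `spectrum_density`.
#' @param band Optional frequency band in Hz to restrict the search.
#' @param min_prominence Prominence threshold relative to the global maximum
#'   (default 0.05).
#' @return Data frame with `freq_Hz`, `period_h`, `density`.
#' @export
spectral_peaks <- function(spec, band = NULL, min_prominence = 0.05) {
  stopifnot(inherits(spec, "spectrum_density"))
  idx <- .local_maxima(spec$density, min_prominence = min_prominence)
  if (!is.null(band))
    idx <- idx[spec$freqs[idx] >= band[1] & spec$freqs[idx] <= band[2]]
  data.frame(freq_Hz = spec$freqs[idx],
             period_h = frequency_to_period(spec$freqs[idx], "hours"),
             density = spec$density[idx])
}

# trapezoidal integral of (freqs, density) restricted to [lo, hi], with
# linear interpolation of the density at the exact band edges
.band_integral <- function(freqs, density, lo, hi) {
  if (hi <= freqs[1] || lo >= tail(freqs, 1L)) return(0)
  lo <- max(lo, freqs[1]); hi <- min(hi, tail(freqs, 1L))
  inner <- freqs > lo & freqs < hi
  xs <- c(lo, freqs[inner], hi)
  ys <- approx(freqs, density, xout = xs)$y
  pracma::trapz(xs, ys)
}

#' Circadian / ultradian band quantification
#'
#' Integrates the normalized spectrum over the circadian band
#' (1.0--2.0 x 1e-5 Hz, about 14--28 h) and the ultradian band
#' (2.0e-5--1.1e-4 Hz, about 2.6--14 h), forms their ratio
#' `R = A_ult / A_cir`, and attaches the circadian period estimate.
#' A large `R` flags records whose within-day rhythmicity dominates the
#' daily rhythm.
#'
#' @param spec A [normalized_spectrum()] result.
#' @param circadian_band,ultradian_band Band edges in Hz.
#' @return An object of class `rhythm_summary`: list with `T_cir_h` (hours,
#'   `NA` if the circadian peak is extinct), `A_cir`, `A_ult`, `R`.
#' @export
band_areas <- function(spec, circadian_band = c(1.0e-5, 2.0e-5),
                       ultradian_band = c(2.0e-5, 1.1e-4)) {
  stopifnot(inherits(spec, "spectrum_density"))
  a_cir <- .band_integral(spec$freqs, spec$density,
                          circadian_band[1], circadian_band[2])
  a_ult <- .band_integral(spec$freqs, spec$density,
                          ultradian_band[1], ultradian_band[2])
  structure(list(T_cir_h = circadian_period(spec, band = circadian_band),
                 A_cir = a_cir, A_ult = a_ult,
                 R = if (a_cir > 0) a_ult / a_cir else NA_real_),
            class = "rhythm_summary")
}

#' @export
print.rhythm_summary <- function(x, ...) {
  cat("<rhythm_summary>\n")
  cat(sprintf("  circadian period T_cir : %s\n",
              if (is.na(x$T_cir_h)) "none (extinct peak)" else
                sprintf("%.2f h", x$T_cir_h)))
  cat(sprintf("  A_cir = %.4g, A_ult = %.4g, R = A_ult/A_cir = %s\n",
              x$A_cir, x$A_ult,
              if (is.na(x$R)) "undefined" else sprintf("%.3f", x$R)))
  invisible(x)
}

#' Write a spectrum as two-column text / a rhythm summary as JSON
#' @param spec A `spectrum_density`.
#' @param x A `rhythm_summary`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_density"))
  write.table(data.frame(freq_Hz = format(spec$freqs, digits = 17),
                         density = format(spec$density, digits = 17)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
write_rhythm_summary <- function(x, path) {
  stopifnot(inherits(x, "rhythm_summary"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
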
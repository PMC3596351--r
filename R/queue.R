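#' Simulate the stochastic priority-queuing model
#'
#' A fixed-length list of `L` demands carries i.i.d. priorities drawn
#' uniformly on `(priority_floor, 1)`. At each time step one demand is
#' selected for execution with probability proportional to `x^alpha`,
#' its waiting time (steps since arrival; initial demands arrive at step 0)
#' is recorded, and it is replaced by a fresh uniformly distributed demand.
#' With proportional choice (`alpha = 1`) the waiting times are heavy
#' tailed with cumulative exponent near `1/alpha = 1`; preferential choice
#' (`alpha > 1`) fattens the tail (smaller exponent), the regime that
#' mirrors increased behavioral intermittency. `alpha = 0` is uniform
#' selection, whose waiting times are geometric with success probability
#' `1/L`.
#'
#' @param L List length (default 10).
#' @param alpha Selection exponent, `>= 0` (default 1).
#' @param steps Number of simulated steps.
#' @param seed Optional RNG seed (`set.seed()` is called when given).
#' @param burnin Steps discarded before statistics (default 1000);
#'   executions during the burn-in are not emitted.
#' @param priority_floor Smallest admissible priority (default `1e-3`).
#'   The floor keeps selection probabilities positive and, crucially, sets
#'   the relaxation time of the queue: demands with priority near the floor
#'   are executed at rate about `floor^alpha`, so the queue reaches its
#'   stationary composition only after roughly `L / floor` arrivals. The
#'   default ensures stationarity well within 1e6-step simulations for
#'   `alpha <= 2` while leaving the waiting-time scaling window (up to
#'   about `E[x^alpha] / floor^alpha` steps) far beyond the tail-fit range.
#'   A much smaller floor makes the queue age for the whole simulation and
#'   flattens the apparent tail below the stationary `1/alpha` exponent.
#' @return An object of class `waiting_times`: integer `taus` (one per
#'   executed demand, each `>= 1`), `executed_priorities`, `censored_ages`
#'   (ages of the `L` demands still queued at the end; excluded from the
#'   statistics because their true waiting times are right-censored),
#'   `n_max_selected` (number of steps on which the executed demand held
#'   the maximal current priority; approaches `steps` as `alpha` grows),
#'   and the configuration.
#' @examples
#' wt <- simulate_queue(L = 10, alpha = 1, steps = 1e4, seed = 1)
#' mean(wt$taus)
#' @export
simulate_queue <- function(L = 10, alpha = 1, steps = 1e5, seed = NULL,
                           burnin = 1000, priority_floor = 1e-3) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (L < 1) stop("L must be >= 1")
  steps <- as.integer(steps); burnin <- as.integer(burnin)
  if (steps < 1) stop("steps must be >= 1")
  if (burnin < 0 || burnin >= steps) stop("need 0 <= burnin < steps")
  if (!is.null(seed)) set.seed(seed)
  res <- simulate_queue_cpp(as.integer(L), alpha, steps, burnin,
                            priority_floor)
  structure(c(res, list(L = L, alpha = alpha, steps = steps,
                        burnin = burnin, priority_floor = priority_floor,
                        seed = seed)),
            class = "waiting_times")
}

#' @export
print.waiting_times <- function(x, ...) {
  cat(sprintf(
    "<waiting_times> L = %d, alpha = %g, %d steps (burn-in %d)\n",
    x$L, x$alpha, x$steps, x$burnin))
  cat(sprintf("  %d waiting times, mean tau = %.3f, max = %d; %d censored\n",
              length(x$taus), mean(x$taus), max(x$taus),
              length(x$censored_ages)))
  invisible(x)
}

#' Empirical waiting-time distribution
#'
#' Survival function `P(>= tau)` of the simulated waiting times on their
#' integer support, optionally rescaled by the mean for direct comparison
#' with rescaled behavioral resting-bout distributions. The tail exponent
#' is estimated by passing the result to [fit_power_law()].
#'
#' @param wt A [simulate_queue()] result.
#' @param rescale Divide waiting times by their mean first (default FALSE).
#' @return A `cumdist` on the (possibly rescaled) waiting-time support.
#' @export
waiting_time_distribution <- function(wt, rescale = FALSE) {
  stopifnot(inherits(wt, "waiting_times"))
  taus <- wt$taus
  if (length(taus) < 1000L)
    stop("need at least 1000 waiting times for a stable distribution")
  if (rescale) taus <- taus / mean(taus)
  empirical_cumulative(taus)
}

#' Burst-onset sequence of a waiting-time sample
#'
#' Maps successive waiting times to event (activity-burst onset) times by
#' cumulative summation, scaled by the duration of one model step. Produces
#' the raster of onsets over a requested span; heavier-tailed waiting times
#' give visibly more intermittent rasters with longer extreme gaps.
#'
#' @param wt A `waiting_times` object (or an integer vector of waiting
#'   times).
#' @param step_seconds Seconds per model step (default 0.1, the behavioral
#'   sampling interval).
#' @param span Optional span in seconds; onsets beyond it are dropped.
#' @return Numeric vector of onset times in seconds.
#' @export
onset_sequence <- function(wt, step_seconds = 0.1, span = NULL) {
  if (step_seconds <= 0) stop("step_seconds must be positive")
  taus <- if (inherits(wt, "waiting_times")) wt$taus else as.numeric(wt)
  onsets <- cumsum(taus) * step_seconds
  if (!is.null(span)) onsets <- onsets[onsets <= span]
  onsets
}
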
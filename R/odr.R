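# Orthogonal distance regression by the ODRPACK device: augment the
# parameter vector with per-point abscissa errors delta_i and minimize
#   sum_i [ (y_i - f(x_i + delta_i; theta))^2 + delta_i^2 ]
# with Levenberg-Marquardt (minpack.lm::nls.lm). Unit weights on both
# coordinates. Multi-start: each start is run to a local minimum and the
# lowest chi-square solution is kept.
#
# fn(x, theta) must be vectorized in x. dtheta(x, theta) returns the
# n x length(theta) matrix of df/dtheta; dx(x, theta) the vector df/dx.
# Supplying both enables the analytic Jacobian of the extended residual.
.odr_fit <- function(x, y, fn, starts, dtheta = NULL, dx = NULL,
                     maxiter = 300) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2L)
  resid_fun <- function(p, np) {
    theta <- p[seq_len(np)]
    delta <- p[-seq_len(np)]
    c(y - fn(x + delta, theta), delta)
  }
  jac_fun <- if (!is.null(dtheta) && !is.null(dx)) {
    function(p, np) {
      theta <- p[seq_len(np)]
      delta <- p[-seq_len(np)]
      xd <- x + delta
      J <- matrix(0, nrow = 2 * n, ncol = np + n)
      J[seq_len(n), seq_len(np)] <- -dtheta(xd, theta)
      fp <- dx(xd, theta)
      J[cbind(seq_len(n), np + seq_len(n))] <- -fp
      J[cbind(n + seq_len(n), np + seq_len(n))] <- 1
      J
    }
  } else NULL
  best <- NULL
  errs <- character(0)
  for (theta0 in starts) {
    np <- length(theta0)
    ans <- tryCatch(
      minpack.lm::nls.lm(par = c(theta0, numeric(n)), fn = resid_fun,
                         jac = jac_fun, np = np,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) e)
    if (inherits(ans, "error")) { errs <- c(errs, conditionMessage(ans)); next }
    chi2 <- ans$deviance
    if (!is.finite(chi2)) next
    if (is.null(best) || chi2 < best$chi2)
      best <- list(theta = ans$par[seq_len(np)],
                   delta = ans$par[-seq_len(np)],
                   chi2 = chi2, info = ans$info, message = ans$message)
  }
  if (is.null(best))
    stop("orthogonal distance regression failed from every start: ",
         paste(unique(errs), collapse = "; "))
  best
}
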
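#' Fit the exponential decay rate from a trajectory prefix
#'
#' Pre-crash, the fraction of active nodes follows
#' `f_a(t) = (1 - a') exp(-lambda t)` with `lambda = p (1 - q)`, so ordinary
#' least squares of `log(f_a)` on `t` over a prefix recovers the decay rate
#' (minus the slope) and the log-prefactor `log(1 - a')` (the intercept).
#'
#' @param x A `decay_trajectory`, or a `data.frame` with columns `t` and
#'   `f_a`.
#' @param fit_start First time included in the fit. `NULL` (default) skips
#'   the first `tau` steps of a trajectory — the transient before the
#'   internally failed fraction reaches its stationary level — or 0 for a
#'   bare data frame.
#' @param fit_end Last time included (use this to fit on a prefix of a full
#'   trajectory, e.g. up to half the expected lifetime).
#' @return An object of class `lifetime_estimate`: `lambda` (decay rate per
#'   step), `intercept` (fitted `log f_a` at `t = 0`), `n` (points used),
#'   `fit_window`, `sigma` (residual standard deviation).
#' @export
#' @seealso [remaining_lifetime()]
fit_decay_rate <- function(x, fit_start = NULL, fit_end = Inf) {
  if (is.null(fit_start)) {
    pars <- attr(x, "params")
    fit_start <- if (!is.null(pars)) pars$tau else 0
  }
  d <- as.data.frame(x)[, c("t", "f_a")]
  d <- d[d$t >= fit_start & d$t <= fit_end, ]
  if (nrow(d) < 10L)
    param_error("need at least 10 points in the fit window; got ", nrow(d))
  if (any(d$f_a <= 0))
    param_error("f_a <= 0 inside the fit window: fit pre-crash data only")
  fit <- stats::lm(log(f_a) ~ t, data = d)
  cf <- stats::coef(fit)
  structure(list(
    lambda = unname(-cf[2L]),
    intercept = unname(cf[1L]),
    n = nrow(d),
    fit_window = c(min(d$t), max(d$t)),
    sigma = stats::sd(stats::residuals(fit))
  ), class = "lifetime_estimate")
}

#' @export
print.lifetime_estimate <- function(x, ...) {
  cat(sprintf(
    "Lifetime estimate: lambda = %.6g, intercept = %.4g (%d points, t in [%g, %g])\n",
    x$lambda, x$intercept, x$n, x$fit_window[1L], x$fit_window[2L]))
  invisible(x)
}

#' Fit the linear decline of crash indicator II
#'
#' Indicator II (the mean excess active-neighbour fraction) declines
#' approximately linearly, `I_0 - alpha t`, with `alpha` comparable to
#' `p (1 - q)`. Least squares over a prefix recovers intercept and slope.
#'
#' @param x A `decay_trajectory` (its `t`/`mean_excess` columns), or a
#'   `data.frame` with columns `t` and `value`.
#' @param fit_start,fit_end Time window for the fit (defaults: all points).
#' @return A list with `I_0` (intercept) and `alpha` (positive for a
#'   declining series) plus `n` points used.
#' @export
fit_linear_indicator <- function(x, fit_start = 0, fit_end = Inf) {
  d <- as.data.frame(x)
  if (inherits(x, "decay_trajectory") || "mean_excess" %in% names(d))
    d <- data.frame(t = d$t, value = d$mean_excess)
  d <- d[d$t >= fit_start & d$t <= fit_end, ]
  if (nrow(d) < 10L) param_error("need at least 10 points; got ", nrow(d))
  cf <- stats::coef(stats::lm(value ~ t, data = d))
  list(I_0 = unname(cf[1L]), alpha = unname(-cf[2L]), n = nrow(d))
}

#' Forecast the remaining network lifetime
#'
#' Inverts the fitted decay law: the network crashes when
#' `exp(intercept - lambda t)` reaches the threshold `T_h`, so the
#' forecast lifetime is `t_c = (intercept - log(T_h)) / lambda` and the
#' quantity of practical interest is the remaining time `t_c - t_now`
#' (floored at 0).
#'
#' @param estimate A `lifetime_estimate` from [fit_decay_rate()].
#' @param T_h Fractional threshold in `(0, 1]`.
#' @param t_now Current time (end of the observed prefix).
#' @return Remaining lifetime in steps, with the full forecast lifetime as
#'   attribute `t_c`. `NA` (with a warning) when the fitted rate is not
#'   positive — no forecast is possible without decay.
#' @export
#' @examples
#' est <- structure(list(lambda = 0.001, intercept = 0),
#'                  class = "lifetime_estimate")
#' remaining_lifetime(est, T_h = 0.5)   # ~693
remaining_lifetime <- function(estimate, T_h, t_now = 0) {
  stopifnot(inherits(estimate, "lifetime_estimate"))
  if (!is.numeric(T_h) || length(T_h) != 1L || T_h <= 0 || T_h > 1)
    param_error("`T_h` must lie in (0, 1]")
  if (!is.finite(estimate$lambda) || estimate$lambda <= 0) {
    warning("fitted decay rate is not positive; no forecast", call. = FALSE)
    return(NA_real_)
  }
  t_c <- (estimate$intercept - log(T_h)) / estimate$lambda
  structure(max(0, t_c - t_now), t_c = t_c)
}
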
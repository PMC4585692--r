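#' Forward moving standard deviation (crash indicator I)
#'
#' Value at index `t` is the sample standard deviation (denominator
#' `n - 1`) of `series[t .. t + window - 1]`; the last `window - 1` indices,
#' where the forward window is incomplete, are `NA`. Applied to the fraction
#' of active nodes with window equal to the recovery delay `tau`, this is
#' the early-warning indicator that spikes just before a network crash.
#'
#' @param series Numeric vector.
#' @param window Window length (>= 2, <= `length(series)`).
#' @return Numeric vector of the same length as `series`.
#' @export
moving_std_forward <- function(series, window) {
  if (!is_count(window, min = 2L)) param_error("`window` must be >= 2")
  if (window > length(series))
    param_error("`window` exceeds series length")
  as.numeric(zoo::rollapply(zoo::zoo(series), width = window, FUN = stats::sd,
                            align = "left", fill = NA_real_, coredata = TRUE))
}

#' Moments of the excess active-neighbour fraction
#'
#' Mean, sample (`n - 1`) variance, and moment-estimator skewness and
#' excess kurtosis of a collection of per-node excess values (active
#' neighbour fraction minus own threshold). The distribution of these
#' excesses changes abruptly — skewness and kurtosis spike — just before a
#' network crash.
#'
#' @param per_node_excess Non-empty numeric vector.
#' @return A list with `mean`, `var`, `skewness`, `kurtosis` (excess), and
#'   `degenerate` (`TRUE` when the input has zero variance, in which case
#'   skewness and kurtosis are reported as flagged zeros).
#' @export
excess_stats <- function(per_node_excess) {
  x <- per_node_excess
  if (!is.numeric(x) || length(x) == 0L)
    param_error("`per_node_excess` must be a non-empty numeric vector")
  mo <- .moments(x)
  degenerate <- length(x) < 2L || mean((x - mean(x))^2) < 1e-24
  list(mean = mo[1L], var = mo[2L], skewness = mo[3L], kurtosis = mo[4L],
       degenerate = degenerate)
}

#' Detect the network lifetime from crash indicator II
#'
#' The lifetime `t_c` is the first time at which indicator II — the mean
#' excess active-neighbour fraction — drops below zero: the average
#' neighbourhood has reached the threshold and the cascade triggers.
#'
#' @param x A `decay_trajectory` (its `mean_excess` column and `t` index are
#'   used) or a bare numeric indicator-II sequence.
#' @param times Optional time stamps for a bare sequence; defaults to
#'   `0, 1, ...` matching the trajectory time origin.
#' @return The time of the first negative value, or `NA` if the indicator
#'   never turns negative.
#' @export
#' @examples
#' detect_tc(c(0.3, 0.1, -0.05, -0.4))   # 2
detect_tc <- function(x, times = NULL) {
  if (inherits(x, "decay_trajectory")) {
    times <- x$t
    x <- x$mean_excess
  } else if (is.null(times)) {
    times <- seq_along(x) - 1
  }
  idx <- which(x < 0)
  if (!length(idx)) return(NA_real_)
  times[idx[1L]]
}

#' Size of the crash drop in the active fraction
#'
#' Measures how far the fraction of active nodes falls during the collapse
#' cascade: the pre-crash level `f_a(t_c)` minus the settled post-crash
#' level (mean `f_a` over `[t_c + settle_window / 2, t_c + settle_window]`).
#' The measured drop can be compared with the `|T_h - r|` scale the theory
#' associates with the cascade, but is reported as-is.
#'
#' @param trajectory A `decay_trajectory`.
#' @param t_c Crash time; defaults to the trajectory's detected `t_c`.
#' @param settle_window Steps after `t_c` over which the post-crash level
#'   is taken; the trajectory must extend at least this far past `t_c`.
#' @return The drop `f_a(t_c) - mean(post-crash f_a)`.
#' @export
crash_drop <- function(trajectory, t_c = NULL, settle_window = 100L) {
  stopifnot(inherits(trajectory, "decay_trajectory"))
  if (is.null(t_c)) t_c <- attr(trajectory, "t_c")
  if (is.null(t_c) || is.na(t_c))
    param_error("no crash in trajectory: `t_c` unset")
  if (!is_count(settle_window, min = 2L))
    param_error("`settle_window` must be >= 2")
  tmax <- max(trajectory$t)
  if (tmax < t_c + settle_window)
    param_error("trajectory too short after the crash: need ",
                settle_window, " steps past t_c = ", t_c)
  pre <- trajectory$f_a[trajectory$t == t_c]
  post <- trajectory$f_a[trajectory$t >= t_c + settle_window / 2 &
                           trajectory$t <= t_c + settle_window]
  pre - mean(post)
}

#' Duration of the crash transition
#'
#' Number of steps `f_a` takes to move from 10% to 90% of its total crash
#' drop (pre-crash level to settled post-crash level). Heterogeneous node
#' thresholds smear the collapse and lengthen this transition.
#'
#' @inheritParams crash_drop
#' @return Width in steps of the 10–90% transition.
#' @export
crash_transition_width <- function(trajectory, t_c = NULL,
                                   settle_window = 100L) {
  stopifnot(inherits(trajectory, "decay_trajectory"))
  if (is.null(t_c)) t_c <- attr(trajectory, "t_c")
  if (is.null(t_c) || is.na(t_c)) param_error("no crash in trajectory")
  tmax <- max(trajectory$t)
  if (tmax < t_c + settle_window)
    param_error("trajectory too short after the crash")
  pre <- trajectory$f_a[trajectory$t == t_c]
  post <- mean(trajectory$f_a[trajectory$t >= t_c + settle_window / 2 &
                                trajectory$t <= t_c + settle_window])
  seg <- trajectory[trajectory$t >= t_c & trajectory$t <= t_c + settle_window, ]
  drop <- pre - post
  if (drop <= 0) return(NA_real_)
  lo <- pre - 0.1 * drop
  hi <- pre - 0.9 * drop
  t10 <- seg$t[which(seg$f_a <= lo)[1L]]
  t90 <- seg$t[which(seg$f_a <= hi)[1L]]
  if (is.na(t10) || is.na(t90)) return(NA_real_)
  t90 - t10
}

#' Histogram of the excess active-neighbour fraction
#'
#' Normalized histogram of per-node excess values over the full support
#' `[-1, 1]`; the bin masses sum to 1.
#'
#' @param per_node_excess Non-empty numeric vector with values in `[-1, 1]`.
#' @param bins Number of bins (>= 2).
#' @return A `data.frame` with columns `mid` (bin centre), `lower`, `upper`
#'   and `mass`.
#' @export
excess_histogram <- function(per_node_excess, bins = 50L) {
  x <- per_node_excess
  if (!is.numeric(x) || length(x) == 0L)
    param_error("`per_node_excess` must be non-empty")
  if (!is_count(bins, min = 2L)) param_error("`bins` must be >= 2")
  if (any(x < -1 | x > 1)) param_error("excess values must lie in [-1, 1]")
  breaks <- seq(-1, 1, length.out = bins + 1L)
  cnt <- tabulate(pmin(bins, findInterval(x, breaks, rightmost.closed = TRUE)),
                  nbins = bins)
  data.frame(mid = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
             lower = breaks[-(bins + 1L)], upper = breaks[-1L],
             mass = cnt / length(x))
}

#' Indicator series of a trajectory
#'
#' Assembles the early-warning indicators of a simulated trajectory:
#' indicator I (forward moving standard deviation of `f_a`, window
#' typically the recovery delay `tau`) and indicator II (mean excess
#' active-neighbour fraction, recorded during the run) together with the
#' per-step moments of the excess distribution.
#'
#' @param trajectory A `decay_trajectory`.
#' @param window Window for indicator I; defaults to the run's `tau`.
#' @return A `data.frame` with columns `t`, `ind_I`, `ind_II`, `mean`,
#'   `var`, `skew`, `kurt`, and attributes `t_c` (from [detect_tc()]) and
#'   `window`.
#' @export
indicator_series <- function(trajectory, window = NULL) {
  stopifnot(inherits(trajectory, "decay_trajectory"))
  if (is.null(window)) window <- attr(trajectory, "params")$tau
  if (!is_count(window, min = 2L)) param_error("`window` must be >= 2")
  out <- data.frame(
    t = trajectory$t,
    ind_I = moving_std_forward(trajectory$f_a, window),
    ind_II = trajectory$mean_excess,
    mean = trajectory$mean_excess,
    var = trajectory$excess_var,
    skew = trajectory$excess_skew,
    kurt = trajectory$excess_kurt
  )
  attr(out, "t_c") <- detect_tc(trajectory)
  attr(out, "window") <- window
  out
}
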
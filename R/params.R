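#' Threshold specifications
#'
#' A node's external robustness is its fractional threshold `T_h`: when the
#' fraction of its active neighbours is `<= T_h`, the node becomes externally
#' inactive with probability `r` at the next step. Thresholds are either a
#' single constant shared by all nodes, or drawn per node from a Gaussian
#' (clamped to `[0, 1]`), modelling heterogeneous node robustness.
#'
#' @param value Constant threshold in `[0, 1]`.
#' @return An object of class `threshold_spec`.
#' @seealso [sample_thresholds()]
#' @export
threshold_constant <- function(value) {
  if (!is_prob(value)) param_error("threshold must lie in [0, 1]")
  structure(list(type = "constant", value = value), class = "threshold_spec")
}

#' @rdname threshold_constant
#' @param mean,sd Mean and standard deviation of the Gaussian threshold
#'   distribution; draws are clamped to `[0, 1]`.
#' @export
threshold_gaussian <- function(mean = 0.5, sd = 0.1) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    param_error("`mean` must be a finite number")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    param_error("`sd` must be >= 0")
  structure(list(type = "gaussian", mean = mean, sd = sd),
            class = "threshold_spec")
}

as_threshold_spec <- function(x) {
  if (inherits(x, "threshold_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(threshold_constant(x))
  param_error("`threshold` must be a number in [0, 1] or a threshold_spec")
}

#' Draw per-node thresholds from a specification
#'
#' Constant specs replicate the value; Gaussian specs draw i.i.d.
#' `N(mean, sd)` values clamped (not resampled) to `[0, 1]`, which for
#' `sd <= 0.2` around `mean = 0.5` leaves the sample mean essentially
#' unchanged.
#'
#' @param spec A [threshold_constant()]/[threshold_gaussian()] spec or a
#'   bare number.
#' @param n Number of nodes.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return Numeric vector of `n` thresholds in `[0, 1]`.
#' @export
sample_thresholds <- function(spec, n, seed = NULL) {
  spec <- as_threshold_spec(spec)
  if (!is_count(n, min = 0L)) param_error("`n` must be a non-negative count")
  with_seed(seed, {
    if (spec$type == "constant") rep.int(spec$value, n)
    else pmin(1, pmax(0, stats::rnorm(n, spec$mean, spec$sd)))
  })
}

#' Model parameters for the decay dynamics
#'
#' Bundles every probability and timescale of the decaying-network model.
#' Per step, each internally active living node fails internally with
#' probability `p`; a failure is permanent (the node dies) with probability
#' `1 - q`, otherwise the node recovers after `tau` steps. A living node
#' whose active-neighbour fraction is `<= ` its threshold becomes externally
#' inactive with probability `r` for one step. Optional extensions: i.i.d.
#' per-step internal link failures (`p_link`) and node creation by living
#' nodes (`p_spawn`).
#'
#' @param p Internal-failure probability per step.
#' @param q Recovery probability; `1 - q` is the probability that an
#'   internal failure is permanent.
#' @param r External-failure probability per step when at or below threshold.
#' @param tau Recovery delay, in steps (>= 1).
#' @param threshold Fractional threshold: a number in `[0, 1]` or a
#'   [threshold_gaussian()] spec.
#' @param p_link Internal link-failure probability per step (0 disables).
#' @param p_spawn Per-living-node probability of creating a new node per
#'   step (0 disables).
#' @param spawn_links Edges given to each new node; default
#'   `max(1, round(mean degree / 2))`, resolved at [init_state()].
#' @param f_a_denominator `"initial"` (default) divides active-node counts
#'   by `N(0)` even when nodes are added; `"current"` divides by `N(t)`.
#' @param seed Master RNG seed for a run.
#' @param horizon Maximum number of steps to simulate.
#' @param extra_steps_after_crash Steps recorded past the (last) detected
#'   crash before stopping, so post-crash levels can be measured.
#' @return An object of class `decay_params`.
#' @export
#' @examples
#' decay_params(p = 0.01, q = 0.9, r = 0.8, tau = 10, threshold = 0.5)
decay_params <- function(p, q, r = 0, tau = 1L, threshold = 0.5,
                         p_link = 0, p_spawn = 0, spawn_links = NULL,
                         f_a_denominator = c("initial", "current"),
                         seed = 1L, horizon = 1000L,
                         extra_steps_after_crash = 200L) {
  for (nm in c("p", "q", "r", "p_link", "p_spawn")) {
    val <- get(nm)
    if (!is_prob(val)) param_error("`", nm, "` must be a probability in [0, 1]")
  }
  if (!is_count(tau, min = 1L)) param_error("`tau` must be an integer >= 1")
  if (!is_count(horizon, min = 1L)) param_error("`horizon` must be >= 1")
  if (!is_count(extra_steps_after_crash, min = 0L))
    param_error("`extra_steps_after_crash` must be >= 0")
  if (!is.null(spawn_links) && !is_count(spawn_links, min = 1L))
    param_error("`spawn_links` must be an integer >= 1")
  structure(list(
    p = p, q = q, r = r, tau = as.integer(tau),
    threshold = as_threshold_spec(threshold),
    p_link = p_link, p_spawn = p_spawn, spawn_links = spawn_links,
    f_a_denominator = match.arg(f_a_denominator),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    horizon = as.integer(horizon),
    extra_steps_after_crash = as.integer(extra_steps_after_crash)
  ), class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  th <- if (x$threshold$type == "constant")
    sprintf("T_h = %g", x$threshold$value)
  else sprintf("T_h ~ N(%g, %g) clamped to [0,1]", x$threshold$mean,
               x$threshold$sd)
  cat("Decay-model parameters\n",
      sprintf("  p = %g, q = %g, r = %g, tau = %d, %s\n",
              x$p, x$q, x$r, x$tau, th),
      if (x$p_link > 0) sprintf("  link failures: p_link = %g\n", x$p_link),
      if (x$p_spawn > 0) sprintf("  node addition: p_spawn = %g\n", x$p_spawn),
      sprintf("  seed = %s, horizon = %d\n",
              if (is.null(x$seed)) "NULL" else x$seed, x$horizon),
      sep = "")
  invisible(x)
}

#' Intervention specification
#'
#' Describes an external intervention that lowers node thresholds (raising
#' robustness) during a run, e.g. a regulator stepping in just before a
#' collapse. Triggered either at a fixed step or at the moment a crash is
#' first detected (indicator II turning negative).
#'
#' @param trigger `"crash"`, or an integer step at which to intervene.
#' @param selector `"all"` (every living node), `list(top_degree = n)` (the
#'   `n` living nodes of largest topological degree, ties by index), or
#'   `list(threshold_above = c)` (living nodes with threshold `> c`).
#' @param delta Amount subtracted from each selected node's threshold;
#'   results are clamped to `[0, 1]`.
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(trigger = "crash", selector = "all",
                              delta = 0.2) {
  if (!(identical(trigger, "crash") || is_count(trigger, min = 0L)))
    param_error("`trigger` must be \"crash\" or a non-negative step")
  ok <- identical(selector, "all") ||
    (is.list(selector) && length(selector) == 1L &&
       names(selector) %in% c("top_degree", "threshold_above"))
  if (!ok) param_error("invalid `selector`")
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta))
    param_error("`delta` must be a finite number")
  structure(list(trigger = trigger, selector = selector, delta = delta),
            class = "intervention_spec")
}
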
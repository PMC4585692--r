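#' Stationary internal-failure probability
#'
#' In the renewal picture a node alternates between internally active
#' periods (geometric, mean `1/p`) and recovery periods of length `tau`;
#' the stationary probability of being internally failed is
#' `p_star = 1 - exp(-p * tau)`.
#'
#' @param p Internal-failure probability per step (vectorised).
#' @param tau Recovery delay in steps (>= 0, vectorised).
#' @return A probability.
#' @export
#' @examples
#' p_star(0.003, 50)   # ~0.139
p_star <- function(p, tau) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    param_error("`p` must be a probability")
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau < 0))
    param_error("`tau` must be >= 0")
  1 - exp(-p * tau)
}

#' Critical-damage probability of a neighbourhood
#'
#' Probability that a node with `k` neighbours, each independently active
#' with probability `active_prob`, has at most `m` active neighbours —
#' i.e. that its neighbourhood is critically damaged under an absolute
#' threshold of `m` (a node needs more than `m` active links to escape
#' external failure).
#'
#' @param m Absolute threshold count, `0 <= m <= k`.
#' @param k Node degree.
#' @param active_prob Per-neighbour activity probability (vectorised).
#' @return `P(Binomial(k, active_prob) <= m)`.
#' @export
damage_prob_E <- function(m, k, active_prob) {
  if (!is_count(k, min = 0L)) param_error("`k` must be a non-negative count")
  if (!is_count(m, min = 0L) || m > k)
    param_error("`m` must be an integer in [0, k]")
  if (any(!is.finite(active_prob)) || any(active_prob < 0 | active_prob > 1))
    param_error("`active_prob` must lie in [0, 1]")
  stats::pbinom(m, k, active_prob)
}

#' Probability that a link is active
#'
#' A link fails either internally (probability `p_tilde`) or because its far
#' endpoint is inactive (probability `a`); the two events are independent,
#' so the link is active with probability `(1 - p_tilde) * (1 - a)`.
#'
#' @param a Fraction (probability) of inactive nodes.
#' @param p_tilde Internal link-failure probability.
#' @return A probability (vectorised over `a`).
#' @export
link_active_prob <- function(a, p_tilde = 0) {
  if (any(!is.finite(a)) || any(a < 0 | a > 1))
    param_error("`a` must lie in [0, 1]")
  if (!is_prob(p_tilde)) param_error("`p_tilde` must be a probability")
  (1 - p_tilde) * (1 - a)
}

# Self-consistency map: a node is inactive if it failed internally (p_star)
# or -- union of independent events -- externally, which requires a
# critically damaged neighbourhood (E) and the external hit (r).
.mf_g <- function(a, p_star, r, k, m, p_tilde) {
  E <- stats::pbinom(m, k, link_active_prob(a, p_tilde))
  p_star + r * E - p_star * r * E
}

#' Self-consistent stationary inactive fraction
#'
#' Solves the mean-field fixed-point equation
#' `a = p* + r E - p* r E`, with
#' `E = P(Binomial(k, (1 - p_tilde)(1 - a)) <= m)`,
#' for the stationary fraction of inactive nodes `a` on a random regular
#' network of degree `k` with absolute threshold `m`. Roots are located by a
#' sign-change scan of `g(a) - a` on a dense grid, refined to
#' `|g(a) - a| <= tol`; up to three fixed points exist, delimiting the
#' bistable (hysteresis) region. Stability is classified by `|g'(a)| < 1`
#' (central differences).
#'
#' @param p_star Stationary internal-failure probability (see [p_star()]).
#' @param r External-failure probability.
#' @param k Degree of the regular network.
#' @param m Absolute threshold count (see [threshold_count()]).
#' @param p_tilde Internal link-failure probability.
#' @param grid_points Number of scan intervals on `[0, 1]` (default 1e4).
#' @param tol Root refinement tolerance on `|g(a) - a|`.
#' @return A list of class `meanfield_solution`: `fixed_points` (sorted),
#'   `stable` (logical per fixed point), `a_prime` (the smallest stable
#'   fixed point — the surviving branch used in the lifetime formula), and
#'   the inputs.
#' @export
#' @examples
#' sol <- self_consistent_a(p_star = 0.1, r = 0.8, k = 10, m = 4)
#' sol$fixed_points
self_consistent_a <- function(p_star, r, k, m, p_tilde = 0,
                              grid_points = 10000L, tol = 1e-10) {
  for (nm in c("p_star", "r", "p_tilde"))
    if (!is_prob(get(nm))) param_error("`", nm, "` must be a probability")
  if (!is_count(k, min = 0L) || !is_count(m, min = 0L) || m > k)
    param_error("need integer 0 <= m <= k")
  if (!is_count(grid_points, min = 100L))
    param_error("`grid_points` must be >= 100")
  g <- function(a) .mf_g(a, p_star, r, k, m, p_tilde)
  grid <- seq(0, 1, length.out = grid_points + 1L)
  h <- g(grid) - grid
  roots <- grid[abs(h) < .Machine$double.eps * 4]   # exact grid hits
  sc <- which(h[-length(h)] * h[-1L] < 0)
  for (idx in sc) {
    roots <- c(roots,
               stats::uniroot(function(a) g(a) - a,
                              c(grid[idx], grid[idx + 1L]),
                              tol = tol)$root)
  }
  roots <- sort(roots)
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) > 1e-8)]     # dedupe near-identical
  dh <- 1e-6
  stable <- vapply(roots, function(a) {
    lo <- max(0, a - dh); hi <- min(1, a + dh)
    abs((g(hi) - g(lo)) / (hi - lo)) < 1
  }, TRUE)
  structure(list(
    fixed_points = roots, stable = stable,
    a_prime = if (any(stable)) min(roots[stable]) else NA_real_,
    p_star = p_star, r = r, k = k, m = m, p_tilde = p_tilde
  ), class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf("Mean-field solution (p* = %g, r = %g, k = %d, m = %d, p~ = %g)\n",
              x$p_star, x$r, x$k, x$m, x$p_tilde))
  for (ii in seq_along(x$fixed_points))
    cat(sprintf("  a = %.6f (%s)\n", x$fixed_points[ii],
                if (x$stable[ii]) "stable" else "unstable"))
  invisible(x)
}

#' Spinodal curves of the bistable region
#'
#' Scans the `(p*, r)` parameter plane of the mean-field map for the region
#' where three fixed points coexist (bistability with hysteresis). For each
#' `r` on the grid the lower and upper `p*` at which the fixed-point count
#' changes between 1 and 3 are located; the two boundary curves merge at a
#' critical point where the bistable interval shrinks to nothing.
#'
#' @inheritParams self_consistent_a
#' @param grid_resolution Number of grid intervals in each of `r` and `p*`
#'   (>= 100).
#' @param a_points Resolution of the fixed-point-counting scan in `a`.
#' @return A `data.frame` with columns `r`, `p_star_lower`, `p_star_upper`
#'   (rows only where a bistable interval exists) and attribute
#'   `critical_point`, a named vector `c(r, p_star)` at the merge point.
#'   Zero rows (with a message) if no bistable region exists at the given
#'   `k`, `m`, `p_tilde`.
#' @export
spinodal_curves <- function(k, m, p_tilde = 0, grid_resolution = 200L,
                            a_points = 2000L) {
  if (!is_count(grid_resolution, min = 100L))
    param_error("`grid_resolution` must be >= 100")
  a_grid <- seq(0, 1, length.out = a_points + 1L)
  E_vec <- stats::pbinom(m, k, link_active_prob(a_grid, p_tilde))
  r_grid <- seq(0, 1, length.out = grid_resolution + 1L)
  p_grid <- seq(0, 1, length.out = grid_resolution + 1L)
  rows <- vector("list", length(r_grid))
  for (ri in seq_along(r_grid)) {
    r <- r_grid[ri]
    rE <- r * E_vec
    # h(a; p*) = p* (1 - rE(a)) + rE(a) - a, linear in p*
    hmat <- outer(1 - rE, p_grid) + (rE - a_grid)   # a rows x p* cols
    sgn <- sign(hmat)
    nroots <- colSums(sgn[-nrow(sgn), , drop = FALSE] *
                        sgn[-1L, , drop = FALSE] < 0)
    multi <- which(nroots >= 3L)
    if (length(multi))
      rows[[ri]] <- data.frame(r = r,
                               p_star_lower = p_grid[min(multi)],
                               p_star_upper = p_grid[max(multi)])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    message("no bistable region found for k = ", k, ", m = ", m,
            ", p_tilde = ", p_tilde)
    out <- data.frame(r = numeric(0), p_star_lower = numeric(0),
                      p_star_upper = numeric(0))
    attr(out, "critical_point") <- c(r = NA_real_, p_star = NA_real_)
    return(out)
  }
  # the critical point sits where the interval is narrowest (merging curves)
  width <- out$p_star_upper - out$p_star_lower
  cp <- which.min(width)
  attr(out, "critical_point") <-
    c(r = out$r[cp],
      p_star = (out$p_star_lower[cp] + out$p_star_upper[cp]) / 2)
  out
}

#' Expected number of living nodes
#'
#' The living-node count decays exponentially,
#' `N(t) = N(0) exp(-(1 - q) p t)`: per step a fraction `p` of nodes fails
#' internally and a fraction `1 - q` of those failures is permanent.
#'
#' @param t Time in steps (vectorised).
#' @param p Internal-failure probability.
#' @param q Recovery probability.
#' @param n0 Initial node count `N(0)`.
#' @return Expected living-node count at `t`.
#' @export
expected_alive <- function(t, p, q, n0) {
  if (any(t < 0)) param_error("`t` must be >= 0")
  n0 * exp(-(1 - q) * p * t)
}

#' Analytic network lifetime
#'
#' The network collapses when the decaying fraction of living neighbours
#' reaches the threshold: `t_c = -ln(T_h) / (p (1 - q))` — the ratio of the
#' logarithmic distance to the threshold to the rate of approach. With the
#' stable-branch prefactor `1 - a_prime` (the stationary active fraction of
#' the surviving branch, see [self_consistent_a()]) the refined form
#' `t_c = ln((1 - a_prime) / T_h) / (p (1 - q))` is returned.
#'
#' @param T_h Fractional threshold in `(0, 1]`.
#' @param p Internal-failure probability.
#' @param q Recovery probability.
#' @param a_prime Optional stationary inactive fraction on the surviving
#'   branch; `NULL` uses the plain formula (prefactor 1).
#' @return Lifetime in steps; `Inf` when `p = 0` or `q = 1` (no permanent
#'   decay).
#' @export
#' @examples
#' lifetime_tc(0.5, 0.003, 0.99)   # ~23105 steps
lifetime_tc <- function(T_h, p, q, a_prime = NULL) {
  if (!is.numeric(T_h) || length(T_h) != 1L || T_h > 1)
    param_error("`T_h` must be a number <= 1")
  if (!is_prob(p) || !is_prob(q)) param_error("`p`, `q` must be probabilities")
  pref <- if (is.null(a_prime)) 1 else {
    if (!is_prob(a_prime)) param_error("`a_prime` must be in [0, 1]")
    1 - a_prime
  }
  if (T_h <= 0) return(Inf)
  if (p == 0 || q == 1) return(if (T_h >= pref) 0 else Inf)
  max(0, log(pref / T_h) / (p * (1 - q)))
}

#' Collapse-time gap between two thresholds
#'
#' When the per-node excess active-neighbour fraction declines linearly as
#' `I_0 - alpha t`, a node of threshold `T_h` collapses when the line meets
#' its threshold; two nodes with thresholds `th1 > th2` therefore collapse
#' `(th1 - th2) / alpha` steps apart. Equal thresholds give a virtually
#' simultaneous collapse.
#'
#' @param th1,th2 The two node thresholds.
#' @param alpha Positive decline rate of the excess (per step), comparable
#'   to `p (1 - q)`.
#' @return The collapse-time gap `t_2 - t_1` in steps.
#' @export
collapse_gap <- function(th1, th2, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    param_error("`alpha` must be > 0")
  (th1 - th2) / alpha
}

#' Absolute threshold count from a fractional threshold
#'
#' Converts the fractional threshold `T_h` into the absolute count `m` used
#' by the mean-field theory: a node is active when its active-neighbour
#' count exceeds `m = floor(T_h * k)`, which encodes "active fraction
#' `> T_h`" for a node of degree `k`.
#'
#' @param T_h Fractional threshold in `[0, 1]`.
#' @param k Node degree.
#' @return Integer `m`.
#' @export
threshold_count <- function(T_h, k) {
  if (!is_prob(T_h)) param_error("`T_h` must be in [0, 1]")
  if (!is_count(k, min = 0L)) param_error("`k` must be a non-negative count")
  as.integer(floor(T_h * k))
}
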
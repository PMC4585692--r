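test_that("stationary internal-failure probability follows 1 - exp(-p tau)", {
  expect_equal(p_star(0, 50), 0)
  expect_equal(p_star(0.003, 50), 1 - exp(-0.15))
  grid <- seq(0, 0.05, by = 0.01)
  expect_true(all(diff(p_star(grid, 20)) > 0))
  expect_true(all(diff(vapply(1:40, function(tt) p_star(0.01, tt), 0)) > 0))
})

test_that("binomial damage probability matches exhaustive enumeration (k <= 12)", {
  for (k in c(1, 2, 3, 5, 8, 12)) {
    for (m in 0:k) {
      for (u in seq(0, 1, by = 0.1)) {
        expect_equal(damage_prob_E(m, k, u), enum_damage_prob(m, k, u),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(damage_prob_E(7, 7, 0.3), 1)   # certain event
  expect_equal(damage_prob_E(3, 9, 1), 0)
  expect_equal(damage_prob_E(1, 2, 0.5), 0.75)
  expect_error(damage_prob_E(5, 3, 0.5), class = "decaynet_param_error")
})

test_that("link activity composes independent internal and external failure", {
  expect_equal(link_active_prob(0, 0), 1)
  expect_equal(link_active_prob(0.3, 1), 0)
  expect_equal(link_active_prob(0.5, 0.2), 0.4)
})

test_that("fixed points of the self-consistency map obey limits, bistability and refinement", {
  # r = 0: unique fixed point at p_star
  s0 <- self_consistent_a(0.3, 0, 10, 4)
  expect_equal(s0$fixed_points, 0.3, tolerance = 1e-9)
  # p* = 1: total failure
  s1 <- self_consistent_a(1, 0.5, 10, 4)
  expect_equal(s1$fixed_points, 1, tolerance = 1e-9)
  # inside the bistable region: exactly 3 fixed points, outer two stable
  s3 <- self_consistent_a(0.1, 0.8, 10, 4)
  expect_length(s3$fixed_points, 3)
  expect_equal(s3$stable, c(TRUE, FALSE, TRUE))
  expect_equal(s3$a_prime, min(s3$fixed_points))
  # every reported point satisfies the fixed-point equation
  g <- function(a) {
    E <- damage_prob_E(4, 10, link_active_prob(a, 0))
    0.1 + 0.8 * E - 0.1 * 0.8 * E
  }
  for (a in s3$fixed_points) expect_lt(abs(g(a) - a), 1e-8)
  # grid refinement leaves the roots in place
  fine <- self_consistent_a(0.1, 0.8, 10, 4, grid_points = 100000L)
  expect_lt(max(abs(fine$fixed_points - s3$fixed_points)), 1e-6)
  # r -> 0 limit approaches p_star continuously
  for (r in c(0.05, 0.01, 0.001)) {
    sr <- self_consistent_a(0.2, r, 10, 4)
    expect_equal(min(sr$fixed_points), 0.2, tolerance = 0.05)
  }
})

test_that("spinodal scan finds the bistable wedge and its closure", {
  sp <- spinodal_curves(10, 4, grid_resolution = 150)
  expect_gt(nrow(sp), 5)
  expect_true(all(sp$p_star_upper >= sp$p_star_lower))
  cp <- attr(sp, "critical_point")
  expect_true(is.finite(cp["r"]) && is.finite(cp["p_star"]))
  # the two branches merge: the interval closes to (nearly) zero width
  expect_lt(min(sp$p_star_upper - sp$p_star_lower), 2.5 / 150)
  # and is genuinely open elsewhere
  expect_gt(max(sp$p_star_upper - sp$p_star_lower), 0.1)
  # no external collapse branch without a threshold
  expect_message(sp0 <- spinodal_curves(10, 0, grid_resolution = 100),
                 "no bistable region")
  expect_equal(nrow(sp0), 0)
  # internal link failures shrink the region
  area <- function(s) if (nrow(s) == 0) 0 else
    sum(s$p_star_upper - s$p_star_lower)
  a0 <- area(sp)
  a1 <- area(spinodal_curves(10, 4, p_tilde = 0.1, grid_resolution = 150))
  a2 <- area(spinodal_curves(10, 4, p_tilde = 0.2, grid_resolution = 150))
  expect_gt(a0, a1)
  expect_gt(a1, a2)
})

test_that("exponential decay law and analytic lifetime evaluate and scale correctly", {
  expect_equal(expected_alive(0, 0.003, 0.99, 10000), 10000)
  expect_equal(expected_alive(500, 0.01, 1, 2000), 2000)
  expect_equal(expected_alive(10000, 0.003, 0.99, 10000), 10000 * exp(-0.3))
  expect_equal(lifetime_tc(1, 0.003, 0.99), 0)
  expect_equal(lifetime_tc(0.5, 0.003, 0.99), -log(0.5) / (0.003 * 0.01))
  expect_equal(lifetime_tc(0.5, 0.003, 0.995), 2 * lifetime_tc(0.5, 0.003, 0.99))
  expect_identical(lifetime_tc(0.5, 0, 0.9), Inf)
  expect_identical(lifetime_tc(0.5, 0.01, 1), Inf)
  expect_identical(lifetime_tc(0, 0.01, 0.9), Inf)
  expect_error(lifetime_tc(1.2, 0.01, 0.9), class = "decaynet_param_error")
  # monotone decreasing in T_h, p and 1 - q
  ths <- c(0.3, 0.5, 0.7, 0.9)
  expect_true(all(diff(vapply(ths, lifetime_tc, 0, p = 0.01, q = 0.9)) < 0))
  ps <- c(0.001, 0.005, 0.02)
  expect_true(all(diff(vapply(ps, function(p) lifetime_tc(0.5, p, 0.9), 0)) < 0))
  qs <- c(0.5, 0.9, 0.99)
  expect_true(all(diff(vapply(qs, function(q) lifetime_tc(0.5, 0.01, q), 0)) > 0))
  # stable-branch prefactor shortens the lifetime
  expect_lt(lifetime_tc(0.5, 0.01, 0.9, a_prime = 0.1),
            lifetime_tc(0.5, 0.01, 0.9))
})

test_that("collapse gap is linear in the threshold spread", {
  expect_equal(collapse_gap(0.5, 0.5, 0.01), 0)
  expect_equal(collapse_gap(0.6, 0.4, 0.01), 20)
  expect_equal(collapse_gap(0.7, 0.3, 0.01), 2 * collapse_gap(0.6, 0.4, 0.01))
  expect_error(collapse_gap(0.6, 0.4, 0), class = "decaynet_param_error")
})

test_that("fractional thresholds map to the absolute count floor(T_h k)", {
  expect_equal(threshold_count(0.5, 10), 5L)
  expect_equal(threshold_count(0.45, 10), 4L)
  expect_equal(threshold_count(0.5, 6), 3L)
  expect_equal(threshold_count(0, 7), 0L)
  expect_equal(threshold_count(1, 7), 7L)
})
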
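test_that("threshold sampling honours constant and clamped-Gaussian specs", {
  expect_equal(sample_thresholds(threshold_gaussian(0.5, 0), 100), rep(0.5, 100))
  th <- sample_thresholds(threshold_gaussian(0.5, 0.2), 10000, seed = 4)
  expect_true(all(th >= 0 & th <= 1))
  expect_equal(mean(th), 0.5, tolerance = 0.01 / 0.5)
  # clamping at sigma = 0.2 barely moves the sd off the nominal value
  expect_equal(sd(th), 0.2, tolerance = 0.03)
  expect_identical(sample_thresholds(threshold_gaussian(0.5, 0.2), 50, seed = 1),
                   sample_thresholds(threshold_gaussian(0.5, 0.2), 50, seed = 1))
  expect_error(threshold_gaussian(0.5, -0.1), class = "decaynet_param_error")
  expect_error(threshold_constant(1.5), class = "decaynet_param_error")
})

test_that("initial state is fully active with unit observables", {
  net <- make_er(200, 6, seed = 2)
  pars <- decay_params(p = 0.01, q = 0.9, r = 0.5, tau = 5, threshold = 0.5,
                       seed = 3)
  st <- init_state(net, pars)
  ob <- observables(st)
  expect_equal(ob$f_a, 1)
  expect_equal(ob$f_l, 1)
  expect_equal(ob$t, 0)
  expect_equal(ob$mean_excess, 0.5)   # 1 - mean threshold on an all-active net
  st2 <- init_state(net, pars)
  expect_identical(st$th, st2$th)
})

test_that("threshold rule is inclusive: a half-active neighbourhood triggers external failure", {
  tri <- triangle_net()
  pars <- decay_params(p = 0, q = 1, r = 1, tau = 1, threshold = 0.5, seed = 1)
  st <- init_state(tri, pars)
  st$int_active[1] <- FALSE               # A internally down
  st2 <- sim_step(st, pars)
  # B and C each see 1 active of 2 neighbours: 1/2 <= 0.5, r = 1 -> down
  expect_equal(st2$ext_active, c(TRUE, FALSE, FALSE))
  expect_equal(st2$t, 1)
  # with nobody internally failed and T_h < 1 nothing happens
  stq <- init_state(tri, pars)
  stq2 <- sim_step(stq, pars)
  expect_true(all(stq2$ext_active) && all(stq2$int_active) && all(stq2$alive))
})

test_that("pure death process matches the (1-p)^t survival law", {
  net <- make_er(5000, 10, seed = 8)
  pars <- decay_params(p = 0.01, q = 0, r = 0, tau = 1, threshold = 0.5,
                       seed = 21, horizon = 100)
  traj <- run_decay(net, pars)
  expected <- (1 - 0.01)^100
  mc_sd <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(traj$n_living[traj$t == 100] / 5000 - expected), 3 * mc_sd)
})

test_that("no failure source means a frozen all-active network", {
  net <- make_er(300, 8, seed = 5)
  pars <- decay_params(p = 0, q = 1, r = 0.9, tau = 3, threshold = 0.5,
                       seed = 2, horizon = 50)
  traj <- run_decay(net, pars)
  expect_true(all(traj$f_a == 1))
  expect_true(all(traj$f_l == 1))
})

test_that("living count is non-increasing, and constant when recovery is certain", {
  net <- make_er(500, 10, seed = 6)
  pars <- decay_params(p = 0.02, q = 0.8, r = 0.8, tau = 5, threshold = 0.5,
                       seed = 9, horizon = 300, extra_steps_after_crash = 30)
  traj <- run_decay(net, pars)
  expect_true(all(diff(traj$n_living) <= 0))
  pq1 <- decay_params(p = 0.02, q = 1, r = 0.8, tau = 5, threshold = 0.5,
                      seed = 9, horizon = 100, extra_steps_after_crash = 10)
  tq1 <- run_decay(net, pq1)
  expect_true(all(tq1$n_living == 500))
})

test_that("a run is bitwise reproducible from its seed", {
  net <- make_ba(400, 5, seed = 3)
  pars <- decay_params(p = 0.01, q = 0.9, r = 0.8, tau = 10, threshold = 0.5,
                       seed = 77, horizon = 600, extra_steps_after_crash = 40)
  t1 <- run_decay(net, pars)
  t2 <- run_decay(net, pars)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "crash_times"), attr(t2, "crash_times"))
})

test_that("observables count links and degrees by hand on a damaged triangle", {
  tri <- triangle_net()
  pars <- decay_params(p = 0, q = 1, r = 0, tau = 1, threshold = 0.2, seed = 1)
  st <- init_state(tri, pars)
  st$alive[1] <- FALSE; st$int_active[1] <- FALSE; st$ext_active[1] <- FALSE
  ob <- observables(st)
  expect_equal(ob$f_a, 2 / 3)
  expect_equal(ob$f_l, 1 / 3)             # only the B-C link survives
  expect_equal(ob$avg_active_degree, 1)
  expect_equal(ob$n_living, 2)
  st$alive[] <- FALSE; st$int_active[] <- FALSE; st$ext_active[] <- FALSE
  ob0 <- observables(st)
  expect_equal(ob0$f_a, 0)
  expect_equal(ob0$f_l, 0)
  expect_equal(ob0$n_living, 0)
})

test_that("isolated nodes never fail externally", {
  lone <- igraph::make_empty_graph(10, directed = FALSE)
  igraph::V(lone)$name <- as.character(1:10)
  pars <- decay_params(p = 0, q = 1, r = 1, tau = 1, threshold = 1,
                       seed = 1, horizon = 20)
  traj <- run_decay(lone, pars)
  expect_true(all(traj$f_a == 1))
})

test_that("interventions select and clamp thresholds as documented", {
  net <- star_plus_path()
  pars <- decay_params(p = 0, q = 1, r = 0, tau = 1, threshold = 0.5, seed = 1)
  st <- init_state(net, pars)
  st1 <- apply_intervention(st, intervention_spec("crash", "all", 0.2))
  expect_equal(st1$th, rep(0.3, 5))
  st2 <- apply_intervention(st, intervention_spec("crash", "all", 0))
  expect_identical(st2$th, st$th)
  st3 <- apply_intervention(st, intervention_spec("crash",
                                                  list(top_degree = 3), 0.4))
  expect_equal(st3$th[1], 0.1)            # the hub is always selected
  expect_equal(sum(abs(st3$th - 0.1) < 1e-12), 3)
  st$th <- c(0.9, 0.2, 0.2, 0.7, 0.2)
  st4 <- apply_intervention(st, intervention_spec("crash",
                                                  list(threshold_above = 0.5), 0.3))
  expect_equal(st4$th, c(0.6, 0.2, 0.2, 0.4, 0.2))
  expect_warning(apply_intervention(st, intervention_spec("crash",
                                                          list(top_degree = 99), 0.1)),
                 "clamped")
  # clamping at zero
  st$th <- rep(0.1, 5)
  st5 <- apply_intervention(st, intervention_spec("crash", "all", 0.5))
  expect_equal(st5$th, rep(0, 5))
})

test_that("fixed-step interventions fire at their trigger time", {
  net <- make_er(500, 10, seed = 4)
  pars <- decay_params(p = 0.01, q = 0.9, r = 0.8, tau = 10, threshold = 0.5,
                       seed = 13, horizon = 400, extra_steps_after_crash = 20)
  tr <- run_decay(net, pars, intervention_spec(50, "all", 0.2))
  appl <- attr(tr, "interventions_applied")
  expect_length(appl, 1)
  expect_equal(appl[[1]]$t, 50)
})

test_that("ensemble lifetimes are reproducible and degenerate cases behave", {
  net <- make_er(300, 8, seed = 10)
  # saturating threshold: every neighbourhood fraction <= 1 from the start
  psat <- decay_params(p = 0.001, q = 0.99, r = 0.8, tau = 5, threshold = 1,
                       seed = 5, horizon = 50, extra_steps_after_crash = 5)
  esat <- ensemble_tc(net, psat, reps = 3)
  expect_true(all(esat$t_c <= 1))         # immediate cascade
  pno <- decay_params(p = 0, q = 1, r = 0.8, tau = 5, threshold = 0.5,
                      seed = 5, horizon = 30)
  expect_warning(eno <- ensemble_tc(net, pno, reps = 2), "no realization")
  expect_equal(eno$n_crashed, 0)
  pr <- decay_params(p = 0.02, q = 0.8, r = 0.8, tau = 5, threshold = 0.5,
                     seed = 8, horizon = 500, extra_steps_after_crash = 10)
  e1 <- ensemble_tc(net, pr, reps = 4)
  e2 <- ensemble_tc(net, pr, reps = 4)
  expect_identical(e1$t_c, e2$t_c)
  expect_equal(e1$n_crashed, 4)
})

test_that("node addition grows the living pool and can use either f_a denominator", {
  net <- make_er(300, 6, seed = 12)
  pars <- decay_params(p = 0.002, q = 0.9, r = 0.8, tau = 5, threshold = 0.5,
                       p_spawn = 0.002, seed = 31, horizon = 150,
                       extra_steps_after_crash = 10)
  traj <- run_decay(net, pars)
  expect_gt(max(traj$n_living), 0)
  expect_false(all(diff(traj$n_living) <= 0))   # births do occur
  pcur <- pars; pcur$f_a_denominator <- "current"
  tcur <- run_decay(net, pcur)
  expect_true(all(tcur$f_a <= 1 + 1e-12))
})

test_that("internal link failures depress the active-link fraction", {
  net <- make_er(500, 10, seed = 14)
  pars <- decay_params(p = 0, q = 1, r = 0, tau = 1, threshold = 0.01,
                       p_link = 0.3, seed = 17, horizon = 40)
  traj <- run_decay(net, pars)
  # all nodes stay active; only the i.i.d. link failures reduce f_l
  expect_equal(mean(traj$f_l[traj$t > 0]), 0.7, tolerance = 0.03)
})
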
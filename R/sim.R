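#' Initialise a simulation state
#'
#' Builds the per-node and per-link state on which [sim_step()] operates:
#' all nodes alive, internally and externally active, recovery timers at 0,
#' all links internally active, time `t = 0`. Per-node thresholds are drawn
#' from the parameter set's threshold spec. Self-loops are excluded from the
#' dynamics (a node is not its own neighbour) and from the link count.
#'
#' @param net An `igraph` network.
#' @param params A [decay_params()] object. `params$seed` seeds the
#'   threshold draw here; inside [run_decay()] the whole run shares one
#'   stream seeded once.
#' @return An object of class `decay_state`.
#' @export
init_state <- function(net, params) {
  stopifnot(inherits(params, "decay_params"))
  with_seed(params$seed, .init_state(net, params))
}

.init_state <- function(net, params) {
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(el) <- "integer"
  loops <- el[, 1L] == el[, 2L]
  if (any(loops)) el <- el[!loops, , drop = FALSE]
  i <- el[, 1L]; j <- el[, 2L]
  deg <- tabulate(c(i, j), nbins = n)
  spawn_links <- params$spawn_links
  if (is.null(spawn_links))
    spawn_links <- max(1L, as.integer(round(mean(deg) / 2)))
  structure(list(
    n = n, n0 = n, e0 = length(i),
    i = i, j = j, deg = deg,
    alive = rep.int(TRUE, n),
    int_active = rep.int(TRUE, n),
    ext_active = rep.int(TRUE, n),
    timer = integer(n),
    th = sample_thresholds(params$threshold, n),
    link_up = rep.int(TRUE, length(i)),
    spawn_links = as.integer(spawn_links),
    t = 0L
  ), class = "decay_state")
}

# Active-neighbour counts / full topological degree, given a logical
# `active` snapshot. Dead and inactive neighbours, and neighbours behind an
# internally failed link, count as inactive but remain in the denominator.
# Isolated nodes get fraction 1 (no neighbourhood to damage them).
.neighbor_fraction <- function(st, active) {
  ai <- active[st$i] & st$link_up
  aj <- active[st$j] & st$link_up
  cnt <- tabulate(c(st$j[ai], st$i[aj]), nbins = st$n)
  frac <- rep.int(1, st$n)
  pos <- st$deg > 0L
  frac[pos] <- cnt[pos] / st$deg[pos]
  frac
}

#' Advance a simulation state by one step
#'
#' One synchronous update from the time-`t` snapshot, in order: (1) internal
#' failures — each alive internally active node fails with probability `p`;
#' a failing node dies permanently with probability `1 - q`, otherwise its
#' recovery timer is set to `tau`; (2) recoveries — running timers
#' decrement, internal activity returns when a timer reaches 0; (3) link
#' status — with `p_link > 0` each link is independently internally
#' inactive this step; (4) external update — every living node whose
#' active-neighbour fraction (measured on the snapshot, denominator = full
#' topological degree) is at or below its threshold becomes externally
#' inactive with probability `r`, all other living nodes are externally
#' active (external failure lasts one step); (5) node addition with
#' probability `p_spawn` per living node.
#'
#' Randomness is taken from the current RNG stream; [run_decay()] seeds it
#' once per run.
#'
#' @param state A `decay_state` from [init_state()].
#' @param params The matching [decay_params()].
#' @return The updated `decay_state` with `t` advanced by one.
#' @export
sim_step <- function(state, params) {
  stopifnot(inherits(state, "decay_state"), inherits(params, "decay_params"))
  .step(state, params)
}

.step <- function(st, pp) {
  active <- st$alive & st$int_active & st$ext_active
  # (1) internal failures; permanence decided at the moment of failure
  just_down <- integer(0)
  if (pp$p > 0) {
    up <- which(st$alive & st$int_active)
    if (length(up)) {
      f <- up[stats::runif(length(up)) < pp$p]
      if (length(f)) {
        dies <- stats::runif(length(f)) < (1 - pp$q)
        dead <- f[dies]; just_down <- f[!dies]
        if (length(dead)) {
          st$alive[dead] <- FALSE
          st$int_active[dead] <- FALSE
          st$ext_active[dead] <- FALSE
        }
        if (length(just_down)) {
          st$int_active[just_down] <- FALSE
          st$timer[just_down] <- pp$tau
        }
      }
    }
  }
  # (2) recoveries (nodes that failed this very step keep their full timer)
  tick <- which(st$alive & st$timer > 0L)
  if (length(just_down)) tick <- setdiff(tick, just_down)
  if (length(tick)) {
    st$timer[tick] <- st$timer[tick] - 1L
    rec <- tick[st$timer[tick] == 0L]
    if (length(rec)) st$int_active[rec] <- TRUE
  }
  # (3) internal link failures, i.i.d. per step
  st$link_up <- if (pp$p_link > 0)
    stats::runif(length(st$i)) >= pp$p_link
  else rep.int(TRUE, length(st$i))
  # (4) external update from the snapshot
  frac <- .neighbor_fraction(st, active)
  la <- which(st$alive)
  st$ext_active[la] <- TRUE
  vul <- la[st$deg[la] > 0L & frac[la] <= st$th[la]]
  if (pp$r > 0 && length(vul)) {
    hit <- vul[stats::runif(length(vul)) < pp$r]
    if (length(hit)) st$ext_active[hit] <- FALSE
  }
  # (5) node addition
  if (pp$p_spawn > 0) st <- .spawn_nodes(st, pp)
  st$t <- st$t + 1L
  st
}

# Each living node spawns a new (fully active) node with probability
# p_spawn. A spawned node links to its parent plus spawn_links - 1 further
# living nodes chosen preferentially by degree.
.spawn_nodes <- function(st, pp) {
  living <- which(st$alive)
  parents <- living[stats::runif(length(living)) < pp$p_spawn]
  for (par in parents) {
    v <- st$n + 1L
    others <- setdiff(which(st$alive), par)
    extra <- min(st$spawn_links - 1L, length(others))
    targets <- par
    if (extra > 0L) {
      w <- st$deg[others] + 1        # +1 keeps degree-0 nodes reachable
      targets <- c(par, others[sample.int(length(others), extra, prob = w)])
    }
    st$n <- st$n + 1L
    st$alive <- c(st$alive, TRUE)
    st$int_active <- c(st$int_active, TRUE)
    st$ext_active <- c(st$ext_active, TRUE)
    st$timer <- c(st$timer, 0L)
    st$th <- c(st$th, sample_thresholds(pp$threshold, 1L))
    st$i <- c(st$i, rep.int(v, length(targets)))
    st$j <- c(st$j, targets)
    st$link_up <- c(st$link_up, rep.int(TRUE, length(targets)))
    st$deg <- c(st$deg, length(targets))
    st$deg[targets] <- st$deg[targets] + 1L
  }
  st
}

# Four moment summaries of a numeric vector: mean, sample (n-1) variance,
# moment-estimator skewness and excess kurtosis. Zero-variance input gets
# skewness/kurtosis 0 (flagged upstream by excess_stats()).
.moments <- function(x) {
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  m <- mean(x)
  d <- x - m
  m2 <- mean(d * d)
  v <- if (n > 1L) sum(d * d) / (n - 1) else NA_real_
  if (!is.finite(m2) || m2 < 1e-24) return(c(m, v, 0, 0))
  c(m, v, mean(d^3) / m2^1.5, mean(d^4) / m2^2 - 3)
}

#' Observables of a simulation state
#'
#' Computes the per-step record: `f_a` (active nodes / `N(0)`, or / `N(t)`
#' if the parameter set says so), `f_l` (internally active links with both
#' endpoints active / initial link count; `NA` for edgeless networks),
#' `avg_active_degree` (mean number of active incident links over active
#' nodes; 0 when no node is active), `n_living`, and the mean, variance,
#' skewness and excess kurtosis over living nodes of the excess
#' active-neighbour fraction (fraction minus own threshold). The mean excess
#' is crash indicator II: its first drop below zero defines the network
#' lifetime `t_c`.
#'
#' @param state A `decay_state`.
#' @param params The matching [decay_params()] (only the `f_a` denominator
#'   choice is consulted); may be omitted for the default `N(0)` denominator.
#' @return A one-row `data.frame`.
#' @export
observables <- function(state, params = NULL) {
  stopifnot(inherits(state, "decay_state"))
  denom <- if (!is.null(params) && params$f_a_denominator == "current")
    state$n else state$n0
  as.data.frame(as.list(.observe(state, denom)))
}

.observe <- function(st, denom_n) {
  active <- st$alive & st$int_active & st$ext_active
  frac <- .neighbor_fraction(st, active)
  eact <- st$link_up & active[st$i] & active[st$j]
  f_l <- if (st$e0 > 0L) sum(eact) / st$e0 else NA_real_
  nact <- sum(active)
  avg_deg <- if (nact > 0L) {
    aid <- tabulate(c(st$i[eact], st$j[eact]), nbins = st$n)
    sum(aid[active]) / nact
  } else 0
  mo <- .moments(frac[st$alive] - st$th[st$alive])
  c(t = st$t, f_a = nact / denom_n, f_l = f_l,
    avg_active_degree = avg_deg, n_living = sum(st$alive),
    mean_excess = mo[1L], excess_var = mo[2L],
    excess_skew = mo[3L], excess_kurt = mo[4L])
}

#' Apply an intervention to a simulation state
#'
#' Lowers the thresholds of the selected living nodes by `delta`, clamped to
#' `[0, 1]`. Selector `"all"` targets every living node;
#' `list(top_degree = n)` the `n` living nodes of largest topological degree
#' (ties by node index, count clamped with a warning if it exceeds the
#' living population); `list(threshold_above = c)` living nodes whose
#' current threshold exceeds `c`.
#'
#' @param state A `decay_state`.
#' @param spec An [intervention_spec()].
#' @return The modified `decay_state`.
#' @export
apply_intervention <- function(state, spec) {
  stopifnot(inherits(state, "decay_state"), inherits(spec, "intervention_spec"))
  living <- which(state$alive)
  sel <- if (identical(spec$selector, "all")) {
    living
  } else if (!is.null(spec$selector$top_degree)) {
    ct <- spec$selector$top_degree
    if (ct > length(living)) {
      warning("top_degree count exceeds living nodes; clamped", call. = FALSE)
      ct <- length(living)
    }
    living[order(-state$deg[living], living)][seq_len(ct)]
  } else {
    living[state$th[living] > spec$selector$threshold_above]
  }
  state$th[sel] <- pmin(1, pmax(0, state$th[sel] - spec$delta))
  state
}

#' Run the decay dynamics
#'
#' Iterates [sim_step()] from an all-active start, recording the
#' observables every step, until the horizon is reached, the network
#' crashes (indicator II — the mean excess active-neighbour fraction —
#' first turns negative) and `extra_steps_after_crash` further steps have
#' been recorded, or no living node remains. Interventions fire at their
#' triggers: a `"crash"` trigger fires at the moment a crash is detected
#' (consuming one pending intervention per crash, so a run with a pending
#' crash intervention keeps going and can record the postponed second
#' crash). The whole run is reproducible from `params$seed`.
#'
#' @param net An `igraph` network.
#' @param params A [decay_params()] object.
#' @param interventions A list of [intervention_spec()] objects (or a single
#'   spec).
#' @return A `decay_trajectory`: a `data.frame` with columns `t`, `f_a`,
#'   `f_l`, `avg_active_degree`, `n_living`, `mean_excess`, `excess_var`,
#'   `excess_skew`, `excess_kurt`, and attributes `params`, `crash_times`
#'   (every downward zero-crossing of indicator II), `t_c` (the first, `NA`
#'   if none), `interventions_applied`, `stopped` (one of `"crash"`,
#'   `"horizon"`, `"extinct"`), `n0`, `e0`.
#' @export
#' @examples
#' net <- make_er(500, 10, seed = 1)
#' pars <- decay_params(p = 0.01, q = 0.9, r = 0.8, tau = 10,
#'                      threshold = 0.5, seed = 1, horizon = 1500)
#' traj <- run_decay(net, pars)
#' detect_tc(traj)
run_decay <- function(net, params, interventions = list()) {
  stopifnot(inherits(params, "decay_params"))
  if (inherits(interventions, "intervention_spec"))
    interventions <- list(interventions)
  stopifnot(all(vapply(interventions, inherits, TRUE, "intervention_spec")))
  with_seed(params$seed, {
    st <- .init_state(net, params)
    denom_current <- params$f_a_denominator == "current"
    H <- params$horizon
    rec <- matrix(NA_real_, H + 1L, 9L)
    pending <- interventions
    applied <- list()
    crash_times <- integer(0)
    prev_me <- Inf
    stop_at <- Inf
    stopped <- "horizon"
    row <- 0L
    repeat {
      ob <- .observe(st, if (denom_current) st$n else st$n0)
      row <- row + 1L
      rec[row, ] <- ob
      me <- ob[[6L]]
      # fixed-step triggers fire right after their step is recorded
      if (length(pending)) {
        fire <- which(vapply(pending, function(sp)
          !identical(sp$trigger, "crash") && sp$trigger == st$t, TRUE))
        for (k in fire) {
          st <- apply_intervention(st, pending[[k]])
          applied <- c(applied, list(list(t = st$t, spec = pending[[k]])))
        }
        if (length(fire)) pending <- pending[-fire]
      }
      if (!is.na(me) && me < 0 && prev_me >= 0) {        # crash detected
        crash_times <- c(crash_times, st$t)
        k <- which(vapply(pending, function(sp)
          identical(sp$trigger, "crash"), TRUE))[1L]
        if (!is.na(k)) {
          st <- apply_intervention(st, pending[[k]])
          applied <- c(applied, list(list(t = st$t, spec = pending[[k]])))
          pending <- pending[-k]
        } else if (!is.finite(stop_at)) {
          stop_at <- st$t + params$extra_steps_after_crash
          stopped <- "crash"
        }
      }
      if (!is.na(me)) prev_me <- me
      if (sum(st$alive) == 0L) { stopped <- "extinct"; break }
      if (st$t >= stop_at) break
      if (st$t >= H) break
      st <- .step(st, params)
    }
    rec <- rec[seq_len(row), , drop = FALSE]
    out <- as.data.frame(rec)
    names(out) <- c("t", "f_a", "f_l", "avg_active_degree", "n_living",
                    "mean_excess", "excess_var", "excess_skew", "excess_kurt")
    structure(out,
              params = params,
              crash_times = crash_times,
              t_c = if (length(crash_times)) crash_times[1L] else NA_integer_,
              interventions_applied = applied,
              stopped = stopped,
              n0 = st$n0, e0 = st$e0,
              class = c("decay_trajectory", "data.frame"))
  })
}

#' @export
print.decay_trajectory <- function(x, ...) {
  tc <- attr(x, "t_c")
  cat(sprintf("Decay trajectory: %d steps, N(0) = %d, %d links\n",
              nrow(x) - 1L, attr(x, "n0"), attr(x, "e0")))
  cat(sprintf("  crash at t_c = %s (stopped: %s), final f_a = %.4f\n",
              if (is.na(tc)) "none" else tc, attr(x, "stopped"),
              x$f_a[nrow(x)]))
  invisible(x)
}

#' Ensemble network lifetime
#'
#' Runs the dynamics `reps` times with child seeds derived from
#' `params$seed` (see [derive_rep_seeds()]) and collects the detected
#' lifetime `t_c` of each realization.
#'
#' @param net An `igraph` network.
#' @param params A [decay_params()] object; `params$seed` is the master
#'   seed.
#' @param reps Number of realizations (>= 1).
#' @return A list of class `ensemble_tc` with elements `t_c` (per rep; `NA`
#'   where no crash occurred), `mean`, `sd` (over crashed reps), `n_crashed`,
#'   and `seeds`. Warns if no rep crashed.
#' @export
ensemble_tc <- function(net, params, reps = 20L) {
  stopifnot(inherits(params, "decay_params"))
  if (!is_count(reps, min = 1L)) param_error("`reps` must be >= 1")
  seeds <- derive_rep_seeds(params$seed, reps)
  tcs <- vapply(seeds, function(s) {
    pr <- params
    pr$seed <- s
    as.numeric(attr(run_decay(net, pr), "t_c"))
  }, 0)
  crashed <- !is.na(tcs)
  if (!any(crashed)) warning("no realization crashed", call. = FALSE)
  structure(list(
    t_c = tcs,
    mean = if (any(crashed)) mean(tcs[crashed]) else NA_real_,
    sd = if (sum(crashed) > 1L) stats::sd(tcs[crashed]) else NA_real_,
    n_crashed = sum(crashed),
    seeds = seeds
  ), class = "ensemble_tc")
}

#' @export
print.ensemble_tc <- function(x, ...) {
  cat(sprintf("Ensemble lifetime: %d/%d reps crashed; mean t_c = %s, sd = %s\n",
              x$n_crashed, length(x$t_c),
              format(x$mean, digits = 5), format(x$sd, digits = 4)))
  invisible(x)
}
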
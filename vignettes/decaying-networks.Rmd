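---
title: "Decaying dynamic networks: model, theory and indicators"
author: "decaynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decaying dynamic networks: model, theory and indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decaynet)
```

## The model

`decaynet` simulates a dynamic network whose nodes carry two kinds of
activity and one irreversible state:

* **Internal failures.** Each internally active, living node fails
  internally with probability `p` per step, independently of its
  neighbours. With probability `1 - q` the failure is permanent — the node
  *dies* and is removed from the living pool forever. Otherwise the node is
  internally inactive for exactly `tau` steps and then recovers. A node
  that is already internally down cannot fail again until it has recovered,
  which makes the internal dynamics a renewal process: the stationary
  probability of being internally failed is `p* = 1 - exp(-p tau)`
  (`p_star()`), and the long-run down fraction is `p tau / (1 + p tau)`.
* **External failures.** Each living node watches the fraction of its
  neighbours that are *active* — alive, internally active and externally
  active — among its full topological degree (dead neighbours count as
  inactive but stay in the denominator; a node is never its own
  neighbour). If at time `t` that fraction is less than or equal to the
  node's threshold `T_h`, the node is externally inactive at `t + 1` with
  probability `r`. External failure lasts a single step and is
  re-evaluated every step. Isolated nodes are always externally active.
* **Updates are synchronous** from the time-`t` snapshot, in a fixed stage
  order (internal failures with permanence decided immediately, timer
  decrements and recoveries, optional i.i.d. link failures, external
  update, optional node addition), with all random draws in node-index
  order from a single seeded stream. A run is therefore bitwise
  reproducible from its seed.

Permanent deaths make the living pool decay exponentially,
`N(t) = N(0) exp(-lambda t)` with `lambda = (1 - q) p` (to first order;
because internally-down nodes cannot re-fail, the exact rate is
`(1-q) p (1 - rho)` with `rho = p tau/(1 + p tau)` the stationary down
fraction — a correction below 10% whenever `p tau <= 0.1`). The decaying
living fraction slowly starves every neighbourhood until the
threshold rule takes over and a cascade of external failures destroys the
remaining activity almost at once. The first time at which the mean excess
active-neighbour fraction (indicator II below) turns negative defines the
network lifetime `t_c`.

## Mean-field theory

On a random regular network of degree `k` with the fractional threshold
encoded as the absolute count `m = floor(T_h k)` (a node survives the
threshold rule exactly when more than `m` of its `k` neighbours are
active), the stationary fraction of inactive nodes `a` solves

```
a = p* + r E - p* r E,     E = P(Binomial(k, u) <= m),  u = (1 - p~)(1 - a)
```

— a node is inactive if it failed internally, or (union of independent
events) its neighbourhood is critically damaged (`E`) and the external hit
lands (`r`). `p~` is the optional internal link-failure probability.
`self_consistent_a()` finds all fixed points by a dense sign-change scan
refined by bisection (default 10^4 grid intervals, refined to
`|g(a) - a| <= 1e-10`; roots are stable under a tenfold grid refinement to
well below 1e-6) and classifies stability by `|g'(a)| < 1` with central
differences (`h = 1e-6`; the map is smooth, so the choice of `h` is
uncritical). For a range of `(p*, r)` the map has three fixed points — two
stable branches separated by an unstable one. `spinodal_curves()` traces
the boundary of that bistable wedge in the `(p*, r)` plane; the two
spinodal branches merge at a critical point (for `k = 10`, `m = 4`:
near `r ≈ 0.60`, `p* ≈ 0.35`). Inside the wedge the network can flip
between the active and the failed branch — with `q < 1` the decay drags it
irreversibly across.

Equating the decaying active fraction `(1 - a') exp(-lambda t)` with the
threshold gives the analytic lifetime

```
t_c = ln((1 - a') / T_h) / (p (1 - q))      (lifetime_tc)
```

with `a'` the stable low-inactivity branch of the self-consistency map
(prefactor 1 if omitted): the logarithmic distance to the threshold over
the rate of approach.

### What the analytic lifetime does and does not capture

The formula above treats the collapse as happening when the *mean*
neighbourhood reaches the threshold. The simulated model is harsher: the
external-failure rule feeds back (externally failed neighbours damage
their neighbours' fractions), so the quiescent branch of the
self-consistency map vanishes — a spinodal — already at a living fraction
`s*` well above `T_h`, and the cascade fires there. Three consequences,
all visible in the package's own tests:

* the collapse is abrupt and first-order-like, with a discrete drop in
  `f_a` (measured by `crash_drop()`) rather than a smooth decline;
* the simulated `t_c` is set by `-ln(s*)/lambda` and is therefore
  substantially *shorter* than `lifetime_tc()` at equal parameters
  (`lifetime_tc()` is an idealized upper scale, not a point prediction of
  the simulation), while remaining proportional to `-ln(T_h)` across
  thresholds and exactly inversely proportional to `1 - q`. Because
  doubling `p` also doubles `p*` and moves the spinodal, `t_c` falls
  faster than `1/p`;
* `s*` depends on the topology: degree heterogeneity postpones the
  spinodal (hubs have many independent chances of keeping enough active
  neighbours), which is why scale-free (preferential-attachment) networks
  outlive Erdős–Rényi networks of equal mean degree under identical
  attack — the ordering the simulator reproduces. A quantitative
  first-principles prediction of `s*` for heterogeneous graphs would need
  a degree-resolved mean field, which is out of scope here: the theory
  module deliberately follows the common-degree assumption.

## Crash indicators

`indicator_series()` assembles two early-warning statistics per run:

* **Indicator I** (`moving_std_forward()`): the forward moving standard
  deviation of `f_a` with window equal to the recovery delay `tau`
  (sample `n - 1` denominator throughout, so figures are reproducible
  bitwise; incomplete tail windows are explicit `NA`s, written as empty
  CSV fields). It spikes when the window first covers the collapse cliff,
  i.e. just before and at the crash.
* **Indicator II**: the mean over living nodes of the *excess* active
  neighbour fraction — each node's active-neighbour fraction minus its own
  threshold `T_hi`. On an all-active network it starts at `1 - mean(T_h)`,
  declines roughly linearly (slope comparable to `p (1 - q)`,
  recoverable with `fit_linear_indicator()`), and its first negative value
  *defines* the detected lifetime (`detect_tc()`). Averaging over living
  nodes (rather than all initial nodes) keeps the indicator meaningful as
  the population shrinks.

The per-step variance, skewness and excess kurtosis of the same per-node
excess values are recorded during the run; their abrupt change inside the
crash bracket — against a quiet pre-crash baseline — is the
distributional fingerprint of the collapse (`excess_stats()`,
`excess_histogram()`).

With heterogeneous thresholds (`threshold_gaussian(mean, sd)`, clamped to
`[0, 1]` rather than resampled, which for `sd <= 0.2` leaves the mean
essentially unchanged), nodes collapse at different times — two nodes of
thresholds `th1 > th2` roughly `(th1 - th2)/alpha` steps apart
(`collapse_gap()`). The single sharp bump of indicator I dissolves into
smaller fluctuations and the 10–90% crash transition
(`crash_transition_width()`) lengthens.

## Forecasting

Pre-crash, `log f_a` is linear in `t`, so `fit_decay_rate()` estimates the
decay rate and prefactor by ordinary least squares on the log scale (the
model is exactly log-linear there; the fit skips the first `tau` steps by
default, the transient before the internally-down fraction reaches
stationarity). `remaining_lifetime()` inverts the fitted law at a target
level: the forecast lifetime is `(intercept - ln T_h)/lambda_hat`, and the
practically relevant quantity is the remaining time `t_c - t_now`. On
noiseless exponential input the pipeline inverts `lifetime_tc()` to within
one step. Against the simulated model the same caveat as for the analytic
formula applies: a forecast that targets the threshold `T_h` inherits the
idealization and overestimates the realized (spinodal-set) lifetime;
targeting an empirically chosen collapse level instead makes forecast
error shrink as the observed prefix grows.

## Interventions

`intervention_spec()` describes threshold reductions — raising robustness
— applied to all living nodes, to the highest-degree nodes, or to nodes
above a threshold cutoff, triggered at a fixed step or at the moment a
crash is detected. Lowering every threshold by 0.2 at `t_c` halts the
cascade (the neighbourhood rule stops firing), producing an immediate
upward jump in `f_a`; since the living pool keeps decaying, the collapse
is postponed, not prevented, and the run continues to the second crash.
Because the count of "largest nodes" to treat is a modelling choice with
no natural default, the top-degree selector takes an explicit count.

## Synthetic topologies and what passing tests show

The generators cover the study conditions: Erdős–Rényi `G(n, p)` at a
target mean degree, Barabási–Albert preferential attachment, a
Holme–Kim-style variant with tunable clustering (each extra link closes a
triangle with probability `triad_prob`), and random regular graphs for the
mean-field comparisons. Real topologies enter through plain-text edge
lists (`read_edge_list()`), which are always projected to their simple
undirected skeleton — duplicate and reverse edges collapsed, extra columns
ignored with a warning, self-loops kept or dropped by flag (they never
enter the dynamics either way) — plus `giant_component()` with a
deterministic smallest-index tie rule. A small synthetic
protein-interaction-style network ships in
`inst/extdata/synthetic_ppi_sample.tsv` for demonstrations; it is
generated, not real data.

The test suite runs the full pipeline at desk scale — networks of 1000 to
5000 nodes, lifetimes of a few hundred steps (e.g. `p = 0.01`, `q = 0.9`
instead of the headline `p = 0.003`, `q = 0.99`, which would put `t_c`
near 23000 steps), 5–10 realizations per claim, seeds derived from one
master via a counter-based mix (`derive_rep_seeds()`). What passes at this
scale — the decay law, the renewal stationarity, the spinodal structure,
the indicator behaviour at the crash, the robustness ordering — are
properties of the model, not of any particular network size; what desk
scale does *not* probe are large-`N` metastability (escape times from the
quiescent branch near, but before, the spinodal) and the long flat
pre-crash plateaus of the slow-decay regime. Synthetic generators also do
not emulate degree correlations, community structure or clustering
patterns of real interactomes beyond what the clustered-BA model adds.

## A worked example

```{r example, eval = FALSE}
net <- make_er(2000, 10, seed = 1)
pars <- decay_params(p = 0.01, q = 0.9, r = 0.8, tau = 10, threshold = 0.5,
                     seed = 42, horizon = 4000)
traj <- run_decay(net, pars)
detect_tc(traj)                      # simulated lifetime
lifetime_tc(0.5, 0.01, 0.9)          # idealized analytic scale (693)
ind <- indicator_series(traj)        # indicators I and II
crash_drop(traj, settle_window = 80) # size of the collapse
```
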
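# decaynet

Simulation, theory and lifetime prediction for **decaying dynamic
networks** under persistent random attack.

Many networked systems — interactomes whose proteins lose function,
financial systems whose banks fail, infrastructures under sustained
attack — do not die gradually: they erode slowly and then collapse all at
once. `decaynet` implements a minimal stochastic model of that behaviour
and the analytics around it, for researchers studying network robustness
as a *dynamic* property (how long a network lives) rather than a static
percolation threshold.

## The model

Each node of a fixed topology is **alive or dead**, **internally
active/failed**, and **externally active/failed**:

* internal failure with probability *p* per step; with probability
  *1 − q* the failure is permanent (the node dies), otherwise the node
  recovers after *τ* steps;
* external failure: if the fraction of a node's *active* neighbours
  (among its full degree, dead neighbours included) is ≤ its threshold
  *T_h*, the node is externally failed with probability *r* for one step;
* a node is *active* only if alive, internally and externally active.

Permanent deaths give an exponential decay of the living pool,
*N(t) = N(0)·exp(−(1 − q)p·t)*, which drags the network to a cascade of
threshold failures — an abrupt collapse at a finite lifetime *t_c*,
detected as the first time the mean excess active-neighbour fraction
(crash indicator II) turns negative. The idealized lifetime scale is

*t_c = ln((1 − a′)/T_h) / (p(1 − q))*,

the log-distance to the threshold over the rate of approach, with
*1 − a′* the stationary active fraction from the mean-field
self-consistency *a = p\* + rE − p\*rE*,
*E = P(Binom(k, (1−p̃)(1−a)) ≤ m)*, *p\* = 1 − e^{−pτ}*, *m = ⌊T_h·k⌋*.
The simulated collapse fires at the spinodal of that map — earlier, abrupt,
and topology-dependent (scale-free networks outlive Erdős–Rényi ones);
see the vignette for what the formula does and does not capture.

## Worked example

```r
library(decaynet)

net  <- make_er(2000, 10, seed = 1)          # ER, N = 2000, <k> = 10
pars <- decay_params(p = 0.01, q = 0.9, r = 0.8, tau = 10,
                     threshold = 0.5, seed = 42, horizon = 4000)
traj <- run_decay(net, pars)
traj
#> Decay trajectory: 427 steps, N(0) = 2000, 10118 links
#>   crash at t_c = 227 (stopped: crash), final f_a = 0.1380

detect_tc(traj)                 # 227  — simulated lifetime (indicator II < 0)
lifetime_tc(0.5, 0.01, 0.9)     # 693  — idealized analytic scale
crash_drop(traj, settle_window = 80)
#> 0.331                         # abrupt fall of the active fraction

ensemble_tc(net, pars, reps = 5)
#> Ensemble lifetime: 5/5 reps crashed; mean t_c = 235.6, sd = 9.397

self_consistent_a(p_star(0.01, 10), 0.8, k = 10, m = 5)
#> Mean-field solution (p* = 0.0951626, r = 0.8, k = 10, m = 5, p~ = 0)
#>   a = 0.096152 (stable)       # quiescent branch (a')
#>   a = 0.445573 (unstable)
#>   a = 0.816055 (stable)       # collapsed branch
```

The simulated lifetime (227) sits well below the idealized 693: the
external-failure feedback tips the cascade at the spinodal of the
mean-field map before the mean neighbourhood ever reaches *T_h*. The same
runs show the early-warning signature: `indicator_series(traj)` gives the
forward moving standard deviation of `f_a` (indicator I, peaking at the
crash) and the declining indicator II whose zero crossing *is* `t_c`.

Real topologies load from plain-text edge lists (always projected to the
simple undirected skeleton):

```r
g <- read_edge_list(system.file("extdata", "synthetic_ppi_sample.tsv",
                                package = "decaynet"))
g <- giant_component(g)
```

## Command line

A thin CLI over the same functions is installed at
`<library>/decaynet/exec/decaynet`:

```sh
decaynet generate  --model ba --nodes 2000 --links-per-node 5 --seed 1 -o net.tsv
decaynet simulate  --edges net.tsv --p 0.01 --q 0.9 --r 0.8 --tau 10 \
                   --th 0.5 --horizon 4000 --seed 42 -o traj.csv
decaynet indicators --traj traj.csv --window 10 -o ind.csv
decaynet predict   --traj traj.csv --up-to 100 --th 0.5
decaynet meanfield --k 10 --m 4 -o spinodals.csv
decaynet tc-analytic --th 0.5 --p 0.003 --q 0.99
```

Exit codes: 0 success, 2 parameter error, 3 I/O error.

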
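---
title: "Spin cascades and barrage intervention on directed networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin cascades and barrage intervention on directed networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by `infinet`, the choices
behind its defaults, what the synthetic benchmark does and does not
emulate, and the package's known limitations.

## Network conventions

A network is a directed, unweighted simple graph. On ingestion
(`read_edge_list()`, TSV or SIF) self-loops are removed and duplicate
edges collapse to a single link, so the adjacency matrix has
`A[i, j] = 1` iff there is an edge `j -> i` and a zero diagonal. Node
identity is handled with dense 1-based integer indices plus the original
name map; all user-facing tables report names and 1-based ranks.

From `A`, `build_transition_matrices()` derives:

* `S_tilde`: columns divided by the out-degree; columns of *dangling*
  nodes (no outgoing links) stay identically zero;
* `S`: column-stochastic, equal to `S_tilde` except that dangling columns
  are replaced by the uniform value `1/N`;
* `W = S_tilde + t(S_tilde)`: the symmetric coupling that drives the spin
  dynamics.

The split matters: the **ranking** uses `S` (a proper Markov transition
matrix), while the **spin dynamics deliberately use `S_tilde`/`W`** — a
dangling node influences nothing, rather than influencing everything
uniformly. The two code paths never mix.

## Google-matrix ranking

PageRank is the stationary vector of `G = alpha * S + (1 - alpha)/N`
(damping `alpha = 0.85`, the standard value for directed information
networks; configurable). `apply_google()` is matrix-free: the sparse
`S_tilde` product, the dangling mass and the teleportation term are added
separately, so the dense `N x N` matrix is never formed and 40k-node
networks are unproblematic. `pagerank()` iterates from the uniform vector
until the L1 change drops below `tol = 1e-12` (default; the result then
satisfies `||G P - P||_1 < 10 * tol`), erroring after `max_iter = 10000`.
CheiRank is PageRank of the link-inverted network. Rank indices order
probabilities decreasingly; ties (which the underlying theory does not
address) break deterministically by ascending node index. Power iteration
was chosen over a linear solve because it mirrors the Markov-process
definition, is memory-light, and converges geometrically at rate `alpha`.

## The spin cascade

Each node carries a spin in {+1, 0, -1} (activated / neutral /
repairing). A panel pins some nodes permanently: red nodes at +1, blue
nodes at -1. A *realization* starts from the pinned values, spin -1 on
the chosen initial-blue nodes (these are **variable** — they may be
overturned later; only the panel blues are pinned) and 0 elsewhere. Each
sweep draws a fresh uniform random permutation of the variable nodes and
updates them one at a time:

* local field `Z_i = sum_{j != i} W_ij * sigma_j`, summed over pinned and
  variable neighbours alike;
* `sigma_i <- sign(Z_i)` if `Z_i != 0`, otherwise unchanged;
* the new value is immediately visible to later updates of the same sweep.

Sweeps repeat up to `tau_max = 100` (default, matching the regime where
ensemble averages are fully converged; benchmark runs converge around
sweep 4-8). When a sweep changes nothing the run stops early: the state
is absorbing, because with no change during the sweep every field is
evaluated at the same configuration regardless of order. The engine
verifies this with one extra sweep after early exit and records
`tau_last`, the first sweep index after which nothing changed.

An ensemble (`simulate_infi()`) runs `R` independent realizations and
reports per-node red/blue outcome fractions, the average `fr` over the
`Nv = N - |pinned|` variable nodes, the per-sweep trajectory `fr(tau)`
(held constant after convergence) and the count of *stable white* nodes —
nodes never red and never blue, exactly those with no symmetrized-graph
path to a pinned node.

### Reproducibility

One master seed spawns a per-realization substream
(`splitmix64(seed << 32 XOR realization)` feeding an `mt19937_64`), so
results are bit-reproducible and independent of execution order. Bounded
draws use rejection sampling rather than
`std::uniform_int_distribution`, whose output is implementation-defined.
The sweep engine is compiled (Rcpp): asynchronous updates are inherently
sequential and cannot be vectorised in R, and ensembles take
`R x tau x Nv` single-node updates (about 10^8 at paper scale). Pure-R
reference implementations of the field evaluation, single-node update and
sweep are exported (`local_field()`, `update_node()`, `sweep_spins()`)
and cross-checked against the engine in the tests.

### The spin-flip symmetry

The update rule is odd in the spins: swapping the pinned red and blue
sets and recolouring initial blues as initial reds, under identical RNG
streams, negates every spin of every realization exactly (IEEE negation
is exact). The test suite asserts this bit-exactly; `sim_config()`
exposes the `initial_sign` used for the mirrored experiment.

## Barrage machinery

* `erdos_set()`: all nodes with `W > 0` coupling to at least one hub
  node, excluding the hub itself and (by default) the pinned blue panel —
  whether panel blues belong in the candidate set is ambiguous in the
  underlying theory, so it is a flag (`exclude_blue = TRUE`).
* `rank_single_blue()`: for each candidate, the ensemble mean red outcome
  `frc(i)` with that candidate as the single fixed initial blue; `Kfr`
  ranks candidates by increasing `frc`, ties by node index.
* `conditional_frc()`: the same quantity estimated *post hoc* from a
  stored random-placement ensemble, conditioning on realizations whose
  draw contains (or exactly equals) the query configuration. Estimates
  with fewer than `min_support = 100` supporting realizations (default;
  reliable averages need on the order of a thousand) are flagged
  undefined rather than reported.
* `evaluate_all_subsets()`: every subset of a small group (at most 12
  nodes) as a fixed configuration, including the empty baseline.
* `select_optimal_group()`: the k candidates minimising the summed `Kfr`
  positions across rankings obtained at several `n_ib` values — a
  deterministic rank-sum stand-in for the informal notion of a group that
  is "uniformly near the top" of all rankings.

Both placement modes of the underlying experiments are supported:
`random_in_set` (fresh uniform draw of `n_ib` distinct candidates per
realization) and `fixed_configuration`.

## Outcome statistics

Histograms use half-open bins `[k*bw, (k+1)*bw)` with the last bin closed
at 1 and density normalised to unit integral. Each bin records the mean
of its members, so the histogram-weighted mean reproduces the arithmetic
mean *exactly*; the ensemble consistency identity
`fr_mean = integral fr p(fr) dfr` is asserted at 1e-12 in the tests. The
empirical CCDF `P(fr)` uses strict inequality (`fr(i) > fr`). The median
is the smallest observed value with CCDF <= 0.5 (no interpolation: at
ensemble resolution the relevant medians are discrete multiples of
`1/R`). Algebraic tails are fitted by ordinary least squares of `log P`
on `log fr` above `fr_min = 5e-3` (at least 10 support points), returning
the slope, its standard error and the residual scale as a
goodness-of-fit flag. `ng_grid()` provides the mixed linear/geometric
barrage-size grid (`n_ib = ng` up to 10, then `round(10 * 1.2^(ng-10))`).

## The synthetic benchmark

Application-grade PPI networks (tens of thousands of nodes, proprietary)
cannot ship with the package, so `generate_network()` builds a miniature
with the same gross structure: `N = 1000` nodes, mean out-degree 7.3,
18% of nodes in a separate component unreachable from the hub (the
stable-white set), a pinned activator panel of 10 and a repairing panel
of 6.

Two structural choices required care at this scale:

* **Heavy-tailed link budgets.** Each arriving node draws its number of
  links from a truncated power law with the target mean (cap
  `max_edge_budget = 12`) instead of a fixed budget. Real interaction
  networks are sparse in the median — most proteins have one or two
  documented links — and that sparseness is what lets a repairing seed
  hold territory; with a fixed budget of 7 every neighbourhood is dense
  and the cascade is deterministically red.
* **Sublinear attachment and panel placement.** With linear preferential
  attachment at N = 1000, the top-10 in-degree nodes are adjacent to half
  the network; in the application networks the activated panel touches
  under 1% of nodes, and the permanently activated disease proteins are
  *not* the global hubs — the global hubs stay variable and are precisely
  the best barrage sites. The default attachment exponent is therefore
  0.3, and the red panel is drawn from the 2nd-20th in-degree percentile
  band (well connected, below the hubs); the blue panel from the
  mid-degree range. With `attachment_exponent >= 1` the generator
  produces the expected heavy (algebraic) in-degree tail, which the tests
  verify.

What the benchmark reproduces qualitatively: a majority-red baseline
(`fr ~ 0.8`) with a sharply peaked `fr(i)` distribution; an exactly
stable white fraction of 0.18; monotone decay of `fr` with the number of
initial blues; markedly stronger suppression when blues are drawn from
the Erdös candidate set than from all variable nodes. What it does not
reproduce: absolute magnitudes that depend on the 40x larger scale —
single-node barrages reduce `fr` only modestly here (at full scale one
top-hub blue can almost extinguish the cascade), reduction factors for
4-node groups are of order a few rather than hundreds, and long-range
`P(fr) ~ fr^-1.5` tails spanning five decades cannot emerge from
`R = 2000` realizations over 984 nodes. Passing tests therefore certify
the machinery and the qualitative physics, not paper-scale numbers.

## Problem sizes used by tests and the acceptance script

Chosen so a full run stays comfortable on one CPU: benchmark ensembles
use `R = 2000` realizations with `tau_max = 50` (baseline runs converge
by sweep ~8); single-node rankings use `R = 400` per candidate;
conditional rankings condition 20,000-realization ensembles; the
exhaustive sweep-order oracle runs on an 8-node fixture with 6 variable
nodes and `tau_max = 2`, where collapsing duplicate intermediate states
makes full enumeration of all `(6!)^2` order sequences exact and cheap.

## Known limitations

* Links are unweighted and mono-functional: activation/inhibition edge
  semantics are out of scope, as are weighted or multigraph inputs.
* The update rule is zero-temperature majority dynamics; no noise term.
* `conditional_frc()` with `mode = "exact"` needs ensembles large enough
  to revisit whole configurations; it is practical only for small `n_ib`.
* The rank-sum group selector is a heuristic; it is exact only in the
  sense of minimising summed rank positions, and ties are broken by node
  index.
* Storing per-realization placements (`store_realizations = TRUE`) keeps
  an `n_ib x R` integer matrix in memory; at `R = 10^5` and large `n_ib`
  this is the dominant memory cost.
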
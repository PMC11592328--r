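# infinet

Three-state spin cascades, Google-matrix ranking and Erdös-barrage
intervention on directed networks.

## The problem

Directed protein–protein interaction (PPI) networks encode which proteins
act on which. When a small panel of proteins is locked into a pathological
activated state (for example fibroblast activation under persistent TGF-β
stimulation), activation can cascade through the network. Two questions
follow for a systems biologist:

1. **How far does the cascade spread**, starting from a handful of
   permanently activated nodes?
2. **Which small set of "repairing" nodes, if held in the healthy state,
   blocks it** — a *barrage* against disease progression?

`infinet` answers both with an Ising-type opinion model. Every node `i`
carries a spin σᵢ ∈ {+1, 0, −1}: activated ("red"), neutral ("white") or
repairing ("blue"). A designated panel is pinned: red nodes stay +1, blue
nodes stay −1, forever. All other spins evolve by asynchronous Monte Carlo
sweeps: in a fresh random order each sweep, every variable node computes
its local field

```
Z_i = Σ_{j≠i} (S̃_ij + S̃_ji) σ_j
```

and adopts σᵢ ← sign(Zᵢ) (unchanged when Zᵢ = 0), each update being
immediately visible to later updates of the same sweep. Here S̃ is the
column-normalised adjacency matrix (S̃ᵢⱼ = Aᵢⱼ/Σₗ Aₗⱼ, zero columns at
dangling nodes), so a node is pulled by the *weighted majority colour* of
its neighbourhood. Repeating the run R times (sweeps capped at τ_max = 100,
fresh random update orders and initial-blue placements each realization)
yields per-node red-outcome fractions `fr(i)` and the network average
`fr = Σᵢ fr(i)/Nv` over the Nv variable nodes.

Around this core the package provides:

* **Google-matrix ranking** — matrix-free PageRank `P` (rank index `K`) on
  `G = αS + (1−α)/N` with α = 0.85, and CheiRank `P*` (`K*`) on the
  link-inverted network, for locating influential and communicative nodes.
* **Erdös barrage** — the candidate set at symmetrized distance 1 from the
  pinned red hub; ranking of candidates by the conditional network-mean red
  outcome `frc(i)` when node `i` is the single initial blue (`Kfr` order);
  conditional estimates from stored random-placement ensembles; exhaustive
  evaluation of all subsets of a small optimal group; rank-sum selection of
  a jointly optimal group.
* **Outcome statistics** — normalised histograms of `fr(i)`, empirical
  complementary CDFs `P(fr)` with algebraic-tail fitting, medians, peaks,
  and the mixed linear/geometric `n_ib` grid for decay curves.
* **A synthetic benchmark generator** — sparse directed scale-free-like
  networks with a pinned activator panel, a mid-degree repairing panel and
  a hub-unreachable component, so every stage is testable without
  proprietary network data.

## Worked example

```r
library(infinet)

gen  <- generate_network(synthetic_spec(N = 1000, seed = 2))
mats <- build_transition_matrices(gen$network)

sim <- simulate_infi(mats, gen$panel, sim_config(R = 2000, tau_max = 50, seed = 1))
glance(sim)
#>   fr_mean    Nv     R white_stable_count white_stable_fraction tau_last_median
#> 1   0.814   984  2000                180                  0.18               4

es <- erdos_set(mats, gen$panel$fixed_red, gen$panel)
length(es)
#> [1] 201

barrage_decay(mats, gen$panel, c(0, 5, 10, 20), candidate_set = es,
              R = 1000, tau_max = 50, seed = 3)
#>    n_ib fr_mean      se
#> 1     0  0.814  0.00122
#> 2     5  0.693  0.00917
#> 3    10  0.390  0.0128
#> 4    20  0.0218 0.00391
```

Reading the numbers: with no intervention the cascade turns 81% of the 984
variable nodes red on average, while 18% of nodes (the hub-unreachable
component) always stay white. Of the 201 nodes one symmetrized link away
from the activated panel, pinning 5/10/20 random ones initially blue drops
the mean red outcome to 0.69 / 0.39 / 0.02 — a barrage of 2% of the network
almost extinguishes the cascade. `tidy(sim)` gives the per-node table;
`autoplot(sim)` and `plot_decay()` draw the histogram, convergence and
decay figures.

A command-line wrapper (`inst/cli/infi`) exposes the same pipeline as
`synth`, `rank`, `simulate`, `barrage` and `stats` subcommands, each
writing TSV/JSON outputs plus a JSON run manifest that `replay` reproduces
bit-for-bit.

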
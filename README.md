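# cycleneutral

Neutral-space analysis of the fission yeast (*Schizosaccharomyces pombe*)
cell-cycle Boolean network.

Gene regulatory networks can often be rewired — edges added, removed or
re-weighted — without losing their biological function. The set of all
parameterizations that preserve a given function is the network's *neutral
space*, and its structure measures topological robustness: a function carried
by one large connected neighborhood of the wildtype is robust to mutation; a
function scattered over isolated genotypes is fragile. `cycleneutral`
implements this analysis for the 10-node threshold Boolean network of the
fission yeast cell cycle, for systems biologists studying regulatory-network
robustness and for anyone constructing Boolean networks with predefined
trajectories.

## The model

Each node *i* (a gene/protein: Start, SK, Cdc2/Cdc13, Ste9, Rum1, Slp1,
Cdc2/Cdc13\*, Wee1/Mik1, Cdc25, PP) is binary. Dynamics follow the threshold
rule

```
            1        if  Σ_j w_ij x_j(t) > θ_i
x_i(t+1) =  0        if  Σ_j w_ij x_j(t) < θ_i
            x_i(t)   if  Σ_j w_ij x_j(t) = θ_i     (hold on tie)
```

with integer weights `w_ij ∈ {−2,…,2}` (negative diagonal entries model
self-degradation) and thresholds `θ_i ∈ {−2, −1, −½, 0, ½, 1, 2}`. Five
updating schemes are supported: parallel, sequential, block-sequential,
deterministic-asynchronous and fully asynchronous. A *functional* network is
one whose parallel dynamics reproduces the ten-state cell-cycle sequence from
the START signal down to the stationary G1 fixed point.

On top of the dynamics engine the package provides:

* exact state-transition graphs over all 2^10 states, attractors (fixed
  points and limit cycles), basins of attraction, and seeded Monte-Carlo
  basin estimation for the fully asynchronous scheme;
* a mutation-only evolution strategy (rank, keep the top *m*% elites, mutate
  elites, refill with random candidates seeded from the wildtype) that
  minimizes the mean per-bit deviation from the target sequence and harvests
  distinct functional networks;
* the neutral graph: nodes are functional genotypes `(W, Θ)`, edges join
  genotypes at Hamming distance 1; component structure relative to the
  wildtype, shortest-path and raw-distance profiles, edge-count histograms,
  per-edge frequency tables and basin-of-attraction comparisons by updating
  scheme, exported as GraphML/TSV.

## Worked example

```r
library(cycleneutral)

wt <- wildtype_network()
wt
#> Threshold Boolean network: 10 nodes, 27 edges ( 8 + / 19 - )
#> Nodes: Start, SK, Cdc2/Cdc13, Ste9, Rum1, Slp1, Cdc2/Cdc13*, Wee1/Mik1, Cdc25, PP

# the wildtype replays the cell cycle from the START state
traj <- simulate_network(wt, cell_cycle_sequence()$states[1, ], 9)
data.frame(t = 1:10, state = apply(traj, 1, paste, collapse = ""),
           phase = cell_cycle_sequence()$phases)
#>     t      state phase
#> 1   1 1001100100 START
#> 2   2 0101100100    G1
#> ...
#> 10 10 0001100100    G1

# exact attractor/basin analysis of all 1024 states, parallel scheme
att <- find_attractors(build_transition_graph(wt, update_scheme("parallel")))
basin_size(att, state_index(g1_fixed_point()))
#> [1] 762
```

The trajectory visits the ten cell-cycle states in order and stops in the
stationary G1 state `0001100100`; that fixed point attracts 762 of the 1024
possible initial conditions — the dynamics funnel essentially the whole state
space into G1. Harvesting functional networks and building the neutral graph:

```r
coll <- harvest_functional(60, es_config(), seed = 42)
ng <- build_neutral_graph(coll)
ng
#> Neutral graph: 60 functional networks, 23 edges, 39 connected components
#> Wildtype component size: 22

comp <- ng$genotypes[wildtype_component(ng)]
positive_activator_fraction(comp, which(wt$labels == "Slp1"))
#> [1] 1
```

Most functional networks are isolated in genotype space, but the wildtype
sits in a sizeable connected neighborhood, and every network in that
neighborhood keeps a positive activator of Slp1 — the edge required to exit
metaphase and complete the cycle.

`run_pipeline(count, seed, out_dir)` chains harvest → neutral graph →
reports with a JSON manifest, and `inst/cli/cycleneutral.R` exposes the same
steps as shell subcommands (`simulate`, `stg`, `basins`, `evolve`, `graph`,
`analyze`, `pipeline`).

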
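---
title: "Methods: neutral-space analysis of the fission yeast cell-cycle network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neutral-space analysis of the fission yeast cell-cycle network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleneutral)
```

# The model and its assumptions

The fission yeast cell cycle is modeled as a threshold Boolean network on ten
nodes (Start, SK, Cdc2/Cdc13, Ste9, Rum1, Slp1, Cdc2/Cdc13\*, Wee1/Mik1,
Cdc25, PP). Node $i$ updates by comparing its weighted input sum
$S_i = \sum_j w_{ij} x_j$ against a threshold $\theta_i$: above the threshold
the node switches on, below it switches off, and on an exact tie it *holds*
its current value. The hold-on-tie variant matters: several transitions of
the cell-cycle sequence (e.g. Ste9 and Rum1 staying on in G1, Wee1/Mik1
persisting through early phases) are carried by ties, and a strict-inequality
rule that resolves ties to 0 or 1 does not replay the sequence. The packaged
wildtype parameterization is shipped as a data fixture
(`extdata/wildtype.json`) rather than hard-coded; its transcription is
enforced by three independent checks rather than trust: the parallel
trajectory from the START state must reproduce all ten cell-cycle states
bit-for-bit, the weight matrix must contain exactly 27 nonzero entries (8
positive, 19 negative), and the G1 fixed point's parallel basin must hold
exactly 762 of the 1024 states. All three hold (see `test-wildtype.R` and
`test-acceptance.R`).

Genotypes are constrained to small value sets — weights in
$\{-2,\dots,2\}$, thresholds in $\{-2,-1,-\tfrac12,0,\tfrac12,1,2\}$ — which
bound the search space of the evolution strategy. Thresholds may be
half-integers, so all comparisons are performed in doubled units
($2S_i$ vs $2\theta_i$, both integers): exact integer arithmetic, no
floating-point tolerance anywhere in the dynamics.

# Updating schemes

Five schemes are implemented: parallel (all nodes at once), sequential (a
full sweep in a fixed order, later nodes seeing earlier updates),
block-sequential (ordered blocks, parallel within a block),
deterministic-asynchronous (one node per step, cycling through a fixed
order) and fully asynchronous (one uniformly random node per step). For the
deterministic schemes one *macro-step* — one edge of the state-transition
graph — is a complete sweep over all nodes or blocks, so each scheme yields a
single transition graph over the $2^{10}$ states; `async_deterministic`
composes its $n$ single-node updates into the equivalent sequential sweep.
The alternative (per-node micro-steps as graph edges) would make transition
graphs incomparable across schemes; the full-sweep convention keeps one
graph per scheme, matching how the basin comparisons are set up.

Fixed points are invariant to the choice of scheme (no single-node update can
leave them), and the test suite asserts this across all four deterministic
schemes on the wildtype and on random 4-node networks. Limit cycles and
basin sizes, by contrast, do change with the scheme, which is exactly what
the basin-by-scheme comparison measures.

# Attractors and basins

`find_attractors()` decomposes the successor map (a functional graph) by
path-following with cycle detection, $O(2^n)$ overall, and assigns every
state to the basin of the attractor its forward orbit reaches. Basin
membership is *inclusive*: an attractor's own states belong to its basin, so
basin sizes partition $2^n$. The convention was fixed empirically — the
inclusive count reproduces the known wildtype value of 762 for the G1 fixed
point under parallel update. An independent naive oracle (forward-iterate
every state $2^n$ steps, label by the smallest state index on the reached
cycle) cross-checks the decomposition on random networks with $n \le 4$.

Under fully asynchronous updating basins are probabilistic.
`estimate_async_basin()` estimates, for each of the $2^n$ initial states, the
probability of absorption into a target fixed point as the fraction of
`runs` independent trajectories that reach it; the expected basin mass is the
sum of these probabilities. Trajectories stop on hitting *any* fixed point or
after `max_steps` single-node updates (default $100n = 1000$): absorption in
this 10-node model is fast, and the default leaves the truncation error far
below the Monte-Carlo noise at the run counts used. All walkers are advanced
in a vectorized batch per run, and the estimate is bit-reproducible for a
fixed seed.

# The evolution strategy

Functional networks — genotypes $(W, \Theta)$ whose parallel dynamics
reproduce the ten-state sequence — are found by a mutation-only evolution
strategy with the parameters `popSize = 20`, elite fraction `m = 20%` and
`maxIters = 100` as defaults:

1. **Initial candidates**: perturb the wildtype `ngh` times, `ngh` uniform on
   $[1, 30]$; each perturbation applies Rule 1 once to $W$ (a uniformly
   chosen entry is zeroed if nonzero, else set to a uniform draw from
   $\{-2,-1,1,2\}$ — it always changes) and Rule 2 once to $\Theta$ (a
   uniformly chosen entry is replaced by a uniform draw from the full
   seven-value set, possibly unchanged).
2. **Fitness**: the mean absolute deviation between the network's parallel
   one-step image of each of the ten target states and the expected image —
   row $t+1$ for $t = 1..9$, and row 10 itself for $t = 10$, which enforces
   the G1 fixed-point condition. With ten targets of ten bits the fitness is
   a multiple of $1/100$; it is zero exactly when the genotype is functional.
   A ten-row trajectory has only nine transitions, so the tenth target is a
   modeling choice; the G1 self-transition is the one that makes "functional"
   imply "G1 is fixed", and only the zero-set of the fitness matters for
   harvesting, so any monotone variant of the deviation (absolute vs squared,
   any positive normalization) yields the same collection.
3. **Generations**: rank ascending by fitness (stable sort, so ties break by
   insertion order — reproducibility), carry the top 4 elites unchanged, add
   8 mutants (each a uniformly drawn elite, with replacement, mutated by one
   Rule 1 plus one Rule 2 application) and 8 fresh initial candidates; stop
   when a candidate hits fitness 0 or after `maxIters` generations.

Each ES run contributes at most one functional network (the first fitness-0
candidate in rank order), and runs are restarted with fresh seeds until the
requested number of *distinct* genotypes — exact duplicates of $(W, \Theta)$
are discarded — has been collected. One-per-run avoids over-representing a
single run's neighborhood in the harvested sample; the alternative
(harvesting every functional network a run encounters) would bias the
neutral graph toward locally clustered genotypes. The wildtype itself is
functional by definition and enters the collection as its first member. Each
run's RNG stream derives from the root seed by a fixed affine counter
(`child_seed(root, run)`), so a harvest is reproducible from
(`count`, config, seed) alone and independent of global RNG state.

# The neutral graph

Nodes are the distinct functional genotypes; an undirected edge joins two
nodes iff their Hamming distance — the number of differing entries — is
exactly 1. The default distance concatenates $W$ and $\Theta$ (110
positions), since the mutation operator touches both and distinct genotypes
should never sit at distance 0; `mode = "matrix_only"` restricts the count
to the weight matrix for the stricter adjacency reading. Construction is
all-pairs, $O(N^2 n^2)$, which is entirely adequate at the collection sizes
used here ($N \le 10^4$ at $n = 10$); no spatial index is attempted.
Components, shortest paths (BFS) and GraphML export are delegated to igraph.
Because each edge changes exactly one entry, the shortest-path length from
any component member to the wildtype is bounded below by the raw genotype
distance — a property-tested invariant.

# Downstream analyses

* **Edge histograms**: unit-width integer bins over $[0, n^2]$ for the
  total/positive/negative nonzero-entry counts, crossed with three groups
  (all, wildtype component, rest) — reproducible tables rather than rendered
  figures.
* **Edge frequencies**: per-position presence/positive/negative fractions in
  a group. "The positive edge activating node X" is operationalized as *any*
  positive inbound entry in row X of $W$; in the wildtype each of the rows in
  question (Slp1, Ste9, Rum1, Wee1/Mik1) has a single positive source, and
  the frequency table reports sources individually.
* **Basins by group**: the G1 basin measure of every functional network under
  a named scheme (exact basin size for deterministic schemes, Monte-Carlo
  expected mass for fully asynchronous), split into wildtype-component vs
  rest, with medians, IQRs and fixed-bin histograms (20 equal bins over
  $[0, 1024]$). A two-sample Kolmogorov–Smirnov statistic is attached as an
  optional, clearly labeled implementation choice; the primary output is the
  raw per-genotype table. Functional networks always have G1 among their
  fixed points (the tenth fitness target forces it), so the basin measure is
  at least 1; a genotype without G1 fixed would be recorded with basin 0 and
  flagged, but cannot arise from the harvest.

The default sequential order for the basin comparison is the canonical node
order, and the default block partition is (Start, SK, Cdc2/Cdc13)(Ste9,
Rum1, Slp1, Cdc2/Cdc13\*)(Wee1/Mik1, Cdc25, PP).

# Problem sizes, and what the harvest does and does not show

The packaged analyses and tests run on harvests of 200 distinct functional
networks (the acceptance script) and 4–60 (unit tests); at these sizes the
full pipeline takes seconds to a few minutes on one CPU. The structural
findings are stable across seeds at this scale: the wildtype component is
the dominant connected component and its members keep the positive
activators of Slp1, Ste9, Wee1/Mik1 and Rum1 without exception; component
members reach the wildtype in a small number of neutral steps; functional
networks outside the component sit at genotype distance typically greater
than 3 from the wildtype; and component members' parallel G1 basins
concentrate around the wildtype's 762 while outsiders spread more widely.

Quantities that are *not* stable at scaled size — the exact fraction of
harvested networks landing in the wildtype component, or the percentage of
component members carrying any particular surplus edge (e.g. a positive
Ste9-to-Cdc25 edge) — are single-run stochastic outcomes of the harvesting
policy and are reported as whatever the local harvest yields, never asserted
against fixed values.

The harvest explores the neutral space reachable by the ES's mutation kernel
seeded from the wildtype; it is a biased sample of the full neutral space
(genotypes far from the wildtype are under-represented by construction), and
nothing in it validates the biological fidelity of the Boolean abstraction
itself — only the internal structure of the model's neutral space.

# Known limitations

* Exact transition graphs enumerate $2^n$ states and are capped at
  $n \le 20$; the attractor decomposition is a plain R loop, adequate at
  $n = 10$ but not tuned for the upper end of that range.
* The neutral-graph build materializes the full $N \times N$ distance
  matrix; beyond $N \approx 10^4$ a neighbor index would be needed.
* The fully asynchronous basin estimator truncates at `max_steps`; for
  networks with long transients the mass estimate is a lower bound.
* No visualization is provided; exports are GraphML and TSV for external
  tools.
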
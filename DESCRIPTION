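Package: cycleneutral
Title: Neutral-Space Analysis of the Fission Yeast Cell-Cycle Boolean Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for threshold Boolean network dynamics (parallel,
    sequential, block-sequential, deterministic-asynchronous and fully
    asynchronous updating schemes; exact state-transition graphs, attractors
    and basins of attraction; Monte-Carlo basin estimation), a mutation-only
    evolution strategy that harvests "functional" networks reproducing the
    ten-state fission yeast (Schizosaccharomyces pombe) cell-cycle sequence,
    and construction and analysis of the neutral graph of functional networks
    (edges at genotype Hamming distance one), including component structure
    relative to the wildtype, edge-count histograms, edge-frequency tables
    and basin-of-attraction comparisons by updating scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
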
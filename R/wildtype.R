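# Packaged fission-yeast cell-cycle model: wildtype parameters, the ten-state
# target sequence, and the stationary G1 state.

#' The fission yeast cell-cycle wildtype network
#'
#' Returns the 10-node threshold Boolean network of the
#' *Schizosaccharomyces pombe* cell cycle: nodes Start, SK, Cdc2/Cdc13, Ste9,
#' Rum1, Slp1, Cdc2/Cdc13*, Wee1/Mik1, Cdc25 and PP, with 27 regulatory edges
#' (8 activating, 19 inhibiting, self-degradation loops included). Parameters
#' are shipped as a versioned JSON fixture (`extdata/wildtype.json`) rather
#' than hard-coded; their correctness is enforced by the packaged cell-cycle
#' sequence (the wildtype reproduces all ten states under parallel update and
#' its G1 basin holds 762 of the 1024 states).
#'
#' @return A [threshold_network()].
#' @examples
#' wt <- wildtype_network()
#' edge_counts(wt$W)
#' @export
wildtype_network <- function() {
  load_network(system.file("extdata", "wildtype.json", package = "cycleneutral",
                           mustWork = TRUE))
}

#' The ten-state cell-cycle target sequence
#'
#' The temporal evolution of the cell cycle: ten consecutive state vectors
#' from the START signal through G1/S, G2 and M back to the stationary G1
#' phase. Functional networks are exactly those whose parallel dynamics
#' reproduce this sequence (and hold the final G1 state fixed).
#'
#' @return List with `states` (10 x 10 integer matrix, one row per time step,
#'   columns in node order) and `phases` (character vector of phase labels).
#' @export
cell_cycle_sequence <- function() {
  path <- system.file("extdata", "cell_cycle_sequence.tsv",
                      package = "cycleneutral", mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE)
  node_cols <- setdiff(names(tab), c("time", "phase"))
  states <- as.matrix(tab[, node_cols])
  storage.mode(states) <- "integer"
  rownames(states) <- NULL
  list(states = states, phases = as.character(tab$phase))
}

#' The stationary G1 fixed point
#'
#' The final row of the cell-cycle sequence: the resting G1 state the
#' dynamics converges to, a fixed point under every updating scheme.
#'
#' @return Integer binary vector of length 10 (named by node).
#' @export
g1_fixed_point <- function() {
  seqs <- cell_cycle_sequence()
  g1 <- seqs$states[10L, ]
  wt <- wildtype_network()
  stopifnot(identical(as.integer(scheme_step(wt, g1, update_scheme("parallel"))),
                      as.integer(g1)))
  g1
}
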
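# Threshold Boolean network core: genotype container, state encoding,
# local update rule and the five updating schemes.

#' Allowed weight values
#'
#' Weight matrix entries are constrained to small integers; thresholds to
#' integers and half-integers. These value sets bound the genotype search
#' space of the evolution strategy.
#'
#' @return Integer (weights) or numeric (thresholds) vector of allowed values.
#' @export
weight_values <- function() c(-2L, -1L, 0L, 1L, 2L)

#' @rdname weight_values
#' @export
threshold_values <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2)

# Thresholds in doubled units so S vs theta comparisons are exact integer
# comparisons (theta may be a half-integer).
theta_doubled <- function(theta) as.integer(round(2 * theta))

#' Construct a threshold Boolean network
#'
#' A threshold Boolean network on `n` nodes is specified by an `n x n`
#' integer weight matrix `W` (entry `W[i, j]` is the weight of the edge from
#' node `j` into node `i`; negative diagonal entries model self-degradation)
#' and a length-`n` threshold vector `theta`. Node `i` switches on when its
#' weighted input sum exceeds `theta[i]`, off when the sum falls below it,
#' and holds its current value on an exact tie.
#'
#' @param W Integer matrix, entries in `weight_values()`.
#' @param theta Numeric vector, entries in `threshold_values()`.
#' @param labels Character vector of unique node names; defaults to
#'   `rownames(W)` or `V1..Vn`.
#' @return An object of class `threshold_network` with fields `n`, `labels`,
#'   `W` (integer matrix) and `theta`.
#' @examples
#' net <- threshold_network(matrix(1L), 0.5, "A")
#' local_update(net, 1L, 1)
#' @export
threshold_network <- function(W, theta, labels = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square, got ", nrow(W), "x", ncol(W))
  n <- nrow(W)
  if (is.null(labels)) labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  if (length(labels) != n) stop("labels: expected ", n, " names, got ", length(labels))
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (length(theta) != n) stop("theta: expected length ", n, ", got ", length(theta))
  if (!all(W %in% weight_values()))
    stop("W: entries must lie in {", paste(weight_values(), collapse = ","), "}")
  storage.mode(W) <- "integer"
  if (!all(theta %in% threshold_values()))
    stop("theta: entries must lie in {", paste(threshold_values(), collapse = ","), "}")
  dimnames(W) <- list(labels, labels)
  structure(list(n = n, labels = labels, W = W, theta = as.numeric(theta)),
            class = "threshold_network")
}

#' @export
print.threshold_network <- function(x, ...) {
  ec <- edge_counts(x$W)
  cat("Threshold Boolean network:", x$n, "nodes,",
      ec[["total"]], "edges (", ec[["positive"]], "+ /", ec[["negative"]], "- )\n")
  cat("Nodes:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Encode and decode network states
#'
#' A state is a binary vector over the nodes; its integer index packs the
#' bits with node 1 as the most significant bit, so index runs over
#' `0 .. 2^n - 1`. The encoding is a file-readability convention only; no
#' result depends on it.
#'
#' @param bits Binary vector (0/1) of length `n`.
#' @param index Integer state index in `[0, 2^n - 1]`.
#' @param n Number of nodes.
#' @return `state_index` returns the integer index; `index_state` the bit
#'   vector.
#' @examples
#' state_index(c(1, 0, 0, 1))      # 9
#' index_state(9, 4)               # c(1, 0, 0, 1)
#' @export
state_index <- function(bits) {
  if (!all(bits %in% c(0L, 1L))) stop("state bits must be 0/1")
  n <- length(bits)
  sum(as.numeric(bits) * 2^((n - 1):0))
}

#' @rdname state_index
#' @export
index_state <- function(index, n) {
  if (index < 0 || index > 2^n - 1) stop("state index out of range [0, 2^n-1]")
  as.integer(bitwAnd(bitwShiftR(as.integer(index), (n - 1):0), 1L))
}

# All 2^n states as an n x 2^n integer matrix; column k holds index k-1.
all_states <- function(n) {
  m <- as.integer(2^n)
  idx <- 0:(m - 1)
  X <- matrix(0L, n, m)
  for (i in seq_len(n)) X[i, ] <- bitwAnd(bitwShiftR(idx, n - i), 1L)
  X
}

# Column-wise state indices of an n x k bit matrix.
states_index <- function(X) {
  n <- nrow(X)
  as.vector(crossprod(2^((n - 1):0), X))
}

#' Single-node threshold update
#'
#' Computes the next value of node `i`: with `S = sum_j W[i, j] * state[j]`,
#' returns 1 if `S > theta[i]`, 0 if `S < theta[i]`, and `state[i]` on an
#' exact tie (hold-on-tie rule). Comparisons are done in doubled-integer
#' units so half-integer thresholds are compared exactly.
#'
#' @param net A `threshold_network`.
#' @param state Binary state vector of length `net$n`.
#' @param i Node index in `1..n`.
#' @return The updated bit for node `i`.
#' @export
local_update <- function(net, state, i) {
  if (length(state) != net$n) stop("state length ", length(state), " != n = ", net$n)
  if (i < 1 || i > net$n) stop("node index out of range")
  s2 <- 2L * sum(net$W[i, ] * as.integer(state))
  t2 <- theta_doubled(net$theta)[i]
  if (s2 > t2) 1L else if (s2 < t2) 0L else as.integer(state[i])
}

#' Updating schemes
#'
#' Constructs an updating-scheme descriptor for [scheme_step()],
#' [simulate_network()] and [build_transition_graph()]:
#' \describe{
#'   \item{parallel}{all nodes updated simultaneously (synchronous).}
#'   \item{sequential}{one full sweep in `order`, each node seeing values
#'     already updated earlier in the sweep.}
#'   \item{block_sequential}{blocks updated in order; nodes within a block
#'     simultaneously, from the values current at block entry.}
#'   \item{async_deterministic}{exactly one node per step, cycling through
#'     `order`.}
#'   \item{fully_async}{exactly one uniformly random node per step
#'     (non-deterministic; uses the R RNG).}
#' }
#'
#' @param mode One of the five scheme names.
#' @param order Node permutation of `1..n` (sequential, async_deterministic).
#' @param blocks List of integer vectors forming an ordered partition of
#'   `1..n` (block_sequential).
#' @param n Node count used to default `order`/`blocks` to `1..n`.
#' @return An `update_scheme` object.
#' @export
update_scheme <- function(mode = c("parallel", "sequential", "block_sequential",
                                   "async_deterministic", "fully_async"),
                          order = NULL, blocks = NULL, n = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("sequential", "async_deterministic")) {
    if (is.null(order)) {
      if (is.null(n)) stop("mode '", mode, "' requires `order` (or `n` to default it)")
      order <- seq_len(n)
    }
    if (!setequal(order, seq_along(order))) stop("`order` must be a permutation of 1..n")
    order <- as.integer(order)
  }
  if (mode == "block_sequential") {
    if (is.null(blocks)) {
      if (is.null(n)) stop("mode 'block_sequential' requires `blocks` (or `n`)")
      blocks <- list(seq_len(n))
    }
    flat <- unlist(blocks)
    if (anyDuplicated(flat) || !setequal(flat, seq_along(flat)) ||
        any(lengths(blocks) == 0))
      stop("`blocks` must be an ordered partition of 1..n into nonempty blocks")
    blocks <- lapply(blocks, as.integer)
  }
  structure(list(mode = mode, order = order, blocks = blocks),
            class = "update_scheme")
}

is_deterministic_scheme <- function(scheme) scheme$mode != "fully_async"

# Sweep decomposition: every deterministic scheme is a block-sequential sweep.
scheme_blocks <- function(scheme, n) {
  switch(scheme$mode,
    parallel = list(seq_len(n)),
    sequential = as.list(scheme$order),
    block_sequential = scheme$blocks,
    async_deterministic = as.list(scheme$order),
    stop("no sweep decomposition for scheme '", scheme$mode, "'"))
}

#' Advance a state by one scheme step
#'
#' One step means: a simultaneous update of all nodes (parallel), a full
#' ordered sweep (sequential, block_sequential), or a single-node update
#' (async_deterministic — the node at position `t` in the cycle through
#' `order`; fully_async — a uniformly random node, drawn from the R RNG, so
#' set a seed for reproducibility).
#'
#' @param net A `threshold_network`.
#' @param state Binary state vector.
#' @param scheme An [update_scheme()].
#' @param t Step counter (1-based), used only by `async_deterministic` to
#'   pick the next node in `order`.
#' @return The next binary state vector.
#' @export
scheme_step <- function(net, state, scheme, t = 1L) {
  n <- net$n
  if (length(state) != n) stop("state length ", length(state), " != n = ", n)
  state <- as.integer(state)
  t2 <- theta_doubled(net$theta)
  upd_block <- function(x, block) {
    s2 <- 2L * as.vector(net$W[block, , drop = FALSE] %*% x)
    tb <- t2[block]
    x[block] <- ifelse(s2 > tb, 1L, ifelse(s2 < tb, 0L, x[block]))
    x
  }
  switch(scheme$mode,
    parallel = upd_block(state, seq_len(n)),
    sequential = {
      for (i in scheme$order) state <- upd_block(state, i)
      state
    },
    block_sequential = {
      for (b in scheme$blocks) state <- upd_block(state, b)
      state
    },
    async_deterministic = {
      i <- scheme$order[((t - 1L) %% n) + 1L]
      upd_block(state, i)
    },
    fully_async = upd_block(state, sample.int(n, 1L)))
}

#' Simulate a trajectory
#'
#' Iterates [scheme_step()] from `init`, returning the whole trajectory
#' (`steps + 1` states, the initial state included).
#'
#' @inheritParams scheme_step
#' @param init Initial binary state vector.
#' @param steps Number of steps (`>= 0`).
#' @return Integer matrix with `steps + 1` rows (states) and `n` columns,
#'   column names = node labels.
#' @examples
#' wt <- wildtype_network()
#' traj <- simulate_network(wt, cell_cycle_sequence()$states[1, ], 9,
#'                          update_scheme("parallel"))
#' @export
simulate_network <- function(net, init, steps, scheme = update_scheme("parallel")) {
  if (steps < 0) stop("steps must be >= 0")
  traj <- matrix(0L, steps + 1L, net$n, dimnames = list(NULL, net$labels))
  traj[1L, ] <- as.integer(init)
  s <- as.integer(init)
  for (k in seq_len(steps)) {
    s <- scheme_step(net, s, scheme, t = k)
    traj[k + 1L, ] <- s
  }
  traj
}
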
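# Exact state-space analysis: transition graphs, attractors, basins,
# and Monte-Carlo basin estimation for the fully asynchronous scheme.

#' Build the exact state-transition graph
#'
#' Enumerates all `2^n` states and computes each state's unique successor
#' under a deterministic updating scheme. For sequential and block-sequential
#' schemes one edge corresponds to one complete sweep over all nodes/blocks
#' (macro-step convention); `async_deterministic` composes its `n` single-node
#' updates into the equivalent full sweep.
#'
#' @param net A [threshold_network()].
#' @param scheme A deterministic [update_scheme()].
#' @return A `transition_graph`: list with `n`, `successor` (integer vector of
#'   length `2^n`; entry `k` is the 0-based successor index of 0-based state
#'   `k - 1`) and `scheme`.
#' @export
build_transition_graph <- function(net, scheme = update_scheme("parallel")) {
  if (!is_deterministic_scheme(scheme))
    stop("transition graphs require a deterministic scheme; got 'fully_async'")
  n <- net$n
  if (n > 20) stop("state space 2^n too large to enumerate (n = ", n, ")")
  X <- all_states(n)
  t2 <- theta_doubled(net$theta)
  for (b in scheme_blocks(scheme, n)) {
    S2 <- 2L * (net$W[b, , drop = FALSE] %*% X)
    up <- S2 > t2[b]
    hold <- S2 == t2[b]
    X[b, ] <- up + hold * X[b, , drop = FALSE]
  }
  structure(list(n = n, successor = as.integer(states_index(X)), scheme = scheme),
            class = "transition_graph")
}

#' Find attractors and basins of attraction
#'
#' Decomposes the functional graph of a [build_transition_graph()] result into
#' its attractors — fixed points (period 1) and limit cycles (period `p > 1`)
#' — and assigns every state to the basin of the attractor its forward orbit
#' reaches. Attractor states belong to their own basin, so basin sizes sum to
#' `2^n`.
#'
#' @param tg A `transition_graph`.
#' @return An `attractor_set`: list with `fixed_points` (0-based state
#'   indices), `limit_cycles` (list of 0-based index vectors in cycle order),
#'   `attractors` (per-attractor descriptors: `type`, `states`, `period`),
#'   `attractor_of` (integer vector over all states, 1-based attractor id)
#'   and `basins` (list of 0-based state-index vectors per attractor).
#' @export
find_attractors <- function(tg) {
  succ <- tg$successor + 1L                   # 1-based functional graph
  m <- length(succ)
  comp <- integer(m)                          # attractor id per state, 0 = unknown
  attractors <- list()
  for (start in seq_len(m)) {
    if (comp[start] != 0L) next
    path <- integer(0)
    pos <- new.env(parent = emptyenv())       # state -> position on current path
    v <- start
    repeat {
      if (comp[v] != 0L) { aid <- comp[v]; break }
      key <- as.character(v)
      p <- pos[[key]]
      if (!is.null(p)) {                      # new cycle found on current path
        cyc <- path[p:length(path)]
        attractors[[length(attractors) + 1L]] <- cyc
        aid <- length(attractors)
        break
      }
      path <- c(path, v)
      pos[[key]] <- length(path)
      v <- succ[v]
    }
    comp[path] <- aid
  }
  types <- vapply(attractors, function(cyc)
    if (length(cyc) == 1L) "fixed_point" else "limit_cycle", "")
  basins <- split(seq_len(m) - 1L, factor(comp, levels = seq_along(attractors)))
  structure(list(
    fixed_points = sort(unlist(lapply(attractors[types == "fixed_point"],
                                      function(cyc) cyc - 1L))),
    limit_cycles = lapply(attractors[types == "limit_cycle"], function(cyc) cyc - 1L),
    attractors = lapply(seq_along(attractors), function(a) list(
      type = types[a], states = attractors[[a]] - 1L,
      period = length(attractors[[a]]))),
    attractor_of = comp,
    basins = basins), class = "attractor_set")
}

#' Basin size of the attractor containing a state
#'
#' @param attractors An [find_attractors()] result.
#' @param target 0-based state index; must belong to some attractor (be a
#'   fixed point or on a limit cycle).
#' @return Number of states in that attractor's basin (attractor states
#'   included).
#' @export
basin_size <- function(attractors, target) {
  aid <- attractors$attractor_of[target + 1L]
  on_att <- target %in% attractors$attractors[[aid]]$states
  if (!on_att) stop("state ", target, " is not an attractor state")
  length(attractors$basins[[aid]])
}

#' Monte-Carlo basin estimation under fully asynchronous updating
#'
#' Under the fully asynchronous scheme one uniformly random node updates per
#' step, so basins are probabilistic. For every initial state this estimates
#' the probability of absorption into the `target` fixed point as the fraction
#' of `runs` independent trajectories that hit it; a trajectory stops when it
#' reaches any fixed point (fixed points are invariant across updating
#' schemes) or after `max_steps` single-node updates.
#'
#' @param net A [threshold_network()].
#' @param target 0-based state index of a fixed point of `net`.
#' @param runs Trajectories per initial state (`>= 1`).
#' @param max_steps Single-node update budget per trajectory; default `100 * n`.
#' @param seed RNG seed for reproducibility.
#' @return List with `prob` (length `2^n` absorption probabilities, multiples
#'   of `1/runs`), `basin_mass` (their sum: the expected basin size in
#'   states), `runs` and `max_steps`.
#' @export
estimate_async_basin <- function(net, target, runs, max_steps = 100L * net$n,
                                 seed = NULL) {
  n <- net$n
  m <- as.integer(2^n)
  fp <- find_attractors(build_transition_graph(net, update_scheme("parallel")))$fixed_points
  if (!target %in% fp) stop("target state ", target, " is not a fixed point")
  if (runs < 1) stop("runs must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  t2 <- theta_doubled(net$theta)
  is_fp <- logical(m); is_fp[fp + 1L] <- TRUE
  hits <- numeric(m)
  for (r in seq_len(runs)) {
    X <- all_states(n)                       # one walker per initial state
    active <- which(!is_fp)                  # fixed-point starts are absorbed at step 0
    for (step in seq_len(max_steps)) {
      if (length(active) == 0L) break
      i <- sample.int(n, length(active), replace = TRUE)
      Xa <- X[, active, drop = FALSE]
      s2 <- 2L * rowSums(net$W[i, , drop = FALSE] * t(Xa))
      old <- Xa[cbind(i, seq_along(active))]
      newbit <- ifelse(s2 > t2[i], 1L, ifelse(s2 < t2[i], 0L, old))
      X[cbind(i, active)] <- newbit
      changed <- newbit != old
      if (any(changed)) {
        idx <- states_index(X[, active[changed], drop = FALSE])
        absorbed <- is_fp[idx + 1L]
        still <- rep(TRUE, length(active))
        still[which(changed)[absorbed]] <- FALSE
        active <- active[still]
      }
    }
    hits <- hits + (states_index(X) == target)
  }
  prob <- hits / runs
  prob[target + 1L] <- 1                     # absorbing start
  list(prob = prob, basin_mass = sum(prob), runs = runs, max_steps = max_steps)
}
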
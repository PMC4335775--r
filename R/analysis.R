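# Downstream analyses over harvested collections: topology histograms,
# per-edge frequencies, and G1 basin-of-attraction comparisons between the
# wildtype component and the rest of the neutral graph.

#' Edge counts of a weight matrix
#'
#' @param W Integer weight matrix (or a genotype / `threshold_network`, in
#'   which case its `W` is used).
#' @return Named numeric vector `total`, `positive`, `negative` counting
#'   nonzero, positive and negative entries (diagonal included).
#' @examples
#' edge_counts(wildtype_network())   # 27 edges: 8 positive, 19 negative
#' @export
edge_counts <- function(W) {
  if (is.list(W)) W <- W$W
  c(total = sum(W != 0), positive = sum(W > 0), negative = sum(W < 0))
}

#' Per-position edge frequencies in a group of genotypes
#'
#' For every weight-matrix position `(i, j)`: the fraction of group members
#' in which that edge is present (nonzero), positive, or negative.
#'
#' @param group Nonempty list of genotypes.
#' @return List of three `n x n` matrices (`presence`, `positive`,
#'   `negative`) with values in `[0, 1]`.
#' @export
edge_frequencies <- function(group) {
  if (length(group) == 0) stop("empty genotype group")
  n2 <- length(group[[1]]$W)
  acc <- function(f) Reduce(`+`, lapply(group, function(g) f(g$W))) / length(group)
  pres <- acc(function(W) (W != 0) * 1)
  pos <- acc(function(W) (W > 0) * 1)
  neg <- acc(function(W) (W < 0) * 1)
  dimnames(pres) <- dimnames(pos) <- dimnames(neg) <- dimnames(group[[1]]$W)
  list(presence = pres, positive = pos, negative = neg)
}

#' Fraction of genotypes with a positive activator of a node
#'
#' "The positive edge that activates node `i`" is operationalized as any
#' positive inbound entry in row `i` of the weight matrix.
#'
#' @param group Nonempty list of genotypes.
#' @param node Node index (row of `W`).
#' @return Fraction in `[0, 1]`.
#' @export
positive_activator_fraction <- function(group, node) {
  if (length(group) == 0) stop("empty genotype group")
  mean(vapply(group, function(g) any(g$W[node, ] > 0), NA))
}

# G1 basin measure of one genotype under one scheme. Deterministic schemes:
# exact basin size from the transition graph (0 if G1 is not a fixed point,
# which cannot happen for functional genotypes). fully_async: expected basin
# mass from Monte-Carlo absorption probabilities.
g1_basin_measure <- function(genotype, scheme, g1_index, labels,
                             async_runs = 10L, max_steps = NULL, seed = NULL) {
  net <- threshold_network(genotype$W, genotype$theta, labels)
  if (scheme$mode == "fully_async") {
    ms <- if (is.null(max_steps)) 100L * net$n else max_steps
    est <- estimate_async_basin(net, g1_index, runs = async_runs,
                                max_steps = ms, seed = seed)
    return(est$basin_mass)
  }
  att <- find_attractors(build_transition_graph(net, scheme))
  aid <- att$attractor_of[g1_index + 1L]
  if (!g1_index %in% att$attractors[[aid]]$states) return(0)
  length(att$basins[[aid]])
}

#' G1 basin distributions by neutral-graph component membership
#'
#' Computes the basin-of-attraction measure of the G1 fixed point for every
#' functional network in a neutral graph, under a chosen updating scheme, and
#' compares the wildtype-component group against the rest: per-group medians
#' and IQRs, fixed-bin histograms, and (optionally) a two-sample
#' Kolmogorov-Smirnov statistic. The KS test is a descriptive implementation
#' choice; the primary output is the raw per-genotype table.
#'
#' @param ng A [build_neutral_graph()] result.
#' @param scheme An [update_scheme()]; for `fully_async` the basin measure is
#'   the Monte-Carlo expected basin mass (seeded, reproducible).
#' @param async_runs Trajectories per initial state for `fully_async`.
#' @param max_steps Per-trajectory update budget for `fully_async`
#'   (default `100 * n`).
#' @param seed RNG seed for the `fully_async` estimates.
#' @param ks Run the two-sample KS test when both groups are nonempty.
#' @param bins Number of equal histogram bins over `[0, 2^n]` (default 20).
#' @return List with `samples` (data.frame `node`, `group`, `basin`),
#'   `summary` (per-group median / IQR / n), `histogram` (per-group counts on
#'   the fixed bin edges) and `ks` (an `htest` or `NULL`).
#' @export
basin_by_group <- function(ng, scheme = update_scheme("parallel"),
                           async_runs = 10L, max_steps = NULL, seed = NULL,
                           ks = TRUE, bins = 20L) {
  labels <- rownames(ng$genotypes[[ng$wildtype_id]]$W)
  g1_index <- state_index(g1_fixed_point())
  n <- length(g1_fixed_point())
  in_comp <- seq_along(ng$genotypes) %in% wildtype_component(ng)
  if (scheme$mode == "fully_async" && !is.null(seed)) set.seed(seed)
  basin <- vapply(seq_along(ng$genotypes), function(k)
    g1_basin_measure(ng$genotypes[[k]], scheme, g1_index, labels,
                     async_runs = async_runs, max_steps = max_steps), 0)
  samples <- data.frame(node = seq_along(ng$genotypes),
                        group = ifelse(in_comp, "component", "rest"),
                        basin = basin)
  edges <- seq(0, 2^n, length.out = bins + 1L)
  by_group <- split(samples$basin, samples$group)
  summary <- lapply(by_group, function(v)
    c(n = length(v), median = stats::median(v),
      q1 = unname(stats::quantile(v, 0.25)), q3 = unname(stats::quantile(v, 0.75))))
  histogram <- lapply(by_group, function(v)
    graphics::hist(v, breaks = edges, plot = FALSE)$counts)
  ks_res <- NULL
  if (ks && length(by_group) == 2 && all(lengths(by_group) > 0))
    ks_res <- suppressWarnings(stats::ks.test(by_group[[1]], by_group[[2]]))
  list(samples = samples, summary = summary,
       histogram = list(breaks = edges, counts = histogram), ks = ks_res)
}

#' Edge-count histogram report
#'
#' Nine fixed-bin histograms of genotype topology: the three count statistics
#' (total / positive / negative nonzero weight entries) crossed with three
#' groups (all networks, wildtype component, rest). Bins are unit-width
#' integer bins over `[0, n^2]`.
#'
#' @param ng A [build_neutral_graph()] result.
#' @return Long data.frame with columns `group`, `statistic`, `count_value`,
#'   `frequency`; per panel the frequencies sum to the group size.
#' @export
histogram_report <- function(ng) {
  ec <- t(vapply(ng$genotypes, function(g) edge_counts(g$W), numeric(3)))
  in_comp <- seq_along(ng$genotypes) %in% wildtype_component(ng)
  n2 <- length(ng$genotypes[[1]]$W)
  groups <- list(all = rep(TRUE, nrow(ec)), component = in_comp, rest = !in_comp)
  out <- list()
  for (gname in names(groups)) {
    sel <- groups[[gname]]
    for (stat in colnames(ec)) {
      tabv <- tabulate(ec[sel, stat] + 1L, nbins = n2 + 1L)
      out[[length(out) + 1L]] <- data.frame(
        group = gname, statistic = stat, count_value = 0:n2, frequency = tabv)
    }
  }
  do.call(rbind, out)
}
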
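# Neutral graph: the metagraph over functional genotypes, with edges joining
# genotypes at Hamming distance 1, and its component structure relative to
# the wildtype.

#' Hamming distance between genotypes
#'
#' Number of positions at which two genotypes differ. By default the genotype
#' is the concatenation of the weight matrix and the threshold vector
#' (`mode = "concatenated"`), so distinct genotypes never sit at distance 0;
#' `mode = "matrix_only"` counts weight-matrix differences alone.
#'
#' @param g1,g2 Genotypes (lists with `W`, `theta`) of equal dimensions.
#' @param mode `"concatenated"` (default) or `"matrix_only"`.
#' @return Non-negative integer; a metric on genotype space.
#' @export
genotype_distance <- function(g1, g2, mode = c("concatenated", "matrix_only")) {
  mode <- match.arg(mode)
  if (!identical(dim(g1$W), dim(g2$W)) || length(g1$theta) != length(g2$theta))
    stop("genotype dimensions differ")
  d <- sum(g1$W != g2$W)
  if (mode == "concatenated")
    d <- d + sum(theta_doubled(g1$theta) != theta_doubled(g2$theta))
  as.integer(d)
}

# Flatten a collection into a genotype matrix (rows = genotypes) for fast
# all-pairs Hamming distance.
genotype_matrix <- function(collection, mode) {
  rows <- lapply(collection, function(g) {
    v <- as.vector(g$W)
    if (mode == "concatenated") v <- c(v, theta_doubled(g$theta))
    v
  })
  do.call(rbind, rows)
}

pairwise_hamming <- function(G) {
  N <- nrow(G)
  D <- matrix(0L, N, N)
  for (k in seq_len(ncol(G))) {
    D <- D + outer(G[, k], G[, k], "!=")
  }
  D
}

#' Build the neutral graph of a functional-network collection
#'
#' Nodes are distinct functional genotypes; an undirected edge joins two
#' nodes iff their [genotype_distance()] is exactly 1. The wildtype is
#' inserted if absent. Construction is all-pairs, `O(N^2)` in the collection
#' size.
#'
#' @param collection List of genotypes (deduplicated; duplicates are an
#'   error).
#' @param wildtype The wildtype genotype (default: the packaged network).
#' @param mode Distance convention, see [genotype_distance()].
#' @return A `neutral_graph`: list with `genotypes`, `graph` (igraph),
#'   `wildtype_id` (node index), `membership` (component id per node),
#'   `distance` (the full pairwise distance matrix) and `mode`.
#' @export
build_neutral_graph <- function(collection, wildtype = NULL,
                                mode = c("concatenated", "matrix_only")) {
  mode <- match.arg(mode)
  if (is.null(wildtype)) {
    wt <- wildtype_network()
    wildtype <- list(W = wt$W, theta = wt$theta)
  }
  keys <- vapply(collection, genotype_key, "")
  if (anyDuplicated(keys)) stop("collection contains duplicate genotypes")
  wt_id <- match(genotype_key(wildtype), keys)
  if (is.na(wt_id)) {
    collection <- c(list(wildtype), collection)
    wt_id <- 1L
  }
  G <- genotype_matrix(collection, mode)
  D <- pairwise_hamming(G)
  adj <- (D == 1L) * 1L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  igraph::V(g)$name <- paste0("g", seq_len(nrow(G)))
  igraph::V(g)$is_wildtype <- seq_len(nrow(G)) == wt_id
  comp <- igraph::components(g)
  structure(list(genotypes = collection, graph = g, wildtype_id = wt_id,
                 membership = comp$membership, distance = D, mode = mode),
            class = "neutral_graph")
}

#' @export
print.neutral_graph <- function(x, ...) {
  ncomp <- length(unique(x$membership))
  cat("Neutral graph:", length(x$genotypes), "functional networks,",
      igraph::ecount(x$graph), "edges,", ncomp, "connected components\n")
  cat("Wildtype component size:", length(wildtype_component(x)), "\n")
  invisible(x)
}

#' Nodes of the wildtype connected component
#'
#' @param ng A [build_neutral_graph()] result.
#' @return Integer node indices of the component containing the wildtype.
#' @export
wildtype_component <- function(ng) {
  unname(which(ng$membership == ng$membership[ng$wildtype_id]))
}

#' Distances of every functional network to the wildtype
#'
#' For nodes in the wildtype component: exact shortest-path length (BFS) to
#' the wildtype through the neutral graph (each edge changes exactly one
#' genotype entry, so the path length is always at least the raw genotype
#' distance). For nodes outside the component the path length is `Inf`; the
#' raw genotype Hamming distance to the wildtype is reported alongside for
#' every node.
#'
#' @param ng A [build_neutral_graph()] result.
#' @return List with `profile` (data.frame: `node`, `in_component`,
#'   `path_length`, `genotype_distance`) and `summary` (per-group median, min,
#'   max of the genotype distance to the wildtype, plus the cross-component
#'   pairwise-distance summary in `between_components`).
#' @export
distance_profile <- function(ng) {
  N <- length(ng$genotypes)
  in_comp <- seq_len(N) %in% wildtype_component(ng)
  sp <- as.vector(igraph::distances(ng$graph, v = ng$wildtype_id))
  gd <- ng$distance[ng$wildtype_id, ]
  profile <- data.frame(node = seq_len(N), in_component = in_comp,
                        path_length = sp, genotype_distance = gd)
  grp_sum <- function(v) if (length(v) == 0) c(median = NA_real_, min = NA_real_, max = NA_real_)
                         else c(median = stats::median(v), min = min(v), max = max(v))
  out_ids <- which(!in_comp)
  between <- if (length(out_ids) >= 2) {
    sub <- ng$distance[out_ids, out_ids]
    grp_sum(sub[upper.tri(sub)])
  } else grp_sum(numeric(0))
  list(profile = profile,
       summary = list(in_component = grp_sum(gd[in_comp]),
                      out_of_component = grp_sum(gd[!in_comp]),
                      between_components = between))
}

#' Export a neutral graph to GraphML (and an edge-list TSV)
#'
#' Node attributes: genotype id, `is_wildtype`, fitness, and total / positive
#' / negative edge counts of the genotype's weight matrix.
#'
#' @param ng A [build_neutral_graph()] result.
#' @param path Output GraphML file path.
#' @param edge_tsv Optional path for a plain TSV edge list.
#' @param target Target sequence used to annotate fitness.
#' @return `path`, invisibly.
#' @export
write_neutral_graphml <- function(ng, path, edge_tsv = NULL,
                                  target = cell_cycle_sequence()) {
  g <- ng$graph
  ec <- t(vapply(ng$genotypes, function(gt) edge_counts(gt$W), numeric(3)))
  igraph::V(g)$fitness <- vapply(ng$genotypes, network_fitness, 0, target = target)
  igraph::V(g)$edges_total <- ec[, "total"]
  igraph::V(g)$edges_positive <- ec[, "positive"]
  igraph::V(g)$edges_negative <- ec[, "negative"]
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(edge_tsv)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    utils::write.table(data.frame(from = el[, 1], to = el[, 2]), edge_tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
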
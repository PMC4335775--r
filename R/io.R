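# Serialization and pipeline plumbing: network JSON, collection JSONL,
# transition-graph TSV, report TSVs and the evolve -> graph -> analyze
# pipeline with a reproducibility manifest.

#' Read and write network JSON
#'
#' Network files are JSON objects with fields `labels` (array of strings),
#' `W` (array of `n` arrays of `n` integers, row `i` = inbound weights of
#' node `i`) and `theta` (array of `n` numbers; half-integers allowed).
#' `load_network` enforces the value-set and dimension invariants with
#' field-specific error messages; `save_network` followed by `load_network`
#' is the identity.
#'
#' @param path File path.
#' @param net A [threshold_network()].
#' @return `load_network` returns a `threshold_network`; `save_network`
#'   returns `path` invisibly.
#' @export
load_network <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("labels", "W", "theta"))
    if (is.null(obj[[field]])) stop("network JSON missing field '", field, "'")
  W <- obj$W
  if (!is.matrix(W)) stop("W: expected an n x n matrix of integers")
  if (any(W != round(W))) stop("W: entries must be integers")
  threshold_network(W, obj$theta, obj$labels)
}

#' @rdname load_network
#' @export
save_network <- function(net, path) {
  obj <- list(labels = net$labels,
              W = unname(net$W),
              theta = net$theta)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read and write functional-network collections (JSONL)
#'
#' One network per line: a JSON object with `labels`, `W`, `theta` and
#' optional metadata (`run`, `generation`). The line-oriented format streams,
#' so large harvests never need to be held in memory by downstream tools.
#'
#' @param collection List of genotypes as returned by [harvest_functional()].
#' @param path File path.
#' @param labels Node labels written with each record.
#' @return `load_collection` returns a list of genotypes; `save_collection`
#'   returns `path` invisibly.
#' @export
save_collection <- function(collection, path, labels = NULL) {
  if (is.null(labels)) labels <- rownames(collection[[1]]$W)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in collection) {
    rec <- list(labels = labels, W = unname(g$W), theta = g$theta)
    for (meta in c("run", "generation"))
      if (!is.null(g[[meta]])) rec[[meta]] <- g[[meta]]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                matrix = "rowmajor"), con)
  }
  invisible(path)
}

#' @rdname save_collection
#' @export
load_collection <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    net <- threshold_network(obj$W, obj$theta, obj$labels)  # validates
    g <- list(W = net$W, theta = net$theta)
    for (meta in c("run", "generation"))
      if (!is.null(obj[[meta]])) g[[meta]] <- obj[[meta]]
    g
  })
}

#' Export a transition graph with attractor annotation (TSV)
#'
#' @param tg A [build_transition_graph()] result.
#' @param path Output TSV path.
#' @param attractors Optional [find_attractors()] result (computed if `NULL`).
#' @return The exported data.frame (columns `state_index`, `state_bits`,
#'   `successor_index`, `attractor_id`, `attractor_type`), invisibly.
#' @export
export_transition_graph <- function(tg, path, attractors = NULL) {
  if (is.null(attractors)) attractors <- find_attractors(tg)
  n <- tg$n
  m <- length(tg$successor)
  bits <- apply(all_states(n), 2, paste, collapse = "")
  aid <- attractors$attractor_of
  types <- vapply(attractors$attractors, `[[`, "", "type")
  df <- data.frame(state_index = 0:(m - 1L), state_bits = bits,
                   successor_index = tg$successor,
                   attractor_id = aid, attractor_type = types[aid])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full harvest -> neutral graph -> analysis pipeline
#'
#' Chains [harvest_functional()], [build_neutral_graph()] and the analysis
#' reports, writing all artifacts plus a JSON manifest (seed, configuration,
#' counts) into `out_dir`. Re-running with the same seed reproduces the
#' outputs byte-for-byte.
#'
#' Artifacts: `networks.jsonl`, `neutral_graph.graphml`, `edges.tsv`,
#' `edge_hist.tsv`, `edge_freq.tsv`, `distances.tsv`,
#' `basin_by_group_<scheme>.tsv` and `manifest.json`.
#'
#' @param count Number of distinct functional networks to harvest.
#' @param seed Root RNG seed.
#' @param out_dir Output directory (created if missing).
#' @param config An [es_config()].
#' @param schemes Character vector of scheme names for the basin comparison
#'   (`"parallel"`, `"sequential"`, `"block_sequential"`, `"fully_async"`).
#'   Sequential order and blocks default to [default_sequential_order()] and
#'   [default_blocks()].
#' @param async_runs Monte-Carlo trajectories per initial state for the
#'   `fully_async` scheme.
#' @param verbose Print harvest progress.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(count, seed, out_dir, config = es_config(),
                         schemes = "parallel", async_runs = 5L,
                         verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- wildtype_network()
  target <- cell_cycle_sequence()
  collection <- harvest_functional(count, config, target,
                                   base = list(W = wt$W, theta = wt$theta),
                                   seed = seed, verbose = verbose)
  save_collection(collection, file.path(out_dir, "networks.jsonl"))
  ng <- build_neutral_graph(collection)
  write_neutral_graphml(ng, file.path(out_dir, "neutral_graph.graphml"),
                        edge_tsv = file.path(out_dir, "edges.tsv"),
                        target = target)
  write_tsv(histogram_report(ng), file.path(out_dir, "edge_hist.tsv"))
  freq <- edge_frequencies(ng$genotypes[wildtype_component(ng)])
  freq_df <- data.frame(
    target_node = rep(wt$labels, times = wt$n),
    source_node = rep(wt$labels, each = wt$n),
    presence = as.vector(freq$presence),
    positive = as.vector(freq$positive),
    negative = as.vector(freq$negative))
  write_tsv(freq_df, file.path(out_dir, "edge_freq.tsv"))
  dp <- distance_profile(ng)
  write_tsv(dp$profile, file.path(out_dir, "distances.tsv"))
  basin_files <- character(0)
  for (sc in schemes) {
    scheme <- named_scheme(sc, wt$n)
    bg <- basin_by_group(ng, scheme, async_runs = async_runs, seed = seed)
    f <- file.path(out_dir, paste0("basin_by_group_", sc, ".tsv"))
    write_tsv(bg$samples, f)
    basin_files <- c(basin_files, basename(f))
  }
  manifest <- list(seed = seed, count = count,
                   pop_size = config$pop_size, m_percent = config$m_percent,
                   max_iters = config$max_iters,
                   ngh_range = config$ngh_range,
                   runs_used = attr(collection, "runs"),
                   n_networks = length(collection),
                   n_edges = igraph::ecount(ng$graph),
                   wildtype_component_size = length(wildtype_component(ng)),
                   schemes = schemes,
                   artifacts = c("networks.jsonl", "neutral_graph.graphml",
                                 "edges.tsv", "edge_hist.tsv", "edge_freq.tsv",
                                 "distances.tsv", basin_files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Default node orderings for the non-parallel schemes
#'
#' The sequential order is the canonical node order (Start, SK, Cdc2/Cdc13,
#' Ste9, Rum1, Slp1, Cdc2/Cdc13*, Wee1/Mik1, Cdc25, PP); the block partition
#' is (Start, SK, Cdc2/Cdc13)(Ste9, Rum1, Slp1, Cdc2/Cdc13*)(Wee1/Mik1,
#' Cdc25, PP).
#'
#' @param n Node count.
#' @return An integer order / a list of integer blocks.
#' @export
default_sequential_order <- function(n = 10L) seq_len(n)

#' @rdname default_sequential_order
#' @export
default_blocks <- function(n = 10L) {
  if (n != 10L) return(list(seq_len(n)))
  list(1:3, 4:7, 8:10)
}

# Scheme from a CLI-style name.
named_scheme <- function(name, n) {
  switch(name,
    parallel = update_scheme("parallel"),
    sequential = update_scheme("sequential", order = default_sequential_order(n)),
    block_sequential = update_scheme("block_sequential", blocks = default_blocks(n)),
    async_deterministic = update_scheme("async_deterministic",
                                        order = default_sequential_order(n)),
    fully_async = update_scheme("fully_async"),
    stop("unknown scheme name '", name, "'"))
}
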
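# Mutation-only evolution strategy that searches genotype space (weight
# matrix + threshold vector) for functional networks: networks whose parallel
# dynamics reproduce the ten-state cell-cycle sequence (fitness 0).

#' Evolution strategy configuration
#'
#' @param pop_size Population size (default 20).
#' @param m_percent Elite fraction carried unchanged each generation
#'   (default 0.2, i.e. top 20\%). `round(pop_size * m_percent)` must give at
#'   least one elite and leave an even remainder, split equally between
#'   mutants of elites and fresh random candidates.
#' @param max_iters Generation cap per run (default 100).
#' @param ngh_range Inclusive integer range for the perturbation count `ngh`
#'   used when seeding random candidates from the wildtype (default `c(1, 30)`;
#'   `c(0, 0)` yields exact copies of the base, useful for testing).
#' @return An `es_config` list.
#' @export
es_config <- function(pop_size = 20L, m_percent = 0.2, max_iters = 100L,
                      ngh_range = c(1L, 30L)) {
  elites <- round(pop_size * m_percent)
  if (elites < 1) stop("pop_size * m_percent must round to at least 1 elite")
  if ((pop_size - elites) %% 2 != 0)
    stop("pop_size - elites must be even (equal mutant/random split), got ",
         pop_size - elites)
  if (length(ngh_range) != 2 || ngh_range[1] > ngh_range[2] || ngh_range[1] < 0)
    stop("ngh_range must be c(lo, hi) with 0 <= lo <= hi")
  structure(list(pop_size = as.integer(pop_size), m_percent = m_percent,
                 elites = as.integer(elites), max_iters = as.integer(max_iters),
                 ngh_range = as.integer(ngh_range)),
            class = "es_config")
}

#' Genotype mutation rules
#'
#' `rule1` perturbs the weight matrix: a uniformly chosen entry is zeroed if
#' nonzero, otherwise set to a uniform draw from \{-2, -1, 1, 2\} — the chosen
#' entry always changes, so one application moves the matrix exactly Hamming
#' distance 1. `rule2` perturbs the threshold vector: a uniformly chosen
#' entry is replaced by a uniform draw from the full seven-value threshold
#' set (which may equal the old value). Both consume the R RNG.
#'
#' @param W Integer weight matrix.
#' @param theta Numeric threshold vector.
#' @return The perturbed matrix / vector.
#' @export
rule1 <- function(W) {
  k <- sample.int(length(W), 1L)
  W[k] <- if (W[k] != 0L) 0L else sample(c(-2L, -1L, 1L, 2L), 1L)
  W
}

#' @rdname rule1
#' @export
rule2 <- function(theta) {
  i <- sample.int(length(theta), 1L)
  theta[i] <- sample(threshold_values(), 1L)
  theta
}

#' Random candidate genotype seeded from a base network
#'
#' Draws `ngh` uniformly from `config$ngh_range`, then applies [rule1()] to
#' the base weight matrix `ngh` times and [rule2()] to the base threshold
#' vector `ngh` times.
#'
#' @param base Genotype: list with `W` and `theta` (e.g. the wildtype).
#' @param config An [es_config()].
#' @return A genotype (list with `W`, `theta`).
#' @export
initial_candidate <- function(base, config = es_config()) {
  lo <- config$ngh_range[1]; hi <- config$ngh_range[2]
  ngh <- if (lo == hi) lo else sample(lo:hi, 1L)
  W <- base$W; theta <- base$theta
  for (k in seq_len(ngh)) {
    W <- rule1(W)
    theta <- rule2(theta)
  }
  list(W = W, theta = theta)
}

# Internal: parallel one-step images of all 10 target rows at once.
# states: 10 x n matrix of target rows.
sequence_outputs <- function(W, theta, states) {
  X <- t(states)                             # n x 10, inputs
  S2 <- 2L * (W %*% X)
  t2 <- theta_doubled(theta)
  (S2 > t2) + (S2 == t2) * X                 # n x 10, outputs
}

#' Fitness of a genotype against the cell-cycle sequence
#'
#' Mean absolute deviation between the network's outputs and the target
#' outputs over all 10 time steps and all `n` nodes: each of the 10 printed
#' states is fed through one parallel update; the expected image of row `t`
#' is row `t + 1` for `t = 1..9` and row 10 itself for `t = 10` (the G1
#' fixed-point condition). Zero fitness therefore means the genotype is
#' functional: it reproduces the whole sequence and holds G1 fixed.
#'
#' @param genotype List with `W` and `theta`.
#' @param target List as returned by [cell_cycle_sequence()] (fields `states`,
#'   10 x n), or a bare 10 x n state matrix.
#' @return Fitness in `[0, 1]` (a multiple of `1 / (10 n)`).
#' @export
network_fitness <- function(genotype, target = cell_cycle_sequence()) {
  states <- if (is.list(target)) target$states else target
  if (ncol(states) != ncol(genotype$W))
    stop("genotype has ", ncol(genotype$W), " nodes but target has ",
         ncol(states), " columns")
  O <- sequence_outputs(genotype$W, genotype$theta, states)
  Tg <- t(states[c(2:nrow(states), nrow(states)), , drop = FALSE])
  sum(abs(O - Tg)) / length(Tg)
}

new_candidate <- function(genotype, target) {
  list(genotype = genotype, fitness = network_fitness(genotype, target))
}

#' One generation of the evolution strategy
#'
#' Ranks the population ascending by fitness (stable ties), carries the top
#' `m%` elites unchanged, adds `(pop_size - elites) / 2` mutants (each a
#' uniformly chosen elite with [rule1()] applied once to `W` and [rule2()]
#' once to `theta`) and the same number of fresh [initial_candidate()] draws,
#' evaluates the newcomers, and returns the new population of `pop_size`
#' candidates (elites first, in rank order).
#'
#' @param pop List of candidates (`genotype`, `fitness`), length `pop_size`.
#' @param config An [es_config()].
#' @param base Base genotype used to seed random candidates.
#' @param target Target sequence for fitness evaluation.
#' @return List of `pop_size` candidates.
#' @export
evolve_generation <- function(pop, config, base, target = cell_cycle_sequence()) {
  if (length(pop) != config$pop_size)
    stop("population size ", length(pop), " != configured ", config$pop_size)
  ord <- order(vapply(pop, `[[`, 0, "fitness"))   # stable in R
  pop <- pop[ord]
  elites <- pop[seq_len(config$elites)]
  half <- (config$pop_size - config$elites) %/% 2L
  mutants <- lapply(seq_len(half), function(k) {
    e <- elites[[sample.int(config$elites, 1L)]]$genotype
    new_candidate(list(W = rule1(e$W), theta = rule2(e$theta)), target)
  })
  randoms <- lapply(seq_len(half), function(k)
    new_candidate(initial_candidate(base, config), target))
  c(elites, mutants, randoms)
}

#' Run the evolution strategy once
#'
#' Seeds a random population from `base`, then evolves until some candidate
#' reaches fitness 0 (a functional network) or `max_iters` generations pass.
#'
#' @inheritParams evolve_generation
#' @param init_pop Optional list of genotypes injected into generation 0
#'   (topped up with random candidates to `pop_size`).
#' @return On success, list with `genotype`, `fitness` (0) and `generation`
#'   (0 for a hit in the initial population); `NULL` if the cap is reached.
#' @export
run_es <- function(config = es_config(), target = cell_cycle_sequence(),
                   base = NULL, init_pop = NULL) {
  if (is.null(base)) {
    wt <- wildtype_network()
    base <- list(W = wt$W, theta = wt$theta)
  }
  seeded <- lapply(init_pop, new_candidate, target = target)
  fill <- config$pop_size - length(seeded)
  if (fill < 0) stop("init_pop larger than pop_size")
  pop <- c(seeded, lapply(seq_len(fill), function(k)
    new_candidate(initial_candidate(base, config), target)))
  best_of <- function(pop) {
    f <- vapply(pop, `[[`, 0, "fitness")
    if (any(f == 0)) pop[[which(f == 0)[1L]]] else NULL
  }
  hit <- best_of(pop)
  if (!is.null(hit)) return(list(genotype = hit$genotype, fitness = 0, generation = 0L))
  for (gen in seq_len(config$max_iters)) {
    pop <- evolve_generation(pop, config, base, target)
    hit <- best_of(pop)
    if (!is.null(hit)) return(list(genotype = hit$genotype, fitness = 0, generation = gen))
  }
  NULL
}

genotype_key <- function(g) {
  paste(c(as.vector(g$W), theta_doubled(g$theta)), collapse = ",")
}

# Child seed for ES run `run` derived from the root seed by a fixed affine
# counter scheme (kept below 2^31 - 1 so set.seed() accepts it).
child_seed <- function(root_seed, run) {
  as.integer((as.numeric(root_seed) + 104729 * run) %% 2147483647)
}

#' Harvest a collection of distinct functional networks
#'
#' Repeatedly runs the evolution strategy — one functional network per
#' successful run, each run on its own RNG stream derived from `seed` by a
#' fixed counter scheme — deduplicating exact `(W, theta)` genotypes until
#' `count` distinct functional networks are collected. The wildtype (the
#' `base` genotype) is functional by definition and is included as the first
#' member of the collection.
#'
#' @inheritParams run_es
#' @param count Number of distinct functional networks to collect (`>= 1`).
#' @param seed Root RNG seed; the harvest is reproducible given
#'   (`count`, `config`, `seed`).
#' @param verbose Print one progress line per ES run.
#' @return List of genotypes (each with `W`, `theta`, and metadata fields
#'   `run` and `generation`; the wildtype has `run = 0`). Attribute `runs`
#'   records the total number of ES runs used.
#' @export
harvest_functional <- function(count, config = es_config(),
                               target = cell_cycle_sequence(), base = NULL,
                               seed = 1L, verbose = FALSE) {
  if (count < 1) stop("count must be >= 1")
  if (is.null(base)) {
    wt <- wildtype_network()
    base <- list(W = wt$W, theta = wt$theta)
  }
  seen <- new.env(parent = emptyenv())
  collection <- list()
  add <- function(g, run, gen) {
    key <- genotype_key(g)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      g$run <- run; g$generation <- gen
      collection[[length(collection) + 1L]] <<- g
      TRUE
    } else FALSE
  }
  add(base, 0L, 0L)                           # wildtype member
  run <- 0L
  while (length(collection) < count) {
    run <- run + 1L
    set.seed(child_seed(seed, run))
    res <- run_es(config, target, base)
    if (!is.null(res)) {
      fresh <- add(res$genotype, run, res$generation)
      if (verbose)
        message(sprintf("run %d: functional at generation %d%s (%d/%d)",
                        run, res$generation, if (fresh) "" else " [duplicate]",
                        length(collection), count))
    } else if (verbose) {
      message(sprintf("run %d: no functional network within %d generations",
                      run, config$max_iters))
    }
  }
  attr(collection, "runs") <- run
  collection
}
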
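test_that("rule1 always changes exactly one weight entry within the value set", {
  set.seed(1)
  g <- wildtype_genotype()
  for (k in 1:200) {
    W2 <- rule1(g$W)
    expect_equal(sum(W2 != g$W), 1)
    expect_true(all(W2 %in% weight_values()))
    changed <- which(W2 != g$W)
    if (g$W[changed] != 0) expect_equal(W2[changed], 0L)
    else expect_true(W2[changed] %in% c(-2L, -1L, 1L, 2L))
  }
})

test_that("rule2 replaces one threshold uniformly over the seven-value set", {
  set.seed(2)
  theta <- rep(0, 10)
  draws <- numeric(7000)
  for (k in seq_along(draws)) {
    t2 <- rule2(theta)
    expect_lte(sum(t2 != theta), 1)
    i <- which(t2 != theta)
    draws[k] <- if (length(i)) t2[i] else theta[1]
  }
  # replacement values drawn uniformly from the 7-value set (chi-square);
  # draws where the new value equals the old 0 land in the 0 cell, as expected
  # under uniformity
  counts <- table(factor(draws, levels = threshold_values()))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("initial candidates respect the perturbation count and value sets", {
  set.seed(3)
  base <- wildtype_genotype()
  expect_identical(initial_candidate(base, es_config(ngh_range = c(0, 0))), base)
  for (k in 1:20) {
    g1 <- initial_candidate(base, es_config(ngh_range = c(1, 1)))
    expect_equal(sum(g1$W != base$W), 1)     # rule1 always changes
    g <- initial_candidate(base, es_config())
    expect_true(all(g$W %in% weight_values()))
    expect_true(all(g$theta %in% threshold_values()))
  }
})

test_that("fitness matches the naive per-bit oracle and its closed-form anchors", {
  target <- cell_cycle_sequence()
  base <- wildtype_genotype()
  expect_equal(network_fitness(base, target), 0)
  set.seed(4)
  for (k in 1:30) {
    g <- random_genotype(10)
    expect_equal(network_fitness(g, target), naive_fitness(g, target$states))
  }
  # a single flipped output bit costs exactly 1/100
  flip <- base
  flip$W["SK", "Start"] <- 0L   # SK no longer switched on by Start at t=1
  expect_equal(network_fitness(flip, target), naive_fitness(flip, target$states))
  expect_equal(network_fitness(flip, target), 1 / 100)
  expect_error(network_fitness(random_genotype(4), target), "nodes")
})

test_that("a generation is elites + mutants + randoms with elitist monotonicity", {
  set.seed(5)
  cfg <- es_config()
  expect_equal(cfg$elites, 4)
  expect_equal((cfg$pop_size - cfg$elites) / 2, 8)
  target <- cell_cycle_sequence()
  base <- wildtype_genotype()
  pop <- lapply(1:20, function(k)
    cycleneutral:::new_candidate(initial_candidate(base, cfg), target))
  best <- min(vapply(pop, `[[`, 0, "fitness"))
  for (gen in 1:10) {
    pop <- evolve_generation(pop, cfg, base, target)
    expect_length(pop, 20)
    nb <- min(vapply(pop, `[[`, 0, "fitness"))
    expect_lte(nb, best)
    best <- nb
    for (cand in pop) {
      expect_true(all(cand$genotype$W %in% weight_values()))
      expect_true(all(cand$genotype$theta %in% threshold_values()))
    }
  }
  expect_error(evolve_generation(pop[1:3], cfg, base, target), "population size")
  expect_error(es_config(pop_size = 21), "even")
  expect_error(es_config(pop_size = 20, m_percent = 0.01), "at least 1 elite")
})

test_that("run_es returns a fitness-0 genotype (or none at iteration cap 0)", {
  set.seed(6)
  base <- wildtype_genotype()
  target <- cell_cycle_sequence()
  hit <- run_es(es_config(), target, base, init_pop = list(base))
  expect_equal(hit$generation, 0L)
  expect_equal(network_fitness(hit$genotype, target), 0)
  # returned genotypes always reproduce the full sequence under parallel update
  res <- run_es(es_config(max_iters = 50), target, base)
  if (!is.null(res)) {
    net <- threshold_network(res$genotype$W, res$genotype$theta)
    traj <- simulate_network(net, target$states[1, ], 9)
    expect_identical(unname(traj), unname(target$states))
  }
  # with no iterations and a hopeless start, none is a legal outcome
  far <- random_genotype(10)
  out <- run_es(es_config(max_iters = 0, ngh_range = c(30, 30)), target,
                base = far)
  expect_true(is.null(out) || out$fitness == 0)
})

test_that("harvests are distinct, functional, and reproducible under a seed", {
  cfg <- es_config()
  h1 <- harvest_functional(6, cfg, seed = 99)
  h2 <- harvest_functional(6, cfg, seed = 99)
  keys1 <- vapply(h1, cycleneutral:::genotype_key, "")
  keys2 <- vapply(h2, cycleneutral:::genotype_key, "")
  expect_identical(keys1, keys2)
  expect_equal(anyDuplicated(keys1), 0)
  expect_identical(keys1[1], cycleneutral:::genotype_key(wildtype_genotype()))
  for (g in h1) expect_equal(network_fitness(g), 0)
  h3 <- harvest_functional(6, cfg, seed = 100)
  expect_false(identical(keys1, vapply(h3, cycleneutral:::genotype_key, "")))
})
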
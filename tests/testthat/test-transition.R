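test_that("transition graph of tiny hand-enumerated networks is exact", {
  # 1-node positive self-loop: both states are fixed points.
  net1 <- threshold_network(matrix(1L), 0.5)
  tg1 <- build_transition_graph(net1)
  expect_equal(tg1$successor, c(0L, 1L))
  # 2-node mutual activation: 00 and 11 fixed, 01 <-> 10 a 2-cycle.
  net2 <- threshold_network(matrix(c(0L, 1L, 1L, 0L), 2, 2), c(0.5, 0.5))
  tg2 <- build_transition_graph(net2)
  expect_equal(tg2$successor, c(0L, 2L, 1L, 3L))
  att <- find_attractors(tg2)
  expect_setequal(att$fixed_points, c(0L, 3L))
  expect_length(att$limit_cycles, 1)
  expect_setequal(att$limit_cycles[[1]], c(1L, 2L))
  expect_equal(att$attractors[[att$attractor_of[2]]]$period, 2)
})

test_that("every deterministic scheme yields a total successor map", {
  wt <- wildtype_network()
  for (mode in c("parallel", "sequential", "block_sequential", "async_deterministic")) {
    sc <- update_scheme(mode, order = 1:10, blocks = default_blocks(10))
    tg <- build_transition_graph(wt, sc)
    expect_length(tg$successor, 1024)
    expect_true(all(tg$successor >= 0 & tg$successor <= 1023))
  }
})

test_that("attractors and basins agree with the naive forward-iteration oracle", {
  set.seed(101)
  for (k in 1:20) {
    n <- sample(2:4, 1)
    net <- random_network(n)
    tg <- build_transition_graph(net)
    att <- find_attractors(tg)
    oracle <- naive_attractor_labels(tg$successor)
    # same partition of states into basins
    expect_equal(length(unique(oracle)), length(att$attractors))
    expect_true(all(tapply(oracle, att$attractor_of, function(v) length(unique(v))) == 1))
    # fixed points agree
    expect_setequal(att$fixed_points, which(tg$successor == 0:(2^n - 1)) - 1L)
    # basins partition the state space
    expect_equal(sum(lengths(att$basins)), 2^n)
    expect_equal(sort(unname(unlist(att$basins))), 0:(2^n - 1))
    # limit cycles really cycle with period > 1
    for (cyc in att$limit_cycles) {
      expect_gt(length(cyc), 1)
      expect_equal(tg$successor[cyc + 1L], c(cyc[-1], cyc[1]))
    }
  }
})

test_that("fixed points are invariant across deterministic updating schemes", {
  check_invariance <- function(net) {
    fps <- lapply(c("parallel", "sequential", "block_sequential", "async_deterministic"),
                  function(mode) {
      blocks <- if (net$n == 4) list(1:2, 3:4) else default_blocks(net$n)
      sc <- update_scheme(mode, order = rev(seq_len(net$n)), blocks = blocks)
      find_attractors(build_transition_graph(net, sc))$fixed_points
    })
    for (fp in fps[-1]) expect_equal(fp, fps[[1]])
  }
  check_invariance(wildtype_network())
  set.seed(202)
  for (k in 1:100) check_invariance(random_network(4))
})

test_that("basin size is inclusive of attractor states and errors off-attractor", {
  wt <- wildtype_network()
  att <- find_attractors(build_transition_graph(wt))
  g1 <- state_index(g1_fixed_point())
  expect_equal(basin_size(att, g1), 762)
  expect_equal(sum(lengths(att$basins)), 1024)
  # a transient state (START) is not an attractor state
  expect_error(basin_size(att, state_index(cell_cycle_sequence()$states[1, ])),
               "not an attractor state")
  # contraction map: all states map to 0, single basin of 2^n
  zero <- threshold_network(matrix(0L, 3, 3), rep(1, 3))
  att0 <- find_attractors(build_transition_graph(zero))
  expect_equal(basin_size(att0, 0), 8)
})

test_that("async basin estimation is exact on hand-enumerable cases and seeded", {
  # 1-node self-inhibition with zero threshold: state 1 -> 0 deterministically
  # (sum -1 < 0), state 0 holds (sum 0 ties the threshold).
  net <- threshold_network(matrix(-1L), 0)
  est <- estimate_async_basin(net, target = 0, runs = 4, seed = 11)
  expect_equal(est$prob, c(1, 1))
  expect_equal(est$basin_mass, 2)
  # probabilities are multiples of 1/runs in [0, 1]; target start has prob 1
  wt <- wildtype_network()
  g1 <- state_index(g1_fixed_point())
  e1 <- estimate_async_basin(wt, g1, runs = 3, max_steps = 200, seed = 5)
  expect_true(all(e1$prob >= 0 & e1$prob <= 1))
  expect_true(all(abs(e1$prob * 3 - round(e1$prob * 3)) < 1e-12))
  expect_equal(e1$prob[g1 + 1], 1)
  e2 <- estimate_async_basin(wt, g1, runs = 3, max_steps = 200, seed = 5)
  expect_identical(e1$prob, e2$prob)   # seed-reproducible
  expect_error(estimate_async_basin(wt, state_index(cell_cycle_sequence()$states[1, ]), runs = 1),
               "not a fixed point")
})
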
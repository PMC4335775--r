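# Shared fixtures: random genotypes/networks within the allowed value sets,
# and naive brute-force oracles kept deliberately independent of the package
# implementations they check.

random_genotype <- function(n) {
  W <- matrix(sample(weight_values(), n * n, replace = TRUE), n, n)
  theta <- sample(threshold_values(), n, replace = TRUE)
  list(W = W, theta = theta)
}

random_network <- function(n) {
  g <- random_genotype(n)
  threshold_network(g$W, g$theta)
}

# Naive attractor oracle over a 0-based successor map: forward-iterate every
# state 2^n times to land on its attractor, then label the attractor by the
# smallest state index on the cycle.
naive_attractor_labels <- function(successor) {
  succ <- successor + 1L
  m <- length(succ)
  labels <- integer(m)
  for (s in seq_len(m)) {
    v <- s
    for (k in seq_len(m)) v <- succ[v]
    cyc <- v
    u <- succ[v]
    while (u != v) {
      cyc <- c(cyc, u)
      u <- succ[u]
    }
    labels[s] <- min(cyc) - 1L
  }
  labels
}

# Naive fitness oracle: per-node threshold rule applied with explicit loops.
naive_fitness <- function(g, states) {
  n <- ncol(states)
  steps <- nrow(states)
  total <- 0
  for (t in seq_len(steps)) {
    x <- states[t, ]
    tgt <- states[min(t + 1L, steps), ]
    for (i in seq_len(n)) {
      s <- sum(g$W[i, ] * x)
      o <- if (s > g$theta[i]) 1L else if (s < g$theta[i]) 0L else x[i]
      total <- total + abs(o - tgt[i])
    }
  }
  unname(total / (steps * n))
}

wildtype_genotype <- function() {
  wt <- wildtype_network()
  list(W = wt$W, theta = wt$theta)
}
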
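# Shared fixtures: small hypergraphs and a fast training configuration used
# throughout the suite. All fixtures are built in code.

toy_hypergraph <- function() {
  # 5 nodes, mixed sizes, every size 2..4 present
  hypergraph(5, list(c(1, 2), c(2, 3), c(4, 5), c(1, 2, 3), c(2, 3, 4),
                     c(1, 3, 4, 5)))
}

small_er <- function(seed = 1, n = 12)
  generate_er_hypergraph(n, c("2" = 0.25, "3" = 0.08, "4" = 0.02), seed = seed)

# Desk-scale optimizer settings: two 16-unit tanh layers, mini-batched
# annealed Adam (small batches escape the flat equilibria of the L1 loss).
quick_cfg <- function(epochs = 300, seed = 1, batch_size = 10, ...)
  train_config(epochs = epochs, learning_rate = 3e-3, l2_lambda = 0,
               hidden = c(16, 16), batch_size = batch_size, rng_seed = seed,
               ...)

with_seed_rnorm <- function(seed, n) { set.seed(seed); rnorm(n) }

# Minimal hand-built training set around a single hypergraph.
new_ts_for_test <- function(H, states, derivs) {
  hyperdyn:::new_training_set(states, derivs, rep(1L, nrow(states)), list(H),
                              list(dynamics = "diffusion", p = 2,
                                   scenario = "point", dt = NA_real_,
                                   seed = NA, k = topological_order(H)))
}
with_seed_runif <- function(seed, n, lo = 0, hi = 1) {
  set.seed(seed)
  runif(n, lo, hi)
}

# Independent brute-force derivative oracle: enumerate hyperedges and sum
# update-function calls per centre node, with no shared code path with rhs().
brute_rhs <- function(H, family, x) {
  out <- numeric(H$num_nodes)
  for (d in names(H$edges_by_size)) {
    f <- family_f(family, as.integer(d))
    for (e in H$edges_by_size[[d]])
      for (i in e)
        out[i] <- out[i] + f(x[i], x[setdiff(e, i)])
  }
  out
}
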
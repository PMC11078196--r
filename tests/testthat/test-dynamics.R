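test_that("rhs matches hand-computed examples", {
  H2 <- hypergraph(2, list(c(1, 2)))
  expect_equal(rhs(H2, kernel_family("diffusion", 2, 2), c(0, 1)), c(1, -1))

  # full-arity sine on a single 3-edge, x = (0, 0, pi/2)
  H3 <- hypergraph(3, list(c(1, 2, 3)))
  fam <- kernel_family("kuramoto", p = 3, k = 3)
  expect_equal(rhs(H3, fam, c(0, 0, pi / 2)), c(1, 1, sin(-pi)))

  expect_error(rhs(H3, fam, c(0, 0)), "length")
})

test_that("per-node summation equals the lift-update-project formulation", {
  for (seed in 1:3) {
    H <- small_er(seed = seed)
    x <- with_seed_rnorm(seed, H$num_nodes)
    for (case in list(c("diffusion", 2), c("kuramoto", 3), c("si", 4),
                      c("mcm", 2))) {
      fam <- kernel_family(case[1], p = as.integer(case[2]), k = 4)
      expect_lt(max(abs(rhs(H, fam, x) - rhs_lifted(H, fam, x))), 1e-12)
    }
  }
})

test_that("rhs agrees with the independent brute-force oracle", {
  H <- toy_hypergraph()
  x <- c(0.2, -0.4, 1.1, 0.5, -0.9)
  for (nm in c("diffusion", "kuramoto", "mcm")) {
    fam <- kernel_family(nm, p = 2, k = 4)
    expect_equal(rhs(H, fam, x), brute_rhs(H, fam, x))
  }
})

test_that("pairwise Kuramoto equals the clique-expansion adjacency form", {
  # independent oracle: A_ij = 1 iff i and j share a hyperedge;
  # xdot_i = sum_j A_ij sin(x_j - x_i)
  H <- small_er(seed = 9)
  x <- with_seed_rnorm(4, H$num_nodes)
  A <- matrix(0, H$num_nodes, H$num_nodes)
  for (grp in H$edges_by_size)
    for (e in grp)
      for (i in e) for (j in e) if (i != j) A[i, j] <- A[i, j] + 1
  oracle <- vapply(seq_len(H$num_nodes),
                   function(i) sum(A[i, ] * sin(x - x[i])), numeric(1))
  fam <- kernel_family("kuramoto", p = 2, k = 4)
  expect_equal(rhs(H, fam, x), oracle)
})

test_that("forward Euler steps and aborts as specified", {
  H <- hypergraph(2, list(c(1, 2)))
  fam <- kernel_family("diffusion", 2, 2)
  tr <- euler_integrate(H, fam, c(0, 1), 0.01, 1)
  expect_equal(tr$states, rbind(c(0, 1), c(0.01, 0.99)))

  tr100 <- euler_integrate(H, fam, c(0, 1), 0.01, 100)
  expect_identical(nrow(tr100$states), 101L)

  # a fixed point stays fixed
  fam_k <- kernel_family("kuramoto", 2, 2)
  trf <- euler_integrate(H, fam_k, c(0.4, 0.4), 0.01, 20)
  expect_true(all(trf$states == 0.4))

  # wildly unstable step must abort with a diagnostic
  Hbig <- hypergraph(2, list(c(1, 2)))
  fam_si <- kernel_family("si", 2, 2)
  expect_error(euler_integrate(Hbig, fam_si, c(1e300, 1e300), 1e10, 5),
               "non-finite")
})

test_that("diffusion conserves the global state sum along trajectories", {
  H <- small_er(seed = 5)
  for (p in 2:4) {
    fam <- kernel_family("diffusion", p = p, k = 4)
    x0 <- with_seed_runif(5, H$num_nodes, -1, 1)
    tr <- euler_integrate(H, fam, x0, 0.01, 50)
    expect_lt(max(abs(rowSums(tr$states) - sum(x0))), 1e-10)
  }
})

test_that("fixed points and sign constraints of the named dynamics hold", {
  H <- small_er(seed = 6)
  const <- rep(0.37, H$num_nodes)
  for (nm in c("kuramoto", "mcm", "diffusion")) {
    fam <- kernel_family(nm, p = 3, k = 4)
    expect_equal(rhs(H, fam, const), numeric(H$num_nodes))
  }
  fam_si <- kernel_family("si", p = 3, k = 4)
  expect_equal(rhs(H, fam_si, rep(1, H$num_nodes)), numeric(H$num_nodes))
  # SI derivatives are non-negative anywhere in [0,1]^N
  for (s in 1:5) {
    x <- with_seed_runif(100 + s, H$num_nodes, 0, 1)
    expect_true(all(rhs(H, fam_si, x) >= 0))
  }
})

test_that("initial-state laws have the stated supports and skew", {
  set.seed(1)
  ku <- sample_initial_state("kuramoto", 1000)
  expect_true(all(ku >= -pi & ku <= pi))
  si <- sample_initial_state("si", 1000)
  expect_true(all(si >= 0 & si <= 1))
  di <- sample_initial_state("diffusion", 1000)
  expect_true(all(di >= -1 & di <= 1))
  mc <- sample_initial_state("mcm", 1e4)
  expect_true(all(mc >= 0 & mc <= 1))
  skew <- mean((mc - mean(mc))^3) / stats::sd(mc)^3
  expect_gt(skew, 0.2)  # right-skewed opinion law
  expect_error(sample_initial_state("unknown", 10))
})
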
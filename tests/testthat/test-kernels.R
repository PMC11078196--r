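test_that("kernel values match hand-computed examples", {
  expect_equal(kernel_value(kernel("diffusion"), 0, 1), 1)
  expect_equal(kernel_value(kernel("kuramoto"), 0, pi / 2), 1)
  expect_equal(kernel_value(kernel("si"), 0.5, c(1, 1)), 0.5)
  # mcm with lambda = -1: exp(-((0 + 1)/2 - 0)) * (1 - 0)
  expect_equal(kernel_value(kernel("mcm"), 0, 1), exp(-0.5))
  expect_equal(kernel_value(kernel("log_product"), 0.5, c(2, 1)), log(1))
  expect_error(kernel("not_a_kernel"))
})

test_that("every kernel is invariant under neighbour permutations", {
  perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
  for (nm in c("kuramoto", "si", "mcm", "diffusion", "log_product")) {
    k <- kernel(nm)
    nb <- c(0.3, 0.7, 0.2)
    vals <- apply(perms3, 1, function(p) kernel_value(k, 0.4, nb[p]))
    expect_true(all(vals == vals[1]), label = nm)
  }
})

test_that("kernel families follow the capped-arity assembly", {
  fam <- kernel_family("diffusion", p = 2, k = 4)
  # d <= p: single full-arity term; d > p: sum over pairwise sub-terms
  expect_equal(family_f(fam, 2)(0, 1), 1)
  expect_equal(family_f(fam, 3)(0, c(1, 2)), 3)    # (1-0) + (2-0)
  expect_equal(family_f(fam, 4)(1, c(1, 2, 3)), 3) # 0 + 1 + 2

  fam4 <- kernel_family("si", p = 4, k = 4)
  expect_equal(family_f(fam4, 4)(0, c(0.5, 0.5, 0.5)), 0.125)
  expect_error(family_f(fam4, 5), "no update function")
  expect_error(kernel_family("si", p = 5, k = 4))

  # family update functions inherit neighbour-permutation invariance
  fam3 <- kernel_family("mcm", p = 3, k = 4)
  nb <- c(0.2, 0.8, 0.5)
  perms3 <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  vals <- apply(perms3, 1, function(p) family_f(fam3, 4)(0.4, nb[p]))
  expect_true(all(vals == vals[1]))
})

test_that("full-arity sine update matches hand evaluation", {
  f3 <- full_kuramoto_f(3)
  expect_equal(f3(0, c(0, pi / 2)), 1)
  expect_equal(f3(0.7, c(0.7, 0.7)), 0)           # zero phase differences
  # d = 2 coincides with the pairwise sine kernel
  f2 <- full_kuramoto_f(2)
  expect_equal(f2(0.3, 1.1), kernel_value(kernel("kuramoto"), 0.3, 1.1))
})

test_that("decomposition verifier certifies the log-product and pairwise-sine
           expansions and rejects the full sine", {
  for (d in c(3, 4)) {
    f_log <- function(y, s) log(y) + sum(log(s))
    expect_lt(verify_decomposition(f_log, log_product_pair_kernel(d), d, 2,
                                   n_samples = 500, domain = c(0.01, 1),
                                   seed = 1), 1e-10)
    # per-edge sum of pairwise sines vs the pairwise kernel sin(y_i - y_1)
    f_pair <- function(y, s) sum(sin(s - y))
    expect_lt(verify_decomposition(f_pair, function(y, s) sin(s[1] - y), d, 2,
                                   n_samples = 500, domain = c(-pi, pi),
                                   seed = 1), 1e-10)
  }
  # full-arity sine on a 3-edge admits no pairwise-sine expansion
  res <- verify_decomposition(full_kuramoto_f(3),
                              function(y, s) sin(s[1] - y), 3, 2,
                              n_samples = 100, domain = c(-pi, pi), seed = 1)
  expect_gt(res, 0.1)
})

test_that("minimal certified order is 2 for reducible families and d for the
           full sine", {
  ord <- minimal_decomposition_order(
    function(y, s) log(y) + sum(log(s)),
    phi_for = function(p) if (p == 2) log_product_pair_kernel(3) else NULL,
    d = 3, domain = c(0.01, 1), seed = 1)
  expect_identical(ord, 2L)
  ord3 <- minimal_decomposition_order(
    full_kuramoto_f(3),
    phi_for = function(p) if (p == 2) function(y, s) sin(s[1] - y) else NULL,
    d = 3, domain = c(-pi, pi), seed = 1)
  expect_identical(ord3, 3L)
})
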
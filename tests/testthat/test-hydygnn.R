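test_that("symmetric evaluation is exactly permutation invariant and matches
           the exhaustive permutation average", {
  perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
  for (p_model in 2:3) {
    m <- hydygnn(4, p_model, hidden = c(8, 8), seed = 11)
    nb <- c(0.3, -0.2, 0.9)
    v0 <- symmetric_eval(m, 4, 0.5, nb)
    for (r in seq_len(nrow(perms3)))
      expect_identical(symmetric_eval(m, 4, 0.5, nb[perms3[r, ]]), v0)

    # brute-force oracle: mean over all orderings of the ordered-subset sum
    net <- m$nets[["4"]]
    p_in <- min(p_model, 4)
    sub <- t(utils::combn(3, p_in - 1))
    f_prime <- function(y1, s) {
      tot <- 0
      for (r in seq_len(nrow(sub)))
        tot <- tot + hyperdyn:::mlp_forward(net, matrix(c(y1, s[sub[r, ]]), 1))
      tot
    }
    brute <- mean(apply(perms3, 1, function(pp) f_prime(0.5, nb[pp])))
    expect_equal(v0, brute, tolerance = 1e-12)
  }
  m <- hydygnn(4, 2, seed = 1)
  expect_error(symmetric_eval(m, 3, 0, 1), "neighbour values")
})

test_that("model forward pass handles empty hypergraphs and size limits", {
  m <- hydygnn(3, 2, seed = 2)
  H0 <- hypergraph(4)
  expect_equal(model_forward(m, H0, rep(0.5, 4)), numeric(4))
  H5 <- hypergraph(5, list(c(1, 2, 3, 4, 5)))
  expect_error(model_forward(m, H5, rep(0, 5)), "larger than")
  expect_error(model_forward(m, hypergraph(2, list(c(1, 2))), c(1)), "mismatch")
})

test_that("model forward pass is equivariant under node relabeling", {
  m <- hydygnn(4, 3, hidden = c(8, 8), seed = 3)
  H <- toy_hypergraph()
  x <- c(0.1, -0.3, 0.8, 0.4, -0.6)
  perm <- c(3, 1, 5, 2, 4)  # node i -> perm[i]
  H_perm <- hypergraph(5, lapply(unlist(H$edges_by_size, recursive = FALSE),
                                 function(e) perm[e]))
  x_perm <- numeric(5)
  x_perm[perm] <- x
  out <- model_forward(m, H, x)
  out_perm <- model_forward(m, H_perm, x_perm)
  expect_equal(out_perm[perm], out, tolerance = 1e-12)
})

test_that("plugging the true kernels into the model reproduces the simulator", {
  H <- small_er(seed = 13)
  x <- with_seed_runif(14, H$num_nodes, 0.05, 1)
  for (nm in c("diffusion", "si", "mcm")) {
    for (p in 2:4) {
      fam <- kernel_family(nm, p = p, k = 4)
      fm <- frozen_kernel_model(4, p, kernel(nm))
      expect_equal(model_forward(fm, H, x), rhs(H, fam, x),
                   tolerance = 1e-10, label = paste(nm, p))
    }
  }
})

test_that("the regularized L1 loss follows its definition", {
  H <- hypergraph(2, list(c(1, 2)))
  fam <- kernel_family("diffusion", 2, 2)
  ts <- new_ts_for_test(H, rbind(c(0, 1)), rbind(rhs(H, fam, c(0, 1))))

  fm <- frozen_kernel_model(2, 2, kernel("diffusion"))
  expect_equal(model_loss(fm, ts, l2_lambda = 0), 0)  # perfect predictions

  # shift the target by 0.3 on one node: L1 loss = 0.3
  ts_off <- ts
  ts_off$derivs[1, 1] <- ts_off$derivs[1, 1] + 0.3
  expect_equal(model_loss(fm, ts_off, 0), 0.3)

  # the penalty enters linearly in lambda
  m <- hydygnn(2, 2, seed = 4)
  l0 <- model_loss(m, ts, 0)
  l1 <- model_loss(m, ts, 0.5)
  l2 <- model_loss(m, ts, 1.0)
  expect_equal(l2 - l1, l1 - l0, tolerance = 1e-10)
})

test_that("rollout mirrors the ground-truth integrator", {
  H <- small_er(seed = 15)
  fam <- kernel_family("diffusion", p = 2, k = 4)
  fm <- frozen_kernel_model(4, 2, kernel("diffusion"))
  x0 <- with_seed_runif(16, H$num_nodes, -1, 1)
  truth <- euler_integrate(H, fam, x0, 0.01, 30)
  pred <- rollout(fm, H, x0, 0.01, 30)
  expect_equal(pred$states, truth$states, tolerance = 1e-9)

  long <- rollout(fm, H, x0, 0.01, 200)
  expect_identical(nrow(long$states), 201L)

  # zeroed-out approximators predict a constant trajectory
  m0 <- hydygnn(4, 2, seed = 5)
  m0$nets <- lapply(m0$nets, function(n) {
    n$W <- lapply(n$W, function(w) w * 0)
    n$b <- lapply(n$b, function(v) v * 0)
    n
  })
  tr0 <- rollout(m0, H, x0, 0.01, 10)
  expect_true(all(tr0$states == rep(x0, each = 11)))
})

test_that("models round-trip through JSON serialization", {
  m <- hydygnn(4, 3, hidden = c(8, 8), seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_hydygnn(m, f)
  m2 <- read_hydygnn(f)
  H <- toy_hypergraph()
  x <- c(0.1, 0.4, -0.2, 0.9, 0.3)
  expect_equal(model_forward(m2, H, x), model_forward(m, H, x),
               tolerance = 1e-12)
  expect_error(write_hydygnn(frozen_kernel_model(3, 2, kernel("si")), f),
               "MLP")
})
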
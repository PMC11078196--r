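test_that("pointwise MAE follows its definition and ties to the L1 loss", {
  expect_equal(pointwise_mae(c(1, 2), c(1, 2)), 0)
  expect_equal(pointwise_mae(1.0, 0.5), 0.5)
  expect_error(pointwise_mae(matrix(0, 2, 2), matrix(0, 3, 2)), "shapes")

  # equals the unregularized loss divided by the node-sample count
  H <- toy_hypergraph()
  set.seed(21)
  states <- matrix(runif(10), 2, 5)
  fam <- kernel_family("si", 2, 4)
  derivs <- t(apply(states, 1, function(x) rhs(H, fam, x)))
  ts <- new_ts_for_test(H, states, derivs + 0.1)
  fm <- frozen_kernel_model(4, 2, kernel("si"))
  expect_equal(model_mae(fm, ts), model_loss(fm, ts, 0) / 10)
})

test_that("trajectory MAE is zero for the true model and orders field errors", {
  ts <- make_trajectory_dataset(2, 15, 0.01, "diffusion", p = 2,
                                list(num_nodes = 8L, probs = c("2" = 0.3)),
                                seed = 51)
  sys <- trajectory_systems(ts)
  fm <- frozen_kernel_model(2, 2, kernel("diffusion"))
  expect_lt(trajectory_mae(fm, sys, 0.01), 1e-9)

  # single-edge fixture: a model with larger per-step field error never
  # attains smaller trajectory MAE (closed-form Euler comparison)
  H1 <- hypergraph(2, list(c(1, 2)))
  fam <- kernel_family("diffusion", 2, 2)
  truth <- euler_integrate(H1, fam, c(0, 1), 0.01, 40)
  sys1 <- list(list(H = H1, x0 = c(0, 1), truth = truth$states))
  biased_model <- function(eps) {
    m <- frozen_kernel_model(2, 2, kernel("diffusion"))
    m$nets[["2"]]$fn <- function(X) (X[, 2] - X[, 1]) * (1 + eps)
    m
  }
  maes <- vapply(c(0.05, 0.2, 0.5), function(e)
    trajectory_mae(biased_model(e), sys1, 0.01), numeric(1))
  expect_true(all(diff(maes) > 0))
})

test_that("MC-perf matches hand-evaluated scores and selects the argmax", {
  sc <- mc_perf(c("2" = 10, "3" = 1, "4" = 1.05), k = 4)
  expect_equal(unname(sc),
               c(exp(-1) * exp(-0.5), exp(-0.1) * exp(-0.75),
                 exp(-0.105) * exp(-1)), tolerance = 1e-12)
  expect_equal(unname(sc), c(0.2231302, 0.4274149, 0.3312109),
               tolerance = 1e-6)
  rep <- order_selection_report(list("2" = 10, "3" = 1, "4" = 1.05), k = 4)
  expect_identical(rep$selected_order, 3L)
  expect_identical(select_effective_order(rep), 3L)
})

test_that("MC-perf is monotone, scale-free, bounded and breaks ties low", {
  # equal losses: the complexity penalty alone decides, scores decrease in p
  eq <- mc_perf(c("2" = 1, "3" = 1, "4" = 1), k = 4)
  expect_true(all(diff(eq) < 0))
  expect_true(all(eq > 0 & eq <= 1))

  # rescaling all losses leaves scores unchanged (L_max normalization)
  a <- mc_perf(c("2" = 3, "3" = 1.2, "4" = 0.6), k = 4)
  b <- mc_perf(c("2" = 300, "3" = 120, "4" = 60), k = 4)
  expect_equal(a, b, tolerance = 1e-12)

  # decreasing in loss at fixed order
  expect_gt(mc_perf(c("2" = 1, "3" = 2), k = 4)[["2"]],
            mc_perf(c("2" = 1.5, "3" = 2), k = 4)[["2"]])

  # ties break toward the smaller order; single candidate returns itself
  # L2 = 1 (= L_max), L3 = 0.75 makes both scores exp(-1.5): an exact tie
  tie <- order_selection_report(list("2" = 1, "3" = 0.75), k = 4)
  expect_identical(tie$selected_order, 2L)
  single <- order_selection_report(list("3" = 0.4), k = 4)
  expect_identical(single$selected_order, 3L)

  expect_error(mc_perf(numeric(0), 4), "no losses")
  expect_error(mc_perf(c("2" = Inf), 4), "finite")
})

test_that("cross-validation produces the full order-by-fold loss grid", {
  hp <- list(num_nodes = 8L, probs = c("2" = 0.25, "3" = 0.08))
  ts <- make_point_dataset(12, "diffusion", p = 2, hp, seed = 52)
  cv <- cross_validate(ts, c(3, 2), n_folds = 3, cfg = quick_cfg(epochs = 25),
                       seed = 9)
  expect_identical(cv$orders, c(2L, 3L))
  expect_identical(dim(cv$fold_mae), c(2L, 3L))
  expect_true(all(is.finite(cv$fold_mae)))
  rep <- order_selection_report(cv, k = 3)
  expect_true(rep$selected_order %in% c(2L, 3L))
  expect_equal(rep$L_max, max(rep$losses))
})

test_that("trajectory-scenario experiments run end to end", {
  cfgl <- list(
    dynamics = "diffusion", p = 2, scenario = "trajectory",
    n_traj = 4, steps = 15, dt = 0.01,
    hypergraph_params = list(num_nodes = 8L, probs = c("2" = 0.3)),
    candidate_orders = 2, n_folds = 2, seed = 3,
    train = list(epochs = 30, learning_rate = 1e-2, hidden = c(8, 8),
                 l2_lambda = 0, rng_seed = 4))
  rep <- run_experiment(cfgl)
  expect_s3_class(rep, "order_selection_report")
  expect_identical(rep$selected_order, 2L)
  expect_true(all(is.finite(rep$fold_losses)))
  # trajectory MAE was the score input
  cv <- attr(rep, "cv")
  expect_false(is.null(cv$fold_traj_mae))
})

test_that("experiment artifacts are written when an output directory is given", {
  dir <- withr::local_tempdir()
  cfgl <- list(
    dynamics = "diffusion", p = 2, scenario = "point", n_systems = 10,
    hypergraph_params = list(num_nodes = 8L, probs = c("2" = 0.3)),
    candidate_orders = 2, n_folds = 2, seed = 5,
    train = list(epochs = 25, learning_rate = 1e-2, hidden = c(8, 8),
                 l2_lambda = 0, rng_seed = 6))
  rep <- run_experiment(cfgl, out_dir = dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "fold_losses.csv")))
  expect_true(file.exists(file.path(dir, "kernel_grid_d2.csv")))
  expect_true(file.exists(file.path(dir, "example_rollout.csv")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$selected_order, 2)
})
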
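#' Learnable hypergraph-dynamics model
#'
#' Creates a model that approximates the per-size update functions
#' \eqn{f_d}, \eqn{d = 2..k}, with multilayer perceptrons whose input
#' dimension is capped at the model order: the size-\eqn{d} approximator
#' takes \eqn{\min(p_{model}, d)} inputs (centre state plus
#' \eqn{\min(p_{model}, d) - 1} neighbour states). For hyperedges larger
#' than the model order, the per-edge update is the sum of the capped
#' approximator over all neighbour subsets, and exact invariance under
#' permutations of the neighbour multiset is enforced by averaging over
#' orderings (see \code{\link{symmetric_eval}}). A model of order
#' \eqn{p_{model} < p_{dyn}} therefore cannot represent dynamics whose
#' update functions do not decompose below \eqn{p_{dyn}} — the gap that
#' order selection exploits.
#'
#' @param k maximum hyperedge size the model supports (topological order).
#' @param p_model model order, \eqn{2 \le p_{model} \le k}.
#' @param hidden integer vector of hidden-layer widths for every
#'   approximator (default two tanh layers of 32 units).
#' @param seed optional seed for weight initialization.
#' @return An object of class \code{"hydygnn"}: list with \code{k},
#'   \code{p_model}, \code{hidden} and \code{nets} (one approximator per
#'   size \code{"2"..as.character(k)}).
#' @export
hydygnn <- function(k, p_model, hidden = c(32, 32), seed = NULL) {
  stopifnot(k >= 2, p_model >= 2, p_model <= k)
  with_seed(seed, {
    nets <- list()
    for (d in 2:k)
      nets[[as.character(d)]] <- mlp_init(min(p_model, d), hidden)
    structure(list(k = as.integer(k), p_model = as.integer(p_model),
                   hidden = as.integer(hidden), nets = nets),
              class = "hydygnn")
  })
}

#' @export
print.hydygnn <- function(x, ...) {
  cat("HyDy-GNN model: order p_model =", x$p_model, "| max size k =", x$k,
      "\n  approximators:",
      paste(vapply(names(x$nets), function(d) {
        n <- x$nets[[d]]
        if (n$type == "mlp")
          sprintf("f_%s: MLP(%s)", d, paste(n$sizes, collapse = "-"))
        else sprintf("f_%s: fixed", d)
      }, character(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Model with approximators frozen to a known kernel
#'
#' Replaces every learnable approximator by the corresponding true kernel
#' evaluation, so the model's forward pass reproduces the simulator exactly
#' (used to validate the model machinery and as a reference in tests).
#'
#' @inheritParams hydygnn
#' @param kern a \code{\link{kernel}} (or kernel name) supplying the true
#'   interaction at each input arity.
#' @return A \code{"hydygnn"} whose nets are fixed functions.
#' @export
frozen_kernel_model <- function(k, p_model, kern) {
  if (!inherits(kern, "kernel")) kern <- kernel(kern)
  nets <- list()
  for (d in 2:k) {
    p_in <- min(p_model, d)
    nets[[as.character(d)]] <- local({
      ev <- kern$evaluate
      list(type = "fn", n_in = p_in,
           fn = function(X)
             apply(X, 1L, function(row) ev(row[1L], row[-1L])))
    })
  }
  structure(list(k = as.integer(k), p_model = as.integer(p_model),
                 hidden = integer(0), nets = nets),
            class = "hydygnn")
}

#' Permutation-symmetric per-edge update of a model
#'
#' Evaluates the model's effective update \eqn{\hat f_d(y_1,
#' \{\{y_2,\dots,y_d\}\})}: the average over all \eqn{(d-1)!} orderings of
#' the neighbour multiset of the ordered-subset sum of the order-capped
#' approximator. The implementation uses the algebraically identical fast
#' path — the sum over unordered neighbour subsets of the order-averaged
#' approximator — so the result is exactly invariant under any permutation
#' of \code{neighbors}.
#'
#' @param model a \code{\link{hydygnn}}.
#' @param d hyperedge size (\eqn{2 \le d \le k}).
#' @param y_center centre node state.
#' @param neighbors numeric vector of \eqn{d - 1} neighbour states.
#' @return Scalar update value.
#' @export
symmetric_eval <- function(model, d, y_center, neighbors) {
  stopifnot(inherits(model, "hydygnn"), d >= 2, d <= model$k)
  if (length(neighbors) != d - 1L)
    stop("expected ", d - 1L, " neighbour values, got ", length(neighbors),
         call. = FALSE)
  p_in <- min(model$p_model, d)
  tmpl <- row_template(d, p_in)
  # canonical (sorted) neighbour order makes the floating-point summation
  # order independent of the input ordering, so invariance is bit-exact
  neighbors <- sort(neighbors)
  X <- cbind(y_center,
             matrix(neighbors[tmpl], nrow(tmpl), p_in - 1L))
  net <- model$nets[[as.character(d)]]
  sum(net_apply(net, X)) / factorial(p_in - 1L)
}

#' Model-predicted derivative field on a hypergraph
#'
#' The learnable analogue of \code{\link{rhs}}: sums the symmetrized
#' per-edge updates \eqn{\hat f_d} over all hyperedges containing each node.
#' \code{model_forward_fn} returns a closure with the edge bookkeeping
#' precomputed, for repeated evaluation (e.g. rollouts).
#'
#' @param model a \code{\link{hydygnn}}.
#' @param H a \code{\link{hypergraph}} with topological order at most
#'   \code{model$k}.
#' @param x numeric state vector.
#' @return \code{model_forward}: predicted derivative vector.
#'   \code{model_forward_fn}: function \code{(x) -> derivative vector}.
#' @export
model_forward <- function(model, H, x) {
  model_forward_fn(model, H)(x)
}

#' @rdname model_forward
#' @export
model_forward_fn <- function(model, H) {
  stopifnot(inherits(model, "hydygnn"), inherits(H, "hypergraph"))
  if (num_edges(H) > 0L && topological_order(H) > model$k)
    stop("hypergraph has hyperedges larger than the model's max size k = ",
         model$k, call. = FALSE)
  design <- build_design(list(H), 1L, H$num_nodes, model$k, model$p_model)
  nets <- model$nets
  function(x) {
    if (length(x) != H$num_nodes)
      stop("state vector length mismatch", call. = FALSE)
    design_forward(design, nets, x)
  }
}

#' Regularized L1 training loss
#'
#' \eqn{L = \sum_i \lVert \hat M(x^{(i)}) - \dot x^{(i)} \rVert_1 +
#' \lambda \lVert \theta \rVert_2^2}: the sum over samples of the L1 norm of
#' the derivative residual plus a squared-L2 (weight-decay) penalty on the
#' concatenated approximator parameters.
#'
#' @param model a \code{\link{hydygnn}}.
#' @param ts a \code{\link{training_set}} (or subset).
#' @param l2_lambda penalty weight \eqn{\lambda \ge 0}.
#' @return Scalar loss.
#' @export
model_loss <- function(model, ts, l2_lambda = 0) {
  stopifnot(inherits(model, "hydygnn"), inherits(ts, "training_set"),
            l2_lambda >= 0, num_samples(ts) >= 1)
  design <- build_design(ts$hypergraphs, ts$hg_id, ncol(ts$states),
                         model$k, model$p_model)
  pred <- design_forward(design, model$nets, as.numeric(t(ts$states)))
  fit <- sum(abs(pred - as.numeric(t(ts$derivs))))
  fit + l2_lambda * model_param_sq_norm(model)
}

model_param_sq_norm <- function(model)
  sum(vapply(model$nets, function(n)
    if (n$type == "mlp") mlp_param_sq_norm(n) else 0, numeric(1)))

#' Roll out a learned model as a dynamical system
#'
#' Forward-Euler integration using the model's predicted derivative field,
#' mirroring \code{\link{euler_integrate}} so learned and ground-truth
#' trajectories are directly comparable.
#'
#' @inheritParams euler_integrate
#' @param model a \code{\link{hydygnn}}.
#' @param H hypergraph to roll out on.
#' @param x0 initial state.
#' @return A \code{"trajectory"} with \code{steps + 1} states.
#' @export
rollout <- function(model, H, x0, dt, steps) {
  stopifnot(dt > 0, steps >= 1)
  euler_run(model_forward_fn(model, H), x0, dt, steps)
}

#' Evaluate a 2-input approximator on a grid
#'
#' Returns the learned pairwise update surface \eqn{(y_1, y_2) \mapsto
#' \mathrm{MLP}_d^2(y_1, y_2)} on a regular grid, for comparison against the
#' generating kernel (learned-update-surface diagnostics). Only defined for
#' sizes whose approximator has input dimension 2.
#'
#' @param model a \code{\link{hydygnn}}.
#' @param d hyperedge size whose approximator to evaluate (default 2).
#' @param y1 grid for the centre state.
#' @param y2 grid for the neighbour state.
#' @return Data frame with columns \code{y1}, \code{y2}, \code{value}.
#' @export
kernel_grid <- function(model, d = 2,
                        y1 = seq(-pi, pi, length.out = 41),
                        y2 = seq(-pi, pi, length.out = 41)) {
  stopifnot(inherits(model, "hydygnn"))
  net <- model$nets[[as.character(d)]]
  if (is.null(net)) stop("model has no size-", d, " approximator", call. = FALSE)
  n_in <- if (net$type == "mlp") net$sizes[1L] else net$n_in
  if (n_in != 2L)
    stop("size-", d, " approximator has input dimension ", n_in,
         "; kernel_grid needs 2", call. = FALSE)
  g <- expand.grid(y1 = y1, y2 = y2)
  g$value <- net_apply(net, cbind(g$y1, g$y2))
  g
}

#' Save / load a model as JSON
#'
#' Serializes the architecture and flattened weights (frozen-kernel models
#' cannot be serialized).
#'
#' @param model a \code{\link{hydygnn}} with MLP approximators.
#' @param path output JSON path.
#' @return \code{path} invisibly (\code{write}); a \code{"hydygnn"}
#'   (\code{read}).
#' @export
write_hydygnn <- function(model, path) {
  stopifnot(inherits(model, "hydygnn"))
  if (any(vapply(model$nets, function(n) n$type != "mlp", logical(1))))
    stop("only MLP-based models can be serialized", call. = FALSE)
  obj <- list(k = model$k, p_model = model$p_model, hidden = model$hidden,
              nets = lapply(model$nets, function(n)
                list(sizes = n$sizes,
                     W = lapply(n$W, function(w) as.numeric(w)),
                     b = n$b)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hydygnn
#' @export
read_hydygnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nets <- list()
  for (d in names(obj$nets)) {
    n <- obj$nets[[d]]
    sizes <- as.integer(n$sizes)
    W <- lapply(seq_along(n$W), function(l)
      matrix(n$W[[l]], sizes[l], sizes[l + 1L]))
    b <- lapply(n$b, as.numeric)
    nets[[d]] <- list(type = "mlp", sizes = sizes, W = W, b = b)
  }
  structure(list(k = as.integer(obj$k), p_model = as.integer(obj$p_model),
                 hidden = as.integer(obj$hidden), nets = nets),
            class = "hydygnn")
}
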
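#' Pointwise mean absolute error between derivative fields
#'
#' Mean over all samples and nodes of the absolute difference between
#' predicted and true derivatives; equals the (unregularized) L1 training
#' loss divided by the total number of node-sample entries.
#'
#' @param predicted numeric matrix or vector of predicted derivatives.
#' @param truth matching matrix or vector of true derivatives.
#' @return Scalar MAE.
#' @export
pointwise_mae <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)) ||
      length(predicted) != length(truth))
    stop("predicted and truth must have matching shapes", call. = FALSE)
  mean(abs(predicted - truth))
}

#' Held-out pointwise MAE of a model on a training set
#'
#' @param model a \code{\link{hydygnn}}.
#' @param ts a \code{\link{training_set}} (typically a held-out fold).
#' @return Scalar MAE over all samples and nodes.
#' @export
model_mae <- function(model, ts) {
  stopifnot(inherits(model, "hydygnn"), inherits(ts, "training_set"))
  design <- build_design(ts$hypergraphs, ts$hg_id, ncol(ts$states),
                         model$k, model$p_model)
  pred <- design_forward(design, model$nets, as.numeric(t(ts$states)))
  mean(abs(pred - as.numeric(t(ts$derivs))))
}

#' Ground-truth test systems from a trajectory training set
#'
#' Reassembles, for each hypergraph of a trajectory-scenario training set,
#' the full ground-truth trajectory (including the final state, recovered
#' from the last forward difference) together with the initial condition.
#'
#' @param ts a trajectory-scenario \code{\link{training_set}}.
#' @return List of systems: \code{list(H, x0, truth)} with \code{truth} a
#'   \code{(steps + 1) x N} state matrix.
#' @export
trajectory_systems <- function(ts) {
  stopifnot(inherits(ts, "training_set"),
            identical(ts$meta$scenario, "trajectory"))
  dt <- ts$meta$dt
  lapply(seq_along(ts$hypergraphs), function(h) {
    idx <- which(ts$hg_id == h)
    states <- ts$states[idx, , drop = FALSE]
    last <- states[length(idx), ] + dt * ts$derivs[idx[length(idx)], ]
    list(H = ts$hypergraphs[[h]], x0 = states[1L, ],
         truth = rbind(states, last))
  })
}

#' Trajectory mean absolute error of a learned model
#'
#' For each test system, rolls the model out from the ground-truth initial
#' condition with the same Euler step and horizon as the reference
#' trajectory and averages the absolute state error over all time points
#' (excluding the shared initial state) and nodes; the result is the mean
#' over systems. A rollout that diverges to non-finite states contributes
#' \code{Inf} with a warning.
#'
#' @param model a \code{\link{hydygnn}}.
#' @param test_systems list of systems as returned by
#'   \code{\link{trajectory_systems}}.
#' @param dt Euler step.
#' @param steps horizon; defaults to the reference trajectory length.
#' @return Scalar trajectory MAE.
#' @export
trajectory_mae <- function(model, test_systems, dt, steps = NULL) {
  per_system <- vapply(test_systems, function(sys) {
    n_steps <- steps %||% (nrow(sys$truth) - 1L)
    tr <- tryCatch(rollout(model, sys$H, sys$x0, dt, n_steps),
                   error = function(e) NULL)
    if (is.null(tr)) {
      warning("rollout diverged; system scored as Inf")
      return(Inf)
    }
    horizon <- seq_len(min(nrow(tr$states), nrow(sys$truth)))[-1L]
    mean(abs(tr$states[horizon, ] - sys$truth[horizon, ]))
  }, numeric(1))
  mean(per_system)
}
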
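#' Synthetic training sets for hypergraph-dynamics learning
#'
#' A training set pairs node-state vectors with state derivatives on known
#' hypergraph topologies. Two observation scenarios are supported:
#' \emph{point} data, where each sample is an independent random initial
#' state with the exact derivative of the dynamics at that state (one fresh
#' hypergraph per sample), and \emph{trajectory} data, where samples are the
#' successive states of forward-Euler trajectories with derivatives taken as
#' forward time differences (one hypergraph per trajectory, so samples within
#' a trajectory share a topology and are temporally correlated).
#'
#' @name training_set
#' @return Objects of class \code{"training_set"}: a list with
#'   \code{states} and \code{derivs} (\eqn{S \times N} matrices),
#'   \code{hg_id} (which hypergraph each sample lives on),
#'   \code{hypergraphs} (list of \code{\link{hypergraph}}) and \code{meta}
#'   (dynamics name, kernel order \code{p}, scenario, \code{dt}, seed).
NULL

new_training_set <- function(states, derivs, hg_id, hypergraphs, meta) {
  stopifnot(nrow(states) == nrow(derivs), nrow(states) == length(hg_id))
  structure(list(states = states, derivs = derivs, hg_id = as.integer(hg_id),
                 hypergraphs = hypergraphs, meta = meta),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("Training set:", nrow(x$states), "samples |",
      length(x$hypergraphs), "hypergraph(s) |", ncol(x$states), "nodes\n")
  cat("  dynamics:", x$meta$dynamics, "| kernel order p =", x$meta$p,
      "| scenario:", x$meta$scenario, "\n")
  invisible(x)
}

#' Number of samples in a training set
#' @param ts a \code{training_set}.
#' @return Integer sample count.
#' @export
num_samples <- function(ts) nrow(ts$states)

default_hypergraph_params <- function() {
  list(num_nodes = 20L, probs = c("2" = 0.1, "3" = 0.01, "4" = 0.001))
}

family_for <- function(dynamics_name, p, hypergraph_params) {
  k <- max(as.integer(names(hypergraph_params$probs)), p)
  kernel_family(dynamics_name, p = p, k = k)
}

#' Point-based training data: independent states with exact derivatives
#'
#' Draws \code{n_systems} samples; each sample gets its own Erdős–Rényi
#' hypergraph, one random initial state from the dynamics' initial-state law
#' and the exact derivative \code{\link{rhs}} evaluated at that state. The
#' defaults (20-node hypergraphs with per-size probabilities 0.1 / 0.01 /
#' 0.001, 500 samples in the full-scale configuration) give order-4
#' topologies.
#'
#' @param n_systems number of samples (= hypergraphs).
#' @param dynamics_name dynamics: \code{"kuramoto"}, \code{"si"},
#'   \code{"mcm"} or \code{"diffusion"}.
#' @param p interaction order of the generating kernels
#'   (\code{\link{kernel_family}}).
#' @param hypergraph_params list with \code{num_nodes} and named \code{probs}
#'   for \code{\link{generate_er_hypergraph}}.
#' @param seed integer seed making the whole set reproducible.
#' @return A \code{\link{training_set}} with scenario \code{"point"}.
#' @export
make_point_dataset <- function(n_systems, dynamics_name, p,
                               hypergraph_params = default_hypergraph_params(),
                               seed = NULL) {
  stopifnot(n_systems >= 1)
  fam <- family_for(dynamics_name, p, hypergraph_params)
  N <- hypergraph_params$num_nodes
  with_seed(seed, {
    hgs <- vector("list", n_systems)
    states <- matrix(NA_real_, n_systems, N)
    derivs <- matrix(NA_real_, n_systems, N)
    for (s in seq_len(n_systems)) {
      hgs[[s]] <- generate_er_hypergraph(N, hypergraph_params$probs)
      x <- sample_initial_state(dynamics_name, N)
      states[s, ] <- x
      derivs[s, ] <- rhs(hgs[[s]], fam, x)
    }
    new_training_set(states, derivs, seq_len(n_systems), hgs,
                     list(dynamics = dynamics_name, p = p, scenario = "point",
                          dt = NA_real_, seed = seed, k = fam$k))
  })
}

#' Trajectory-based training data: Euler rollouts with forward differences
#'
#' Simulates \code{n_traj} forward-Euler trajectories (one fresh
#' Erdős–Rényi hypergraph and random initial state each) and extracts one
#' sample per time point \eqn{t = 0, \dots,} \code{steps}\eqn{ - 1}: the
#' state \eqn{x(t)} paired with the forward difference
#' \eqn{(x(t+\Delta) - x(t))/\Delta}. Under the Euler scheme the forward
#' difference equals the exact derivative at \eqn{x(t)}, but samples within
#' a trajectory are not independent. The full-scale configuration (25
#' trajectories of 100 steps at \eqn{\Delta = 0.01}) yields 2500 samples.
#'
#' @inheritParams make_point_dataset
#' @param n_traj number of trajectories (= hypergraphs).
#' @param steps Euler steps per trajectory (= samples per trajectory).
#' @param dt Euler time step.
#' @return A \code{\link{training_set}} with scenario \code{"trajectory"}.
#' @export
make_trajectory_dataset <- function(n_traj, steps, dt, dynamics_name, p,
                                    hypergraph_params = default_hypergraph_params(),
                                    seed = NULL) {
  stopifnot(n_traj >= 1, steps >= 1, dt > 0)
  fam <- family_for(dynamics_name, p, hypergraph_params)
  N <- hypergraph_params$num_nodes
  with_seed(seed, {
    hgs <- vector("list", n_traj)
    S <- n_traj * steps
    states <- matrix(NA_real_, S, N)
    derivs <- matrix(NA_real_, S, N)
    hg_id <- integer(S)
    r <- 0L
    for (tr in seq_len(n_traj)) {
      hgs[[tr]] <- generate_er_hypergraph(N, hypergraph_params$probs)
      x0 <- sample_initial_state(dynamics_name, N)
      traj <- euler_integrate(hgs[[tr]], fam, x0, dt, steps)
      idx <- r + seq_len(steps)
      states[idx, ] <- traj$states[seq_len(steps), , drop = FALSE]
      derivs[idx, ] <- (traj$states[seq_len(steps) + 1L, , drop = FALSE] -
                          traj$states[seq_len(steps), , drop = FALSE]) / dt
      hg_id[idx] <- tr
      r <- r + steps
    }
    new_training_set(states, derivs, hg_id, hgs,
                     list(dynamics = dynamics_name, p = p,
                          scenario = "trajectory", dt = dt, seed = seed,
                          k = fam$k, steps = steps))
  })
}

#' Subset a training set by sample indices
#'
#' Keeps only the referenced samples (and the hypergraphs they live on,
#' re-indexed).
#'
#' @param ts a \code{training_set}.
#' @param idx integer vector of sample indices.
#' @return A \code{training_set}.
#' @export
subset_training_set <- function(ts, idx) {
  stopifnot(inherits(ts, "training_set"))
  keep_hg <- sort(unique(ts$hg_id[idx]))
  new_training_set(ts$states[idx, , drop = FALSE],
                   ts$derivs[idx, , drop = FALSE],
                   match(ts$hg_id[idx], keep_hg),
                   ts$hypergraphs[keep_hg], ts$meta)
}

#' K-fold split grouped by hypergraph
#'
#' Partitions the samples into \code{k} cross-validation folds such that all
#' samples sharing a hypergraph land in the same fold (fold sizes differ by
#' at most one hypergraph). Grouping by topology prevents leakage between
#' temporally correlated samples of one trajectory.
#'
#' @param ts a \code{training_set}.
#' @param k number of folds (\eqn{2 \le k \le} number of hypergraphs).
#' @param seed optional seed for the fold assignment shuffle.
#' @return List of \code{k} elements, each \code{list(train = idx, test =
#'   idx)}; the test indices partition the samples.
#' @export
kfold_split <- function(ts, k, seed = NULL) {
  stopifnot(inherits(ts, "training_set"), k >= 2)
  n_hg <- length(ts$hypergraphs)
  if (k > n_hg)
    stop("k = ", k, " exceeds the number of distinct hypergraphs (", n_hg, ")",
         call. = FALSE)
  with_seed(seed, {
    fold_of_hg <- sample(rep_len(seq_len(k), n_hg))
    lapply(seq_len(k), function(f) {
      test_hg <- which(fold_of_hg == f)
      test <- which(ts$hg_id %in% test_hg)
      list(train = setdiff(seq_len(num_samples(ts)), test), test = test)
    })
  })
}

#' Write / read a training set as plain-text files
#'
#' Serializes a training set to a directory: \code{states.csv} and
#' \code{derivs.csv} (one row per sample), \code{hg_id.csv}, one hyperedge
#' list per hypergraph under \code{hypergraphs/}, and \code{meta.json}.
#'
#' @param ts a \code{training_set}.
#' @param dir output directory (created if missing).
#' @return \code{dir} invisibly (\code{write}); a \code{training_set}
#'   (\code{read}).
#' @export
write_training_set <- function(ts, dir) {
  stopifnot(inherits(ts, "training_set"))
  dir.create(file.path(dir, "hypergraphs"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(as.data.frame(ts$states),
                   file.path(dir, "states.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ts$derivs),
                   file.path(dir, "derivs.csv"), row.names = FALSE)
  utils::write.csv(data.frame(hg_id = ts$hg_id),
                   file.path(dir, "hg_id.csv"), row.names = FALSE)
  for (i in seq_along(ts$hypergraphs))
    write_hyperedge_list(ts$hypergraphs[[i]],
                         file.path(dir, "hypergraphs", sprintf("hg_%04d.txt", i)))
  meta <- ts$meta
  meta$num_nodes <- ncol(ts$states)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  states <- as.matrix(utils::read.csv(file.path(dir, "states.csv")))
  derivs <- as.matrix(utils::read.csv(file.path(dir, "derivs.csv")))
  dimnames(states) <- dimnames(derivs) <- NULL
  hg_id <- utils::read.csv(file.path(dir, "hg_id.csv"))$hg_id
  files <- sort(list.files(file.path(dir, "hypergraphs"), full.names = TRUE))
  hgs <- lapply(files, read_hyperedge_list, num_nodes = meta$num_nodes,
                labels = as.character(seq_len(meta$num_nodes)))
  new_training_set(states, derivs, hg_id, hgs, meta)
}
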
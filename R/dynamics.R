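#' Time derivative of a hypergraph dynamical system
#'
#' Computes \eqn{\dot x_i = \sum_{d} \sum_{E \in \mathcal{E}_d : i \in E}
#' f_d(x_i, \{\{x_j : j \in E, j \ne i\}\})}: every hyperedge containing a
#' node contributes one update-function evaluation with that node as centre,
#' and the contributions are summed. The single-node term is identically
#' zero.
#'
#' @param H a \code{\link{hypergraph}}.
#' @param family a \code{\link{kernel_family}} whose \code{k} is at least the
#'   topological order of \code{H}.
#' @param x numeric state vector of length \code{H$num_nodes}.
#' @return Numeric derivative vector of length \code{H$num_nodes}.
#' @examples
#' H <- hypergraph(2, list(c(1, 2)))
#' rhs(H, kernel_family("diffusion", 2, 2), c(0, 1))  # c(1, -1)
#' @export
rhs <- function(H, family, x) {
  stopifnot(inherits(H, "hypergraph"), inherits(family, "kernel_family"))
  if (length(x) != H$num_nodes)
    stop("state vector length ", length(x), " != num_nodes ", H$num_nodes,
         call. = FALSE)
  xdot <- numeric(H$num_nodes)
  for (dch in names(H$edges_by_size)) {
    d <- as.integer(dch)
    edges <- H$edges_by_size[[dch]]
    if (length(edges) == 0L) next
    f <- family_f(family, d)
    for (e in edges) {
      ye <- x[e]
      for (pos in seq_len(d)) {
        i <- e[pos]
        xdot[i] <- xdot[i] + f(ye[pos], ye[-pos])
      }
    }
  }
  xdot
}

#' Time derivative via the lift--update--project formulation
#'
#' Equivalent form of \code{\link{rhs}} built from the sparse lifting
#' operators: the state is lifted edge-wise with \eqn{L_d}, the per-edge
#' update map applied in the lifted coordinates, and the result projected
#' back with \eqn{L_d^\top}, i.e. \eqn{\dot x = \sum_d L_d^\top F_d(L_d x)}.
#' Agrees with the per-node summation to machine precision; kept as an
#' independent formulation (and used as a cross-check in the test suite).
#'
#' @inheritParams rhs
#' @return Numeric derivative vector of length \code{H$num_nodes}.
#' @export
rhs_lifted <- function(H, family, x) {
  stopifnot(inherits(H, "hypergraph"), inherits(family, "kernel_family"))
  if (length(x) != H$num_nodes)
    stop("state vector length mismatch", call. = FALSE)
  xdot <- numeric(H$num_nodes)
  for (dch in names(H$edges_by_size)) {
    d <- as.integer(dch)
    if (length(H$edges_by_size[[dch]]) == 0L) next
    L <- lifting_matrix(H, d)
    y <- as.numeric(L$matrix %*% x)
    f <- family_f(family, d)
    upd <- numeric(length(y))
    for (a in seq_len(L$num_edges)) {
      blk <- (a - 1L) * d + seq_len(d)
      yb <- y[blk]
      for (pos in seq_len(d))
        upd[blk[pos]] <- f(yb[pos], yb[-pos])
    }
    xdot <- xdot + as.numeric(Matrix::crossprod(L$matrix, upd))
  }
  xdot
}

#' Integrate a hypergraph dynamical system with forward Euler
#'
#' Fixed-step explicit Euler: \eqn{x(t + \Delta) = x(t) + \Delta\,\dot x(t)}.
#' The same scheme (and default \eqn{\Delta = 0.01}) is used to build
#' trajectory training data and to roll out learned models, so ground truth
#' and model predictions are compared like for like.
#'
#' @inheritParams rhs
#' @param x0 initial state vector.
#' @param dt time step \eqn{\Delta > 0}.
#' @param steps number of Euler steps (\eqn{\ge 1}).
#' @return An object of class \code{"trajectory"}: list with \code{states}
#'   (\code{(steps + 1) x N} matrix, row 1 the initial state) and \code{dt}.
#' @export
euler_integrate <- function(H, family, x0, dt, steps) {
  stopifnot(dt > 0, steps >= 1)
  deriv <- function(x) rhs(H, family, x)
  euler_run(deriv, x0, dt, steps)
}

# Shared Euler loop for true and learned vector fields.
euler_run <- function(deriv, x0, dt, steps) {
  N <- length(x0)
  states <- matrix(NA_real_, steps + 1L, N)
  states[1L, ] <- x0
  x <- x0
  for (t in seq_len(steps)) {
    x <- x + dt * deriv(x)
    if (any(!is.finite(x)))
      stop("non-finite state at step ", t, "; integration aborted",
           call. = FALSE)
    states[t + 1L, ] <- x
  }
  structure(list(states = states, dt = dt), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$states) - 1L, "Euler steps |",
      ncol(x$states), "nodes | dt =", x$dt, "\n")
  invisible(x)
}

#' Draw a random initial state for a named dynamics
#'
#' Initial-state laws per dynamics: Kuramoto phases uniform on
#' \eqn{[-\pi, \pi]}; SI infection probabilities uniform on \eqn{[0, 1]};
#' MCM opinions from a right-skewed Beta(2, 5) law on \eqn{[0, 1]} (the
#' nonlinear reinforcement only matters away from symmetric opinion
#' profiles); diffusion states uniform on \eqn{[-1, 1]}.
#'
#' @param dynamics_name one of \code{"kuramoto"}, \code{"si"}, \code{"mcm"},
#'   \code{"diffusion"} (\code{"full_kuramoto"} uses the Kuramoto law).
#' @param n number of nodes.
#' @param mcm_shape Beta shape parameters for the MCM law.
#' @return Numeric vector of \code{n} independent draws (uses the current
#'   RNG stream).
#' @export
sample_initial_state <- function(dynamics_name, n,
                                 mcm_shape = c(2, 5)) {
  switch(match.arg(dynamics_name,
                   c("kuramoto", "full_kuramoto", "si", "mcm", "diffusion")),
         kuramoto = ,
         full_kuramoto = stats::runif(n, -pi, pi),
         si = stats::runif(n, 0, 1),
         mcm = stats::rbeta(n, mcm_shape[1], mcm_shape[2]),
         diffusion = stats::runif(n, -1, 1))
}

#' Numerically verify a decomposition of an update function
#'
#' Checks whether a size-\eqn{d} update function \eqn{f_d} equals the sum of
#' a candidate \eqn{p}-ary kernel over all neighbour subsets of size
#' \eqn{p - 1}, i.e. \eqn{f_d(y_1, s) = \sum_{v \subseteq s, |v| = p - 1}
#' \phi(y_1, v)}, by drawing random argument tuples and returning the largest
#' absolute residual. A residual at machine precision certifies that the
#' decomposition holds on the sampled domain (and hence that the dynamical
#' order is at most \eqn{p}); a residual bounded away from zero is a
#' counterexample.
#'
#' @param f size-\eqn{d} update function \code{(y_center, neighbors)} with
#'   \code{length(neighbors) == d - 1}.
#' @param phi candidate kernel: a \code{\link{kernel}} or a function
#'   \code{(y_center, neighbors)} taking \eqn{p - 1} neighbours.
#' @param d hyperedge size (\eqn{\ge p}).
#' @param p candidate decomposition order (\eqn{2 \le p \le d}).
#' @param n_samples number of random tuples.
#' @param domain length-2 numeric range the tuple entries are drawn from
#'   uniformly; choose it inside the kernel's domain of validity (e.g.
#'   positive values for \code{log_product}, \eqn{[-\pi,\pi]} for phase
#'   kernels).
#' @param seed optional RNG seed.
#' @return Maximum absolute residual over the sampled tuples.
#' @examples
#' res <- verify_decomposition(
#'   function(y, s) log(y) + sum(log(s)), log_product_pair_kernel(3),
#'   d = 3, p = 2, n_samples = 100, domain = c(0.05, 1), seed = 1)
#' res < 1e-10
#' @export
verify_decomposition <- function(f, phi, d, p, n_samples = 1000,
                                 domain = c(0, 1), seed = NULL) {
  stopifnot(p >= 2, p <= d, n_samples >= 1)
  ev <- if (inherits(phi, "kernel")) phi$evaluate else phi
  sub <- subsets_of_size(d - 1L, p - 1L)
  with_seed(seed, {
    worst <- 0
    for (s in seq_len(n_samples)) {
      tup <- stats::runif(d, domain[1], domain[2])
      y1 <- tup[1L]
      nb <- tup[-1L]
      expand <- 0
      for (r in seq_len(nrow(sub)))
        expand <- expand + ev(y1, nb[sub[r, ]])
      worst <- max(worst, abs(f(y1, nb) - expand))
    }
    worst
  })
}

#' Smallest decomposition order certified numerically
#'
#' Scans candidate orders \eqn{p = 2, 3, \dots, d} and returns the smallest
#' one whose candidate kernel (supplied by \code{phi_for}) passes
#' \code{\link{verify_decomposition}} below \code{tol}. At \eqn{p = d} the
#' update function itself is the (trivial) kernel, so the scan always
#' terminates.
#'
#' @param f size-\eqn{d} update function.
#' @param phi_for function \code{(p)} returning the candidate \eqn{p}-ary
#'   kernel for the decomposition at order \eqn{p}, or \code{NULL} when no
#'   candidate is available at that order (the order is then skipped).
#' @param d hyperedge size.
#' @param tol residual tolerance certifying a pass.
#' @inheritParams verify_decomposition
#' @return The smallest certified order \eqn{p}.
#' @export
minimal_decomposition_order <- function(f, phi_for, d, n_samples = 1000,
                                        domain = c(0, 1), tol = 1e-10,
                                        seed = NULL) {
  for (p in 2:d) {
    phi <- if (p == d) function(y, s) f(y, s) else phi_for(p)
    if (is.null(phi)) next
    res <- verify_decomposition(f, phi, d, p, n_samples, domain, seed)
    if (res < tol) return(p)
  }
  d
}
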
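#' Interaction kernels for hypergraph dynamics
#'
#' A kernel \eqn{\phi^p(y_i, \{\{y_j\}\})} is the local interaction rule
#' evaluated at a centre node \eqn{i} with a multiset of \eqn{p - 1}
#' neighbour states; every kernel is invariant to permutations of the
#' neighbour multiset. The arity \eqn{p} is implicit in the number of
#' neighbour values supplied. Available kernels:
#' \describe{
#'   \item{\code{kuramoto} (alias \code{full_kuramoto})}{phase coupling
#'     \eqn{\sin\sum_j (y_j - y_i)}, the sum running over all \eqn{p} members
#'     of the interaction (the centre's own term vanishes).}
#'   \item{\code{si}}{susceptible--infected contagion
#'     \eqn{(1 - y_i)\prod_j y_j}, the product over the \eqn{p - 1}
#'     neighbours; states are infection probabilities.}
#'   \item{\code{mcm}}{multi-way consensus with homophily reinforcement
#'     \eqn{\exp[\lambda(\bar y - y_i)]\sum_j (y_j - y_i)} where \eqn{\bar y}
#'     is the mean over the \eqn{p} interacting states; the homophily
#'     coefficient \eqn{\lambda} defaults to \eqn{-1}.}
#'   \item{\code{diffusion}}{linear consensus \eqn{\sum_j (y_j - y_i)}.}
#'   \item{\code{log_product}}{\eqn{\log(y_i \prod_j y_j)}, the classic
#'     example of a fully pairwise-decomposable nonlinear update (positive
#'     states only).}
#' }
#'
#' @param name kernel name (see above).
#' @param params named list of parameters; \code{mcm} accepts \code{lambda}.
#' @return An object of class \code{"kernel"} with fields \code{name},
#'   \code{params} and \code{evaluate(y_center, neighbors)}.
#' @examples
#' kernel_value(kernel("diffusion"), 0, 1)       # 1
#' kernel_value(kernel("si"), 0.5, c(1, 1))      # 0.5
#' @export
kernel <- function(name, params = list()) {
  name <- match.arg(name, c("kuramoto", "si", "mcm", "diffusion",
                            "full_kuramoto", "log_product"))
  if (name == "mcm" && is.null(params$lambda)) params$lambda <- -1
  evaluate <- switch(
    name,
    kuramoto = ,
    full_kuramoto = function(y_center, neighbors)
      sin(sum(neighbors - y_center)),
    si = function(y_center, neighbors)
      (1 - y_center) * prod(neighbors),
    mcm = {
      lambda <- params$lambda
      function(y_center, neighbors) {
        p <- length(neighbors) + 1L
        exp(lambda * ((y_center + sum(neighbors)) / p - y_center)) *
          sum(neighbors - y_center)
      }
    },
    diffusion = function(y_center, neighbors)
      sum(neighbors - y_center),
    log_product = function(y_center, neighbors)
      log(y_center) + sum(log(neighbors))
  )
  structure(list(name = name, params = params, evaluate = evaluate),
            class = "kernel")
}

#' Evaluate a kernel at a centre value and neighbour multiset
#'
#' @param k a \code{\link{kernel}}.
#' @param y_center centre node state (scalar).
#' @param neighbors numeric vector of neighbour states (length \eqn{p - 1},
#'   non-empty).
#' @return Scalar kernel value.
#' @export
kernel_value <- function(k, y_center, neighbors) {
  stopifnot(inherits(k, "kernel"), length(neighbors) >= 1L)
  k$evaluate(y_center, neighbors)
}

#' @export
print.kernel <- function(x, ...) {
  cat("Interaction kernel:", x$name)
  if (length(x$params))
    cat(" (", paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Assemble per-size update functions from a kernel of capped arity
#'
#' Builds the family of per-hyperedge update functions
#' \eqn{f_d(y_1, \{\{y_2,\dots,y_d\}\})} for \eqn{d = 2..k} driven by a
#' kernel of arity at most \code{p}: for \eqn{d \le p} the update is the
#' single full-arity kernel term, and for \eqn{d > p} it is the sum of the
#' \eqn{p}-ary kernel over all neighbour subsets of size \eqn{p - 1}. The
#' single-node term \eqn{f_1} is identically zero throughout the package.
#' Setting \code{p = k} yields the irreducible ("full") variant in which no
#' hyperedge update decomposes, e.g. the hypergraph Kuramoto model in which
#' the sine wraps the whole hyperedge.
#'
#' @param k_or_name a \code{\link{kernel}} or a kernel name.
#' @param p interaction order of the generating kernel (\eqn{2 \le p \le k}).
#' @param k maximum hyperedge size the family supports.
#' @param params kernel parameters, used when a name is supplied.
#' @return An object of class \code{"kernel_family"}: list with
#'   \code{kernel}, \code{p}, \code{k} and \code{f} (functions indexed by
#'   size; \code{family_f(fam, d)} retrieves one).
#' @examples
#' fam <- kernel_family("diffusion", p = 2, k = 4)
#' family_f(fam, 3)(0, c(1, 2))  # (1 - 0) + (2 - 0) = 3
#' @export
kernel_family <- function(k_or_name, p, k, params = list()) {
  kern <- if (inherits(k_or_name, "kernel")) k_or_name else
    kernel(k_or_name, params)
  stopifnot(p >= 2, p <= k)
  f <- list()
  for (d in 2:k) {
    f[[as.character(d)]] <- if (d <= p) {
      local({
        ev <- kern$evaluate
        function(y_center, neighbors) ev(y_center, neighbors)
      })
    } else {
      local({
        ev <- kern$evaluate
        sub <- subsets_of_size(d - 1L, p - 1L)
        function(y_center, neighbors) {
          tot <- 0
          for (r in seq_len(nrow(sub)))
            tot <- tot + ev(y_center, neighbors[sub[r, ]])
          tot
        }
      })
    }
  }
  structure(list(kernel = kern, p = as.integer(p), k = as.integer(k), f = f),
            class = "kernel_family")
}

#' Retrieve the size-d update function of a kernel family
#'
#' @param fam a \code{\link{kernel_family}}.
#' @param d hyperedge size in \code{2..fam$k}.
#' @return Function \code{(y_center, neighbors) -> scalar}.
#' @export
family_f <- function(fam, d) {
  stopifnot(inherits(fam, "kernel_family"))
  f <- fam$f[[as.character(d)]]
  if (is.null(f)) stop("family has no update function for size ", d, call. = FALSE)
  f
}

#' @export
print.kernel_family <- function(x, ...) {
  cat("Kernel family:", x$kernel$name, "| order p =", x$p,
      "| max size k =", x$k, "\n")
  invisible(x)
}

#' Full-arity sine update function
#'
#' The size-\eqn{d} update \eqn{f_d(y_1,\dots,y_d) =
#' \sin[\sum_{i}(y_i - y_1)]} in which the sine wraps the whole hyperedge.
#' For \eqn{d \ge 3} this function admits no pairwise decomposition, so the
#' dynamical order of a system driven by it equals the hyperedge size —
#' unlike the pairwise Kuramoto variant, which sums sines of pairwise phase
#' differences and is always reducible to order 2.
#'
#' @param d hyperedge size (\eqn{\ge 2}).
#' @return Function \code{(y_center, neighbors) -> scalar}.
#' @examples
#' full_kuramoto_f(3)(0, c(0, pi / 2))  # sin(pi/2) = 1
#' @export
full_kuramoto_f <- function(d) {
  stopifnot(d >= 2)
  function(y_center, neighbors) {
    stopifnot(length(neighbors) == d - 1L)
    sin(sum(neighbors - y_center))
  }
}

#' Pairwise kernel certifying the log-product decomposition
#'
#' For the update family \eqn{f_d(y_1,\dots,y_d) = \log(y_1 \cdots y_d)} the
#' pairwise kernel \eqn{\phi_d^2(y_1, y_i) = \log(y_1)/(d-1) + \log(y_i)}
#' reproduces \eqn{f_d} exactly when summed over all neighbours, certifying
#' dynamical order 2. The kernel depends on \eqn{d} through the splitting of
#' the centre term.
#'
#' @param d the hyperedge size whose update is being decomposed.
#' @return Function \code{(y_center, neighbors) -> scalar} (pairwise: one
#'   neighbour).
#' @export
log_product_pair_kernel <- function(d) {
  stopifnot(d >= 2)
  function(y_center, neighbors) log(y_center) / (d - 1) + log(neighbors[1L])
}
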
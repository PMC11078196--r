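#' Lifting operator for one hyperedge size
#'
#' For each size-\eqn{d} hyperedge \eqn{E_\alpha} with nodes in ascending
#' order, its indicator block is the \eqn{d \times N} 0/1 matrix whose rows
#' are the unit vectors of the edge's nodes; stacking the blocks over all
#' \eqn{M_d} hyperedges gives the sparse lifting matrix
#' \eqn{L_d \in \{0,1\}^{dM_d \times N}}. \eqn{L_d x} collects the node states
#' edge by edge, and \eqn{L_d^\top} projects per-edge updates back onto the
#' nodes by summation, so \eqn{L_d^\top L_d} is diagonal with the per-node
#' size-\eqn{d} degrees on the diagonal.
#'
#' @param H a \code{hypergraph}.
#' @param d hyperedge size (\eqn{\ge 2}). An empty size group yields a
#'   zero-row operator.
#' @return An object of class \code{"lifting_operator"}: a list with
#'   \code{size}, \code{num_edges}, \code{matrix} (a
#'   \code{\link[Matrix]{sparseMatrix}}) and \code{edge_node_order} (list of
#'   the per-edge node orderings used for the blocks).
#' @examples
#' H <- hypergraph(3, list(c(1, 2), c(2, 3)))
#' L <- lifting_matrix(H, 2)
#' Matrix::diag(Matrix::crossprod(L$matrix))  # size-2 degrees (1, 2, 1)
#' @export
lifting_matrix <- function(H, d) {
  stopifnot(inherits(H, "hypergraph"))
  if (d < 2) stop("hyperedge size must be >= 2", call. = FALSE)
  edges <- edges_of_size(H, d)
  M <- length(edges)
  cols <- if (M > 0L) unlist(edges) else integer(0)
  mat <- Matrix::sparseMatrix(
    i = seq_len(d * M), j = cols, x = 1,
    dims = c(d * M, H$num_nodes)
  )
  structure(
    list(size = as.integer(d), num_edges = M, matrix = mat,
         edge_node_order = edges),
    class = "lifting_operator"
  )
}

#' @export
print.lifting_operator <- function(x, ...) {
  cat("Lifting operator: size", x$size, "|", x$num_edges, "hyperedge(s) |",
      paste(dim(x$matrix), collapse = " x "), "matrix\n")
  invisible(x)
}
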
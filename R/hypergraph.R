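#' Construct a hypergraph from a list of hyperedges
#'
#' A hypergraph is a set of nodes \code{1..num_nodes} together with hyperedges,
#' each a set of two or more distinct nodes. Hyperedges are stored grouped by
#' cardinality \eqn{d}, with the nodes of every hyperedge kept in ascending
#' order, so that downstream operators (lifting matrices, model design
#' matrices) are deterministic.
#'
#' @param num_nodes number of nodes \eqn{N} (positive integer).
#' @param edges list of integer vectors, each a hyperedge over nodes in
#'   \code{1..num_nodes} with at least two distinct members. Duplicate
#'   hyperedges (as sets) are dropped with a warning.
#' @param labels optional character vector of length \code{num_nodes} giving
#'   the original node labels (kept by file I/O round trips).
#'
#' @return An object of class \code{"hypergraph"} with fields
#'   \code{num_nodes}, \code{edges_by_size} (a named list: element \code{"d"}
#'   is a list of sorted integer vectors of length \code{d}) and
#'   \code{labels}.
#' @examples
#' H <- hypergraph(4, list(c(1, 2), c(2, 3, 4)))
#' topological_order(H)
#' @export
hypergraph <- function(num_nodes, edges = list(), labels = NULL) {
  stopifnot(length(num_nodes) == 1L, num_nodes >= 1, num_nodes == round(num_nodes))
  num_nodes <- as.integer(num_nodes)
  if (!is.null(labels)) stopifnot(length(labels) == num_nodes)

  norm <- lapply(edges, function(e) {
    e <- sort(unique(as.integer(e)))
    if (length(e) < 2L)
      stop("hyperedge must contain at least 2 distinct nodes", call. = FALSE)
    if (any(e < 1L) || any(e > num_nodes))
      stop("hyperedge node index outside 1..num_nodes", call. = FALSE)
    e
  })

  keys <- vapply(norm, function(e) paste(e, collapse = ","), character(1))
  if (anyDuplicated(keys)) {
    warning(sum(duplicated(keys)), " duplicate hyperedge(s) dropped")
    norm <- norm[!duplicated(keys)]
  }

  sizes <- vapply(norm, length, integer(1))
  edges_by_size <- list()
  for (d in sort(unique(sizes)))
    edges_by_size[[as.character(d)]] <- norm[sizes == d]

  structure(
    list(num_nodes = num_nodes, edges_by_size = edges_by_size, labels = labels),
    class = "hypergraph"
  )
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("Hypergraph:", x$num_nodes, "nodes\n")
  if (length(x$edges_by_size) == 0L) {
    cat("  (no hyperedges)\n")
  } else {
    for (d in names(x$edges_by_size))
      cat("  size ", d, ": ", length(x$edges_by_size[[d]]), " hyperedge(s)\n",
          sep = "")
    cat("  topological order:", topological_order(x), "\n")
  }
  invisible(x)
}

#' Hyperedges of one cardinality
#'
#' @param H a \code{hypergraph}.
#' @param d hyperedge size.
#' @return List of integer vectors (possibly empty).
#' @export
edges_of_size <- function(H, d) {
  stopifnot(inherits(H, "hypergraph"))
  H$edges_by_size[[as.character(d)]] %||% list()
}

#' Number of hyperedges, optionally of one size
#'
#' @param H a \code{hypergraph}.
#' @param d hyperedge size; \code{NULL} counts all hyperedges.
#' @return Integer count.
#' @export
num_edges <- function(H, d = NULL) {
  stopifnot(inherits(H, "hypergraph"))
  if (!is.null(d)) return(length(edges_of_size(H, d)))
  sum(vapply(H$edges_by_size, length, integer(1)))
}

#' Topological order of a hypergraph
#'
#' The topological order \eqn{k} is the cardinality of the largest hyperedge.
#'
#' @param H a \code{hypergraph} with at least one hyperedge.
#' @return Integer \eqn{k \ge 2}.
#' @export
topological_order <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  sizes <- as.integer(names(H$edges_by_size))
  sizes <- sizes[vapply(H$edges_by_size, length, integer(1)) > 0L]
  if (length(sizes) == 0L) stop("hypergraph has no hyperedges", call. = FALSE)
  max(sizes)
}

#' Drop hyperedges above a maximum cardinality
#'
#' Removes every hyperedge with more than \code{k_max} members; all smaller
#' hyperedges are kept unchanged. Oversized hyperedges are dropped whole, not
#' expanded into sub-edges.
#'
#' @param H a \code{hypergraph}.
#' @param k_max maximum hyperedge size to keep (\eqn{\ge 2}).
#' @return A \code{hypergraph} of topological order at most \code{k_max}.
#' @export
truncate_to_order <- function(H, k_max) {
  stopifnot(inherits(H, "hypergraph"), k_max >= 2)
  keep <- H$edges_by_size[as.integer(names(H$edges_by_size)) <= k_max]
  out <- H
  out$edges_by_size <- keep
  out
}

#' Per-node degree within one hyperedge size
#'
#' @param H a \code{hypergraph}.
#' @param d hyperedge size.
#' @return Integer vector of length \code{num_nodes}: how many size-\code{d}
#'   hyperedges each node belongs to.
#' @export
size_degree <- function(H, d) {
  stopifnot(inherits(H, "hypergraph"))
  deg <- integer(H$num_nodes)
  for (e in edges_of_size(H, d)) deg[e] <- deg[e] + 1L
  deg
}
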
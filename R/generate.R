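#' Generate an Erdős–Rényi hypergraph
#'
#' Every candidate node subset of size \eqn{d} is included as a hyperedge
#' independently with probability \code{probs[[d]]}. All candidate subsets are
#' enumerated explicitly and one Bernoulli draw made per subset, so the
#' per-subset inclusion probabilities hold exactly; this is feasible at the
#' scales used here (e.g. \eqn{N = 20} has 190 pairs, 1140 triples and 4845
#' quadruples). The default probabilities (0.1 for pairs, 0.01 for triples,
#' 0.001 for quadruples on 20 nodes) give hypergraphs of topological order 4
#' with high probability.
#'
#' @param num_nodes number of nodes \eqn{N}; must be at least the largest
#'   subset size in \code{probs}.
#' @param probs named numeric vector (or list) mapping subset size to
#'   inclusion probability in \eqn{[0,1]}, e.g.
#'   \code{c("2" = 0.1, "3" = 0.01, "4" = 0.001)}.
#' @param seed optional integer seed; the same seed always yields the same
#'   hypergraph and the caller's RNG stream is left untouched.
#' @return A \code{\link{hypergraph}}.
#' @examples
#' H <- generate_er_hypergraph(20, seed = 1)
#' num_edges(H, 2)
#' @export
generate_er_hypergraph <- function(num_nodes,
                                   probs = c("2" = 0.1, "3" = 0.01, "4" = 0.001),
                                   seed = NULL) {
  probs <- unlist(probs)
  sizes <- as.integer(names(probs))
  if (length(sizes) == 0L || anyNA(sizes))
    stop("probs must be named by subset size, e.g. c(\"2\" = 0.1)", call. = FALSE)
  if (any(probs < 0) || any(probs > 1))
    stop("inclusion probabilities must lie in [0, 1]", call. = FALSE)
  if (any(sizes < 2))
    stop("subset sizes must be >= 2", call. = FALSE)
  if (num_nodes < max(sizes))
    stop("num_nodes must be at least the largest subset size", call. = FALSE)

  with_seed(seed, {
    edges <- list()
    for (j in order(sizes)) {
      d <- sizes[j]
      p <- probs[j]
      if (p == 0) next
      cand <- utils::combn(num_nodes, d)
      keep <- stats::rbinom(ncol(cand), 1L, p) == 1L
      if (any(keep))
        edges <- c(edges, lapply(which(keep), function(i) cand[, i]))
    }
    H <- hypergraph(num_nodes, edges)
    # record empty groups the caller asked about, so probs = c("2" = 0) still
    # yields an (empty) size-2 group
    for (d in sort(sizes)) {
      key <- as.character(d)
      if (is.null(H$edges_by_size[[key]])) H$edges_by_size[[key]] <- list()
    }
    o <- order(as.integer(names(H$edges_by_size)))
    H$edges_by_size <- H$edges_by_size[o]
    H
  })
}
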
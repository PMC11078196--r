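#' Read a hypergraph from a hyperedge-list file
#'
#' The file holds one hyperedge per line, node labels separated by whitespace
#' or commas (the SocioPatterns-style contact-list layout). Labels are mapped
#' to contiguous node indices \code{1..N} in order of first appearance; the
#' original labels are kept in the \code{labels} field so that
#' \code{\link{write_hyperedge_list}} can restore them. Duplicate hyperedges
#' are dropped with a warning; blank lines are skipped.
#'
#' @param path path to the text file.
#' @param num_nodes optional known node count (for isolated nodes that appear
#'   in no hyperedge); must be at least the number of distinct labels.
#' @param labels optional character vector fixing the label-to-index mapping
#'   (label \code{labels[i]} becomes node \code{i}); unknown labels in the
#'   file are an error. Used when node identities must line up with external
#'   per-node data.
#' @return A \code{\link{hypergraph}}.
#' @export
read_hyperedge_list <- function(path, num_nodes = NULL, labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) {
    t <- strsplit(trimws(l), "[,[:space:]]+")[[1]]
    t[nzchar(t)]
  })
  nonempty <- which(lengths(toks) > 0L)
  for (i in nonempty) {
    if (length(unique(toks[[i]])) < 2L)
      stop("line ", i, ": hyperedge has fewer than 2 distinct labels",
           call. = FALSE)
  }
  seen <- unique(unlist(toks[nonempty]))
  if (!is.null(labels)) {
    unknown <- setdiff(seen, labels)
    if (length(unknown))
      stop("labels not in the supplied label universe: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  } else {
    labels <- seen
  }
  if (is.null(num_nodes)) {
    num_nodes <- length(labels)
  } else if (num_nodes < length(labels)) {
    stop("num_nodes smaller than the number of distinct labels", call. = FALSE)
  }
  if (num_nodes > length(labels))
    labels <- c(labels, paste0(".isolated", seq_len(num_nodes - length(labels))))
  edges <- lapply(toks[nonempty], function(t) match(unique(t), labels))
  hypergraph(num_nodes, edges, labels = labels)
}

#' Write a hypergraph as a hyperedge-list file
#'
#' One hyperedge per line, labels separated by single spaces. Original labels
#' are used when the hypergraph carries them (e.g. after
#' \code{\link{read_hyperedge_list}}); otherwise node indices are written.
#' Writing then reading reproduces the hypergraph up to within-edge ordering.
#'
#' @param H a \code{hypergraph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hyperedge_list <- function(H, path) {
  stopifnot(inherits(H, "hypergraph"))
  labels <- H$labels %||% as.character(seq_len(H$num_nodes))
  lines <- unlist(lapply(H$edges_by_size, function(grp)
    vapply(grp, function(e) paste(labels[e], collapse = " "), character(1))))
  writeLines(lines %||% character(0), path)
  invisible(path)
}
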
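# Internal batched "design" structure for the learnable model.
#
# The symmetrized per-edge update f_hat_d(y_1, s) equals the sum over all
# unordered neighbour subsets v of size p_in - 1 of the order-averaged MLP on
# (y_1, v): averaging the ordered-subset sum over all (d-1)! permutations of
# the neighbour multiset collapses, by a counting argument, to
#   f_hat_d(y_1, s) = (1/(p_in-1)!) * sum over subsets v, orderings of v of
#                     MLP_d^{p_in}(y_1, v_ordered).
# (Each ordered (p_in-1)-tuple of distinct neighbours appears in
# C(d-1, p_in-1) * (d-p_in)! of the (d-1)! permutation terms.)
# We therefore materialize one input row per (edge, centre, subset, ordering)
# tuple, run each per-size MLP once over its stacked rows, and scatter-add
# the outputs (weighted by 1/(p_in-1)!) back onto the centre nodes with a
# sparse projection matrix. The exhaustive permutation average is retained
# in symmetric_eval()'s documentation contract and checked against this fast
# path in the tests.

# Row templates per (d, p_in): index matrix into a d-vector (position 1 is
# the centre) with columns [centre, neighbour subset ordering...].
row_template <- function(d, p_in) {
  nb <- seq_len(d - 1L)                          # neighbour slots
  sub <- subsets_of_size(d - 1L, p_in - 1L)      # unordered subsets
  per <- permutations(p_in - 1L)                 # orderings within a subset
  rows <- matrix(0L, nrow(sub) * nrow(per), p_in - 1L)
  r <- 0L
  for (s in seq_len(nrow(sub)))
    for (q in seq_len(nrow(per))) {
      r <- r + 1L
      rows[r, ] <- sub[s, per[q, ], drop = TRUE]
    }
  rows  # indices into the neighbour vector (1..d-1)
}

# Template for one hypergraph: local (within-sample) node index rows.
# Returns list(idx = R x p_in matrix of node indices, tgt = centre node per
# row) for one hyperedge size.
hg_template <- function(H, d, p_in) {
  edges <- edges_of_size(H, d)
  if (length(edges) == 0L)
    return(list(idx = matrix(integer(0), 0L, p_in), tgt = integer(0)))
  tmpl <- row_template(d, p_in)
  per_center <- nrow(tmpl)
  R <- length(edges) * d * per_center
  idx <- matrix(0L, R, p_in)
  tgt <- integer(R)
  r <- 0L
  for (e in edges) {
    for (pos in seq_len(d)) {
      nb <- e[-pos]
      rows <- r + seq_len(per_center)
      idx[rows, 1L] <- e[pos]
      if (p_in > 1L)
        idx[rows, -1L] <- matrix(nb[tmpl], per_center, p_in - 1L)
      tgt[rows] <- e[pos]
      r <- r + per_center
    }
  }
  list(idx = idx, tgt = tgt)
}

# Full design over a sample batch. hgs: list of hypergraphs; hg_id: which
# hypergraph each of the S samples uses; N: nodes per sample. Flat state
# layout: sample s, node i -> (s-1)*N + i.
build_design <- function(hgs, hg_id, N, k, p_model) {
  S <- length(hg_id)
  out <- list()
  for (d in 2:k) {
    p_in <- min(p_model, d)
    tmpls <- lapply(hgs, hg_template, d = d, p_in = p_in)
    nrows <- vapply(tmpls, function(t) nrow(t$idx), integer(1))
    total <- sum(nrows[hg_id])
    if (total == 0L) next
    idx <- matrix(0L, total, p_in)
    tgt <- integer(total)
    row_sample <- integer(total)
    r <- 0L
    for (s in seq_len(S)) {
      t <- tmpls[[hg_id[s]]]
      n <- nrow(t$idx)
      if (n == 0L) next
      rows <- r + seq_len(n)
      off <- (s - 1L) * N
      idx[rows, ] <- t$idx + off
      tgt[rows] <- t$tgt + off
      row_sample[rows] <- s
      r <- r + n
    }
    w <- 1 / factorial(p_in - 1L)
    P <- Matrix::sparseMatrix(i = tgt, j = seq_len(total), x = w,
                              dims = c(S * N, total))
    out[[as.character(d)]] <- list(d = d, p_in = p_in, idx = idx, tgt = tgt,
                                   row_sample = row_sample, w = w, P = P)
  }
  attr(out, "S") <- S
  attr(out, "N") <- N
  out
}

# Restrict a design to a subset of samples (rows kept, scatter matrix
# rebuilt over the same full flat layout so predictions stay comparable).
design_subset_rows <- function(blk, samples) {
  keep <- blk$row_sample %in% samples
  list(idx = blk$idx[keep, , drop = FALSE], tgt = blk$tgt[keep])
}

# Predicted flat derivative vector for a batch given flat states xf.
design_forward <- function(design, nets, xf) {
  pred <- numeric(attr(design, "S") * attr(design, "N"))
  for (blk in design) {
    if (nrow(blk$idx) == 0L) next
    X <- xf[blk$idx]
    dim(X) <- dim(blk$idx)
    net <- nets[[as.character(blk$d)]]
    out <- net_apply(net, X)
    pred <- pred + as.numeric(blk$P %*% out)
  }
  pred
}

# Apply an approximator (MLP or frozen function) to a batch matrix.
net_apply <- function(net, X) {
  if (net$type == "mlp") mlp_forward(net, X)
  else net$fn(X)
}
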
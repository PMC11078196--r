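# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded package functions do not perturb
# the global stream. `seed = NULL` uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# All permutations of 1..n as a matrix with one permutation per row (n! rows).
# Only needed for small n: neighbor multisets have at most k - 1 <= 4 members.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    idx <- seq_len(nrow(sub)) + r
    out[idx, pos] <- n
    out[idx, -pos] <- sub
    r <- r + nrow(sub)
  }
  out
}

# All size-m subsets of 1..n, one subset per row, in lexicographic order.
subsets_of_size <- function(n, m) {
  if (m == 0L) return(matrix(integer(0), 1L, 0L))
  t(utils::combn(n, m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
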
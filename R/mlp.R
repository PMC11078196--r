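# Internal multilayer perceptron used for the per-size update approximators.
# Plain matrix code: layers are dense, hidden activations tanh, output linear
# and scalar. Forward/backward operate on a whole batch (rows = inputs) so an
# epoch is a handful of BLAS calls.

mlp_init <- function(n_in, hidden = c(32, 32)) {
  sizes <- c(n_in, hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    a <- sqrt(6 / (sizes[l] + sizes[l + 1L]))  # Glorot-uniform for tanh nets
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -a, a),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  # damp the scalar output layer: a near-zero initial field keeps the early
  # L1 descent direction consistent across initializations, which markedly
  # reduces run-to-run variance of the converged loss
  W[[length(W)]] <- W[[length(W)]] * 0.1
  list(type = "mlp", sizes = sizes, W = W, b = b)
}

# X: batch matrix (R x n_in). Returns list(out, cache) when cache = TRUE.
mlp_forward <- function(net, X, cache = FALSE) {
  A <- X
  acts <- if (cache) vector("list", length(net$W)) else NULL
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    if (cache) acts[[l]] <- A
    Z <- A %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    A <- if (l < nl) tanh(Z) else Z
  }
  out <- as.numeric(A)
  if (cache) list(out = out, acts = acts) else out
}

# g_out: dLoss/d(out), length R. Returns gradients in the shape of W/b.
mlp_backward <- function(net, acts, g_out) {
  nl <- length(net$W)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  G <- matrix(g_out, ncol = 1L)
  for (l in rev(seq_len(nl))) {
    A <- acts[[l]]
    gW[[l]] <- crossprod(A, G)
    gb[[l]] <- colSums(G)
    if (l > 1L) {
      G <- G %*% t(net$W[[l]])
      # A was the tanh output of layer l-1, so tanh'(z) = 1 - A^2
      G <- G * (1 - A * A)
    }
  }
  list(W = gW, b = gb)
}

mlp_num_params <- function(net)
  sum(vapply(net$W, length, numeric(1))) + sum(vapply(net$b, length, numeric(1)))

mlp_param_sq_norm <- function(net)
  sum(vapply(net$W, function(w) sum(w * w), numeric(1))) +
  sum(vapply(net$b, function(v) sum(v * v), numeric(1)))

# --- Adam optimizer state over a list of nets -------------------------------

adam_init <- function(nets) {
  lapply(nets, function(net) {
    if (net$type != "mlp") return(NULL)
    list(mW = lapply(net$W, function(w) w * 0),
         vW = lapply(net$W, function(w) w * 0),
         mb = lapply(net$b, function(v) v * 0),
         vb = lapply(net$b, function(v) v * 0))
  })
}

adam_step <- function(net, st, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grads$W[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grads$b[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, state = st)
}
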
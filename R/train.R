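#' Training configuration
#'
#' Bundles the optimizer and regularization settings for
#' \code{\link{train_hydygnn}}. Defaults: Adam with learning rate
#' \code{1e-3}, full-batch gradients, 2000 epochs, squared-L2 penalty
#' \code{1e-5}. When \code{lambda_grid} holds more than one value, the
#' penalty weight is chosen by a hyperparameter search on a validation split
#' (one fifth of the hypergraphs) before the final fit on all data. The
#' scaled-down experiment presets in \code{\link{run_experiment}} use fewer
#' epochs and a higher learning rate; the package vignette discusses the
#' trade-off.
#'
#' @param epochs number of optimization epochs.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size in samples; \code{NULL} = full batch.
#' @param l2_lambda squared-L2 penalty weight \eqn{\lambda \ge 0}.
#' @param lambda_grid candidate \eqn{\lambda} values for the search
#'   (defaults to just \code{l2_lambda}).
#' @param hidden hidden-layer widths of each approximator.
#' @param val_fraction fraction of hypergraphs held out for early stopping;
#'   0 disables early stopping.
#' @param patience early-stopping patience in validation checks (validation
#'   loss is checked every \code{eval_every} epochs).
#' @param eval_every epochs between validation checks.
#' @param rng_seed seed for weight initialization and batch shuffling.
#' @return A list of class \code{"train_config"}.
#' @export
train_config <- function(epochs = 2000, learning_rate = 1e-3,
                         batch_size = NULL, l2_lambda = 1e-5,
                         lambda_grid = NULL, hidden = c(32, 32),
                         val_fraction = 0, patience = 10, eval_every = 25,
                         rng_seed = NULL) {
  stopifnot(l2_lambda >= 0, epochs >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = batch_size, l2_lambda = l2_lambda,
                 lambda_grid = lambda_grid %||% l2_lambda,
                 hidden = as.integer(hidden),
                 val_fraction = val_fraction, patience = patience,
                 eval_every = as.integer(eval_every), rng_seed = rng_seed),
            class = "train_config")
}

#' Fit a HyDy-GNN to a training set
#'
#' Minimizes the regularized L1 loss (\code{\link{model_loss}}) with Adam.
#' Gradients are exact subgradients of the L1 term plus the weight-decay
#' gradient; full-batch by default, mini-batched when
#' \code{cfg$batch_size} is set. If \code{cfg$lambda_grid} holds several
#' penalty weights, each candidate is trained against a validation split of
#' the hypergraphs and the weight with the lowest validation mean absolute
#' error is used for the final fit on the full data.
#'
#' @param model a \code{\link{hydygnn}} (its weights are the starting
#'   point), or \code{NULL} to initialize one of order \code{p_model}.
#' @param ts a \code{\link{training_set}}.
#' @param cfg a \code{\link{train_config}}.
#' @param p_model model order used when \code{model} is \code{NULL}.
#' @param verbose print the loss every \code{cfg$eval_every} epochs.
#' @return The fitted \code{"hydygnn"} with attributes \code{"log"} (data
#'   frame of per-epoch training loss) and \code{"l2_lambda"} (the penalty
#'   weight used).
#' @export
train_hydygnn <- function(model = NULL, ts, cfg = train_config(),
                          p_model = NULL, verbose = FALSE) {
  stopifnot(inherits(ts, "training_set"))
  k <- ts$meta$k %||% max(vapply(ts$hypergraphs, topological_order, integer(1)))
  if (is.null(model)) {
    stopifnot(!is.null(p_model))
    model <- hydygnn(k, p_model, hidden = cfg$hidden, seed = cfg$rng_seed)
  }

  grid <- unique(cfg$lambda_grid)
  if (length(grid) > 1L) {
    # hyperparameter search: hold out ~1/5 of the hypergraphs
    n_hg <- length(ts$hypergraphs)
    val_hg <- with_seed(cfg$rng_seed,
                        sample(n_hg, max(1L, floor(n_hg / 5))))
    val_idx <- which(ts$hg_id %in% val_hg)
    tr <- subset_training_set(ts, setdiff(seq_len(num_samples(ts)), val_idx))
    va <- subset_training_set(ts, val_idx)
    val_mae <- vapply(grid, function(lam) {
      cfg_i <- cfg
      cfg_i$lambda_grid <- cfg_i$l2_lambda <- lam
      m <- train_hydygnn(model, tr, cfg_i, verbose = FALSE)
      mean(vapply(seq_len(num_samples(va)), function(s) {
        H <- va$hypergraphs[[va$hg_id[s]]]
        mean(abs(model_forward(m, H, va$states[s, ]) - va$derivs[s, ]))
      }, numeric(1)))
    }, numeric(1))
    best <- grid[which.min(val_mae)]
    cfg$lambda_grid <- cfg$l2_lambda <- best
    if (verbose)
      message("lambda search: chose ", best, " (val MAE ",
              signif(min(val_mae), 4), ")")
  }

  fit_adam(model, ts, cfg, verbose)
}

fit_adam <- function(model, ts, cfg, verbose = FALSE) {
  N <- ncol(ts$states)
  S <- num_samples(ts)
  lam <- cfg$l2_lambda

  val_idx <- integer(0)
  if (cfg$val_fraction > 0) {
    n_hg <- length(ts$hypergraphs)
    val_hg <- with_seed(cfg$rng_seed,
                        sample(n_hg, max(1L, floor(n_hg * cfg$val_fraction))))
    val_idx <- which(ts$hg_id %in% val_hg)
  }
  fit_idx <- setdiff(seq_len(S), val_idx)

  design <- build_design(ts$hypergraphs, ts$hg_id, N, model$k, model$p_model)
  # per-sample design-row index, for fast mini-batch row selection
  rows_by_sample <- lapply(design, function(blk)
    split(seq_along(blk$row_sample), blk$row_sample))
  xf <- as.numeric(t(ts$states))
  yf <- as.numeric(t(ts$derivs))
  node_of <- function(samples) rep((samples - 1L) * N, each = N) + seq_len(N)
  fit_nodes <- node_of(fit_idx)

  nets <- model$nets
  opt <- adam_init(nets)
  t_adam <- 0L
  log_loss <- numeric(cfg$epochs)
  n_ep <- 0L
  best <- NULL
  best_val <- Inf
  stall <- 0L

  run_epoch <- function(batch_samples) {
    # forward + L1 subgradient on the batch nodes, then one Adam step per net
    batch_nodes <- node_of(batch_samples)
    pred <- numeric(S * N)
    caches <- list()
    Xs <- list()
    rows <- list()
    for (dch in names(design)) {
      blk <- design[[dch]]
      keep <- if (length(batch_samples) == S) seq_len(nrow(blk$idx)) else
        unlist(rows_by_sample[[dch]][as.character(batch_samples)],
               use.names = FALSE)
      if (length(keep) == 0L) next
      idx <- blk$idx[keep, , drop = FALSE]
      X <- xf[idx]
      dim(X) <- dim(idx)
      fw <- mlp_forward(nets[[dch]], X, cache = TRUE)
      # scatter-add weighted outputs onto centre nodes
      contrib <- rowsum(fw$out * blk$w, blk$tgt[keep])
      at <- as.integer(rownames(contrib))
      pred[at] <- pred[at] + contrib[, 1L]
      caches[[dch]] <- fw$acts
      Xs[[dch]] <- X
      rows[[dch]] <- keep
    }
    resid <- pred[batch_nodes] - yf[batch_nodes]
    gflat <- numeric(S * N)
    gflat[batch_nodes] <- sign(resid)
    t_adam <<- t_adam + 1L
    lr <- cfg$learning_rate * lr_scale
    for (dch in names(caches)) {
      blk <- design[[dch]]
      keep <- rows[[dch]]
      g_out <- gflat[blk$tgt[keep]] * blk$w
      grads <- mlp_backward(nets[[dch]], caches[[dch]], g_out)
      if (lam > 0) {
        for (l in seq_along(grads$W)) {
          grads$W[[l]] <- grads$W[[l]] + 2 * lam * nets[[dch]]$W[[l]]
          grads$b[[l]] <- grads$b[[l]] + 2 * lam * nets[[dch]]$b[[l]]
        }
      }
      st <- adam_step(nets[[dch]], opt[[dch]], grads, lr, t_adam)
      nets[[dch]] <<- st$net
      opt[[dch]] <<- st$state
    }
    sum(abs(resid))
  }

  eval_mae <- function(samples) {
    nodes <- node_of(samples)
    pred <- design_forward(design, nets, xf)
    mean(abs(pred[nodes] - yf[nodes]))
  }

  lr_scale <- 1
  with_seed(cfg$rng_seed, {
    for (ep in seq_len(cfg$epochs)) {
      # L1 subgradients do not vanish at the optimum, so anneal the step
      # size: x0.3 at 50%, 75% and 90% of the epoch budget
      lr_scale <- 0.3^findInterval(ep / cfg$epochs, c(0.5, 0.75, 0.9))
      if (is.null(cfg$batch_size) || cfg$batch_size >= length(fit_idx)) {
        l1 <- run_epoch(fit_idx)
      } else {
        sh <- sample(fit_idx)
        l1 <- 0
        for (b in split(sh, ceiling(seq_along(sh) / cfg$batch_size)))
          l1 <- l1 + run_epoch(b)
      }
      if (!is.finite(l1))
        stop("training loss diverged (non-finite) at epoch ", ep, call. = FALSE)
      log_loss[ep] <- l1
      n_ep <- ep
      if (length(val_idx) && ep %% cfg$eval_every == 0L) {
        vm <- eval_mae(val_idx)
        if (vm < best_val - 1e-12) {
          best_val <- vm
          best <- nets
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$patience) break
        }
      }
      if (verbose && ep %% cfg$eval_every == 0L)
        message("epoch ", ep, ": L1 = ", signif(l1, 5))
    }
  })

  model$nets <- if (!is.null(best)) best else nets
  attr(model, "log") <- data.frame(epoch = seq_len(n_ep),
                                   l1_loss = log_loss[seq_len(n_ep)])
  attr(model, "l2_lambda") <- lam
  model
}
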
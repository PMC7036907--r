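# ---------------------------------------------------------------------------
# Focal-loss objective and the Adam training loop.
# ---------------------------------------------------------------------------

FOCAL_EPS <- 1e-7

#' Focal loss
#'
#' The class-balanced focal loss for binary targets:
#' `-alpha * (1 - p)^gamma * log(p)` when `y = 1` and
#' `-(1 - alpha) * p^gamma * log(1 - p)` when `y = 0` (natural logarithm).
#' With `gamma = 0` it reduces to (alpha-scaled) cross entropy; larger
#' `gamma` down-weights easy examples, which counteracts extreme class
#' imbalance. Probabilities are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param y Binary targets (0/1), any shape.
#' @param y_hat Predicted probabilities, same shape.
#' @param gamma Focusing parameter, >= 0 (default 2).
#' @param alpha Positive-class balance weight in \[0, 1\] (default 0.5).
#' @return Element-wise non-negative losses, same shape as `y`.
#' @export
focal_loss <- function(y, y_hat, gamma = 2, alpha = 0.5) {
  if (!all(y %in% c(0, 1))) {
    stop("focal_loss: y must be binary (0/1)", call. = FALSE)
  }
  stopifnot(gamma >= 0, alpha >= 0, alpha <= 1,
            length(y) == length(y_hat))
  p <- pmin(pmax(y_hat, FOCAL_EPS), 1 - FOCAL_EPS)
  out <- ifelse(y == 1,
                -alpha * (1 - p)^gamma * log(p),
                -(1 - alpha) * p^gamma * log(1 - p))
  if (!is.null(dim(y_hat))) dim(out) <- dim(y_hat)
  out
}

#' Mean focal loss over a prediction matrix
#'
#' @param y_matrix Binary target matrix (samples x tasks).
#' @param y_hat_matrix Probability matrix, same shape.
#' @inheritParams focal_loss
#' @return Scalar mean of the element-wise focal losses.
#' @export
batch_loss <- function(y_matrix, y_hat_matrix, gamma = 2, alpha = 0.5) {
  y <- as.matrix(y_matrix); p <- as.matrix(y_hat_matrix)
  if (!all(dim(y) == dim(p))) {
    stop("batch_loss: shape mismatch", call. = FALSE)
  }
  mean(focal_loss(y, p, gamma, alpha))
}

# d(mean focal loss)/d(y_hat), element-wise; zero where the clamp is active
.focal_loss_grad <- function(y, y_hat, gamma, alpha) {
  p <- pmin(pmax(y_hat, FOCAL_EPS), 1 - FOCAL_EPS)
  gpos <- if (gamma == 0) {
    -alpha / p
  } else {
    alpha * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p)
  }
  gneg <- if (gamma == 0) {
    (1 - alpha) / (1 - p)
  } else {
    -(1 - alpha) * (gamma * p^(gamma - 1) * log(1 - p) - p^gamma / (1 - p))
  }
  g <- ifelse(y == 1, gpos, gneg)
  g[y_hat < FOCAL_EPS | y_hat > 1 - FOCAL_EPS] <- 0
  g / length(y)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: 3 hidden layers of width 1024,
#' batch size 64, 200 epochs, Adam with learning rate 0.0005, focal-loss
#' gamma 2 and alpha 0.5.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param gamma,alpha Focal-loss parameters.
#' @param depth,width Network architecture.
#' @param seed Integer seed governing initialization and shuffling.
#' @param tied Tie self/neighbour convolution matrices (see [gcn_params()]).
#' @return A `fit_config` list.
#' @export
fit_config <- function(learning_rate = 0.0005, batch_size = 64L,
                       epochs = 200L, gamma = 2, alpha = 0.5,
                       depth = 3L, width = 1024L, seed = 1L, tied = TRUE) {
  stopifnot(gamma >= 0, alpha >= 0, alpha <= 1, epochs >= 0,
            batch_size >= 1, depth >= 1, width >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), gamma = gamma, alpha = alpha,
                 depth = as.integer(depth), width = as.integer(width),
                 seed = as.integer(seed), tied = tied),
            class = "fit_config")
}

# ---- Adam on the nested parameter list --------------------------------------

.grad_leaves <- function(params) {
  # addresses of trainable tensors (running stats are not trained)
  leaves <- list()
  for (t in seq_along(params$conv)) {
    for (d in seq_along(params$conv[[t]]$W)) {
      leaves[[length(leaves) + 1L]] <- c("conv", t, "W", d)
      leaves[[length(leaves) + 1L]] <- c("conv", t, "b", d)
      if (!is.null(params$conv[[t]]$W_self)) {
        leaves[[length(leaves) + 1L]] <- c("conv", t, "W_self", d)
      }
    }
    leaves[[length(leaves) + 1L]] <- c("bn", t, "gamma")
    leaves[[length(leaves) + 1L]] <- c("bn", t, "beta")
  }
  for (d in seq_along(params$gather$Phi)) {
    leaves[[length(leaves) + 1L]] <- c("gather", "Phi", d)
  }
  leaves[[length(leaves) + 1L]] <- c("gather", "beta")
  leaves[[length(leaves) + 1L]] <- c("head", "W")
  leaves[[length(leaves) + 1L]] <- c("head", "b")
  leaves
}

.pluck <- function(x, path) {
  for (p in path) x <- x[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
  x
}

.poke <- function(x, path, value) {
  p <- if (grepl("^[0-9]+$", path[1])) as.integer(path[1]) else path[1]
  if (length(path) == 1L) {
    x[[p]] <- value
  } else {
    x[[p]] <- .poke(x[[p]], path[-1], value)
  }
  x
}

.adam_init <- function(params, leaves) {
  lapply(leaves, function(path) {
    v <- .pluck(params, path)
    list(m = v * 0, v = v * 0)
  })
}

.adam_step <- function(params, grads, state, leaves, lr, step,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(leaves)) {
    path <- leaves[[i]]
    g <- .pluck(grads, path)
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[i]] <- st
    mhat <- st$m / (1 - beta1^step)
    vhat <- st$v / (1 - beta2^step)
    val <- .pluck(params, path) - lr * mhat / (sqrt(vhat) + eps)
    params <- .poke(params, path, val)
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------
# Fit loop
# ---------------------------------------------------------------------------

#' Train the multi-task GCN
#'
#' Runs mini-batch Adam on the mean focal loss over shuffled training
#' batches, records per-epoch mean training loss and validation macro
#' ROC-AUC, and returns the parameters from the epoch with the best
#' validation macro-AUC. Deterministic for a given seed.
#'
#' @param graphs List of `mol_graph`s for the full dataset.
#' @param labels A [label_matrix()] (rows parallel to `graphs`).
#' @param split A [split_result] from one of the splitting functions.
#' @param config A [fit_config()].
#' @param verbose Print one line per epoch.
#' @param log_file Optional path; per-epoch lines are appended there.
#' @return A `gcn_fit` list: `params` (best-epoch `gcn_params`), `history`
#'   (data frame epoch/train_loss/valid_macro_auc), `best_epoch`, `config`.
#' @export
fit_gcn <- function(graphs, labels, split, config = fit_config(),
                    verbose = FALSE, log_file = NULL) {
  stopifnot(inherits(labels, "label_matrix"))
  y <- labels$labels
  stopifnot(length(graphs) == nrow(y))
  tr <- split$train; va <- split$valid
  stopifnot(all(tr >= 1), all(tr <= length(graphs)))
  pos_tr <- colSums(y[tr, , drop = FALSE])
  neg_tr <- colSums(1 - y[tr, , drop = FALSE])
  if (!any(pos_tr >= 1 & neg_tr >= 1)) {
    stop("fit_gcn: no task has both positives and negatives in training",
         call. = FALSE)
  }
  zero_pos <- labels$task_names[pos_tr == 0]
  if (length(zero_pos)) {
    warning("tasks with zero training positives: ",
            paste(zero_pos, collapse = ", "))
  }
  set.seed(config$seed)
  params <- gcn_params(ncol(graphs[[1]]$atom_features), ncol(y),
                       depth = config$depth, width = config$width,
                       tied = config$tied)
  leaves <- .grad_leaves(params)
  adam <- .adam_init(params, leaves)
  valid_batch <- if (length(va)) graph_batch(graphs[va]) else NULL
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        valid_macro_auc = numeric(0))
  best_auc <- -Inf; best_params <- params; best_epoch <- 0L
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- tr[sample.int(length(tr))]
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    # a trailing singleton molecule could still be >= 2 atoms; batches are
    # atom-level for BN so this is safe for any real molecule
    epoch_losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      batch <- graph_batch(graphs[idx])
      cache <- .gcn_forward_impl(params, batch, mode = "train",
                                 keep_cache = TRUE)
      params <- cache$params               # running stats updated
      yb <- y[idx, , drop = FALSE]
      epoch_losses[bi] <- batch_loss(yb, cache$probs,
                                     config$gamma, config$alpha)
      dP <- .focal_loss_grad(yb, cache$probs, config$gamma, config$alpha)
      grads <- .gcn_backward(cache, dP)
      step <- step + 1L
      upd <- .adam_step(params, grads, adam, leaves,
                        config$learning_rate, step)
      params <- upd$params; adam <- upd$state
    }
    v_auc <- NA_real_
    if (!is.null(valid_batch)) {
      pv <- .gcn_forward_impl(params, valid_batch, mode = "eval")$probs
      aucs <- vapply(seq_len(ncol(y)), function(k) {
        yk <- y[va, k]
        if (min(yk) == max(yk)) NA_real_ else roc_auc(yk, pv[, k])
      }, numeric(1))
      v_auc <- if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(epoch_losses),
      valid_macro_auc = v_auc))
    line <- sprintf("epoch %d loss %.6f valid_macro_auc %s", epoch,
                    mean(epoch_losses),
                    if (is.na(v_auc)) "NA" else sprintf("%.4f", v_auc))
    if (verbose) message(line)
    if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
    if (!is.na(v_auc) && v_auc > best_auc) {
      best_auc <- v_auc; best_params <- params; best_epoch <- epoch
    }
  }
  if (!is.finite(best_auc)) { best_params <- params; best_epoch <- config$epochs }
  structure(list(params = best_params, history = history,
                 best_epoch = best_epoch, config = config),
            class = "gcn_fit")
}

#' @export
print.gcn_fit <- function(x, ...) {
  cat("gcn_fit:", nrow(x$history), "epochs; best epoch", x$best_epoch, "\n")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat("  final train loss", sprintf("%.5f", last$train_loss),
        "valid macro AUC",
        if (is.na(last$valid_macro_auc)) "NA"
        else sprintf("%.4f", last$valid_macro_auc), "\n")
  }
  invisible(x)
}
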
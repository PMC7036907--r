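# ---------------------------------------------------------------------------
# Degree-indexed graph convolutional network.
#
# Per hidden layer: graph convolution with weights shared by node degree
# (clipped to 0..6), ReLU, node-level batch normalization over all atoms in
# the batch, then neighbourhood max-pooling over each atom's closed
# neighbourhood. A degree-weighted gather layer sums transformed atom
# vectors into one tanh graph embedding per molecule, followed by a dense
# multi-task sigmoid head.
#
# The convolution applies the SAME degree-indexed matrix to the centre atom
# and the neighbour sum, W_d (h(v) + sum_u h(u)) + b_d, as printed; set
# `tied = FALSE` in gcn_params() for separate self/neighbour matrices.
# ---------------------------------------------------------------------------

MAX_DEGREE <- 6L

.runif_mat <- function(nr, nc, fan_in) {
  s <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialize GCN parameters
#'
#' Weights are scaled-uniform (fan-in based) draws from the current RNG
#' stream; biases are zero; batch-norm scale/shift start at 1/0 with running
#' mean 0 and variance 1. Degree-indexed collections cover degrees 0..6
#' (higher degrees are clipped to 6 when indexing).
#'
#' @param feature_dim Input atom-feature width.
#' @param n_tasks Number of output tasks.
#' @param depth Number of hidden (convolution + pooling) layers.
#' @param width Hidden width (also the gather embedding width).
#' @param seed Optional integer; when given, seeds the RNG before drawing.
#' @param tied Use one matrix for self and neighbour terms (the printed
#'   form); `FALSE` adds a separate self matrix per degree.
#' @return A `gcn_params` object.
#' @export
gcn_params <- function(feature_dim, n_tasks, depth = 3L, width = 1024L,
                       seed = NULL, tied = TRUE) {
  stopifnot(depth >= 1, width >= 1, n_tasks >= 1)
  if (!is.null(seed)) set.seed(seed)
  nd <- MAX_DEGREE + 1L
  conv <- vector("list", depth)
  bn <- vector("list", depth)
  in_dim <- feature_dim
  for (t in seq_len(depth)) {
    lay <- list(W = lapply(seq_len(nd), function(d) .runif_mat(width, in_dim, in_dim)),
                b = lapply(seq_len(nd), function(d) numeric(width)))
    if (!tied) {
      lay$W_self <- lapply(seq_len(nd),
                           function(d) .runif_mat(width, in_dim, in_dim))
    }
    conv[[t]] <- lay
    bn[[t]] <- list(gamma = rep(1, width), beta = numeric(width),
                    running_mean = numeric(width), running_var = rep(1, width))
    in_dim <- width
  }
  gather <- list(Phi = lapply(seq_len(nd), function(d) .runif_mat(width, width, width)),
                 beta = numeric(width))
  head <- list(W = .runif_mat(n_tasks, width, width), b = numeric(n_tasks))
  structure(list(conv = conv, bn = bn, gather = gather, head = head,
                 feature_dim = feature_dim, n_tasks = n_tasks,
                 depth = depth, width = width, tied = tied),
            class = "gcn_params")
}

#' @export
print.gcn_params <- function(x, ...) {
  cat("gcn_params: depth", x$depth, "width", x$width, "tasks", x$n_tasks,
      if (x$tied) "(tied self/neighbour)" else "(untied)", "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Batch assembly: concatenate molecules into one atom table
# ---------------------------------------------------------------------------

#' Assemble molecules into a batched graph
#'
#' Concatenates a list of `mol_graph`s into one atom table with a sparse
#' adjacency matrix, per-(clipped-)degree atom index groups for the
#' degree-indexed affine transforms, and closed-neighbourhood index tables
#' for max-pooling.
#'
#' @param graphs A list of `mol_graph` objects (or a single one).
#' @return A `graph_batch` object.
#' @export
graph_batch <- function(graphs) {
  if (inherits(graphs, "graph_batch")) return(graphs)
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  n_atoms <- vapply(graphs, `[[`, integer(1), "n_atoms")
  offsets <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  N <- sum(n_atoms)
  X <- do.call(rbind, lapply(graphs, `[[`, "atom_features"))
  mol_id <- rep(seq_along(graphs), n_atoms)
  deg <- unlist(lapply(graphs, `[[`, "degrees"), use.names = FALSE)
  nbr_flat <- unlist(lapply(seq_along(graphs), function(m) {
    unlist(graphs[[m]]$neighbors, use.names = FALSE) + offsets[m]
  }), use.names = FALSE)
  src <- rep(seq_len(N), deg)
  adj <- Matrix::sparseMatrix(i = src, j = nbr_flat, x = 1, dims = c(N, N))
  dclip <- pmin(deg, MAX_DEGREE)
  deg_idx <- lapply(0:MAX_DEGREE, function(d) which(dclip == d))
  # pooling groups use the true degree (all neighbours participate)
  ptr <- c(0L, cumsum(deg))               # nbr_flat slice per atom
  pool <- lapply(sort(unique(deg)), function(d) {
    idx <- which(deg == d)
    nbr <- if (d > 0) {
      pos <- sequence(rep(d, length(idx)), from = ptr[idx] + 1L)
      matrix(nbr_flat[pos], nrow = length(idx), ncol = d, byrow = TRUE)
    } else NULL
    list(d = d, idx = idx, nbr = nbr)
  })
  structure(list(X = X, mol_id = mol_id, n_mols = length(graphs),
                 n_atoms_total = N, deg = deg, deg_idx = deg_idx,
                 adj = adj, pool = pool),
            class = "graph_batch")
}

# ---------------------------------------------------------------------------
# Layer operations (each also usable standalone on a single molecule)
# ---------------------------------------------------------------------------

.as_state <- function(state) {
  if (is.null(dim(state))) matrix(state, nrow = 1) else as.matrix(state)
}

#' Degree-indexed graph convolution
#'
#' For each atom v with clipped degree d:
#' `out(v) = ReLU(W_d (h(v) + sum_u h(u)) + b_d)` over the neighbours u of
#' v; degree-0 atoms use an empty neighbour sum. With untied parameters the
#' self term uses `W_self_d`.
#'
#' @param state Numeric matrix, one row per atom.
#' @param graph A `mol_graph` or `graph_batch`.
#' @param layer_params List with `W` and `b` (length-7 lists, degree 0..6),
#'   optionally `W_self`.
#' @param layer Layer index used in error messages.
#' @return Matrix of activations, one row per atom.
#' @export
graph_conv <- function(state, graph, layer_params, layer = 1L) {
  batch <- graph_batch(graph)
  H <- .as_state(state)
  in_dim <- ncol(layer_params$W[[1]])
  if (ncol(H) != in_dim) {
    stop(sprintf("graph_conv layer %d: state width %d != weight input %d",
                 layer, ncol(H), in_dim), call. = FALSE)
  }
  NS <- as.matrix(batch$adj %*% H)
  out <- matrix(0, nrow(H), nrow(layer_params$W[[1]]))
  tied <- is.null(layer_params$W_self)
  for (d in 0:MAX_DEGREE) {
    idx <- batch$deg_idx[[d + 1L]]
    if (!length(idx)) next
    pre <- if (tied) {
      (H[idx, , drop = FALSE] + NS[idx, , drop = FALSE]) %*%
        t(layer_params$W[[d + 1L]])
    } else {
      H[idx, , drop = FALSE] %*% t(layer_params$W_self[[d + 1L]]) +
        NS[idx, , drop = FALSE] %*% t(layer_params$W[[d + 1L]])
    }
    out[idx, ] <- pre + rep(layer_params$b[[d + 1L]], each = length(idx))
  }
  pmax(out, 0)
}

#' Node-level batch normalization
#'
#' Train mode normalizes every feature channel to zero mean and unit
#' (population) variance over all atoms in the batch, applies the learned
#' scale and shift, and updates running statistics; eval mode uses the
#' running statistics.
#'
#' @param state Numeric matrix, one row per atom.
#' @param bn_params List with `gamma`, `beta`, `running_mean`,
#'   `running_var`.
#' @param mode `"train"` or `"eval"`.
#' @param eps Variance guard.
#' @param momentum Running-statistics momentum.
#' @return List with `state` (normalized matrix) and `bn_params` (updated
#'   in train mode).
#' @export
node_batch_norm <- function(state, bn_params, mode = c("eval", "train"),
                            eps = 1e-5, momentum = 0.9) {
  mode <- match.arg(mode)
  H <- .as_state(state)
  if (mode == "train") {
    if (nrow(H) < 2) {
      stop("node_batch_norm: degenerate batch (< 2 atoms) in train mode",
           call. = FALSE)
    }
    mu <- colMeans(H)
    v <- colMeans(H^2) - mu^2
    v <- pmax(v, 0)
    xhat <- sweep(sweep(H, 2, mu), 2, sqrt(v + eps), "/")
    bn_params$running_mean <- momentum * bn_params$running_mean +
      (1 - momentum) * mu
    bn_params$running_var <- momentum * bn_params$running_var +
      (1 - momentum) * v
  } else {
    xhat <- sweep(sweep(H, 2, bn_params$running_mean), 2,
                  sqrt(bn_params$running_var + eps), "/")
  }
  out <- sweep(sweep(xhat, 2, bn_params$gamma, "*"), 2, bn_params$beta, "+")
  list(state = out, bn_params = bn_params)
}

#' Neighbourhood max-pooling
#'
#' Replaces each atom's vector with the element-wise maximum over its
#' closed neighbourhood (the atom itself and its neighbours).
#'
#' @inheritParams graph_conv
#' @return Matrix of pooled activations (same shape as `state`).
#' @export
graph_max_pool <- function(state, graph) {
  batch <- graph_batch(graph)
  H <- .as_state(state)
  out <- H
  for (grp in batch$pool) {
    if (grp$d == 0 || !length(grp$idx)) next
    M <- H[grp$idx, , drop = FALSE]
    for (k in seq_len(grp$d)) {
      M <- pmax(M, H[grp$nbr[, k], , drop = FALSE])
    }
    out[grp$idx, ] <- M
  }
  out
}

#' Degree-weighted graph gather
#'
#' Aggregates all atom vectors of each molecule into one graph-level
#' embedding: `g = tanh(sum_v Phi_deg(v) h(v) + beta)` with a single shared
#' bias vector added after the sum.
#'
#' @inheritParams graph_conv
#' @param gather_params List with `Phi` (length-7 list) and `beta`.
#' @return Matrix with one embedding row per molecule, entries in (-1, 1).
#' @export
graph_gather <- function(state, graph, gather_params) {
  batch <- graph_batch(graph)
  H <- .as_state(state)
  if (ncol(H) != ncol(gather_params$Phi[[1]])) {
    stop(sprintf("graph_gather: state width %d != gather input %d",
                 ncol(H), ncol(gather_params$Phi[[1]])), call. = FALSE)
  }
  Tm <- matrix(0, nrow(H), nrow(gather_params$Phi[[1]]))
  for (d in 0:MAX_DEGREE) {
    idx <- batch$deg_idx[[d + 1L]]
    if (!length(idx)) next
    Tm[idx, ] <- H[idx, , drop = FALSE] %*% t(gather_params$Phi[[d + 1L]])
  }
  U <- rowsum(Tm, batch$mol_id)
  U <- sweep(U, 2, gather_params$beta, "+")
  tanh(U)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# column-wise affine X * a + b (a, b length ncol(X)); recycling runs down
# the columns of t(X), avoiding sweep's aperm overhead in the hot loop
.col_affine <- function(X, a, b) t(t(X) * a + b)
.col_scale <- function(X, a) t(t(X) * a)
.col_shift <- function(X, b) t(t(X) + b)

# ---------------------------------------------------------------------------
# Full forward pass (with optional cache for backprop)
# ---------------------------------------------------------------------------

.gcn_forward_impl <- function(params, batch, mode, keep_cache = FALSE,
                              bn_eps = 1e-5, bn_momentum = 0.9) {
  H <- batch$X
  cache <- if (keep_cache) list(layers = vector("list", params$depth)) else NULL
  for (t in seq_len(params$depth)) {
    lp <- params$conv[[t]]
    in_dim <- ncol(lp$W[[1]])
    if (ncol(H) != in_dim) {
      stop(sprintf("forward: layer %d expects width %d, got %d",
                   t, in_dim, ncol(H)), call. = FALSE)
    }
    NS <- as.matrix(batch$adj %*% H)
    S <- H + NS
    C <- matrix(0, nrow(H), nrow(lp$W[[1]]))
    tied <- is.null(lp$W_self)
    for (d in 0:MAX_DEGREE) {
      idx <- batch$deg_idx[[d + 1L]]
      if (!length(idx)) next
      pre <- if (tied) {
        S[idx, , drop = FALSE] %*% t(lp$W[[d + 1L]])
      } else {
        H[idx, , drop = FALSE] %*% t(lp$W_self[[d + 1L]]) +
          NS[idx, , drop = FALSE] %*% t(lp$W[[d + 1L]])
      }
      C[idx, ] <- pre + rep(lp$b[[d + 1L]], each = length(idx))
    }
    R <- pmax(C, 0)
    bn <- params$bn[[t]]
    if (mode == "train") {
      if (nrow(R) < 2) {
        stop("forward: degenerate batch (< 2 atoms) in train mode",
             call. = FALSE)
      }
      mu <- colMeans(R)
      v <- pmax(colMeans(R^2) - mu^2, 0)
      params$bn[[t]]$running_mean <- bn_momentum * bn$running_mean +
        (1 - bn_momentum) * mu
      params$bn[[t]]$running_var <- bn_momentum * bn$running_var +
        (1 - bn_momentum) * v
    } else {
      mu <- bn$running_mean
      v <- bn$running_var
    }
    inv_sd <- 1 / sqrt(v + bn_eps)
    xhat <- .col_affine(R, inv_sd, -mu * inv_sd)
    B <- .col_affine(xhat, bn$gamma, bn$beta)
    # max-pool with winner tracking for backprop
    P <- B
    winner <- matrix(seq_len(nrow(B)), nrow(B), ncol(B))
    for (grp in batch$pool) {
      if (grp$d == 0 || !length(grp$idx)) next
      M <- B[grp$idx, , drop = FALSE]
      Wn <- winner[grp$idx, , drop = FALSE]
      for (k in seq_len(grp$d)) {
        cand <- B[grp$nbr[, k], , drop = FALSE]
        upd <- cand > M
        M[upd] <- cand[upd]
        Wn[upd] <- matrix(grp$nbr[, k], length(grp$idx), ncol(B))[upd]
      }
      P[grp$idx, ] <- M
      winner[grp$idx, ] <- Wn
    }
    if (keep_cache) {
      cache$layers[[t]] <- list(H_in = H, S = S, NS = NS, relu_mask = C > 0,
                                xhat = xhat, inv_sd = inv_sd, winner = winner)
    }
    H <- P
  }
  gp <- params$gather
  Tm <- matrix(0, nrow(H), nrow(gp$Phi[[1]]))
  for (d in 0:MAX_DEGREE) {
    idx <- batch$deg_idx[[d + 1L]]
    if (!length(idx)) next
    Tm[idx, ] <- H[idx, , drop = FALSE] %*% t(gp$Phi[[d + 1L]])
  }
  U <- .col_shift(rowsum(Tm, batch$mol_id), gp$beta)
  G <- tanh(U)
  L <- .col_shift(G %*% t(params$head$W), params$head$b)
  probs <- .sigmoid(L)
  dimnames(probs) <- NULL
  if (keep_cache) {
    cache$H_final <- H
    cache$G <- G
    cache$probs <- probs
    cache$batch <- batch
    cache$params <- params     # params with updated running stats
    return(cache)
  }
  list(probs = probs, params = params)
}

#' GCN forward pass
#'
#' Applies `depth` blocks of \[convolution, batch norm, max-pool\], the
#' gather readout, and the sigmoid multi-task head.
#'
#' @param params A `gcn_params` object.
#' @param graphs List of `mol_graph`s (or a `graph_batch`).
#' @param mode `"eval"` uses running batch-norm statistics; `"train"` uses
#'   batch statistics and updates the running ones (returned via
#'   `attr(, "params")`).
#' @return Probability matrix (molecules x tasks), entries in (0, 1). In
#'   train mode the updated parameters are attached as attribute `params`.
#' @export
gcn_forward <- function(params, graphs, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  batch <- graph_batch(graphs)
  res <- .gcn_forward_impl(params, batch, mode)
  probs <- res$probs
  if (mode == "train") attr(probs, "params") <- res$params
  probs
}

# ---------------------------------------------------------------------------
# Backward pass: gradients of mean focal loss w.r.t. all parameters
# ---------------------------------------------------------------------------

# scatter-add dH rows to the winner source rows recorded during pooling
# (sparseMatrix sums duplicate (i, j) entries, giving a fast bincount)
.maxpool_backward <- function(dH, winner) {
  n <- nrow(dH); k <- ncol(dH)
  as.matrix(Matrix::sparseMatrix(
    i = as.vector(winner), j = rep(seq_len(k), each = n),
    x = as.vector(dH), dims = c(n, k)))
}

# dProbs: gradient of the scalar loss w.r.t. the probability matrix
.gcn_backward <- function(cache, dProbs) {
  params <- cache$params
  batch <- cache$batch
  grads <- list(conv = vector("list", params$depth),
                bn = vector("list", params$depth))
  P <- cache$probs
  dL <- dProbs * P * (1 - P)                      # through sigmoid
  grads$head <- list(W = t(dL) %*% cache$G, b = colSums(dL))
  dG <- dL %*% params$head$W
  dU <- dG * (1 - cache$G^2)                      # through tanh
  grads$gather <- list(Phi = vector("list", MAX_DEGREE + 1L),
                       beta = colSums(dU))
  H <- cache$H_final
  dT <- dU[batch$mol_id, , drop = FALSE]
  dH <- matrix(0, nrow(H), ncol(H))
  for (d in 0:MAX_DEGREE) {
    idx <- batch$deg_idx[[d + 1L]]
    Phi <- params$gather$Phi[[d + 1L]]
    if (!length(idx)) {
      grads$gather$Phi[[d + 1L]] <- matrix(0, nrow(Phi), ncol(Phi))
      next
    }
    grads$gather$Phi[[d + 1L]] <- t(dT[idx, , drop = FALSE]) %*%
      H[idx, , drop = FALSE]
    dH[idx, ] <- dT[idx, , drop = FALSE] %*% Phi
  }
  for (t in rev(seq_len(params$depth))) {
    lc <- cache$layers[[t]]
    lp <- params$conv[[t]]
    bn <- params$bn[[t]]
    dB <- .maxpool_backward(dH, lc$winner)
    # batch norm backward (train-mode batch statistics)
    grads$bn[[t]] <- list(gamma = colSums(dB * lc$xhat), beta = colSums(dB))
    dxhat <- .col_scale(dB, bn$gamma)
    mean_dxhat <- colMeans(dxhat)
    mean_dxhat_xhat <- colMeans(dxhat * lc$xhat)
    dR <- t((t(dxhat) - mean_dxhat - t(lc$xhat) * mean_dxhat_xhat) *
              lc$inv_sd)
    dC <- dR * lc$relu_mask
    tied <- is.null(lp$W_self)
    gl <- list(W = vector("list", MAX_DEGREE + 1L),
               b = vector("list", MAX_DEGREE + 1L))
    if (!tied) gl$W_self <- vector("list", MAX_DEGREE + 1L)
    dS <- matrix(0, nrow(dC), ncol(lc$H_in))
    dH_self <- NULL
    if (!tied) dH_self <- matrix(0, nrow(dC), ncol(lc$H_in))
    for (d in 0:MAX_DEGREE) {
      idx <- batch$deg_idx[[d + 1L]]
      W <- lp$W[[d + 1L]]
      if (!length(idx)) {
        gl$W[[d + 1L]] <- matrix(0, nrow(W), ncol(W))
        gl$b[[d + 1L]] <- numeric(nrow(W))
        if (!tied) gl$W_self[[d + 1L]] <- matrix(0, nrow(W), ncol(W))
        next
      }
      dCd <- dC[idx, , drop = FALSE]
      gl$b[[d + 1L]] <- colSums(dCd)
      if (tied) {
        gl$W[[d + 1L]] <- t(dCd) %*% lc$S[idx, , drop = FALSE]
        dS[idx, ] <- dCd %*% W
      } else {
        gl$W[[d + 1L]] <- t(dCd) %*% lc$NS[idx, , drop = FALSE]
        gl$W_self[[d + 1L]] <- t(dCd) %*% lc$H_in[idx, , drop = FALSE]
        dS[idx, ] <- dCd %*% W
        dH_self[idx, ] <- dCd %*% lp$W_self[[d + 1L]]
      }
    }
    grads$conv[[t]] <- gl
    # S = H + A H (tied) or neighbour-sum path only (untied)
    dH <- if (tied) dS + as.matrix(batch$adj %*% dS)
          else dH_self + as.matrix(batch$adj %*% dS)
  }
  grads
}

# ---------------------------------------------------------------------------
# Checkpoint serialization (plain-text JSON, bit-exact doubles)
# ---------------------------------------------------------------------------

#' Write or read a parameter checkpoint
#'
#' A versioned JSON container mapping named tensors to values; doubles are
#' serialized at full precision so write/read round-trips are bit-exact.
#'
#' @param params A `gcn_params` object.
#' @param path Checkpoint file path.
#' @return `read_checkpoint()` returns the `gcn_params`.
#' @export
write_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "gcn_params"))
  payload <- list(format_version = 1L, model = unclass(params))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$format_version) || payload$format_version != 1L) {
    stop("unsupported checkpoint format version", call. = FALSE)
  }
  m <- payload$model
  as_vec <- function(x) as.numeric(unlist(x, use.names = FALSE))
  as_mat <- function(x) do.call(rbind, lapply(x, as_vec))
  conv <- lapply(m$conv, function(lay) {
    out <- list(W = lapply(lay$W, as_mat), b = lapply(lay$b, as_vec))
    if (!is.null(lay$W_self)) out$W_self <- lapply(lay$W_self, as_mat)
    out
  })
  bn <- lapply(m$bn, function(l) lapply(l, as_vec))
  params <- list(
    conv = conv, bn = bn,
    gather = list(Phi = lapply(m$gather$Phi, as_mat),
                  beta = as_vec(m$gather$beta)),
    head = list(W = as_mat(m$head$W), b = as_vec(m$head$b)),
    feature_dim = as.integer(m$feature_dim),
    n_tasks = as.integer(m$n_tasks),
    depth = as.integer(m$depth), width = as.integer(m$width),
    tied = isTRUE(m$tied))
  class(params) <- "gcn_params"
  params
}
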
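# Independent oracles and fixture builders used across the suite.
# Every oracle here is a deliberately naive re-implementation (per-node
# loops, all-pairs counting) kept separate from the package's vectorized
# code paths.

# -- fixture: hand-built graph (bypasses SMILES parsing) ----------------------

make_graph <- function(neighbors, features, elements = NULL,
                       aromatic = NULL, bond_order = 1) {
  n <- length(neighbors)
  features <- as.matrix(features)
  stopifnot(nrow(features) == n)
  pairs <- do.call(rbind, lapply(seq_len(n), function(v) {
    nb <- neighbors[[v]]
    if (!length(nb)) return(NULL)
    cbind(pmin(v, nb), pmax(v, nb))
  }))
  if (is.null(pairs)) {
    bi <- integer(0); bj <- integer(0)
  } else {
    pairs <- unique(pairs)
    bi <- pairs[, 1]; bj <- pairs[, 2]
  }
  structure(list(
    smiles = NA_character_, n_atoms = n,
    elements = if (is.null(elements)) rep("C", n) else elements,
    aromatic = if (is.null(aromatic)) rep(FALSE, n) else aromatic,
    charge = integer(n), n_h = integer(n),
    degrees = lengths(neighbors), neighbors = neighbors,
    bonds = list(i = bi, j = bj, order = rep(bond_order, length(bi))),
    atom_features = features
  ), class = "mol_graph")
}

# random connected graph with <= max_n nodes and degree <= 6
random_graph <- function(max_n = 6, dim = 4) {
  n <- sample(1:max_n, 1)
  neighbors <- replicate(n, integer(0), simplify = FALSE)
  if (n > 1) {
    for (v in 2:n) {                       # random spanning tree
      u <- sample(v - 1L, 1)
      neighbors[[v]] <- c(neighbors[[v]], u)
      neighbors[[u]] <- c(neighbors[[u]], v)
    }
    extra <- sample(0:min(2, n * (n - 1) / 2 - (n - 1)), 1)
    for (e in seq_len(extra)) {
      uv <- sample(n, 2)
      u <- uv[1]; v <- uv[2]
      if (!(v %in% neighbors[[u]]) && length(neighbors[[u]]) < 6 &&
          length(neighbors[[v]]) < 6) {
        neighbors[[u]] <- c(neighbors[[u]], v)
        neighbors[[v]] <- c(neighbors[[v]], u)
      }
    }
  }
  make_graph(neighbors, matrix(rnorm(n * dim), n, dim))
}

random_layer_params <- function(in_dim, out_dim) {
  list(W = lapply(1:7, function(d) matrix(rnorm(out_dim * in_dim), out_dim)),
       b = lapply(1:7, function(d) rnorm(out_dim)))
}

random_gather_params <- function(in_dim, out_dim) {
  list(Phi = lapply(1:7, function(d) matrix(rnorm(out_dim * in_dim), out_dim)),
       beta = rnorm(out_dim))
}

# -- naive layer oracles (per-node loops) -------------------------------------

oracle_conv <- function(h, graph, lp) {
  h <- as.matrix(h)
  out <- matrix(0, nrow(h), nrow(lp$W[[1]]))
  for (v in seq_len(graph$n_atoms)) {
    d <- min(graph$degrees[v], 6L)
    s <- h[v, ]
    for (u in graph$neighbors[[v]]) s <- s + h[u, ]
    out[v, ] <- pmax(lp$W[[d + 1]] %*% s + lp$b[[d + 1]], 0)
  }
  out
}

oracle_max_pool <- function(h, graph) {
  h <- as.matrix(h)
  out <- h
  for (v in seq_len(graph$n_atoms)) {
    m <- h[v, ]
    for (u in graph$neighbors[[v]]) m <- pmax(m, h[u, ])
    out[v, ] <- m
  }
  out
}

oracle_gather <- function(h, graph, gp) {
  h <- as.matrix(h)
  acc <- gp$beta
  for (v in seq_len(graph$n_atoms)) {
    d <- min(graph$degrees[v], 6L)
    acc <- acc + as.vector(gp$Phi[[d + 1]] %*% h[v, ])
  }
  tanh(acc)
}

# -- brute-force ROC-AUC (all positive/negative pairs) ------------------------

oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# -- independently coded circular-hash fingerprint oracle ---------------------
# Follows the documented algorithm (FNV-1a over little-endian int bytes;
# per-iteration re-hash with neighbour identifiers sorted by
# (10*order, id)) but is written recursively and with its own hash code.

oracle_fnv <- function(values) {
  state <- 2166136261
  xor32 <- function(a, b) {
    al <- a %% 65536; bl <- b %% 65536
    bitwXor(al, bl) + bitwXor((a - al) / 65536, (b - bl) / 65536) * 65536
  }
  for (val in values) {
    val <- val %% 4294967296
    bytes <- c(val %% 256,
               (val %/% 256) %% 256,
               (val %/% 65536) %% 256,
               (val %/% 16777216) %% 256)
    for (byte in bytes) {
      state <- xor32(state, byte)
      low <- state %% 65536
      high <- (state - low) / 65536
      state <- (low * 16777619 + ((high * 16777619) %% 65536) * 65536) %%
        4294967296
    }
  }
  state
}

oracle_fingerprint <- function(graph, radius, n_bits) {
  spec <- atom_feature_spec()
  elcode <- match(graph$elements, spec$elements)
  elcode[is.na(elcode)] <- length(spec$elements)
  id0 <- sapply(seq_len(graph$n_atoms), function(v) {
    oracle_fnv(c(elcode[v], graph$degrees[v], graph$n_h[v],
                 graph$charge[v] + 10, as.integer(graph$aromatic[v])))
  })
  order_of <- function(v, u) {
    hit <- (graph$bonds$i == min(v, u)) & (graph$bonds$j == max(v, u))
    graph$bonds$order[hit][1]
  }
  ids_at <- function(r) {
    if (r == 0) return(id0)
    prev <- ids_at(r - 1)
    sapply(seq_len(graph$n_atoms), function(v) {
      nb <- graph$neighbors[[v]]
      payload <- c(r, prev[v])
      if (length(nb)) {
        ords <- sapply(nb, function(u) order_of(v, u))
        for (k in order(ords, prev[nb])) {
          payload <- c(payload, round(ords[k] * 10), prev[nb][k])
        }
      }
      oracle_fnv(payload)
    })
  }
  all_ids <- unlist(lapply(0:radius, ids_at))
  bits <- integer(n_bits)
  bits[unique(all_ids %% n_bits) + 1] <- 1L
  bits
}

# -- misc ---------------------------------------------------------------------

permute_graph <- function(graph, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  make_graph(
    neighbors = lapply(perm, function(v) inv[graph$neighbors[[v]]]),
    features = graph$atom_features[perm, , drop = FALSE],
    elements = graph$elements[perm],
    aromatic = graph$aromatic[perm]
  )
}

random_label_matrix <- function(n, k, p = 0.2) {
  y <- matrix(rbinom(n * k, 1, p), n, k)
  label_matrix(sprintf("c%04d", seq_len(n)), rep("C", n), y,
               paste0("t", seq_len(k)))
}
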
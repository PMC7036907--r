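# ---------------------------------------------------------------------------
# Hashed circular (ECFP-style) fingerprints.
#
# Algorithm (documented so it can be re-implemented independently):
#   1. initial atom identifier = fnv1a32 of the integer tuple
#      (element code, degree, n_h, charge + 10, aromatic)
#      where element code indexes the atom_feature_spec() element list;
#   2. for iterations r = 1..radius, the new identifier of atom v is
#      fnv1a32 of (r, id(v), then for each neighbour u sorted by
#      (10 * bond_order(v,u), id(u)): the two values of that pair);
#      bond order uses 1.5 for aromatic bonds, hence the x10 scaling;
#   3. the bit set is { id mod n_bits : all identifiers from iterations
#      0..radius }.
# This is a simplified ECFP: duplicate-environment pruning is omitted
# because folded bits are OR-ed anyway. Radius 2 at 1024 bits corresponds
# to the ECFP4 configuration.
# ---------------------------------------------------------------------------

# FNV-1a over 32-bit integers, 4 little-endian bytes each; arithmetic mod
# 2^32 done in doubles (exact: intermediates stay far below 2^53).
.fnv1a32 <- function(ints) {
  h <- 2166136261
  for (x in ints) {
    x <- x %% 4294967296
    for (b in 0:3) {
      byte <- (x %/% (256^b)) %% 256
      h <- .xor32(h, byte)
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    }
  }
  h
}

.xor32 <- function(a, b) {
  # bitwXor on values possibly >= 2^31: split into 16-bit halves
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(a_lo, b_lo) + bitwXor(a_hi, b_hi) * 65536
}

.atom_init_ids <- function(graph) {
  spec <- atom_feature_spec()
  el <- match(graph$elements, spec$elements)
  el[is.na(el)] <- length(spec$elements)
  vapply(seq_len(graph$n_atoms), function(v) {
    .fnv1a32(c(el[v], graph$degrees[v], graph$n_h[v],
               graph$charge[v] + 10L, as.integer(graph$aromatic[v])))
  }, numeric(1))
}

.circular_ids <- function(graph, radius) {
  ids <- .atom_init_ids(graph)
  all_ids <- ids
  if (radius >= 1) {
    # bond order lookup by atom pair
    bkey <- paste(pmin(graph$bonds$i, graph$bonds$j),
                  pmax(graph$bonds$i, graph$bonds$j))
    bord <- graph$bonds$order
    names(bord) <- bkey
    for (r in seq_len(radius)) {
      new_ids <- ids
      for (v in seq_len(graph$n_atoms)) {
        nb <- graph$neighbors[[v]]
        if (length(nb)) {
          ords <- as.numeric(bord[paste(pmin(v, nb), pmax(v, nb))])
          o <- order(ords, ids[nb])
          pairs <- as.vector(rbind(round(ords[o] * 10), ids[nb][o]))
        } else {
          pairs <- numeric(0)
        }
        new_ids[v] <- .fnv1a32(c(r, ids[v], pairs))
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  all_ids
}

#' Hashed circular substructure fingerprint
#'
#' Iteratively hashed circular atom environments of diameter `2 * radius`,
#' folded into `n_bits` bits (`radius = 2`, `n_bits = 1024` reproduces the
#' ECFP4 setting). Deterministic per input SMILES.
#'
#' @param smiles A single SMILES string, or a `mol_graph`.
#' @param radius Neighbourhood radius (non-negative integer).
#' @param n_bits Fingerprint length.
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
circular_fingerprint <- function(smiles, radius = 2, n_bits = 1024) {
  stopifnot(radius >= 0, n_bits >= 1)
  graph <- if (inherits(smiles, "mol_graph")) smiles else
    smiles_to_graph(smiles)
  ids <- .circular_ids(graph, radius)
  bits <- integer(n_bits)
  bits[unique(ids %% n_bits) + 1L] <- 1L
  bits
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles Character vector of SMILES (or list of `mol_graph`s).
#' @inheritParams circular_fingerprint
#' @return Integer matrix, one row per molecule, `n_bits` columns named
#'   `bit0...`.
#' @export
fingerprint_matrix <- function(smiles, radius = 2, n_bits = 1024) {
  graphs <- if (is.character(smiles)) parse_molecules(smiles) else smiles
  out <- matrix(0L, nrow = length(graphs), ncol = n_bits,
                dimnames = list(NULL, paste0("bit", seq_len(n_bits) - 1L)))
  for (m in seq_along(graphs)) {
    out[m, ] <- circular_fingerprint(graphs[[m]], radius, n_bits)
  }
  out
}
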
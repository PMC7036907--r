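# ---------------------------------------------------------------------------
# Subgraph monomorphism matching (motif containment) and Bemis-Murcko
# scaffolds. Matching is a backtracking search: motif atoms are compatible
# with molecule atoms of the same element and aromaticity, and every motif
# bond must exist in the molecule with the same bond class (aromatic = 1.5).
# Extra molecule bonds among matched atoms are allowed (monomorphism, the
# substructure-search convention).
# ---------------------------------------------------------------------------

.bond_lookup <- function(graph) {
  if (!length(graph$bonds$i)) return(numeric(0))
  key <- paste(pmin(graph$bonds$i, graph$bonds$j),
               pmax(graph$bonds$i, graph$bonds$j))
  stats::setNames(graph$bonds$order, key)
}

# order motif atoms so each (after the first) touches an earlier one
.match_order <- function(motif) {
  n <- motif$n_atoms
  ord <- 1L
  seen <- rep(FALSE, n); seen[1L] <- TRUE
  while (length(ord) < n) {
    nxt <- NA_integer_
    for (v in ord) {
      cand <- motif$neighbors[[v]][!seen[motif$neighbors[[v]]]]
      if (length(cand)) { nxt <- cand[1]; break }
    }
    if (is.na(nxt)) nxt <- which(!seen)[1]   # disconnected motif fragment
    ord <- c(ord, nxt); seen[nxt] <- TRUE
  }
  ord
}

#' Substructure containment test
#'
#' Tests whether `motif` occurs as a substructure of `graph` (subgraph
#' monomorphism with element + aromaticity atom compatibility and exact
#' bond-class agreement; aromatic bonds only match aromatic bonds).
#'
#' @param graph A `mol_graph` (the molecule).
#' @param motif A `mol_graph` (the query fragment), or a SMILES string.
#' @return Logical scalar.
#' @export
has_substructure <- function(graph, motif) {
  if (is.character(motif)) motif <- smiles_to_graph(motif)
  nm <- motif$n_atoms
  if (nm > graph$n_atoms) return(FALSE)
  gb <- .bond_lookup(graph)
  mb <- .bond_lookup(motif)
  compat <- matrix(FALSE, nm, graph$n_atoms)
  for (p in seq_len(nm)) {
    compat[p, ] <- graph$elements == motif$elements[p] &
      graph$aromatic == motif$aromatic[p] &
      graph$degrees >= motif$degrees[p]
  }
  if (any(rowSums(compat) == 0)) return(FALSE)
  ord <- .match_order(motif)
  assign_map <- integer(nm)           # motif atom -> molecule atom (0 unset)
  used <- rep(FALSE, graph$n_atoms)
  try_match <- function(k) {
    if (k > nm) return(TRUE)
    p <- ord[k]
    prev <- motif$neighbors[[p]][motif$neighbors[[p]] %in% ord[seq_len(k - 1L)]]
    cand <- if (length(prev)) {
      # restrict to molecule neighbours of an already-matched anchor
      intersect(which(compat[p, ] & !used),
                graph$neighbors[[assign_map[prev[1]]]])
    } else {
      which(compat[p, ] & !used)
    }
    for (g in cand) {
      ok <- TRUE
      for (q in prev) {
        mo <- mb[paste(min(p, q), max(p, q))]
        go <- gb[paste(min(g, assign_map[q]), max(g, assign_map[q]))]
        if (is.na(go) || go != mo) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_map[p] <<- g; used[g] <<- TRUE
      if (try_match(k + 1L)) return(TRUE)
      assign_map[p] <<- 0L; used[g] <<- FALSE
    }
    FALSE
  }
  try_match(1L)
}

# ---------------------------------------------------------------------------
# Bemis-Murcko scaffolds
# ---------------------------------------------------------------------------

# indices of scaffold atoms: iteratively prune degree-1 atoms until only
# ring systems and linkers remain; acyclic molecules return integer(0)
.murcko_atoms <- function(graph) {
  keep <- rep(TRUE, graph$n_atoms)
  deg <- graph$degrees
  repeat {
    leaf <- which(keep & deg <= 1L)
    if (!length(leaf)) break
    keep[leaf] <- FALSE
    for (v in leaf) {
      for (u in graph$neighbors[[v]]) if (keep[u]) deg[u] <- deg[u] - 1L
    }
    deg[leaf] <- 0L
  }
  which(keep)
}

# V2000 molfile text of an atom-induced subgraph; aromatic bonds written
# as order 4 so OpenBabel re-perceives aromaticity
.subgraph_molfile <- function(graph, atoms) {
  remap <- integer(graph$n_atoms); remap[atoms] <- seq_along(atoms)
  bsel <- which(graph$bonds$i %in% atoms & graph$bonds$j %in% atoms)
  n <- length(atoms); nb <- length(bsel)
  lines <- c("", " molgcn", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in atoms) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, graph$elements[a]))
  }
  for (b in bsel) {
    ord <- graph$bonds$order[b]
    code <- if (ord == 1.5) 4L else as.integer(ord)
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              remap[graph$bonds$i[b]],
                              remap[graph$bonds$j[b]], code))
  }
  chg <- which(graph$charge[atoms] != 0L)
  for (k in chg) {
    lines <- c(lines, sprintf("M  CHG  1%4d%4d", k, graph$charge[atoms][k]))
  }
  paste0(paste(c(lines, "M  END", "$$$$"), collapse = "\n"), "\n")
}

#' Bemis-Murcko scaffold keys
#'
#' Computes the molecular scaffold (ring systems plus linkers; all side
#' chains pruned) of each molecule and returns a canonical SMILES key per
#' molecule. Acyclic molecules have an empty scaffold and share the key
#' `""`.
#'
#' @param smiles Character vector of SMILES, or list of `mol_graph`s.
#' @return Character vector of scaffold keys, one per molecule.
#' @export
scaffold_keys <- function(smiles) {
  graphs <- if (is.character(smiles)) parse_molecules(smiles) else smiles
  keys <- character(length(graphs))
  mol_idx <- integer(0)
  molfiles <- character(0)
  for (m in seq_along(graphs)) {
    atoms <- .murcko_atoms(graphs[[m]])
    if (!length(atoms)) {
      keys[m] <- ""
    } else {
      mol_idx <- c(mol_idx, m)
      molfiles <- c(molfiles, .subgraph_molfile(graphs[[m]], atoms))
    }
  }
  if (length(mol_idx)) {
    out <- .ob_convert("SDF", "CAN", paste(molfiles, collapse = ""))
    res <- strsplit(out, "\n", fixed = TRUE)[[1]]
    res <- sub("\t.*$", "", res)
    res <- res[nzchar(res)]
    if (length(res) != length(mol_idx)) {
      stop("scaffold canonicalization failed for ",
           length(mol_idx) - length(res), " molecules", call. = FALSE)
    }
    keys[mol_idx] <- res
  }
  keys
}
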
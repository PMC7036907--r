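# ---------------------------------------------------------------------------
# SMILES -> molecular graph
#
# Structure perception (ring/aromaticity perception, implicit hydrogens,
# formal charges, canonicalization) is delegated to OpenBabel through
# ChemmineOB. We request MOL2 output with explicit hydrogens and parse the
# text directly: MOL2 carries aromatic atom/bond flags and formal charges
# (UNITY_ATOM_ATTR), and round-trips single-atom molecules correctly.
# ---------------------------------------------------------------------------

#' Atom feature encoding specification
#'
#' Describes the fixed per-atom input encoding used by the graph network:
#' one-hot element identity over a fixed list (unknown elements map to
#' "other"), one-hot topological degree 0--6, one-hot attached-hydrogen
#' count 0--4 (clipped), an aromaticity flag, and one-hot formal charge
#' clipped to \[-2, +2\]. The network learns higher-level atom descriptions
#' from this conventional initial encoding.
#'
#' @return A list with elements `elements`, `max_degree`, `max_h`,
#'   `charge_range` and the total `feature_dim`.
#' @export
atom_feature_spec <- function() {
  elements <- c("C", "N", "O", "S", "F", "P", "Cl", "Br", "I", "other")
  spec <- list(
    elements = elements,
    max_degree = 6L,
    max_h = 4L,
    charge_range = c(-2L, 2L)
  )
  spec$feature_dim <- length(elements) + (spec$max_degree + 1L) +
    (spec$max_h + 1L) + 1L + (spec$charge_range[2] - spec$charge_range[1] + 1L)
  spec
}

#' Per-atom feature vector
#'
#' @param element Element symbol (e.g. `"C"`, `"Cl"`).
#' @param degree Heavy-atom degree of the atom.
#' @param n_h Number of attached hydrogens.
#' @param aromatic Logical aromaticity flag.
#' @param charge Integer formal charge.
#' @param spec Encoding specification from [atom_feature_spec()].
#' @return Numeric vector of length `spec$feature_dim`.
#' @export
atom_feature_vector <- function(element, degree, n_h, aromatic, charge,
                                spec = atom_feature_spec()) {
  el <- if (element %in% spec$elements) element else "other"
  v_el <- as.numeric(spec$elements == el)
  d <- min(max(as.integer(degree), 0L), spec$max_degree)
  v_deg <- as.numeric(seq.int(0L, spec$max_degree) == d)
  h <- min(max(as.integer(n_h), 0L), spec$max_h)
  v_h <- as.numeric(seq.int(0L, spec$max_h) == h)
  ch <- min(max(as.integer(charge), spec$charge_range[1]), spec$charge_range[2])
  v_ch <- as.numeric(seq.int(spec$charge_range[1], spec$charge_range[2]) == ch)
  c(v_el, v_deg, v_h, as.numeric(isTRUE(aromatic)), v_ch)
}

# Cheap syntax screen applied before handing SMILES to OpenBabel, which
# silently "repairs" some malformed inputs (e.g. an unclosed branch).
.smiles_syntax_ok <- function(s) {
  if (!nzchar(s)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return(FALSE)
  }
  # ring-closure digits must pair up (two-digit %nn closures handled too)
  stripped <- gsub("\\[[^]]*\\]", "A", s)        # bracket atoms hide digits
  ring <- c(regmatches(stripped, gregexpr("%[0-9]{2}", stripped))[[1]],
            regmatches(gsub("%[0-9]{2}", "", stripped),
                       gregexpr("[0-9]", gsub("%[0-9]{2}", "", stripped)))[[1]])
  if (length(ring) && any(table(ring) %% 2L != 0L)) return(FALSE)
  TRUE
}

.ob_convert <- function(from, to, text, add_h = FALSE) {
  if (add_h) {
    suppressWarnings(ChemmineOB::convertFormat(
      from, to, source = text, options = data.frame(names = "h", args = "")))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text))
  }
}

# Parse one MOL2 record (character vector of lines) into atom/bond tables.
.parse_mol2_record <- function(lines) {
  sec <- function(tag) {
    i <- which(lines == paste0("@<TRIPOS>", tag))
    if (!length(i)) return(character(0))
    j <- grep("^@<TRIPOS>", lines)
    j <- j[j > i[1]]
    end <- if (length(j)) j[1] - 1L else length(lines)
    if (end < i[1] + 1L) return(character(0))
    lines[(i[1] + 1L):end]
  }
  atoms <- sec("ATOM")
  atoms <- atoms[nzchar(trimws(atoms))]
  n <- length(atoms)
  type <- character(n); elem <- character(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(atoms[k]), "[[:space:]]+")[[1]]
    type[k] <- f[6]
    elem[k] <- strsplit(f[6], ".", fixed = TRUE)[[1]][1]
  }
  bonds <- sec("BOND")
  bonds <- bonds[nzchar(trimws(bonds))]
  bi <- integer(0); bj <- integer(0); btype <- character(0)
  if (length(bonds)) {
    bf <- do.call(rbind, strsplit(trimws(bonds), "[[:space:]]+"))
    bi <- as.integer(bf[, 2]); bj <- as.integer(bf[, 3]); btype <- bf[, 4]
  }
  charge <- integer(n)
  attr_lines <- sec("UNITY_ATOM_ATTR")
  if (length(attr_lines)) {
    k <- 1L
    while (k <= length(attr_lines)) {
      hd <- strsplit(trimws(attr_lines[k]), "[[:space:]]+")[[1]]
      atom_id <- as.integer(hd[1]); n_attr <- as.integer(hd[2])
      for (a in seq_len(n_attr)) {
        av <- strsplit(trimws(attr_lines[k + a]), "[[:space:]]+")[[1]]
        if (av[1] == "charge") charge[atom_id] <- as.integer(av[2])
      }
      k <- k + 1L + n_attr
    }
  }
  list(elem = elem, type = type, bi = bi, bj = bj, btype = btype,
       charge = charge)
}

# Numeric bond class used for motif matching and valence: aromatic 1.5,
# amide 1, else the printed order.
.bond_order_num <- function(btype) {
  vapply(btype, function(b) switch(b, "ar" = 1.5, "am" = 1,
                                   suppressWarnings(as.numeric(b))), 0)
}

.build_mol_graph <- function(rec, smiles, feature_spec) {
  heavy <- which(rec$elem != "H")
  if (!length(heavy)) {
    stop("molecule has no heavy atoms: ", smiles, call. = FALSE)
  }
  remap <- integer(length(rec$elem)); remap[heavy] <- seq_along(heavy)
  n <- length(heavy)
  n_h <- integer(n)
  neighbors <- vector("list", n)
  for (k in seq_len(n)) neighbors[[k]] <- integer(0)
  bond_i <- integer(0); bond_j <- integer(0); bond_class <- numeric(0)
  aromatic <- logical(n)
  if (length(rec$bi)) {
    ord <- .bond_order_num(rec$btype)
    for (b in seq_along(rec$bi)) {
      i <- rec$bi[b]; j <- rec$bj[b]
      hi <- rec$elem[i] == "H"; hj <- rec$elem[j] == "H"
      if (hi && hj) next
      if (hi || hj) {
        hv <- remap[if (hi) j else i]
        n_h[hv] <- n_h[hv] + 1L
        next
      }
      ii <- remap[i]; jj <- remap[j]
      neighbors[[ii]] <- c(neighbors[[ii]], jj)
      neighbors[[jj]] <- c(neighbors[[jj]], ii)
      bond_i <- c(bond_i, ii); bond_j <- c(bond_j, jj)
      bond_class <- c(bond_class, ord[b])
      if (rec$btype[b] == "ar") aromatic[c(ii, jj)] <- TRUE
    }
  }
  aromatic <- aromatic | grepl("\\.ar$", rec$type[heavy])
  degrees <- lengths(neighbors)
  elements <- rec$elem[heavy]
  charge <- rec$charge[heavy]
  feats <- matrix(0, nrow = n, ncol = feature_spec$feature_dim)
  for (k in seq_len(n)) {
    feats[k, ] <- atom_feature_vector(elements[k], degrees[k], n_h[k],
                                      aromatic[k], charge[k], feature_spec)
  }
  structure(list(
    smiles = smiles,
    n_atoms = n,
    elements = elements,
    aromatic = aromatic,
    charge = charge,
    n_h = n_h,
    degrees = degrees,
    neighbors = neighbors,
    bonds = list(i = bond_i, j = bond_j, order = bond_class),
    atom_features = feats
  ), class = "mol_graph")
}

#' Parse SMILES strings into molecular graphs
#'
#' Converts each SMILES into a heavy-atom molecular graph (hydrogens are
#' implicit and counted into the atom features). Aromaticity, implicit
#' hydrogens and formal charges are perceived by OpenBabel.
#'
#' @param smiles Character vector of SMILES strings.
#' @param feature_spec Atom encoding from [atom_feature_spec()].
#' @return A list of `mol_graph` objects (named after `smiles` names when
#'   present). Each has fields `atom_features` (matrix), `neighbors`
#'   (list of integer vectors), `degrees`, `elements`, `aromatic`,
#'   `charge`, `n_h`, `bonds` and `smiles`.
#' @export
parse_molecules <- function(smiles, feature_spec = atom_feature_spec()) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  bad <- !vapply(smiles, .smiles_syntax_ok, logical(1))
  if (any(bad)) {
    stop("unparseable SMILES: ", paste(smiles[which(bad)[1]]), call. = FALSE)
  }
  txt <- paste0(paste(smiles, collapse = "\n"), "\n")
  mol2 <- .ob_convert("SMI", "MOL2", txt, add_h = TRUE)
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  starts <- which(lines == "@<TRIPOS>MOLECULE")
  if (length(starts) != length(smiles)) {
    stop("unparseable SMILES: OpenBabel rejected ",
         length(smiles) - length(starts), " of ", length(smiles),
         " molecules", call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(smiles))
  for (m in seq_along(starts)) {
    rec <- .parse_mol2_record(lines[starts[m]:ends[m]])
    out[[m]] <- .build_mol_graph(rec, smiles[m], feature_spec)
  }
  names(out) <- names(smiles)
  out
}

#' @rdname parse_molecules
#' @details `smiles_to_graph()` is the single-molecule form.
#' @export
smiles_to_graph <- function(smiles, feature_spec = atom_feature_spec()) {
  stopifnot(length(smiles) == 1)
  parse_molecules(smiles, feature_spec)[[1]]
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph:", x$smiles, "\n")
  cat(" ", x$n_atoms, "heavy atoms;", length(x$bonds$i), "bonds; degrees",
      paste(range(x$degrees), collapse = "-"), "\n")
  invisible(x)
}

#' Canonical SMILES
#'
#' OpenBabel canonical SMILES, used to merge identical compounds reported
#' under different SMILES spellings.
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES, same length.
#' @export
canonical_smiles <- function(smiles) {
  bad <- !vapply(smiles, .smiles_syntax_ok, logical(1))
  if (any(bad)) {
    stop("unparseable SMILES: ", smiles[which(bad)[1]], call. = FALSE)
  }
  txt <- paste0(paste(smiles, collapse = "\n"), "\n")
  out <- .ob_convert("SMI", "CAN", txt)
  res <- strsplit(out, "\n", fixed = TRUE)[[1]]
  res <- sub("\t.*$", "", res)
  res <- res[nzchar(res)]
  if (length(res) != length(smiles)) {
    stop("unparseable SMILES: OpenBabel rejected ",
         length(smiles) - length(res), " molecules", call. = FALSE)
  }
  res
}

# ---------------------------------------------------------------------------
# Label matrix container and assembly from herb-level annotations
# ---------------------------------------------------------------------------

#' Construct a compound x task label matrix
#'
#' @param compound_ids Character vector of unique compound identifiers.
#' @param smiles Character vector of SMILES, parallel to `compound_ids`.
#' @param labels Binary matrix, rows parallel to `compound_ids`.
#' @param task_names Column names; defaults to `colnames(labels)`.
#' @return A `label_matrix` object.
#' @export
label_matrix <- function(compound_ids, smiles, labels, task_names = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(task_names)) task_names <- colnames(labels)
  if (is.null(task_names)) task_names <- paste0("task", seq_len(ncol(labels)))
  stopifnot(length(compound_ids) == nrow(labels),
            length(smiles) == nrow(labels),
            length(task_names) == ncol(labels),
            all(labels %in% c(0L, 1L)),
            !anyDuplicated(compound_ids))
  colnames(labels) <- task_names
  rownames(labels) <- compound_ids
  structure(list(compound_ids = as.character(compound_ids),
                 smiles = as.character(smiles),
                 task_names = as.character(task_names),
                 labels = labels),
            class = "label_matrix")
}

#' @export
print.label_matrix <- function(x, ...) {
  cat("label_matrix:", nrow(x$labels), "compounds x", ncol(x$labels),
      "tasks\n  positives per task:",
      paste(colSums(x$labels), collapse = " "), "\n")
  invisible(x)
}

#' The twelve organ-Meridian task names
#' @return Character vector of length 12.
#' @export
meridian_tasks <- function() {
  c("liver", "stomach", "lung", "spleen", "kidney", "heart",
    "large_intestine", "bladder", "gallbladder", "small_intestine",
    "cardiovascular", "three_end")
}

#' Assemble compound-level labels from herb-level annotations
#'
#' Each compound inherits the binary task annotations of every herb that
#' contains it; a compound occurring in several herbs receives the
#' element-wise union (OR) of those herbs' label vectors. Herbs without a
#' label row are skipped. Compounds are merged by canonical SMILES so the
#' same structure listed under two herbs collapses into one row.
#'
#' @param herb_labels Data frame: column `herb_id` plus one 0/1 column per
#'   task.
#' @param herb_compounds Data frame with columns `herb_id`, `compound_id`,
#'   `smiles`.
#' @return A [label_matrix()] with one row per unique compound.
#' @export
assemble_compound_labels <- function(herb_labels, herb_compounds) {
  stopifnot("herb_id" %in% names(herb_labels),
            all(c("herb_id", "compound_id", "smiles") %in%
                  names(herb_compounds)))
  task_names <- setdiff(names(herb_labels), "herb_id")
  keep <- herb_compounds$herb_id %in% herb_labels$herb_id
  hc <- herb_compounds[keep, , drop = FALSE]
  if (!nrow(hc)) stop("no labeled compounds: herb tables do not intersect",
                      call. = FALSE)
  can <- canonical_smiles(hc$smiles)
  key <- can
  uniq <- !duplicated(key)
  ids <- hc$compound_id[uniq]
  smi <- can[uniq]
  lab <- matrix(0L, nrow = sum(uniq), ncol = length(task_names),
                dimnames = list(NULL, task_names))
  row_of <- match(key, key[uniq])
  hl <- as.matrix(herb_labels[, task_names, drop = FALSE])
  storage.mode(hl) <- "integer"
  herb_row <- match(hc$herb_id, herb_labels$herb_id)
  for (r in seq_len(nrow(hc))) {
    lab[row_of[r], ] <- pmax(lab[row_of[r], ], hl[herb_row[r], ])
  }
  label_matrix(ids, smi, lab, task_names)
}

# ---------------------------------------------------------------------------
# Delimited-text interfaces
# ---------------------------------------------------------------------------

#' Read and write compound tables
#'
#' A compound table is a CSV with columns `compound_id`, `smiles`, then one
#' 0/1 column per task.
#'
#' @param path File path.
#' @return `read_compound_table()` returns a [label_matrix()].
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("compound_id", "smiles") %in% names(df)))
  tasks <- setdiff(names(df), c("compound_id", "smiles"))
  label_matrix(df$compound_id, df$smiles,
               as.matrix(df[, tasks, drop = FALSE]), tasks)
}

#' @rdname read_compound_table
#' @param x A `label_matrix`.
#' @export
write_compound_table <- function(x, path) {
  stopifnot(inherits(x, "label_matrix"))
  df <- data.frame(compound_id = x$compound_ids, smiles = x$smiles,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(x$labels, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a .smi SMILES list file
#'
#' One record per line: SMILES, optionally followed by whitespace and an id.
#'
#' @param path File path.
#' @return Named character vector of SMILES (names are ids when present).
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  smi <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                character(1))
  if (any(nzchar(ids))) names(smi) <- ids
  smi
}

#' Export a fingerprint matrix as delimited text
#'
#' Writes a dense 0/1 matrix (rows = compounds, columns = bit indices) so
#' external baseline classifiers can consume the fingerprints.
#'
#' @param smiles Character vector of SMILES.
#' @param path Output path (tab-separated).
#' @param ids Optional row identifiers.
#' @param radius,n_bits Fingerprint parameters (radius 2, 1024 bits is the
#'   ECFP4 setting).
#' @return The matrix, invisibly.
#' @export
write_fingerprint_matrix <- function(smiles, path, ids = NULL,
                                     radius = 2, n_bits = 1024) {
  fp <- fingerprint_matrix(smiles, radius = radius, n_bits = n_bits)
  df <- data.frame(compound_id = if (is.null(ids)) seq_along(smiles) else ids)
  df <- cbind(df, as.data.frame(fp))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(fp)
}
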
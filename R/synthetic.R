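# ---------------------------------------------------------------------------
# Synthetic planted-motif molecular datasets.
#
# Molecules are assembled by seeded random concatenation of 2-6 fragments
# from a built-in library of valence-safe SMILES fragments (every fragment
# starts and ends with an atom that tolerates one extra single bond, so any
# concatenation is a valid SMILES). Task positives additionally incorporate
# that task's motif fragment at a random position. Labels are then defined
# honestly by substructure containment, so they remain correct even when
# motifs interact; the base library is crafted so no task motif can arise
# by chance from base fragments alone.
# ---------------------------------------------------------------------------

#' Built-in fragment library
#'
#' ~30 chain-safe SMILES fragments (alkyl chains and branches, benzene
#' rings, cycloalkanes, internal ethers and ketones). The library
#' deliberately contains no N, S, halogens, alkenes/alkynes, O at a
#' fragment boundary, or carbonyl-adjacent O, so the default task motifs
#' cannot be formed accidentally by concatenation.
#'
#' @return Character vector of SMILES fragments.
#' @export
fragment_library <- function() {
  c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCCC",
    "C(C)C", "CC(C)C", "C(C)(C)C", "CC(C)(C)C", "CCC(C)CC",
    "COC", "CCOC", "CCOCC", "CCCOC", "CC(C)OC(C)C",
    "CC(=O)C", "CC(=O)CC", "CCC(=O)C",
    "c1ccccc1", "c1ccc(C)cc1", "c1ccc(CC)cc1", "c1ccccc1C",
    "C1CCCCC1", "C1CCCC1", "C1CC1", "C1CCCCCC1",
    "CC1CCCCC1", "C1CCCCC1C")
}

#' Default task motifs
#'
#' One planted substructure per task; each contains a feature (element,
#' bond order or aromatic heteroatom) absent from [fragment_library()] and
#' no motif matches a molecule planted with a different motif.
#'
#' @param n_tasks How many motifs to return (up to 12).
#' @return Character vector of SMILES fragments, named by task.
#' @export
task_motifs <- function(n_tasks = 12L) {
  motifs <- c("C(=O)OC",        # ester
              "C(Cl)",          # chloro carbon
              "C(F)(F)",        # gem-difluoro
              "CSC",            # thioether
              "c1ccncc1",       # pyridine
              "C(C#N)",         # nitrile branch
              "OCO",            # acetal oxygen pattern
              "C(Br)",          # bromo carbon
              "N(C)C",          # tertiary amine
              "C(I)",           # iodo carbon
              "c1ccc(O)cc1",    # phenol
              "C=C")            # alkene
  stopifnot(n_tasks >= 1, n_tasks <= length(motifs))
  stats::setNames(motifs[seq_len(n_tasks)],
                  meridian_tasks()[seq_len(n_tasks)])
}

#' Synthetic dataset specification
#'
#' The default emulates the imbalance profile of the herb-Meridian data:
#' 761 compounds, 12 tasks with positive fractions from 0.53 down to 0.007
#' (the per-Meridian herb counts scaled by the 761 labeled herbs).
#'
#' @param n_molecules Number of molecules.
#' @param n_tasks Number of tasks.
#' @param positive_fraction Per-task positive fraction in (0, 1); recycled
#'   to `n_tasks`.
#' @param motifs Per-task planted substructures (SMILES fragments).
#' @param label_noise Probability in \[0, 0.5) of flipping each label cell.
#' @param seed Integer seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_molecules = 761L, n_tasks = 12L,
                       positive_fraction = c(0.53, 0.37, 0.34, 0.32, 0.28,
                                             0.26, 0.17, 0.08, 0.05, 0.035,
                                             0.007, 0.007)[seq_len(n_tasks)],
                       motifs = task_motifs(n_tasks),
                       label_noise = 0, seed = 1L) {
  positive_fraction <- rep_len(positive_fraction, n_tasks)
  stopifnot(n_molecules >= 1, n_tasks >= 1,
            all(positive_fraction > 0), all(positive_fraction < 1),
            length(motifs) == n_tasks,
            label_noise >= 0, label_noise < 0.5)
  if (any(round(positive_fraction * n_molecules) > n_molecules)) {
    stop("synth_spec: positives exceed n_molecules", call. = FALSE)
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 n_tasks = as.integer(n_tasks),
                 positive_fraction = positive_fraction,
                 motifs = motifs, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate synthetic molecules
#'
#' Each molecule is a concatenation of 2-6 random library fragments; for
#' each task, `round(fraction * n)` molecules (sampled without replacement)
#' get that task's motif spliced in at a random interior position. All
#' outputs are valid SMILES.
#'
#' @param spec A [synth_spec()].
#' @return Character vector of SMILES of length `spec$n_molecules`, with
#'   attribute `planted` (logical matrix, molecules x tasks).
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  lib <- fragment_library()
  n <- spec$n_molecules
  frag_lists <- lapply(seq_len(n), function(i) {
    k <- sample(2:6, 1)
    sample(lib, k, replace = TRUE)
  })
  planted <- matrix(FALSE, n, spec$n_tasks,
                    dimnames = list(NULL, names(spec$motifs)))
  for (t in seq_len(spec$n_tasks)) {
    n_pos <- round(spec$positive_fraction[t] * n)
    if (n_pos > n) stop("generate_molecules: infeasible positive count",
                        call. = FALSE)
    pos <- sample.int(n, n_pos)
    planted[pos, t] <- TRUE
    for (i in pos) {
      at <- sample.int(length(frag_lists[[i]]) + 1L, 1) - 1L
      frag_lists[[i]] <- append(frag_lists[[i]], spec$motifs[t], after = at)
    }
  }
  smiles <- vapply(frag_lists, paste, character(1), collapse = "")
  attr(smiles, "planted") <- planted
  smiles
}

#' Generate labels by substructure containment
#'
#' A cell is 1 iff the molecule contains the task motif as a substructure;
#' each cell is then flipped independently with probability
#' `spec$label_noise` (noise draws are seeded by `spec$seed + 1`).
#'
#' @param molecules SMILES from [generate_molecules()] (or any SMILES).
#' @param spec A [synth_spec()].
#' @param graphs Optional pre-parsed `mol_graph` list for `molecules`.
#' @return A [label_matrix()].
#' @export
generate_labels <- function(molecules, spec, graphs = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(graphs)) graphs <- parse_molecules(as.character(molecules))
  motif_graphs <- parse_molecules(spec$motifs)
  y <- matrix(0L, length(graphs), spec$n_tasks,
              dimnames = list(NULL, names(spec$motifs)))
  for (t in seq_len(spec$n_tasks)) {
    y[, t] <- vapply(graphs, has_substructure, logical(1),
                     motif = motif_graphs[[t]])
  }
  if (spec$label_noise > 0) {
    set.seed(spec$seed + 1L)
    flip <- matrix(stats::runif(length(y)) < spec$label_noise, nrow(y))
    y[flip] <- 1L - y[flip]
  }
  label_matrix(sprintf("mol%05d", seq_along(graphs)),
               as.character(molecules), y, names(spec$motifs))
}

#' Simulate a complete compound table
#'
#' Runs [generate_molecules()] then [generate_labels()] and returns the
#' table plus parsed graphs, ready for splitting and training.
#'
#' @param spec A [synth_spec()].
#' @return List with `labels` (a [label_matrix()]), `graphs`, `spec`.
#' @export
simulate_dataset <- function(spec = synth_spec()) {
  smiles <- generate_molecules(spec)
  graphs <- parse_molecules(as.character(smiles))
  labels <- generate_labels(smiles, spec, graphs = graphs)
  list(labels = labels, graphs = graphs, spec = spec)
}

#' Focal-loss imbalance benchmark
#'
#' Trains the GCN on planted-motif data across a grid of positive fractions
#' and focal-loss settings, recording test AUC and minority-class recall at
#' threshold 0.5 for each (fraction, gamma, alpha, seed) cell. The
#' `gamma = 0, alpha = 0.5` rows correspond to (scaled) cross-entropy
#' training.
#'
#' @param fractions Positive fractions to test.
#' @param gammas,alphas Focal-loss settings (paired with `expand.grid`).
#' @param seeds Integer seeds; one run per grid cell per seed.
#' @param n_molecules,label_noise Dataset conditions.
#' @param config Base [fit_config()]; gamma/alpha/seed are overridden per
#'   cell.
#' @param motif Planted motif for the single task.
#' @return Data frame: fraction, gamma, alpha, seed, test_auc,
#'   minority_recall.
#' @export
imbalance_benchmark <- function(fractions = c(0.02, 0.1, 0.3),
                                gammas = c(0, 2), alphas = 0.5,
                                seeds = 1:3, n_molecules = 500L,
                                label_noise = 0,
                                config = fit_config(depth = 2L, width = 64L,
                                                    epochs = 40L),
                                motif = task_motifs(1L)) {
  grid <- expand.grid(fraction = fractions, gamma = gammas, alpha = alphas,
                      seed = seeds)
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    spec <- synth_spec(n_molecules = n_molecules, n_tasks = 1L,
                       positive_fraction = g$fraction, motifs = motif,
                       label_noise = label_noise, seed = g$seed)
    ds <- simulate_dataset(spec)
    split <- stratified_split(ds$labels, seed = g$seed)
    cfg <- config
    cfg$gamma <- g$gamma; cfg$alpha <- g$alpha; cfg$seed <- g$seed
    fit <- fit_gcn(ds$graphs, ds$labels, split, cfg)
    rep <- evaluate_model(fit$params, ds$graphs, ds$labels, split$test)
    tp <- rep$per_task$tp[1]; fn <- rep$per_task$fn[1]
    rows[[r]] <- data.frame(fraction = g$fraction, gamma = g$gamma,
                            alpha = g$alpha, seed = g$seed,
                            test_auc = rep$per_task$auc[1],
                            minority_recall = if (tp + fn > 0)
                              tp / (tp + fn) else NA_real_)
  }
  do.call(rbind, rows)
}
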
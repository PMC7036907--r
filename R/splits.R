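# ---------------------------------------------------------------------------
# Dataset splitting: index, random, iterative multi-label stratified, and
# Bemis-Murcko scaffold splits, all 80/10/10 train/valid/test.
# ---------------------------------------------------------------------------

.resample <- function(x) x[sample.int(length(x))]

.split_result <- function(train, valid, test, strategy, seed,
                          fractions = c(0.8, 0.1, 0.1)) {
  structure(list(train = as.integer(train), valid = as.integer(valid),
                 test = as.integer(test), strategy = strategy,
                 seed = seed, fractions = fractions),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("split_result (", x$strategy, "): ",
      length(x$train), "/", length(x$valid), "/", length(x$test),
      " train/valid/test\n", sep = "")
  invisible(x)
}

# largest-remainder apportionment keeps every fold within one sample of
# its exact fractional size (floor(0.8n)/floor(0.1n)/rest can drift almost
# two samples on the remainder fold)
.split_sizes <- function(n, fractions = c(0.8, 0.1, 0.1)) {
  .apportion(n, fractions)
}

#' Index-based split
#'
#' First 80% of samples (in input order) become the training set, the next
#' 10% validation, and the remainder test.
#'
#' @param n Number of samples (>= 10).
#' @return A `split_result` with 1-based index vectors.
#' @export
index_split <- function(n) {
  if (n < 10) stop("index_split: need n >= 10", call. = FALSE)
  s <- .split_sizes(n)
  .split_result(seq_len(s[1]), seq_len(s[2]) + s[1],
                seq_len(s[3]) + s[1] + s[2], "index", NA_integer_)
}

#' Random split
#'
#' Permutes the sample order with a seeded generator, then applies the
#' index split to the permutation.
#'
#' @param n Number of samples (>= 10).
#' @param seed Integer seed.
#' @return A `split_result`.
#' @export
random_split <- function(n, seed = 1L) {
  if (n < 10) stop("random_split: need n >= 10", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  s <- .split_sizes(n)
  .split_result(perm[seq_len(s[1])], perm[seq_len(s[2]) + s[1]],
                perm[seq_len(s[3]) + s[1] + s[2]], "random", seed)
}

#' Iterative multi-label stratified split
#'
#' Processes tasks from rarest to most common; for each task, distributes
#' its not-yet-assigned positive samples 80/10/10 at random, placing one in
#' any fold that still lacks a positive for that task first, so that every
#' task with at least 3 positives ends with at least one positive per fold.
#' Remaining samples fill the folds to their target sizes at random. Tasks
#' with 1-2 positives place their positives in train (with a warning);
#' all-negative tasks are unconstrained.
#'
#' @param labels A [label_matrix()] or a binary matrix (samples x tasks).
#' @param seed Integer seed.
#' @return A `split_result`.
#' @export
stratified_split <- function(labels, seed = 1L) {
  y <- if (inherits(labels, "label_matrix")) labels$labels else
    as.matrix(labels)
  n <- nrow(y)
  if (n < 10) stop("stratified_split: need n >= 10", call. = FALSE)
  if (!any(y == 1)) stop("stratified_split: no positive labels",
                         call. = FALSE)
  set.seed(seed)
  sizes <- .split_sizes(n)
  fold <- rep(0L, n)                      # 0 unassigned, 1 train, 2 valid, 3 test
  room <- sizes
  task_order <- order(colSums(y))
  place <- function(samples, f) {
    take <- min(length(samples), room[f])
    if (take > 0) {
      fold[samples[seq_len(take)]] <<- f
      room[f] <<- room[f] - take
      samples <- samples[-seq_len(take)]
    }
    samples
  }
  for (k in task_order) {
    p_all <- which(y[, k] == 1)
    if (!length(p_all)) {
      warning("task ", k, " has no positives; no stratification constraint")
      next
    }
    un <- p_all[fold[p_all] == 0L]
    if (!length(un)) next
    if (length(p_all) < 3) {
      warning("task ", k, " has fewer than 3 positives; placed in train")
      place(.resample(un), 1L)
      next
    }
    un <- .resample(un)
    # evict a sample from full fold f whose tasks all keep >= 2 positives
    # there, returning it to the unassigned pool; FALSE when impossible
    free_slot <- function(f) {
      for (s in .resample(which(fold == f))) {
        tasks_s <- which(y[s, ] == 1)
        if (k %in% tasks_s) next
        movable <- all(vapply(tasks_s, function(j) {
          sum(y[fold == f, j]) >= 2
        }, logical(1)))
        if (movable) {
          fold[s] <<- 0L
          room[f] <<- room[f] + 1L
          return(TRUE)
        }
      }
      FALSE
    }
    # coverage first: every fold must see a positive of this task
    for (f in 1:3) {
      if (!length(un)) break
      if (sum(fold[p_all] == f) > 0L) next
      if (room[f] > 0L || free_slot(f)) {
        place(un[1], f)
        un <- un[-1]
        next
      }
      # fold full and nothing freely evictable: swap out a sample whose
      # sole-carrier tasks the incoming positive also covers
      swapped <- FALSE
      for (s_out in .resample(which(fold == f))) {
        if (y[s_out, k] == 1) next
        crit <- which(y[s_out, ] == 1)
        crit <- crit[vapply(crit, function(j) sum(y[fold == f, j]) == 1,
                            logical(1))]
        cand_in <- un[vapply(un, function(s) all(y[s, crit] == 1),
                             logical(1))]
        if (length(cand_in)) {
          fold[s_out] <- 0L
          fold[cand_in[1]] <- f
          un <- setdiff(un, cand_in[1])
          swapped <- TRUE
          break
        }
      }
      if (!swapped) {
        warning("fold ", f, " cannot receive a positive of task ", k)
      }
    }
    if (!length(un)) next
    # allocate the task's FULL positive count 80/10/10, minus the
    # positives already assigned while stratifying rarer tasks
    target <- .apportion(length(p_all), c(0.8, 0.1, 0.1))
    existing <- vapply(1:3, function(f) sum(fold[p_all] == f), integer(1))
    counts <- pmax(target - existing, 0L)
    excess <- sum(counts) - length(un)
    while (excess > 0) {                   # trim, largest first
      cand <- which(counts > 0L)
      f <- cand[which.max(counts[cand])]
      counts[f] <- counts[f] - 1L
      excess <- excess - 1L
    }
    if (excess < 0) counts[1] <- counts[1] - excess   # extras go to train
    ix <- 0L
    for (f in 1:3) {
      if (counts[f] > 0) {
        un_f <- un[ix + seq_len(counts[f])]
        ix <- ix + counts[f]
        leftover <- place(un_f, f)
        # fold full: spill into the fold with most room
        while (length(leftover) && any(room > 0)) {
          g <- which.max(room)
          leftover <- place(leftover, g)
        }
      }
    }
  }
  rest <- .resample(which(fold == 0L))
  for (f in 1:3) rest <- place(rest, f)
  .split_result(which(fold == 1L), which(fold == 2L), which(fold == 3L),
                "random_stratified", seed)
}

# split m items into integer counts proportional to fractions
# (largest-remainder rule)
.apportion <- function(m, fractions) {
  raw <- m * fractions
  base <- floor(raw)
  left <- m - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Bemis-Murcko scaffold split
#'
#' Groups molecules by identical canonical scaffold (ring systems plus
#' linkers; acyclic molecules form one shared group), sorts groups by size
#' descending (ties broken by scaffold string), and assigns whole groups
#' greedily: to train until it holds at least 80% of samples, then to
#' validation until 10%, remainder to test. Molecules sharing a scaffold
#' therefore never straddle folds.
#'
#' @param smiles Character vector of SMILES (or list of `mol_graph`s).
#' @param seed Kept for interface symmetry; the allocation is
#'   deterministic.
#' @return A `split_result`.
#' @export
scaffold_split <- function(smiles, seed = 1L) {
  n <- if (is.character(smiles)) length(smiles) else length(smiles)
  if (n < 10) stop("scaffold_split: need n >= 10", call. = FALSE)
  keys <- scaffold_keys(smiles)
  groups <- split(seq_len(n), keys)
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  target_tr <- 0.8 * n; target_va <- 0.1 * n
  train <- integer(0); valid <- integer(0); test <- integer(0)
  for (g in groups) {
    if (length(train) < target_tr) {
      train <- c(train, g)
    } else if (length(valid) < target_va) {
      valid <- c(valid, g)
    } else {
      test <- c(test, g)
    }
  }
  .split_result(train, valid, test, "scaffold", seed)
}

#' Dispatch a split strategy by name
#'
#' @param strategy One of `"index"`, `"random"`, `"random_stratified"`,
#'   `"scaffold"`.
#' @param labels A [label_matrix()] (supplies n, labels and SMILES).
#' @param seed Integer seed.
#' @return A `split_result`.
#' @export
make_split <- function(strategy = c("random_stratified", "random",
                                    "index", "scaffold"),
                       labels, seed = 1L) {
  strategy <- match.arg(strategy)
  n <- nrow(labels$labels)
  switch(strategy,
         index = index_split(n),
         random = random_split(n, seed),
         random_stratified = stratified_split(labels, seed),
         scaffold = scaffold_split(labels$smiles, seed))
}

#' Write split index files plus a provenance sidecar
#'
#' Writes `train.idx`, `valid.idx`, `test.idx` (one compound id per line)
#' and `split.json` (strategy, seed, fractions, per-task positive counts
#' per fold) into `dir`.
#'
#' @param split A `split_result`.
#' @param labels A [label_matrix()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- labels$compound_ids
  for (f in c("train", "valid", "test")) {
    writeLines(ids[split[[f]]], file.path(dir, paste0(f, ".idx")))
  }
  counts <- lapply(c(train = "train", valid = "valid", test = "test"),
                   function(f) {
                     as.list(colSums(labels$labels[split[[f]], ,
                                                   drop = FALSE]))
                   })
  jsonlite::write_json(
    list(strategy = split$strategy, seed = split$seed,
         fractions = split$fractions, positives_per_fold = counts),
    file.path(dir, "split.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
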
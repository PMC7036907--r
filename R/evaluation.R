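# ---------------------------------------------------------------------------
# Confusion matrices, ROC-AUC (per task and macro), task cosine similarity.
# ---------------------------------------------------------------------------

#' Confusion matrix at a probability threshold
#'
#' A sample is predicted positive iff its score is at least `threshold`.
#'
#' @param y Binary target vector.
#' @param y_hat Probability/score vector of equal length.
#' @param threshold Decision threshold (default 0.5).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_matrix <- function(y, y_hat, threshold = 0.5) {
  if (length(y) != length(y_hat) || !length(y)) {
    stop("confusion_matrix: length mismatch or empty input", call. = FALSE)
  }
  pred <- y_hat >= threshold
  c(tp = sum(pred & y == 1), fp = sum(pred & y == 0),
    tn = sum(!pred & y == 0), fn = sum(!pred & y == 1))
}

#' ROC-AUC (Mann-Whitney)
#'
#' Probability that a random positive is scored above a random negative,
#' with half credit for ties: computed via midranks, equivalent to
#' `(#\{score_pos > score_neg\} + 0.5 #ties) / (n_pos * n_neg)`.
#'
#' @param y Binary target vector with at least one positive and one
#'   negative.
#' @param y_hat Score vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc: undefined for single-class input", call. = FALSE)
  }
  r <- rank(y_hat, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro-averaged AUC
#'
#' Unweighted mean over tasks with a defined AUC (tasks whose evaluation
#' set has a single class are skipped, not imputed).
#'
#' @param aucs Numeric vector of per-task AUCs, `NA` where undefined, or an
#'   `eval_report`.
#' @return Scalar macro AUC.
#' @export
macro_auc <- function(aucs) {
  if (inherits(aucs, "eval_report")) aucs <- aucs$per_task$auc
  if (all(is.na(aucs))) {
    stop("macro_auc: no task has a defined AUC", call. = FALSE)
  }
  mean(aucs, na.rm = TRUE)
}

#' Evaluate multi-task predictions
#'
#' Per-task confusion matrices at a fixed threshold and ROC-AUCs, plus the
#' macro average over tasks with a defined AUC.
#'
#' @param y Binary matrix (samples x tasks) or [label_matrix()].
#' @param y_hat Probability matrix of matching shape.
#' @param threshold Confusion-matrix threshold.
#' @param task_names Optional task names.
#' @return An `eval_report`: list with `per_task` (data frame: task, tp,
#'   fp, tn, fn, auc, n) and `macro_auc`.
#' @export
evaluate_predictions <- function(y, y_hat, threshold = 0.5,
                                 task_names = NULL) {
  if (inherits(y, "label_matrix")) {
    if (is.null(task_names)) task_names <- y$task_names
    y <- y$labels
  }
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  stopifnot(all(dim(y) == dim(y_hat)))
  K <- ncol(y)
  if (is.null(task_names)) task_names <- colnames(y)
  if (is.null(task_names)) task_names <- paste0("task", seq_len(K))
  rows <- lapply(seq_len(K), function(k) {
    cm <- confusion_matrix(y[, k], y_hat[, k], threshold)
    auc <- if (min(y[, k]) == max(y[, k])) NA_real_ else
      roc_auc(y[, k], y_hat[, k])
    data.frame(task = task_names[k], tp = cm["tp"], fp = cm["fp"],
               tn = cm["tn"], fn = cm["fn"], auc = auc, n = nrow(y),
               row.names = NULL)
  })
  per_task <- do.call(rbind, rows)
  structure(list(per_task = per_task,
                 macro_auc = macro_auc(per_task$auc),
                 threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: macro AUC", sprintf("%.4f", x$macro_auc),
      "over", sum(!is.na(x$per_task$auc)), "defined tasks\n")
  print(x$per_task)
  invisible(x)
}

#' Cosine similarity between task label columns
#'
#' Entry (i, j) is the cosine of the angle between the binary label columns
#' of tasks i and j; the diagonal is 1 and the mean of the off-diagonal
#' entries is attached as attribute `offdiag_mean`. All-zero columns yield
#' `NA` entries (flagged with a warning).
#'
#' @param labels A [label_matrix()] or binary matrix (samples x tasks).
#' @return Symmetric matrix with unit diagonal.
#' @export
label_cosine_matrix <- function(labels) {
  y <- if (inherits(labels, "label_matrix")) labels$labels else
    as.matrix(labels)
  nrm <- sqrt(colSums(y^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning("all-zero task columns have undefined cosine similarity: ",
            paste(colnames(y)[zero], collapse = ", "))
  }
  cp <- crossprod(y)
  denom <- outer(nrm, nrm)
  sim <- cp / denom
  sim[!is.finite(sim)] <- NA_real_
  d <- diag(sim); d[!zero] <- 1; diag(sim) <- d
  off <- sim[upper.tri(sim)]
  attr(sim, "offdiag_mean") <- mean(off, na.rm = TRUE)
  sim
}

#' Evaluate a trained model on an index set
#'
#' Forward pass in eval mode on the selected molecules followed by
#' [evaluate_predictions()].
#'
#' @param params A `gcn_params`.
#' @param graphs List of `mol_graph`s (full dataset).
#' @param labels A [label_matrix()].
#' @param indices Evaluation indices (e.g. `split$test`).
#' @param threshold Confusion-matrix threshold.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(params, graphs, labels, indices,
                           threshold = 0.5) {
  probs <- gcn_forward(params, graphs[indices], mode = "eval")
  evaluate_predictions(labels$labels[indices, , drop = FALSE], probs,
                       threshold, labels$task_names)
}
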
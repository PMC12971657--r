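# Multiclass evaluation: confusion counts, precision/recall/F1 with the
# zero-denominator-gives-zero convention, rank-based one-vs-rest AUC with
# mid-rank tie handling, and macro (unweighted) averaging across classes.

#' Confusion matrix and one-vs-rest counts
#'
#' @param y_true,y_pred Integer label vectors in `0..k-1`, equal length.
#' @param k Number of classes.
#' @return List with `matrix` (`k x k`, rows = true class, columns =
#'   predicted) and `per_class`, a list of `(TP, TN, FP, FN)` count vectors.
#' @export
confusion <- function(y_true, y_pred, k) {
  if (length(y_true) != length(y_pred)) stop("label vectors must have equal length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(y_true < 0L | y_true >= k) || any(y_pred < 0L | y_pred >= k)) {
    stop("labels out of range [0, ", k, ")")
  }
  m <- matrix(0L, k, k, dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_along(y_true)) {
    m[y_true[i] + 1L, y_pred[i] + 1L] <- m[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  n <- length(y_true)
  per_class <- lapply(seq_len(k), function(ci) {
    tp <- m[ci, ci]
    fn <- sum(m[ci, ]) - tp
    fp <- sum(m[, ci]) - tp
    c(TP = tp, TN = n - tp - fn - fp, FP = fp, FN = fn)
  })
  names(per_class) <- paste0("class", 0:(k - 1))
  list(matrix = m, per_class = per_class)
}

#' Precision, recall and F1 from one-vs-rest counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F1` their harmonic mean;
#' any zero denominator yields 0 by convention (flagged in the `degenerate`
#' field).
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN` (as produced by
#'   [confusion()]).
#' @return Named list `precision`, `recall`, `f1`, `degenerate`.
#' @export
prf1 <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  degenerate <- character(0)
  p <- if (tp + fp == 0) { degenerate <- c(degenerate, "precision"); 0 } else tp / (tp + fp)
  r <- if (tp + fn == 0) { degenerate <- c(degenerate, "recall"); 0 } else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, degenerate = degenerate)
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' `AUC = (sum of positive ranks - M(M+1)/2) / (M * N)` with ascending ranks
#' and mid-ranks for ties, which equals the probability that a random
#' positive outscores a random negative (ties counting one half). Perfect
#' separation gives 1.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param is_positive Logical vector marking the positive samples.
#' @return The AUC as a single number.
#' @export
auc_rank <- function(scores, is_positive) {
  if (length(scores) != length(is_positive)) stop("scores/labels length mismatch")
  if (!all(is.finite(scores))) stop("scores must be finite")
  is_positive <- as.logical(is_positive)
  M <- sum(is_positive); N <- sum(!is_positive)
  if (M == 0L) stop("AUC undefined: no positive samples")
  if (N == 0L) stop("AUC undefined: no negative samples")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - M * (M + 1) / 2) / (M * N)
}

#' ROC curve points
#'
#' @param scores Numeric scores.
#' @param is_positive Logical positives.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_curve <- function(scores, is_positive) {
  is_positive <- as.logical(is_positive)
  M <- sum(is_positive); N <- sum(!is_positive)
  if (M == 0L || N == 0L) stop("ROC undefined without both classes")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- numeric(length(th)); tpr <- numeric(length(th))
  for (i in seq_along(th)) {
    pos_call <- scores >= th[i]
    tpr[i] <- sum(pos_call & is_positive) / M
    fpr[i] <- sum(pos_call & !is_positive) / N
  }
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Evaluate per-class probability scores
#'
#' Argmax predictions feed the confusion matrix and per-class
#' precision/recall/F1; each class's probability column feeds a one-vs-rest
#' rank AUC. Macro values are unweighted means across classes (micro
#' accuracy-style aggregates are reported alongside but are not the headline).
#'
#' @param scores `n x k` matrix of class probabilities (rows summing to ~1).
#' @param y_true Integer labels in `0..k-1`.
#' @return An object of class `metrics_report`: accuracy, per-class and macro
#'   precision/recall/F1 and AUC, the confusion matrix, and per-class ROC
#'   curves.
#' @export
evaluate_scores <- function(scores, y_true) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (length(y_true) != n) stop("scores and labels disagree in length")
  if (any(abs(rowSums(scores) - 1) > 1e-6)) {
    warning("score rows do not sum to 1; treating them as unnormalized scores")
  }
  y_pred <- max.col(scores, ties.method = "first") - 1L
  cm <- confusion(y_true, y_pred, k)
  per <- lapply(cm$per_class, prf1)
  acc <- sum(diag(cm$matrix)) / n
  aucs <- numeric(k); rocs <- vector("list", k)
  for (ci in seq_len(k)) {
    pos <- y_true == (ci - 1L)
    if (!any(pos) || all(pos)) {
      aucs[ci] <- NA_real_
      rocs[[ci]] <- NULL
      warning("class ", ci - 1L, " absent on one side; its AUC is NA")
    } else {
      aucs[ci] <- auc_rank(scores[, ci], pos)
      rocs[[ci]] <- roc_curve(scores[, ci], pos)
    }
  }
  pr <- vapply(per, `[[`, 0, "precision")
  rc <- vapply(per, `[[`, 0, "recall")
  f1 <- vapply(per, `[[`, 0, "f1")
  micro_tp <- sum(diag(cm$matrix))
  structure(list(
    accuracy = acc,
    per_class = data.frame(class = 0:(k - 1), precision = pr, recall = rc,
                           f1 = f1, auc = aucs, row.names = NULL),
    macro = list(precision = mean(pr), recall = mean(rc), f1 = mean(f1),
                 auc = mean(aucs, na.rm = TRUE)),
    micro = list(precision = micro_tp / n, recall = micro_tp / n),
    confusion = cm$matrix,
    roc = rocs
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f\n", x$accuracy))
  cat(sprintf("macro precision %.4f | recall %.4f | F1 %.4f | AUC %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$f1, x$macro$auc))
  cat("per class:\n")
  print(x$per_class, digits = 4)
  cat("confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Flat key/value text report plus one two-column (fpr, tpr) CSV per class.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory (created if missing).
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- nrow(report$per_class)
  lines <- c(sprintf("accuracy: %.6f", report$accuracy),
             sprintf("macro_precision: %.6f", report$macro$precision),
             sprintf("macro_recall: %.6f", report$macro$recall),
             sprintf("macro_f1: %.6f", report$macro$f1),
             sprintf("macro_auc: %.6f", report$macro$auc))
  for (ci in seq_len(k)) {
    r <- report$per_class[ci, ]
    lines <- c(lines,
               sprintf("class%d_precision: %.6f", r$class, r$precision),
               sprintf("class%d_recall: %.6f", r$class, r$recall),
               sprintf("class%d_f1: %.6f", r$class, r$f1),
               sprintf("class%d_auc: %.6f", r$class, r$auc))
    if (!is.null(report$roc[[ci]])) {
      utils::write.csv(report$roc[[ci]][, c("fpr", "tpr")],
                       file.path(dir, sprintf("roc_class%d.csv", r$class)),
                       row.names = FALSE)
    }
  }
  writeLines(lines, file.path(dir, "metrics.txt"))
  invisible(file.path(dir, "metrics.txt"))
}
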
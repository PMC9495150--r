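## Evaluation suite: one-vs-rest confusion counts, precision/recall/F1,
## accuracy, top-5 accuracy, pairwise-indicator AUC, average precision /
## mAP, ROC curves (per-class, micro, macro) and 2-D PCA embedding.

#' One-vs-rest confusion counts
#'
#' For every class, counts true/false positives/negatives treating that
#' class as "positive" and all others as "negative".
#'
#' @param predictions Predicted label vector.
#' @param truths True label vector of the same length.
#' @param classes Optional class universe (defaults to the union of labels).
#' @return Data frame with columns `class, TP, FP, FN, TN`.
#' @export
confusion_counts <- function(predictions, truths, classes = NULL) {
  predictions <- as.character(predictions); truths <- as.character(truths)
  if (length(predictions) != length(truths)) {
    stop("confusion_counts: length mismatch")
  }
  if (is.null(classes)) classes <- sort(unique(c(predictions, truths)))
  if (!all(predictions %in% classes) || !all(truths %in% classes)) {
    stop("confusion_counts: label outside the class universe")
  }
  n <- length(truths)
  do.call(rbind, lapply(classes, function(k) {
    tp <- sum(predictions == k & truths == k)
    fp <- sum(predictions == k & truths != k)
    fn <- sum(predictions != k & truths == k)
    data.frame(class = k, TP = tp, FP = fp, FN = fn,
               TN = n - tp - fp - fn, stringsAsFactors = FALSE)
  }))
}

#' Per-class precision, recall and F1
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`; any 0/0 is
#' reported as 0 (with a warning), the convention for classes never
#' predicted or never present.
#'
#' @param counts Data frame from [confusion_counts()].
#' @return `counts` with `precision`, `recall`, `f1` columns appended.
#' @export
prf1 <- function(counts) {
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  if (any((counts$TP + counts$FP) == 0) || any((counts$TP + counts$FN) == 0)) {
    warning("prf1: degenerate class (0/0) reported as 0")
  }
  precision <- safe_div(counts$TP, counts$TP + counts$FP)
  recall <- safe_div(counts$TP, counts$TP + counts$FN)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  cbind(counts, precision = precision, recall = recall, f1 = f1)
}

#' Classification accuracy
#' @param predictions Predicted labels.
#' @param truths True labels.
#' @return Fraction of correct classifications.
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths)) stop("accuracy: length mismatch")
  mean(as.character(predictions) == as.character(truths))
}

#' Top-5 accuracy
#'
#' Fraction of samples whose true class is among the five highest-scoring
#' classes.  Score ties at the fifth rank are broken by ascending class
#' (column) index, deterministically.
#'
#' @param scores `n x K` score matrix (columns named by class, or classes
#'   supplied via `classes`).
#' @param truths True labels (length n).
#' @param k Number of top ranks (default 5).
#' @param classes Optional class names for unnamed columns.
#' @return Top-k accuracy in `[0, 1]`.
#' @export
top5_accuracy <- function(scores, truths, k = 5L, classes = NULL) {
  if (is.null(classes)) classes <- colnames(scores)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(scores)))
  if (ncol(scores) < k) {
    stop("top5_accuracy: need at least ", k, " classes, have ", ncol(scores))
  }
  truths <- as.character(truths)
  hits <- vapply(seq_len(nrow(scores)), function(i) {
    ord <- order(-scores[i, ], seq_len(ncol(scores)))[seq_len(k)]
    truths[i] %in% classes[ord]
  }, logical(1))
  mean(hits)
}

#' Pairwise-indicator AUC
#'
#' The probability that a positive sample's score exceeds a negative
#' sample's, estimated over all positive/negative pairs:
#' `sum_{t0 in D0} sum_{t1 in D1} I[f(t0) < f(t1)] / (|D0| |D1|)`.
#' Ties contribute 0.5 by default; `strict = TRUE` reproduces the bare
#' indicator (ties contribute 0).
#'
#' @param scores_for_class Numeric score vector.
#' @param is_positive Logical vector (`TRUE` = positive sample).
#' @param strict Score ties contribute 0 instead of 0.5? Default `FALSE`.
#' @return AUC in `[0, 1]`.
#' @export
auc_pairwise <- function(scores_for_class, is_positive, strict = FALSE) {
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) {
    stop("auc_pairwise: need at least one positive and one negative")
  }
  if (!strict) {
    r <- rank(scores_for_class, ties.method = "average")
    return((sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg))
  }
  # literal indicator: only strictly greater positive scores count
  neg_sorted <- sort(scores_for_class[!is_positive])
  cnt_lt <- findInterval(scores_for_class[is_positive], neg_sorted,
                         left.open = TRUE)
  sum(cnt_lt) / (n_pos * n_neg)
}

#' Macro and micro AUC over all classes
#'
#' Macro: unweighted mean of per-class one-vs-rest AUCs (classes with no
#' positives or no negatives are skipped with a warning).  Micro: all
#' `(score, indicator)` pairs pooled before a single AUC.
#'
#' @param scores `n x K` score matrix.
#' @param truths True labels.
#' @param classes Optional class names.
#' @return List with `per_class` (named vector), `macro`, `micro`.
#' @export
auc_multiclass <- function(scores, truths, classes = NULL) {
  if (is.null(classes)) classes <- colnames(scores)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(scores)))
  truths <- as.character(truths)
  per <- rep(NA_real_, length(classes)); names(per) <- classes
  for (ci in seq_along(classes)) {
    pos <- truths == classes[ci]
    if (any(pos) && any(!pos)) per[ci] <- auc_pairwise(scores[, ci], pos)
  }
  if (anyNA(per)) {
    warning("auc_multiclass: classes without positives/negatives skipped: ",
            paste(names(per)[is.na(per)], collapse = ", "))
  }
  pooled_pos <- as.vector(vapply(seq_along(classes),
                                 function(ci) truths == classes[ci],
                                 logical(length(truths))))
  list(per_class = per, macro = mean(per, na.rm = TRUE),
       micro = auc_pairwise(as.vector(scores), pooled_pos))
}

#' Average precision for one class
#'
#' Samples are sorted by descending class-k score (ties broken by original
#' index); `AP = sum_s P(k_s) * dR(k_s)` where `P(k_s)` is the precision
#' over the first `s` ranked samples and `dR(k_s)` the recall increment
#' from rank `s-1` to `s`.
#'
#' @param scores_for_class Score vector for the class.
#' @param is_positive Logical vector of ground truth for the class.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores_for_class, is_positive) {
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive)
  if (n_pos == 0) stop("average_precision: class has no positive samples")
  ord <- order(-scores_for_class, seq_along(scores_for_class))
  pos_sorted <- is_positive[ord]
  prec_at <- cumsum(pos_sorted) / seq_along(pos_sorted)
  sum(prec_at[pos_sorted]) / n_pos      # dR = 1/n_pos at each positive
}

#' Mean average precision
#'
#' Unweighted mean of per-class average precisions; classes with no
#' positive samples are skipped with a warning.
#'
#' @param scores `n x K` score matrix.
#' @param truths True labels.
#' @param classes Optional class names.
#' @return mAP in `[0, 1]`.
#' @export
map_score <- function(scores, truths, classes = NULL) {
  if (is.null(classes)) classes <- colnames(scores)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(scores)))
  truths <- as.character(truths)
  aps <- rep(NA_real_, length(classes))
  for (ci in seq_along(classes)) {
    pos <- truths == classes[ci]
    if (any(pos)) aps[ci] <- average_precision(scores[, ci], pos)
  }
  if (anyNA(aps)) {
    warning("map_score: classes without positives skipped")
  }
  mean(aps, na.rm = TRUE)
}

#' ROC curve
#'
#' Thresholds at every distinct score; returns the (FPR, TPR) staircase
#' including the `(0, 0)` and `(1, 1)` endpoints.  The trapezoidal area
#' under this curve equals [auc_pairwise()] (with the 0.5 tie convention).
#'
#' @param scores_for_class Score vector.
#' @param is_positive Logical ground-truth vector.
#' @return Data frame with columns `fpr`, `tpr`, `threshold` (monotone
#'   non-decreasing in both rates).
#' @export
roc_curve <- function(scores_for_class, is_positive) {
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_curve: need at least one positive and one negative")
  }
  thr <- sort(unique(scores_for_class), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(is_positive & scores_for_class >= s),
                numeric(1)) / n_pos
  fpr <- vapply(thr, function(s) sum(!is_positive & scores_for_class >= s),
                numeric(1)) / n_neg
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr), threshold = c(Inf, thr))
}

# Trapezoidal area under an ROC staircase.
roc_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}

#' Per-class, micro- and macro-averaged ROC curves
#'
#' Micro pools every `(score, indicator)` one-vs-rest pair; macro averages
#' per-class TPR over a common FPR grid.
#'
#' @param scores `n x K` score matrix.
#' @param truths True labels.
#' @param classes Optional class names.
#' @param grid_n Number of FPR grid points for the macro average.
#' @return List with `per_class` (list of curves), `micro`, `macro`.
#' @export
roc_multiclass <- function(scores, truths, classes = NULL, grid_n = 101L) {
  if (is.null(classes)) classes <- colnames(scores)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(scores)))
  truths <- as.character(truths)
  per <- list()
  for (ci in seq_along(classes)) {
    pos <- truths == classes[ci]
    if (any(pos) && any(!pos)) {
      per[[classes[ci]]] <- roc_curve(scores[, ci], pos)
    }
  }
  pooled_pos <- as.vector(vapply(seq_along(classes),
                                 function(ci) truths == classes[ci],
                                 logical(length(truths))))
  micro <- roc_curve(as.vector(scores), pooled_pos)
  grid <- seq(0, 1, length.out = grid_n)
  tpr_mat <- vapply(per, function(cv) {
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max,
                  yleft = 0, yright = 1)$y
  }, numeric(grid_n))
  macro <- data.frame(fpr = grid, tpr = rowMeans(tpr_mat))
  list(per_class = per, micro = micro, macro = macro)
}

#' 2-D PCA embedding
#'
#' Flattens each feature matrix (or accepts a sample-by-variable matrix),
#' mean-centers, and projects onto the top `n_components` principal axes
#' via [stats::prcomp()].
#'
#' @param x List of feature matrices, or an `n x p` numeric matrix.
#' @param n_components Number of components (default 2).
#' @return `n x n_components` coordinate matrix.
#' @export
pca_embed <- function(x, n_components = 2L) {
  if (is.list(x)) x <- t(vapply(x, as.vector, numeric(length(x[[1]]))))
  if (nrow(x) < n_components + 1) {
    stop("pca_embed: need more samples than components")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  unname(pr$x[, seq_len(n_components), drop = FALSE])
}

#' Full metrics report for a score set
#'
#' Assembles the seven headline metrics — accuracy, macro precision /
#' recall / F1, macro (and micro) AUC, top-5 accuracy, and mAP — plus the
#' per-class table.  Predictions are the per-row score argmax.
#'
#' @param scores `n x K` row-stochastic score matrix.
#' @param truths True labels (length n).
#' @param classes Optional class names.
#' @return A `metrics_report`: list with `per_class` data frame and
#'   `summary` named list.
#' @export
evaluate_scores <- function(scores, truths, classes = NULL) {
  if (is.null(classes)) classes <- colnames(scores)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(scores)))
  if (!nrow(scores)) stop("evaluate_scores: empty score set")
  truths <- as.character(truths)
  preds <- classes[max.col(scores, "first")]
  tab <- prf1(confusion_counts(preds, truths, classes))
  auc <- auc_multiclass(scores, truths, classes)
  tab$auc <- unname(auc$per_class[tab$class])
  tab$ap <- vapply(seq_along(classes), function(ci) {
    pos <- truths == classes[ci]
    if (any(pos)) average_precision(scores[, ci], pos) else NA_real_
  }, numeric(1))
  summary <- list(
    accuracy = accuracy(preds, truths),
    precision = mean(tab$precision),
    recall = mean(tab$recall),
    f1 = mean(tab$f1),
    auc_macro = auc$macro,
    auc_micro = auc$micro,
    top5_accuracy = if (ncol(scores) >= 5) {
      top5_accuracy(scores, truths, classes = classes)
    } else NA_real_,
    map = mean(tab$ap, na.rm = TRUE))
  structure(list(per_class = tab, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<metrics_report: acc %.4f  prec %.4f  rec %.4f  ",
                     "F1 %.4f  AUC %.4f  top5 %.4f  mAP %.4f>\n"),
              s$accuracy, s$precision, s$recall, s$f1, s$auc_macro,
              if (is.na(s$top5_accuracy)) NaN else s$top5_accuracy, s$map))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Writes `per_class.csv` and `summary.json` into `dir`.
#'
#' @param report A `metrics_report` from [evaluate_scores()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_class, file.path(dir, "per_class.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Evaluate a trained model on a featurized test set
#'
#' @param model A trained `bc_model` (with `classes`).
#' @param X Test features (matrix list or array).
#' @param truths True labels.
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, X, truths) {
  if (!length(truths)) stop("evaluate_model: empty test set")
  scores <- predict_model(model, X)
  evaluate_scores(scores, truths, classes = model_classes(model))
}
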
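#' Binarize score matrices at an operating threshold
#'
#' Scores at or above the threshold map to 1 (the boundary counts as
#' positive), below to 0.
#'
#' @param scores numeric matrix of per-class scores.
#' @param threshold operating threshold in (0, 1).
#' @export
binarize <- function(scores, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stopf("`threshold` must lie strictly between 0 and 1")
  }
  (scores >= threshold) * 1
}

#' Confusion counts for one class
#'
#' @param pred 0/1 predictions.
#' @param truth 0/1 labels.
#' @return list with `TP`, `FP`, `FN`, `TN` (summing to the record count).
#' @export
confusion_counts <- function(pred, truth) {
  list(TP = sum(pred == 1 & truth == 1), FP = sum(pred == 1 & truth == 0),
       FN = sum(pred == 0 & truth == 1), TN = sum(pred == 0 & truth == 0))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(FP+TP)`, `recall = TP/(FN+TP)`, and F1 is their
#' harmonic mean. A zero denominator yields 0 for that metric, with the
#' `degenerate` flag set, so macro averages never propagate NaN.
#'
#' @param counts list with TP, FP, FN (e.g. from [confusion_counts()]),
#'   or the TP count if `FP`/`FN` given separately.
#' @param FP,FN optional counts when `counts` is the TP scalar.
#' @return list with `precision`, `recall`, `f1`, `degenerate`.
#' @export
precision_recall_f1 <- function(counts, FP = NULL, FN = NULL) {
  if (is.list(counts)) {
    TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  } else {
    TP <- counts
  }
  degenerate <- FALSE
  if (TP + FP == 0) { precision <- 0; degenerate <- TRUE } else precision <- TP / (TP + FP)
  if (TP + FN == 0) { recall <- 0; degenerate <- TRUE } else recall <- TP / (TP + FN)
  if (precision + recall == 0) { f1 <- 0; degenerate <- TRUE } else {
    f1 <- 2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1, degenerate = degenerate)
}

#' F1 score from a precision/recall pair
#'
#' Convenience form of the harmonic mean `2 P R / (P + R)`, accepting
#' values on either the [0, 1] or percentage scale.
#'
#' @param precision,recall precision and recall values.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a uniformly random
#' positive record outscores a uniformly random negative one, with ties
#' counting one half. Undefined (NA) when only one label value is present.
#'
#' @param scores numeric score vector for one class.
#' @param labels 0/1 labels.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a model on labeled records
#'
#' Produces the per-class and macro evaluation report: precision, recall,
#' F1 at the operating threshold, and AUROC. Macro values are unweighted
#' means over the classes with defined metrics.
#'
#' @param model an `ncp_model`, or a function mapping input to a score
#'   matrix, or a precomputed score matrix.
#' @param data labeled records (list of recordings or preprocessed
#'   dataset); ignored when `model` is already a score matrix except for
#'   its labels.
#' @param labels optional label matrix overriding the one in `data`.
#' @param threshold operating threshold.
#' @return An `eval_report`: data.frame `per_class`, list `macro`, plus
#'   the threshold used.
#' @export
evaluate_model <- function(model, data, labels = NULL, threshold = 0.5) {
  if (is.matrix(model)) {
    scores <- model
  } else {
    scores <- predict_scores(model, data)
  }
  y <- labels
  if (is.null(y)) {
    y <- if (is.list(data) && !is.null(data$y)) data$y else label_matrix(data)
  }
  if (nrow(y) == 0) stopf("empty evaluation set")
  stopifnot(nrow(y) == nrow(scores), ncol(y) == ncol(scores))
  pred <- binarize(scores, threshold)
  cls <- colnames(y) %||% ECG_CLASSES[seq_len(ncol(y))]
  rows <- lapply(seq_len(ncol(y)), function(k) {
    prf <- precision_recall_f1(confusion_counts(pred[, k], y[, k]))
    defined <- length(unique(y[, k])) > 1
    data.frame(class = cls[k],
               precision = prf$precision, recall = prf$recall, f1 = prf$f1,
               auroc = auroc(scores[, k], y[, k]),
               degenerate = prf$degenerate, undefined = !defined)
  })
  per_class <- do.call(rbind, rows)
  ok <- !per_class$undefined
  macro <- list(precision = mean(per_class$precision[ok]),
                recall = mean(per_class$recall[ok]),
                f1 = mean(per_class$f1[ok]),
                auroc = mean(per_class$auroc[ok]))
  structure(list(per_class = per_class, macro = macro, threshold = threshold,
                 n_records = nrow(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d records, threshold %.2f\n", x$n_records, x$threshold))
  df <- x$per_class
  df[2:5] <- lapply(df[2:5], function(v) sprintf("%.1f%%", 100 * v))
  print(df[, 1:5], row.names = FALSE)
  cat(sprintf("  macro: P %.1f%%  R %.1f%%  F1 %.1f%%  AUROC %.1f%%\n",
              100 * x$macro$precision, 100 * x$macro$recall,
              100 * x$macro$f1, 100 * x$macro$auroc))
  invisible(x)
}
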
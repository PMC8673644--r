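# Confusion matrices, per-class precision/recall, probability-threshold
# sweeps, and bin-level accounting of truly present classes that received no
# label ("none").

#' Confusion matrix
#'
#' Rows are predicted classes, columns true classes; cell (p, t) counts
#' items predicted p with truth t. Row-normalized diagonals give
#' per-predicted-class precision and column-normalized diagonals give
#' per-true-class recall. (Monitoring reports sometimes print the
#' column-wise quantity under the name "precision"; here the row-wise
#' statistic is always called precision and the column-wise one recall.)
#'
#' @param true,pred label vectors of equal length.
#' @param classes class ordering; defaults to the union of observed labels.
#' @param mode `"counts"` or `"percent"` (percent of the total, summing to
#'   100 over all cells).
#' @return a `confusion_matrix`: `table` (matrix), `precision`, `recall`
#'   (named vectors, NA where undefined), `accuracy`, `mode`.
#' @export
confusion <- function(true, pred, classes = NULL,
                      mode = c("counts", "percent")) {
  mode <- match.arg(mode)
  if (length(true) != length(pred)) stopf("label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(c(true, pred)))
  tab <- table(factor(pred, classes), factor(true, classes))
  m <- matrix(as.numeric(tab), length(classes), length(classes),
              dimnames = list(predicted = classes, true = classes))
  total <- sum(m)
  acc <- if (total > 0) sum(diag(m)) / total else NA_real_
  precision <- diag(m) / rowSums(m)
  recall <- diag(m) / colSums(m)
  precision[rowSums(m) == 0] <- NA_real_
  recall[colSums(m) == 0] <- NA_real_
  out <- m
  if (mode == "percent" && total > 0) out <- m / total * 100
  structure(list(table = out, counts = m, precision = precision,
                 recall = recall, accuracy = acc, mode = mode),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat(sprintf("<confusion_matrix> accuracy %.3f (%s)\n", x$accuracy, x$mode))
  print(round(x$table, digits))
  invisible(x)
}

#' Precision/recall sweep over probability thresholds
#'
#' At each threshold only labels with confidence at or above it are
#' retained. Items dropped by the threshold still count against recall
#' (they are missed) but not against precision; with zero retained labels
#' for a class, precision is undefined (NA).
#'
#' @param preds a `prediction_set`.
#' @param true true labels.
#' @param thresholds increasing probability thresholds.
#' @return data.frame with `threshold`, `class`, `precision`, `recall`,
#'   `n_retained`.
#' @export
pr_sweep <- function(preds, true,
                     thresholds = seq(0, 0.95, by = 0.05)) {
  thresholds <- sort(thresholds)
  classes <- preds$class_names
  rows <- list()
  for (tau in thresholds) {
    keep <- preds$score >= tau
    for (cl in classes) {
      pred_cl <- keep & preds$label == cl
      tp <- sum(pred_cl & true == cl)
      n_true <- sum(true == cl)
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = tau, class = cl,
        precision = if (sum(pred_cl) > 0) tp / sum(pred_cl) else NA_real_,
        recall = if (n_true > 0) tp / n_true else NA_real_,
        n_retained = sum(pred_cl)
      )
    }
  }
  do.call(rbind, rows)
}

#' Bin-level confusion with "none" accounting
#'
#' Aligns per-bin class predictions with per-bin truth. For every
#' (bin, true class) pair: a same-class prediction in that bin scores a
#' diagonal cell; otherwise a leftover prediction in the bin scores a
#' confusion cell; otherwise the pair scores in the "none" row — the class
#' was truly present but no cluster/label was produced. Precision and
#' recall are reported both including and excluding the "none" row.
#'
#' @param truth data.frame with columns `bin`, `class`: classes truly
#'   present per bin.
#' @param predictions data.frame with columns `bin`, `class`: labels
#'   emitted per bin.
#' @param classes class ordering (defaults to classes observed in truth).
#' @param include_false_alarms also count predictions matching no truth
#'   class, in a "none" *column*.
#' @return a `confusion_matrix` whose rows include `"none"`, plus
#'   `recall_without_none` (per-class recall ignoring missed bins).
#' @export
bin_level_align <- function(truth, predictions,
                            classes = sort(unique(truth$class)),
                            include_false_alarms = FALSE) {
  pred_only <- setdiff(unique(predictions$class), classes)
  all_rows <- c(classes, pred_only, "none")
  all_cols <- if (include_false_alarms) c(classes, "none") else classes
  m <- matrix(0, length(all_rows), length(all_cols),
              dimnames = list(predicted = all_rows, true = all_cols))
  for (b in unique(truth$bin)) {
    t_cl <- truth$class[truth$bin == b]
    p_cl <- predictions$class[predictions$bin == b]
    # first pass: same-class matches score the diagonal
    remaining_t <- character(0)
    for (cl in t_cl) {
      hit <- match(cl, p_cl)
      if (!is.na(hit)) {
        m[cl, cl] <- m[cl, cl] + 1
        p_cl <- p_cl[-hit]
      } else {
        remaining_t <- c(remaining_t, cl)
      }
    }
    # second pass: leftover predictions absorb unmatched truth classes;
    # truth classes with no prediction at all go to the "none" row
    for (cl in sort(remaining_t)) {
      if (length(p_cl)) {
        m[p_cl[1], cl] <- m[p_cl[1], cl] + 1
        p_cl <- p_cl[-1]
      } else {
        m["none", cl] <- m["none", cl] + 1
      }
    }
    if (include_false_alarms && length(p_cl)) {
      for (cl in p_cl) m[cl, "none"] <- m[cl, "none"] + 1
    }
  }
  counts <- m
  total <- sum(counts)
  diag_idx <- cbind(match(classes, all_rows), match(classes, all_cols))
  acc <- if (total > 0) sum(counts[diag_idx]) / total else NA_real_
  recall_with <- counts[diag_idx] / colSums(counts)[classes]
  no_none <- counts[setdiff(all_rows, "none"), , drop = FALSE]
  recall_without <- no_none[cbind(classes, classes)] /
    colSums(no_none)[classes]
  precision <- counts[diag_idx] / rowSums(counts)[classes]
  structure(list(table = counts, counts = counts,
                 precision = precision,
                 recall = recall_with,
                 recall_without_none = recall_without,
                 accuracy = acc, mode = "counts"),
            class = "confusion_matrix")
}

#' Histograms of label confidence scores per predicted class
#'
#' @param preds a `prediction_set`.
#' @param breaks histogram bin edges on \[0, 1\].
#' @return named list of histogram count vectors, one per class.
#' @export
probability_histogram <- function(preds, breaks = seq(0, 1, by = 0.05)) {
  out <- list()
  for (cl in preds$class_names) {
    s <- preds$score[preds$label == cl]
    out[[cl]] <- graphics::hist(s, breaks = breaks, plot = FALSE,
                                include.lowest = TRUE)$counts
  }
  out
}
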
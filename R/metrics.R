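#' Confusion counts at a score threshold
#'
#' An exam is predicted positive when its score is strictly greater than
#' the threshold.
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels binary vector (0 = negative, 1 = positive) of equal length.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("`labels` must be binary 0/1", call. = FALSE)
  pred <- scores > threshold
  structure(list(tp = sum(pred & labels == 1),
                 fp = sum(pred & labels == 0),
                 tn = sum(!pred & labels == 0),
                 fn = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("degenerate denominator for %s; returning 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 from a
#' set of confusion counts. Degenerate denominators (for instance no
#' predicted positives) yield 0 with a warning rather than an error, so
#' batch evaluation never aborts.
#'
#' @param counts a `confusion_counts` object (or list with `tp`, `fp`,
#'   `tn`, `fn`).
#' @return named list: `acc`, `precision`, `recall`, `specificity`, `f1`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated exams", call. = FALSE)
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  list(acc = (tp + tn) / total,
       precision = precision,
       recall = recall,
       specificity = safe_div(tn, tn + fp, "specificity"),
       f1 = safe_div(2 * precision * recall, precision + recall, "F1"))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all unique score values (predicted
#' positive means score strictly greater than the threshold) and computes
#' the false-positive rate `FP / (TN + FP)` and true-positive rate
#' `TP / (TP + FN)` at each, with a `-Inf` sentinel so the curve ends at
#' (1, 1). The AUC is the trapezoidal integral of TPR over FPR, which for
#' this construction equals the Mann-Whitney pairwise statistic with ties
#' counted one half.
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 vector; both classes must be present.
#' @return object of class `roc_curve` with descending `thresholds`,
#'   `fpr`, `tpr`, and scalar `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0L)
    stop("`scores` and `labels` must be non-empty and of equal length",
         call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("`labels` must be binary 0/1", call. = FALSE)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  u <- sort(unique(scores), decreasing = TRUE)
  thresholds <- c(u, -Inf)
  # counts of positives/negatives at each unique score, in descending order
  pos_at <- vapply(u, function(v) sum(scores == v & labels == 1), numeric(1))
  neg_at <- vapply(u, function(v) sum(scores == v & labels == 0), numeric(1))
  # at threshold u[k], predicted positive iff score > u[k]: scores above u[k]
  tp <- c(0, cumsum(pos_at))
  fp <- c(0, cumsum(neg_at))
  tpr <- tp / npos
  fpr <- fp / nneg
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Accuracy-maximizing adaptive threshold
#'
#' Evaluates accuracy at every candidate threshold — the midpoints between
#' adjacent sorted unique scores, plus `-Inf`/`+Inf` sentinels — and
#' returns the candidate with maximal accuracy. Ties are broken by the
#' smallest threshold (favouring sensitivity); a tie is reported with a
#' message. Fit this on validation scores only, then freeze it for test.
#'
#' @param scores validation score vector.
#' @param labels binary 0/1 validation labels; both classes must be present.
#' @return scalar threshold.
#' @export
adaptive_threshold <- function(scores, labels) {
  if (length(scores) == 0L) stop("empty validation set", call. = FALSE)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in validation", call. = FALSE)
  u <- sort(unique(scores))
  cands <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  acc <- vapply(cands, function(t) mean((scores > t) == labels), numeric(1))
  best <- max(acc)
  winners <- which(acc >= best - 1e-15)
  if (length(winners) > 1L)
    message(sprintf("adaptive threshold: %d candidates tie at accuracy %.4f; using smallest",
                    length(winners), best))
  cands[winners[1L]]
}

#' Best epoch by validation AUC
#'
#' @param auc_history numeric vector of per-epoch validation AUC values.
#' @return epoch index of the maximum (earliest in case of ties).
#' @export
select_best_epoch <- function(auc_history) {
  if (length(auc_history) == 0L) stop("empty history", call. = FALSE)
  stop_if_not_finite(auc_history, "auc_history")
  which.max(auc_history)
}

#' Evaluation report for a set of scored exams
#'
#' Builds the confusion counts at the given threshold, the five
#' threshold-dependent metrics, and the threshold-free AUC.
#'
#' @param scores numeric positive-class scores.
#' @param labels binary 0/1 labels (both classes present).
#' @param threshold decision threshold (e.g. from [adaptive_threshold()]
#'   on validation data); default 0.5.
#' @param exam_ids optional identifiers stored alongside the scores.
#' @return object of class `eval_report`: `counts`, `acc`, `precision`,
#'   `recall`, `specificity`, `f1`, `auc`, `threshold`, `scores`,
#'   `labels`, `exam_ids`.
#' @export
eval_report <- function(scores, labels, threshold = 0.5, exam_ids = NULL) {
  counts <- confusion(scores, labels, threshold)
  m <- classification_metrics(counts)
  roc <- roc_auc(scores, labels)
  structure(c(list(counts = counts), m,
              list(auc = roc$auc, roc = roc, threshold = threshold,
                   scores = scores, labels = labels,
                   exam_ids = exam_ids %||% seq_along(scores))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation of %d exams (threshold %.4g)\n",
              length(x$scores), x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  cat(sprintf("  AUC %.4f  ACC %.4f  Precision %.4f  Recall %.4f  Specificity %.4f  F1 %.4f\n",
              x$auc, x$acc, x$precision, x$recall, x$specificity, x$f1))
  invisible(x)
}

#' Write evaluation artifacts to disk
#'
#' Writes a tab-separated metrics table (columns AUC, ACC, Precision,
#' Recall, Specificity, F1 — one row per report), per-report ROC points as
#' two-column text, and a machine-readable JSON run summary.
#'
#' @param reports a single `eval_report` or a named list of them.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"eval"`).
#' @return invisibly, the paths written.
#' @export
write_eval_report <- function(reports, dir, prefix = "eval") {
  if (inherits(reports, "eval_report")) reports <- list(model = reports)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    Model = names(reports),
    AUC = vapply(reports, function(r) r$auc, numeric(1)),
    ACC = vapply(reports, function(r) r$acc, numeric(1)),
    Precision = vapply(reports, function(r) r$precision, numeric(1)),
    Recall = vapply(reports, function(r) r$recall, numeric(1)),
    Specificity = vapply(reports, function(r) r$specificity, numeric(1)),
    F1 = vapply(reports, function(r) r$f1, numeric(1)))
  metrics_path <- file.path(dir, paste0(prefix, "_metrics.tsv"))
  write.table(tab, metrics_path, sep = "\t", row.names = FALSE, quote = FALSE)
  roc_paths <- character(0)
  for (nm in names(reports)) {
    rp <- file.path(dir, paste0(prefix, "_roc_", nm, ".tsv"))
    write.table(data.frame(fpr = reports[[nm]]$roc$fpr,
                           tpr = reports[[nm]]$roc$tpr),
                rp, sep = "\t", row.names = FALSE, quote = FALSE)
    roc_paths <- c(roc_paths, rp)
  }
  summary_path <- file.path(dir, paste0(prefix, "_summary.json"))
  summ <- lapply(reports, function(r)
    list(counts = r$counts[c("tp", "fp", "tn", "fn")],
         auc = r$auc, acc = r$acc, precision = r$precision,
         recall = r$recall, specificity = r$specificity, f1 = r$f1,
         threshold = r$threshold))
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(metrics_path, roc_paths, summary_path))
}
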
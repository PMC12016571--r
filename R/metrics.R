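# Evaluation suite: confusion-matrix statistics (sensitivity, specificity,
# precision, F1, accuracy, MCC) plus threshold-free AUC, aggregated as
# mean +/- sd over repeated splits.

#' Confusion counts from labels and hard predictions
#'
#' @param labels True 0/1 labels.
#' @param predicted Predicted 0/1 labels.
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted),
            all(labels %in% 0:1), all(predicted %in% 0:1))
  c(tp = sum(labels == 1L & predicted == 1L),
    fp = sum(labels == 0L & predicted == 1L),
    tn = sum(labels == 0L & predicted == 0L),
    fn = sum(labels == 1L & predicted == 0L))
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity (recall) TP/(TP+FN), specificity TN/(TN+FP), precision
#' TP/(TP+FP), F1, accuracy and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Ratios with a zero
#' denominator are reported as `NA`, never coerced to 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts, or a single named
#'   vector passed as `tp`.
#' @return Named numeric vector of the six metrics.
#' @export
metrics_from_confusion <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 4L) {
    fp <- tp[["fp"]]; tn <- tp[["tn"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp, fp, tn, fn)
  stopifnot(length(counts) == 4L, all(counts >= 0))
  if (sum(counts) == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  acc <- (tp + tn) / sum(counts)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  c(sensitivity = sens, specificity = spec, precision = prec,
    f1 = f1, accuracy = acc, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator; ties receive average ranks. AUC is
#' therefore invariant under any strictly monotone transform of the scores.
#'
#' @param labels True 0/1 labels.
#' @param scores Numeric prediction scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Aggregate per-repeat metrics into a report
#'
#' @param per_repeat Data frame, one row per repeat, one column per metric.
#' @return A `metrics_report` with `mean`, `sd` (0 when a single repeat) and
#'   the raw per-repeat values.
#' @export
metrics_report <- function(per_repeat) {
  stopifnot(is.data.frame(per_repeat), nrow(per_repeat) >= 1L)
  m <- vapply(per_repeat, mean, numeric(1L), na.rm = TRUE)
  s <- if (nrow(per_repeat) == 1L) setNames(numeric(ncol(per_repeat)),
                                            names(per_repeat))
  else vapply(per_repeat, sd, numeric(1L), na.rm = TRUE)
  structure(list(mean = m, sd = s, raw = per_repeat,
                 n_repeats = nrow(per_repeat)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Evaluation over", x$n_repeats, "repeat(s) (percent):\n")
  for (k in names(x$mean)) {
    cat(sprintf("  %-12s %6.2f ± %.2f\n", k, 100 * x$mean[[k]],
                100 * x$sd[[k]]))
  }
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(metric = names(x$mean), mean = unname(x$mean),
             sd = unname(x$sd), stringsAsFactors = FALSE)
}
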
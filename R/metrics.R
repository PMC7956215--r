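#' Confusion matrix counts
#'
#' @param truth 0/1 ground-truth labels.
#' @param pred 0/1 predicted labels.
#' @return List of class `"confusion_matrix"` with counts `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0,
            all(truth %in% 0:1), all(pred %in% 0:1))
  structure(list(tp = sum(truth == 1 & pred == 1),
                 tn = sum(truth == 0 & pred == 0),
                 fp = sum(truth == 0 & pred == 1),
                 fn = sum(truth == 1 & pred == 0)),
            class = "confusion_matrix")
}

#' Rank-based AUC with ties credited one half
#'
#' `P(X1 > X0) + 0.5 P(X1 = X0)` over all positive/negative score pairs —
#' equivalent to the Mann-Whitney statistic computed from mean ranks. A
#' constant scorer therefore earns exactly 0.5.
#'
#' @param scores numeric decision values, higher meaning more positive.
#' @param truth 0/1 labels aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs both classes present in the truth")
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric set
#'
#' Accuracy `(TP+TN)/total`; AUC as `P(X1 > X0)` with ties credited 0.5
#' ([auc_score()]); Gmean `sqrt(sensitivity * specificity)` with
#' sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`; F1
#' `2TP/(2TP+FP+FN)`, defined as 0 when `TP = 0` with errors present.
#' Degenerate rate denominators (a class absent from the truth) contribute
#' a 0 rate. An all-negative predictor on 100 samples with 5 positives and
#' constant scores illustrates why accuracy alone misleads under
#' imbalance: ACC 0.95 but AUC 0.50, Gmean 0 and F1 0.
#'
#' @param cm a `"confusion_matrix"` from [confusion_counts()].
#' @param scores per-sample decision values (for the AUC).
#' @param truth 0/1 labels aligned with `scores`.
#' @return List of class `"metric_set"`: `acc`, `auc`, `gmean`, `f1`, all
#'   in `[0, 1]`.
#' @export
compute_metrics <- function(cm, scores, truth) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  acc <- (cm$tp + cm$tn) / total
  sens <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
  spec <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else 0
  gmean <- sqrt(sens * spec)
  f1 <- if (2 * cm$tp + cm$fp + cm$fn > 0)
    2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn) else 0
  structure(list(acc = acc, auc = auc_score(scores, truth),
                 gmean = gmean, f1 = f1),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  AUC %.2f%%  Gmean %.2f%%  F1 %.2f%%\n",
              100 * x$acc, 100 * x$auc, 100 * x$gmean, 100 * x$f1))
  invisible(x)
}

#' Annotated confusion report
#'
#' Formats the counts with rows as the predicted class and columns as the
#' true class, annotated the way the per-subject matrices are usually
#' displayed: first row TN, FP and the false-omission rate; second row FN,
#' TP and precision; third row the false-negative rate, specificity and
#' overall accuracy.
#'
#' @param cm a `"confusion_matrix"`.
#' @return Object of class `"confusion_report"`: the 3x3 annotation matrix
#'   (`layout`) plus the raw counts.
#' @export
confusion_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  rate <- function(num, den) if (den > 0) num / den else 0
  layout <- matrix(c(
    cm$tn, cm$fp, rate(cm$fn, cm$tn + cm$fn),        # false-omission rate
    cm$fn, cm$tp, rate(cm$tp, cm$tp + cm$fp),        # precision
    rate(cm$fn, cm$fn + cm$tp),                      # false-negative rate
    rate(cm$tn, cm$tn + cm$fp),                      # specificity
    (cm$tp + cm$tn) / total                          # accuracy
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("pred 0", "pred 1", "rates"),
                  c("true 0", "true 1", "rate")))
  structure(list(layout = layout, counts = cm), class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("confusion report (rows = predicted, columns = true)\n")
  m <- x$layout
  m[1:2, 3] <- round(m[1:2, 3], 4)
  m[3, ] <- round(m[3, ], 4)
  print(m)
  invisible(x)
}

#' Aggregate metric sets over models
#'
#' Arithmetic mean and mean absolute deviation around the mean, per
#' metric — the dispersion convention used to summarize per-subject and
#' leave-one-subject-out model collections.
#'
#' @param metric_sets list of `"metric_set"` objects (>= 1).
#' @return Data frame with one row per metric and columns `mean`, `mad`.
#' @export
aggregate_models <- function(metric_sets) {
  if (!length(metric_sets)) stop("need at least one model")
  ok <- vapply(metric_sets, inherits, logical(1), "metric_set")
  stopifnot(all(ok))
  metrics <- c("acc", "auc", "gmean", "f1")
  vals <- sapply(metrics, function(m)
    vapply(metric_sets, `[[`, numeric(1), m))
  vals <- matrix(vals, ncol = length(metrics),
                 dimnames = list(NULL, metrics))
  data.frame(metric = metrics,
             mean = colMeans(vals),
             mad = apply(vals, 2, function(v) mean(abs(v - mean(v)))),
             row.names = NULL)
}
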
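#' Binarize a PAD self-report into a fear label
#'
#' Fear occupies the low-valence, high-arousal, low-dominance octant of the
#' pleasure-arousal-dominance space. Each 1–9 SAM scale is split at
#' `midpoint` (default 5, the scale center): the label is 1 exactly when
#' `valence <= midpoint`, `arousal > midpoint` and `dominance <= midpoint`,
#' so a rating of 5 counts as "low" for valence and dominance and as "not
#' high" for arousal. With midpoint 5 this maps 100 of the 729 rating
#' combinations to the positive class. The function is pure and vectorized.
#'
#' @param report a [self_report()], or the valence vector when `arousal`
#'   and `dominance` are given.
#' @param arousal,dominance optional numeric vectors (1–9) when calling
#'   with plain ratings.
#' @param midpoint scale split point (default 5).
#' @return Integer 0/1 vector.
#' @examples
#' binarize_pad(self_report(2, 8, 2))   # 1: the fear octant
#' binarize_pad(8, 2, 8)                # 0
#' @export
binarize_pad <- function(report, arousal = NULL, dominance = NULL,
                         midpoint = 5) {
  if (inherits(report, "self_report")) {
    v <- report$valence; a <- report$arousal; d <- report$dominance
  } else {
    v <- report; a <- arousal; d <- dominance
    if (is.null(a) || is.null(d))
      stop("supply a self_report or all three rating vectors")
  }
  bad <- !is.finite(v) | !is.finite(a) | !is.finite(d) |
    v < 1 | v > 9 | a < 1 | a > 9 | d < 1 | d > 9
  if (any(bad)) stop("ratings must lie in [1, 9]")
  as.integer(v <= midpoint & a > midpoint & d <= midpoint)
}

#' Per-subject positive-class fraction
#'
#' Reports the fraction of fear-labeled samples per subject — the imbalance
#' profile that drives the choice of evaluation metrics.
#'
#' @param labels 0/1 vector.
#' @param subject_id vector of subject identifiers aligned with `labels`.
#' @return Named numeric vector of per-subject positive fractions, in
#'   first-appearance order.
#' @export
class_distribution <- function(labels, subject_id) {
  if (!length(labels)) stop("no labels supplied")
  stopifnot(length(labels) == length(subject_id))
  subject_id <- factor(subject_id, levels = unique(as.character(subject_id)))
  vapply(split(labels, subject_id), mean, numeric(1))
}
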
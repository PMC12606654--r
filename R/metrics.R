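# Binary-classification evaluation: confusion counts at a threshold, the
# six scalar statistics (accuracy, sensitivity, specificity, precision,
# F1, Matthews correlation coefficient), and the two curve areas (ROC via
# the tie-corrected rank statistic, precision-recall by interpolation).
# Metrics with a zero denominator are reported as NA, never as 0.

check_labels_scores <- function(labels, scores) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(scores))
    stop("labels and scores have different lengths")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (any(!is.finite(scores))) stop("scores must be finite")
}

#' Confusion counts at a threshold
#'
#' Predictions are `score >= threshold`.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusionCounts(c(1, 0), c(0.9, 0.1))
#' @export
confusionCounts <- function(labels, scores, threshold = 0.5) {
  check_labels_scores(labels, scores)
  pred <- as.integer(scores >= threshold)
  c(TP = sum(pred == 1L & labels == 1),
    TN = sum(pred == 0L & labels == 0),
    FP = sum(pred == 1L & labels == 0),
    FN = sum(pred == 0L & labels == 1))
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Scalar metrics from confusion counts
#'
#' Standard definitions: `acc = (TP+TN)/N`, `sn = TP/(TP+FN)`,
#' `sp = TN/(TN+FP)`, `precision = TP/(TP+FP)`,
#' `f1 = 2*precision*sn/(precision+sn)` and
#' `mcc = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric whose denominator vanishes is `NA`.
#'
#' @param counts named vector from [confusionCounts()].
#' @return Named numeric vector `acc`, `sn`, `sp`, `precision`, `f1`,
#'   `mcc`.
#' @examples
#' scalarMetrics(c(TP = 8, TN = 6, FP = 2, FN = 4))
#' @export
scalarMetrics <- function(counts) {
  tp <- as.numeric(counts["TP"]); tn <- as.numeric(counts["TN"])
  fp <- as.numeric(counts["FP"]); fn <- as.numeric(counts["FN"])
  if (any(is.na(c(tp, tn, fp, fn))) || any(c(tp, tn, fp, fn) < 0))
    stop("counts must be non-negative TP/TN/FP/FN")
  n <- tp + tn + fp + fn
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sn) || prec + sn == 0) NA_real_
        else 2 * prec * sn / (prec + sn)
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  c(acc = safe_div(tp + tn, n), sn = sn, sp = sp, precision = prec,
    f1 = f1, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Computed as the tie-corrected Mann-Whitney rank statistic: the
#' probability that a random positive scores above a random negative,
#' counting ties as one half.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
rocAUC <- function(labels, scores) {
  check_labels_scores(labels, scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Precision-recall points are taken at every distinct score cut-off
#' (ties grouped) and the area is accumulated by linear interpolation in
#' recall, anchored at recall 0 with the precision of the top score
#' group.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores numeric scores.
#' @return AUCPR in `[0, 1]`.
#' @export
prAUC <- function(labels, scores) {
  check_labels_scores(labels, scores)
  n1 <- sum(labels == 1)
  if (n1 == 0L || n1 == length(labels)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp_end <- cumsum(rle(sc)$lengths)        # last index of each tie group
  tp <- cumsum(lab)[grp_end]
  pred_pos <- grp_end
  prec <- tp / pred_pos
  rec <- tp / n1
  area <- prec[1] * rec[1]                  # anchor segment from recall 0
  if (length(rec) > 1L)
    area <- area + sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
  area
}

#' Full evaluation report
#'
#' @param labels 0/1 vector.
#' @param scores probabilities.
#' @param threshold decision threshold for the scalar metrics.
#' @return An [EvalReport-class] with the six scalar metrics plus `auc`
#'   and `aucpr`.
#' @export
evaluateScores <- function(labels, scores, threshold = 0.5) {
  counts <- confusionCounts(labels, scores, threshold)
  metrics <- c(scalarMetrics(counts),
               auc = rocAUC(labels, scores), aucpr = prAUC(labels, scores))
  new("EvalReport", counts = counts, metrics = metrics,
      threshold = threshold)
}

#' Metrics of an EvalReport
#' @param report an [EvalReport-class]
#' @return named numeric vector of the eight metrics
#' @export
reportMetrics <- function(report) report@metrics

#' Confusion counts of an EvalReport
#' @param report an [EvalReport-class]
#' @return named integer vector TP/TN/FP/FN
#' @export
reportCounts <- function(report) report@counts

#' Export ROC or precision-recall curve points
#'
#' One row per distinct score cut-off, for external plotting.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param type `"roc"` (columns fpr, tpr) or `"pr"` (columns recall,
#'   precision).
#' @return data.frame of curve points ordered by descending threshold.
#' @export
curvePoints <- function(labels, scores, type = c("roc", "pr")) {
  type <- match.arg(type)
  check_labels_scores(labels, scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp_end <- cumsum(rle(sc)$lengths)
  tp <- cumsum(lab)[grp_end]
  fp <- grp_end - tp
  if (type == "roc")
    data.frame(threshold = sc[grp_end], fpr = fp / n0, tpr = tp / n1)
  else
    data.frame(threshold = sc[grp_end], recall = tp / n1,
               precision = tp / grp_end)
}
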
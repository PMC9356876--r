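#' Confusion-matrix metrics
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)` and
#' `F1 = 2TP/(2TP+FP+FN)`. A metric whose denominator is zero (or which
#' needs an undefined TN) is returned as `NA`.
#'
#' @param c a [confusion_counts()].
#' @return named numeric vector with elements `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `f1`.
#' @export
confusion_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  tn <- c$tn
  c(sensitivity = safe(c$tp, c$tp + c$fn),
    specificity = if (is.na(tn)) NA_real_ else safe(tn, tn + c$fp),
    accuracy = if (is.na(tn)) NA_real_ else
      safe(c$tp + tn, c$tp + tn + c$fp + c$fn),
    precision = safe(c$tp, c$tp + c$fp),
    f1 = safe(2 * c$tp, 2 * c$tp + c$fp + c$fn))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the true-positive-rate versus false-positive-rate
#' curve swept over the score threshold; ties are rank-averaged, so the value
#' equals the concordance (Mann-Whitney) statistic.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 class labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("roc_auc needs both classes present")
  as.numeric(pROC::auc(pROC::roc(labels, as.numeric(scores),
                                 direction = "<", quiet = TRUE)))
}

#' Match detected points to ground truth
#'
#' Greedy one-to-one assignment by increasing distance: prediction-truth
#' pairs within `tolerance` pixels are matched closest-first; matched
#' predictions are TP, unmatched predictions FP, unmatched truths FN. TN is
#' undefined for point detection.
#'
#' @param pred,truth [junction_points()] tables.
#' @param tolerance match radius, pixels.
#' @return a [confusion_counts()] with `tn = NA`.
#' @export
match_detections <- function(pred, truth, tolerance = 5) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0)
    return(confusion_counts(tp = 0, fp = np, fn = nt))
  d <- sqrt(outer(pred$row, truth$row, "-")^2 +
            outer(pred$col, truth$col, "-")^2)
  cand <- which(d <= tolerance, arr.ind = TRUE)
  tp <- 0L
  if (nrow(cand)) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_p <- rep(FALSE, np); used_t <- rep(FALSE, nt)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      tp <- tp + 1L
    }
  }
  confusion_counts(tp = tp, fp = np - tp, fn = nt - tp)
}

#' Registration error against ground-truth correspondences
#'
#' Mean Euclidean distance between the homography-mapped sensed control
#' points and their reference counterparts.
#'
#' @param h a [homography()] mapping sensed to reference coordinates.
#' @param gt a [correspondence_set()].
#' @param statistic `"mean"` (default), `"median"` or `"max"`.
#' @return non-negative error in pixels.
#' @export
registration_error <- function(h, gt, statistic = c("mean", "median", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(gt, "correspondence_set"))
  mapped <- transform_point(h, gt$sensed)
  e <- sqrt(rowSums((mapped - gt$ref)^2))
  switch(statistic, mean = mean(e), median = stats::median(e), max = max(e))
}

#' Success-rate curve over error thresholds
#'
#' For per-pair registration errors (failed registrations carry `Inf`), the
#' success rate at threshold `t` is the fraction of pairs with error `<= t`.
#' The curve is evaluated on thresholds 0 to 25 and its trapezoidal area is
#' normalized by the 25-unit span, so the AUC lies in `[0, 1]`.
#'
#' @param errors numeric vector of per-pair errors (may contain `Inf`).
#' @param step threshold grid step, pixels.
#' @param max_threshold top of the threshold range.
#' @return list of class `success_rate_curve` with `thresholds`,
#'   `success_rates` and `auc`.
#' @export
success_rate_curve <- function(errors, step = 0.1, max_threshold = 25) {
  if (!length(errors)) stop("need at least one registration error")
  thresholds <- seq(0, max_threshold, by = step)
  rates <- vapply(thresholds, function(t) mean(errors <= t), numeric(1))
  auc <- sum((rates[-1] + rates[-length(rates)]) / 2 * diff(thresholds)) /
    max_threshold
  structure(list(thresholds = thresholds, success_rates = rates, auc = auc),
            class = "success_rate_curve")
}

#' @export
print.success_rate_curve <- function(x, ...) {
  cat(sprintf("<success_rate_curve auc=%.4f over [0, %g]>\n", x$auc,
              max(x$thresholds)))
  invisible(x)
}
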
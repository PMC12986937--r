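# Anomaly scoring (uncertainty-weighted reconstruction error), Youden-index
# threshold selection and threshold-dependent evaluation metrics.

#' Per-timepoint anomaly scores
#'
#' `S_t = exp(-sigma) * (x_hat - x)^2 + epsilon` elementwise: squared
#' reconstruction error down-weighted where the model predicts high
#' variance, plus a small constant for numerical stability.
#'
#' @param out A `reconstruction_output` (or any list with `x_hat`, `sigma`).
#' @param x Original signal, same shape.
#' @param epsilon Stability constant (default 1e-10).
#' @return Nonnegative matrix of scores, same shape as `x`.
#' @export
score_timepoints <- function(out, x, epsilon = 1e-10) {
  check_number(epsilon, "epsilon", lower = .Machine$double.xmin)
  if (!identical(dim(out$x_hat), dim(x)) || !identical(dim(out$sigma), dim(x)))
    stop(sprintf("shape mismatch: x_hat %s, sigma %s, x %s",
                 paste(dim(out$x_hat), collapse = "x"),
                 paste(dim(out$sigma), collapse = "x"),
                 paste(dim(x), collapse = "x")), call. = FALSE)
  exp(-out$sigma) * (out$x_hat - x)^2 + epsilon
}

#' Per-sample anomaly score
#'
#' Mean of the per-timepoint scores over all leads and time points.
#'
#' @param per_timepoint Matrix/array from [score_timepoints()].
#' @return Scalar score.
#' @export
score_sample <- function(per_timepoint) {
  if (length(per_timepoint) == 0L)
    stop("empty per-timepoint score array", call. = FALSE)
  mean(per_timepoint)
}

#' Score a list of records with a trained model
#'
#' @param model A trained [stae_init()] model.
#' @param records List of preprocessed [ecg_record]s.
#' @param epsilon Stability constant for [score_timepoints()].
#' @return Numeric vector of per-sample scores.
#' @export
score_records <- function(model, records, epsilon = 1e-10) {
  vapply(records, function(r) {
    out <- stae_forward(model, r, training = FALSE)
    score_sample(score_timepoints(out, r$samples, epsilon))
  }, numeric(1))
}

#' Min-max normalize sample scores to \[0, 1\]
#'
#' `(s - min) / (max - min)` over the evaluated score set. Rank order (and
#' hence ROC-AUC) is unchanged. Degenerate all-equal input maps to 0.5 with
#' a warning.
#'
#' @param sample_scores Numeric vector, length >= 2.
#' @return Normalized scores in `[0, 1]`.
#' @export
normalize_scores <- function(sample_scores) {
  if (!is.numeric(sample_scores) || length(sample_scores) < 2L)
    stop("need at least 2 scores to normalize", call. = FALSE)
  lo <- min(sample_scores); hi <- max(sample_scores)
  if (hi == lo) {
    warning("all scores equal; normalizing to 0.5", call. = FALSE)
    return(rep(0.5, length(sample_scores)))
  }
  (sample_scores - lo) / (hi - lo)
}

# Candidate thresholds: midpoints between sorted distinct scores plus
# -Inf/+Inf sentinels.
candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
}

# Confusion counts for rule `score >= threshold => positive (abnormal)`.
confusion_at <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  c(TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L))
}

#' ROC curve over all candidate thresholds
#'
#' @param scores Numeric anomaly scores (higher = more abnormal).
#' @param labels 0/1 labels (1 = abnormal, the positive class).
#' @return Data frame with `threshold`, `fpr`, `tpr` (one row per candidate
#'   threshold, decreasing threshold order).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("both classes must be present", call. = FALSE)
  th <- rev(candidate_thresholds(scores))  # +Inf first: (0,0) -> (1,1)
  tpr <- fpr <- numeric(length(th))
  for (i in seq_along(th)) {
    cm <- confusion_at(scores, labels, th[i])
    tpr[i] <- cm["TP"] / np
    fpr[i] <- cm["FP"] / nn
  }
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Youden-index optimal threshold
#'
#' Maximizes `J = TPR + TNR - 1` over all candidate thresholds (midpoints
#' between sorted distinct scores, plus sentinels). Ties are broken toward
#' the higher threshold (fewer positives).
#'
#' @inheritParams roc_points
#' @return List with `threshold` and `J`.
#' @export
youden_threshold <- function(scores, labels) {
  rp <- roc_points(scores, labels)
  J <- rp$tpr - rp$fpr  # TNR = 1 - FPR
  best <- max(J)
  # rows are in decreasing threshold order; first maximum = highest threshold
  i <- which(J == best)[1]
  list(threshold = rp$threshold[i], J = best)
}

# Trapezoidal AUC from ROC points (sorted by increasing FPR).
trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
}

# Average precision: precision-weighted recall increments over decreasing
# thresholds.
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(1L - lab)
  # collapse tied scores to the last row of each tie group
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate anomaly scores against binary labels
#'
#' Builds the ROC curve, computes its trapezoidal AUC and the average
#' precision, selects (or accepts) a decision threshold, and reports the
#' confusion counts and threshold metrics at `score >= threshold ->
#' abnormal`:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and their harmonic mean F1.
#'
#' @inheritParams roc_points
#' @param threshold Decision threshold; defaults to the Youden-optimal one.
#' @return An `eval_report` list: `auc`, `average_precision`, `roc`,
#'   `threshold`, `youden_j`, `confusion`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL) {
  rp <- roc_points(scores, labels)
  auc <- trapezoid_auc(rp$fpr, rp$tpr)
  ap <- average_precision(scores, labels)
  if (is.null(threshold)) {
    yt <- youden_threshold(scores, labels)
    threshold <- yt$threshold
    J <- yt$J
  } else {
    check_number(threshold, "threshold")
    cm0 <- confusion_at(scores, labels, threshold)
    J <- cm0["TP"] / (cm0["TP"] + cm0["FN"]) +
      cm0["TN"] / (cm0["TN"] + cm0["FP"]) - 1
  }
  cm <- confusion_at(scores, labels, threshold)
  acc <- (cm["TP"] + cm["TN"]) / sum(cm)
  prec <- if (cm["TP"] + cm["FP"] > 0) cm["TP"] / (cm["TP"] + cm["FP"]) else 0
  rec <- if (cm["TP"] + cm["FN"] > 0) cm["TP"] / (cm["TP"] + cm["FN"]) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  structure(list(auc = auc, average_precision = ap, roc = rp,
                 threshold = threshold, youden_j = unname(J),
                 confusion = cm, accuracy = unname(acc),
                 precision = unname(prec), recall = unname(rec),
                 f1 = unname(f1)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> AUC %.4f  AP %.4f  threshold %.4g\n",
                     "  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
                     "  confusion TP=%d TN=%d FP=%d FN=%d\n"),
              x$auc, x$average_precision, x$threshold, x$accuracy,
              x$precision, x$recall, x$f1,
              x$confusion["TP"], x$confusion["TN"], x$confusion["FP"],
              x$confusion["FN"]))
  invisible(x)
}
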
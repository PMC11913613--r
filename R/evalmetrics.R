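## Confusion-matrix metrics (PRE, SEN, SPE, ACC, F1), ROC-AUC and PR-AUC,
## and pooled out-of-fold cross-validation reporting.

new_eval_report <- function(PRE, SEN, SPE, ACC, F1, ROC_AUC, PR_AUC,
                            n_positive, n_negative, counts = NULL,
                            model = NULL) {
  structure(list(PRE = PRE, SEN = SEN, SPE = SPE, ACC = ACC, F1 = F1,
                 ROC_AUC = ROC_AUC, PR_AUC = PR_AUC,
                 n_positive = n_positive, n_negative = n_negative,
                 counts = counts, model = model),
            class = "eval_report")
}

#' Threshold metrics from a confusion matrix
#'
#' Precision `tp/(tp+fp)` (0 by convention when the denominator is 0),
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy, and
#' `F1 = 2*PRE*SEN/(PRE+SEN)` (0 when PRE+SEN = 0).
#'
#' @param tp,fp,tn,fn Non-negative counts; at least one actual positive
#'   (`tp+fn >= 1`) and one actual negative (`tn+fp >= 1`).
#' @return An `eval_report` (ROC/PR AUC fields are `NA`: they need scores).
#' @examples
#' confusion_metrics(tp = 8, fp = 2, tn = 88, fn = 2)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero confusion matrix")
  if (tp + fn < 1 || tn + fp < 1)
    stop("need at least one actual positive and one actual negative")
  PRE <- if (tp + fp > 0) tp / (tp + fp) else 0
  SEN <- tp / (tp + fn)
  SPE <- tn / (tn + fp)
  ACC <- (tp + tn) / sum(counts)
  F1 <- if (PRE + SEN > 0) 2 * PRE * SEN / (PRE + SEN) else 0
  new_eval_report(PRE, SEN, SPE, ACC, F1, NA_real_, NA_real_,
                  n_positive = tp + fn, n_negative = tn + fp,
                  counts = counts)
}

#' ROC-AUC and PR-AUC from scores
#'
#' ROC-AUC is the Mann-Whitney statistic (probability that a random positive
#' outscores a random negative, ties credited 0.5) — identical to the
#' trapezoidal area under the ROC curve over all thresholds. PR-AUC uses
#' step-wise (no linear) interpolation of the precision-recall curve,
#' sweeping thresholds from the highest score down; linear interpolation
#' would overestimate it.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels 0/1 labels containing both classes.
#' @return Named numeric vector `c(roc_auc, pr_auc)`.
#' @examples
#' roc_pr_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
#' @export
roc_pr_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!is_binary01(labels)) stop("labels must be coded 0/1")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("labels must contain both classes")
  r <- rank(scores)  # midranks: ties get 0.5 credit
  roc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ## PR curve over unique-score thresholds, highest first
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  cum_tp <- cumsum(y); cum_fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cum_tp[last]; fp <- cum_fp[last]
  recall <- tp / npos
  precision <- tp / (tp + fp)
  pr <- sum(diff(c(0, recall)) * precision)
  c(roc_auc = roc, pr_auc = pr)
}

## Build a full eval_report from pooled scores + labels.
#' Evaluation report from predicted scores
#'
#' Dichotomizes `scores` at `threshold` for the confusion-matrix metrics and
#' adds ROC-AUC / PR-AUC computed from the raw scores.
#'
#' @param labels 0/1 labels with both classes present.
#' @param scores Predicted probabilities or scores.
#' @param threshold Classification cut (default 0.5).
#' @param model Optional model identifier carried in the report.
#' @return An `eval_report`.
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5,
                                 model = NULL) {
  pred <- as.integer(scores >= threshold)
  rep0 <- confusion_metrics(tp = sum(pred == 1 & labels == 1),
                            fp = sum(pred == 1 & labels == 0),
                            tn = sum(pred == 0 & labels == 0),
                            fn = sum(pred == 0 & labels == 1))
  auc <- roc_pr_auc(scores, labels)
  rep0$ROC_AUC <- unname(auc["roc_auc"])
  rep0$PR_AUC <- unname(auc["pr_auc"])
  rep0$model <- model
  rep0
}

#' Pooled out-of-fold cross-validation report
#'
#' Runs stratified k-fold cross-validation of the base model on the columns
#' a mask retains, pools the out-of-fold predicted probabilities, and
#' computes one [evaluate_predictions()] report on the pooled set (pooling
#' is steadier than averaging per-fold metrics, especially for PR-AUC on
#' small folds). Deterministic given the seed; fold assignment matches
#' [mask_objective()] for the same (cohort, folds, seed).
#'
#' @inheritParams mask_objective
#' @param threshold Classification cut for the threshold metrics.
#' @return An `eval_report`.
#' @export
crossval_report <- function(cohort, mask, base_model, folds = 5L, seed = 1L,
                            threshold = 0.5, label = "nodule") {
  xy <- cohort_xy(cohort, label)
  mask <- as.integer(as.logical(mask))
  if (!any(mask)) stop("empty feature mask is infeasible")
  xsel <- xy$x[, mask == 1L, drop = FALSE]
  fold <- make_folds(xy$y, folds, seed)
  probs <- numeric(length(xy$y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (length(unique(xy$y[tr])) < 2)
      stop("degenerate cohort: a training fold lacks both classes")
    probs[!tr] <- fit_predict_prob(base_model, xsel[tr, , drop = FALSE],
                                   xy$y[tr], xsel[!tr, , drop = FALSE],
                                   seed = seed + 1000L * k)
  }
  evaluate_predictions(xy$y, probs, threshold = threshold,
                       model = base_model)
}

#' ROC and PR curve points
#'
#' Sweeps thresholds at every unique score (highest first) and returns the
#' curve coordinates, suitable for export as two-column text and plotting.
#'
#' @inheritParams roc_pr_auc
#' @return List with data frames `roc` (fpr, tpr) and `pr`
#'   (recall, precision), each including the curve's origin point.
#' @export
roc_pr_curves <- function(scores, labels) {
  if (!is_binary01(labels)) stop("labels must be coded 0/1")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("labels must contain both classes")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  list(roc = data.frame(fpr = c(0, fp / nneg), tpr = c(0, tp / npos)),
       pr = data.frame(recall = c(0, tp / npos),
                       precision = c(1, tp / (tp + fp))))
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  if (!is.null(x$model)) cat("Model:", x$model, "\n")
  v <- unlist(x[c("PRE", "SEN", "SPE", "ACC", "F1", "ROC_AUC", "PR_AUC")])
  names(v) <- c("PRE", "SEN", "SPE", "ACC", "F1", "ROC-AUC", "PR-AUC")
  print(round(v, digits))
  cat(sprintf("(n+ = %d, n- = %d)\n", x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(model = x$model %||% NA_character_,
             PRE = x$PRE, SEN = x$SEN, SPE = x$SPE, ACC = x$ACC, F1 = x$F1,
             ROC_AUC = x$ROC_AUC, PR_AUC = x$PR_AUC)
}
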
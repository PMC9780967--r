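# Evaluation surface: confusion matrix, percent metrics, ROC/AUC and the
# closest-to-(0,1) operating point. Positive class = Pre-levodopa (OFF).

#' Confusion counts for ON/OFF phase predictions
#'
#' @param truth,predicted Vectors of labels in `{"pre", "post"}` (or any two
#'   labels with `positive` naming the positive one). Pre-levodopa (OFF) is
#'   the positive class.
#' @param positive Positive-class label (default `"pre"`).
#' @return `list(tp, tn, fp, fn)` of non-negative integers summing to the
#'   number of observations.
#' @export
confusion <- function(truth, predicted, positive = "pre") {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  labs <- unique(c(truth, predicted))
  if (length(setdiff(labs, c("pre", "post"))) > 0L && positive == "pre") {
    stop("labels must be 'pre' or 'post'", call. = FALSE)
  }
  t_pos <- truth == positive
  p_pos <- predicted == positive
  list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
       fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
}

#' Percent classification metrics from confusion counts
#'
#' Accuracy `(tp+tn)/n`, recall `tp/(tp+fn)`, precision `tp/(tp+fp)`,
#' F1 `2tp/(2tp+fn+fp)` and specificity `tn/(tn+fp)`, all in percent.
#' Ratios with a zero denominator are reported as `NaN` with
#' `undefined = TRUE`.
#'
#' @param tp,tn,fp,fn Confusion counts (or a single list with those fields).
#' @return `list(accuracy_pct, recall_pct, precision_pct, f1_pct,
#'   specificity_pct, n, undefined)`.
#' @export
classification_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    cc <- tp; tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  }
  n <- tp + tn + fp + fn
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NaN else 100 * num / den
  out <- list(accuracy_pct = ratio(tp + tn, n),
              recall_pct = ratio(tp, tp + fn),
              precision_pct = ratio(tp, tp + fp),
              f1_pct = ratio(2 * tp, 2 * tp + fn + fp),
              specificity_pct = ratio(tn, tn + fp),
              n = n)
  out$undefined <- any(is.nan(unlist(out[1:5])))
  out
}

#' F1 from precision and recall; accuracy from recall and specificity
#'
#' Worked-example identities of the percent metrics: the F1 score is the
#' harmonic mean `2PR/(P+R)` of precision and recall, and with balanced
#' classes the accuracy is the arithmetic mean of recall (sensitivity) and
#' specificity.
#'
#' @param precision_pct,recall_pct,specificity_pct Percent values.
#' @return Percent value.
#' @export
f1_from_precision_recall <- function(precision_pct, recall_pct) {
  2 * precision_pct * recall_pct / (precision_pct + recall_pct)
}

#' @rdname f1_from_precision_recall
#' @export
accuracy_from_recall_specificity <- function(recall_pct, specificity_pct) {
  (recall_pct + specificity_pct) / 2
}

#' ROC curve, AUC and the closest-to-(0,1) operating point
#'
#' Sweeps the decision threshold over the unique scores (observations sharing
#' a score move together), yielding the standard step ROC from (0,0) to
#' (1,1); the AUC is the trapezoidal area, and the reported operating point
#' is the ROC vertex minimizing the Euclidean distance to the ideal corner
#' (FPR, TPR) = (0, 1).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth Labels in `{"pre", "post"}` (both classes present).
#' @param positive Positive-class label (default `"pre"`).
#' @return A list of class `wo_roc`: `roc` (data.frame `threshold`, `fpr`,
#'   `tpr`), `auc`, `operating_point` (list `fpr`, `tpr`, `threshold`).
#' @export
roc_auc <- function(scores, truth, positive = "pre") {
  stopifnot(length(scores) == length(truth))
  y <- truth == positive
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one observation of each class", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yy); fp <- cumsum(!yy)
  last <- !duplicated(grp, fromLast = TRUE)  # last element of each tie group
  thr <- s[last]
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  thr <- c(Inf, thr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  d2 <- fpr^2 + (1 - tpr)^2
  i <- which.min(d2)
  structure(list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc,
                 operating_point = list(fpr = fpr[i], tpr = tpr[i],
                                        threshold = thr[i])),
            class = "wo_roc")
}

#' @export
print.wo_roc <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf("<wo_roc> AUC = %.4f; operating point FPR %.3f, TPR %.3f (thr %.3g)\n",
              x$auc, op$fpr, op$tpr, op$threshold))
  invisible(x)
}

#' Full evaluation report of a model on a labelled feature table
#'
#' Confusion matrix, percent metrics (rounded half-up to 2 decimals for
#' display; exact values retained), ROC/AUC and operating point.
#'
#' @param model A `wo_model`.
#' @param table Labelled feature data.frame (`condition` column).
#' @return A list of class `wo_eval`: `confusion`, `metrics`, `roc`,
#'   `auc`, `operating_point`, `n`.
#' @export
evaluate_model <- function(model, table) {
  pr <- predict_table(model, table)
  cc <- confusion(table$condition, pr$label, positive = model$positive)
  mets <- classification_metrics(cc)
  roc <- roc_auc(pr$score, table$condition, positive = model$positive)
  structure(list(confusion = cc, metrics = mets, roc = roc$roc, auc = roc$auc,
                 operating_point = roc$operating_point, n = mets$n,
                 family = model$spec$family),
            class = "wo_eval")
}

#' @export
print.wo_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<wo_eval> %s on %d observations\n", x$family %||% "model", x$n))
  cat(sprintf("  tp %d  fn %d | fp %d  tn %d\n",
              x$confusion$tp, x$confusion$fn, x$confusion$fp, x$confusion$tn))
  cat(sprintf("  accuracy %.2f  recall %.2f  precision %.2f  F1 %.2f  specificity %.2f  AUC %.2f\n",
              round_half_up(m$accuracy_pct, 2), round_half_up(m$recall_pct, 2),
              round_half_up(m$precision_pct, 2), round_half_up(m$f1_pct, 2),
              round_half_up(m$specificity_pct, 2), x$auc))
  invisible(x)
}
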
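# The 15-metric classification evaluation suite.
#
# Metrics are computed one-versus-rest. For binary problems the positive
# class is the lexicographically second class level unless overridden; for
# more than two classes every metric is computed once per class (that class
# against the rest, using that class's probability column as the score for
# AUROC and Brier) and averaged with equal class weights (macro averaging).

#' Metric identifiers of the evaluation suite
#' @return character vector of the 15 metric ids.
#' @export
metric_ids <- function() {
  c("auroc", "accuracy", "balanced_accuracy", "brier", "f1", "fdr", "fnr",
    "fpr", "mcc", "mmce", "npv", "ppv", "recall", "tnr", "tpr")
}

#' One-vs-rest confusion counts
#'
#' @param pred a `cb_predictions` table (see [predict_model()]).
#' @param positive the class label treated as positive.
#' @return a list with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, positive) {
  if (!positive %in% union(pred$class_levels, unique(pred$actual)))
    cb_stop("cb_parameter_error", "unknown class '%s'", positive)
  actual_pos <- pred$actual == positive
  pred_pos <- pred$predicted == positive
  list(tp = sum(actual_pos & pred_pos),
       fp = sum(!actual_pos & pred_pos),
       tn = sum(!actual_pos & !pred_pos),
       fn = sum(actual_pos & !pred_pos))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the proportion of (positive, negative) pairs in which the positive
#' sample receives the higher score, counting ties as half. Computed through
#' midranks, which is algebraically identical to the pairwise definition.
#'
#' @param scores numeric score per sample (higher = more positive).
#' @param is_positive logical truth per sample.
#' @return AUROC in \[0, 1\], or `NA` when only one class is present.
#' @export
auroc <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Brier score
#'
#' Mean squared difference between the predicted probability of the positive
#' class and the 0/1 outcome.
#'
#' @param prob_positive predicted probability per sample, in \[0, 1\].
#' @param is_positive logical truth per sample.
#' @return Brier score in \[0, 1\].
#' @export
brier <- function(prob_positive, is_positive) {
  stopifnot(length(prob_positive) == length(is_positive),
            all(prob_positive >= 0 & prob_positive <= 1))
  mean((prob_positive - as.numeric(is_positive))^2)
}

#' Metrics derived from a confusion table
#'
#' Computes the discrete-prediction metrics from one-vs-rest confusion
#' counts. A ratio with denominator 0 yields 0; the affected metric ids are
#' recorded in the `"degenerate"` attribute so tidy outputs stay rectangular
#' without silently propagating undefined values.
#'
#' @param counts a list with fields `tp`, `fp`, `tn`, `fn` (see [confusion()]).
#' @return named numeric vector over the non-AUROC, non-Brier metric ids.
#' @export
derived_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  degenerate <- character(0)
  safe <- function(num, den, id) {
    if (den == 0) {
      degenerate <<- c(degenerate, id)
      0
    } else num / den
  }
  acc <- safe(tp + tn, n, "accuracy")
  tpr <- safe(tp, tp + fn, "tpr")
  tnr <- safe(tn, tn + fp, "tnr")
  ppv <- safe(tp, tp + fp, "ppv")
  npv <- safe(tn, tn + fn, "npv")
  f1 <- safe(2 * tp, 2 * tp + fp + fn, "f1")
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "mcc")
    0
  } else {
    # clamp: the quotient can land an ulp outside [-1, 1]
    min(1, max(-1, (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den))
  }
  out <- c(accuracy = acc, balanced_accuracy = (tpr + tnr) / 2, f1 = f1,
           fdr = 1 - ppv, fnr = 1 - tpr, fpr = 1 - tnr, mcc = mcc,
           mmce = 1 - acc, npv = npv, ppv = ppv, recall = tpr, tnr = tnr,
           tpr = tpr)
  attr(out, "degenerate") <- unique(degenerate)
  out
}

#' Score a prediction table with the full metric suite
#'
#' For two classes, metrics use the designated positive class (the
#' lexicographically second class level unless `positive` is given). For
#' more than two classes, every metric is computed once per class
#' one-vs-rest and macro-averaged. AUROC is recorded as `NA` when the truth
#' contains a single class.
#'
#' @param pred a `cb_predictions` table.
#' @param positive optional positive class override (binary problems only).
#' @return named numeric vector over all 15 metric ids.
#' @export
score_predictions <- function(pred, positive = NULL) {
  levels <- pred$class_levels
  if (length(levels) < 2)
    cb_stop("cb_parameter_error", "need at least two class levels to score")

  one_class <- function(cls) {
    is_pos <- pred$actual == cls
    counts <- confusion(pred, cls)
    der <- derived_metrics(counts)
    p <- pred$probabilities[, cls]
    c(auroc = auroc(p, is_pos), brier = brier(p, is_pos), der)
  }

  if (length(levels) == 2) {
    pos <- positive %||% levels[2]
    if (!pos %in% levels)
      cb_stop("cb_parameter_error", "unknown positive class '%s'", pos)
    vals <- one_class(pos)
  } else {
    per_class <- vapply(levels, one_class, numeric(15))
    vals <- rowMeans(per_class, na.rm = TRUE)
    vals[is.nan(vals)] <- NA_real_
  }
  vals[metric_ids()]
}
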
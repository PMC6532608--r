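# Evaluation criteria. Classification metrics operate on a confusion matrix
# (counts[i, j] = instances of true class i predicted as class j) plus, for
# the ranking-based ones (AUC, AUPRC), a per-instance class-probability
# table. Multi-class versions are one-vs-rest averages weighted by class
# prevalence; MCC uses the generalized (Gorodkin) form.

#' Criterion direction registry
#'
#' Maps each supported optimisation criterion to whether it is maximised (a
#' performance) or minimised (an error).
#'
#' @return Named character vector, values `"maximize"` or `"minimize"`.
#' @export
criterion_directions <- function() {
  c(acc = "maximize", mcc = "maximize", auc = "maximize",
    auprc = "maximize", sensitivity = "maximize", specificity = "maximize",
    cc = "maximize", ber = "minimize", rmse = "minimize")
}

#' Build a confusion matrix from paired label vectors
#'
#' @param truth Vector of true class labels.
#' @param predicted Vector of predicted labels, same length.
#' @param classes Optional label universe fixing row/column order; defaults
#'   to the sorted union of labels seen in `truth`.
#' @return A `confusion_matrix`: square integer matrix, rows = truth,
#'   columns = predicted.
#' @export
confusion_from_predictions <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ", call. = FALSE)
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(truth))
  classes <- as.character(classes)
  extra <- setdiff(unique(predicted), classes)
  if (length(extra)) classes <- c(classes, sort(extra))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- unclass(cm)
  dimnames(cm) <- list(truth = classes, predicted = classes)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Balanced error rate
#'
#' Mean over classes of the per-class misclassification rate
#' (1 - recall). Classes with no true instances are excluded from the mean
#' with a warning.
#'
#' @param cm A `confusion_matrix`.
#' @return BER in \[0, 1\].
#' @export
balanced_error_rate <- function(cm) {
  totals <- rowSums(cm)
  if (any(totals == 0))
    warning("class(es) with no true instances excluded from BER: ",
            paste(rownames(cm)[totals == 0], collapse = ", "), call. = FALSE)
  keep <- totals > 0
  mean(1 - diag(cm)[keep] / totals[keep])
}

#' Matthews correlation coefficient
#'
#' Binary confusion matrices use the classical formula
#' \eqn{(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}};
#' larger matrices the generalized multi-class (Gorodkin) form. A zero
#' denominator (e.g. all instances predicted as one class) yields 0.
#'
#' @param cm A `confusion_matrix`.
#' @return MCC in \[-1, 1\].
#' @export
matthews_cc <- function(cm) {
  cm <- matrix(as.numeric(cm), nrow(cm))
  n <- sum(cm)
  truth_tot <- rowSums(cm)
  pred_tot <- colSums(cm)
  num <- sum(diag(cm)) * n - sum(truth_tot * pred_tot)
  den <- sqrt(n^2 - sum(pred_tot^2)) * sqrt(n^2 - sum(truth_tot^2))
  if (den == 0) return(0)
  num / den
}

# Mann-Whitney AUC for one positive class: probability that a random
# positive outranks a random negative, ties counted 1/2.
rank_auc <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Average precision (step-interpolated, as the area under the
# precision-recall curve): sum over ranked positives of precision at each
# recall increment. Ties in score are processed as a block using the block's
# cumulative precision.
average_precision <- function(scores, positive) {
  n_pos <- sum(positive)
  if (n_pos == 0 || all(positive)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  sum(prec[pos]) / n_pos
}

#' Full classification metric vector
#'
#' Computes acc, ber, mcc plus the one-vs-rest, class-prevalence-weighted
#' sensitivity, specificity, AUC and AUPRC. AUC/AUPRC need per-instance
#' class probability scores; without them they are reported as `NA`
#' (undefined), never as 0.
#'
#' @param cm A `confusion_matrix`.
#' @param scores Optional numeric matrix (instances x classes, columns named
#'   by class) of probability scores.
#' @param truth Label vector matching `scores` rows (required with
#'   `scores`).
#' @return Named numeric vector with elements `acc`, `ber`, `mcc`, `auc`,
#'   `auprc`, `sensitivity`, `specificity`.
#' @export
weighted_classification_metrics <- function(cm, scores = NULL,
                                            truth = NULL) {
  classes <- rownames(cm)
  totals <- rowSums(cm)
  n <- sum(cm)
  w <- totals / n                       # class prevalence weights
  keep <- totals > 0

  sens <- diag(cm) / ifelse(totals == 0, NA, totals)
  spec <- vapply(seq_along(classes), function(i) {
    tn <- n - sum(cm[i, ]) - sum(cm[, i]) + cm[i, i]
    neg <- n - totals[i]
    if (neg == 0) NA_real_ else tn / neg
  }, numeric(1))

  auc <- auprc <- rep(NA_real_, length(classes))
  if (!is.null(scores)) {
    if (is.null(truth))
      stop("truth labels required alongside scores", call. = FALSE)
    truth <- as.character(truth)
    for (i in seq_along(classes)) {
      if (!classes[i] %in% colnames(scores)) next
      pos <- truth == classes[i]
      auc[i] <- rank_auc(scores[, classes[i]], pos)
      auprc[i] <- average_precision(scores[, classes[i]], pos)
    }
  }
  wmean <- function(v) {
    ok <- keep & !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  c(acc = sum(diag(cm)) / n,
    ber = suppressWarnings(balanced_error_rate(cm)),
    mcc = matthews_cc(cm),
    auc = wmean(auc), auprc = wmean(auprc),
    sensitivity = wmean(sens), specificity = wmean(spec))
}

#' Regression metrics
#'
#' Pearson correlation coefficient and root mean squared error between true
#' and predicted outcomes. Zero variance in either vector yields `cc = 0`
#' with a warning.
#'
#' @param truth Numeric vector.
#' @param predicted Numeric vector, same length (>= 2).
#' @return Named numeric vector with elements `cc`, `rmse`.
#' @export
regression_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 2L)
    stop("truth and predicted must have equal length >= 2", call. = FALSE)
  cc <- if (stats::sd(truth) == 0 || stats::sd(predicted) == 0) {
    warning("zero variance: correlation coefficient set to 0",
            call. = FALSE)
    0
  } else {
    stats::cor(truth, predicted)
  }
  c(cc = cc, rmse = sqrt(mean((truth - predicted)^2)))
}

# Metric vector from raw predictions; dispatches on problem type.
metrics_from_predictions <- function(truth, predicted, scores = NULL,
                                     problem_type = "classification",
                                     classes = NULL) {
  if (problem_type == "classification") {
    cm <- confusion_from_predictions(truth, predicted, classes)
    weighted_classification_metrics(cm, scores, truth)
  } else {
    regression_metrics(truth, predicted)
  }
}

#' Look up a criterion in a metric vector
#'
#' @param metrics Named metric vector.
#' @param criterion Criterion name (see [criterion_directions()]).
#' @return List with `value` and `direction`.
#' @export
criterion_value <- function(metrics, criterion) {
  dirs <- criterion_directions()
  if (!criterion %in% names(dirs))
    stop("unknown criterion '", criterion, "'", call. = FALSE)
  if (!criterion %in% names(metrics))
    stop("criterion '", criterion, "' is not available for this problem ",
         "type", call. = FALSE)
  list(value = unname(metrics[[criterion]]), direction = dirs[[criterion]])
}
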
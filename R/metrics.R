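# Binary classification metrics for the ES/HS task. Positive class is ES
# ("true positive refers to the true ES").

#' Matthews correlation coefficient
#'
#' `(TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`, with 0 returned
#' whenever any factor of the denominator is 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion-matrix counts (vectorized).
#' @return MCC in `[-1, 1]`.
#' @export
mcc_score <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  num <- tp * tn - fn * fp
  ifelse(den > 0, num / sqrt(den), 0)
}

#' Rank-statistic ROC-AUC
#'
#' Wilcoxon–Mann–Whitney formulation: the probability that a random ES
#' score exceeds a random HS score, ties counted half.
#'
#' @param scores Numeric scores (higher = more ES-like).
#' @param labels `"ES"`/`"HS"` labels (or logical, `TRUE` = ES).
#' @return AUC in `[0, 1]`; `NA` with a warning when only one class is
#'   present.
#' @export
auc_rank <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "ES"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate ES/HS classification scores
#'
#' Thresholds the scores (default 0.5, score = predicted ES probability),
#' builds the confusion matrix with ES as the positive class, and computes
#' accuracy, Matthews correlation coefficient and rank-statistic ROC-AUC.
#'
#' @param scores Numeric vector of ES-probability scores.
#' @param labels `"ES"`/`"HS"` vector of true classes.
#' @param threshold Classification threshold (default 0.5).
#' @return An object of class `srp_eval`: list with `acc`, `mcc`, `auc`,
#'   `confusion` (named vector tp/tn/fp/fn) and `n`.
#' @export
#' @examples
#' evaluate_classifier(c(.9, .8, .3, .1), c("ES", "HS", "ES", "HS"))
evaluate_classifier <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), length(scores) >= 1L)
  pos <- labels == "ES"
  pred <- scores >= threshold
  tp <- sum(pred & pos); tn <- sum(!pred & !pos)
  fp <- sum(pred & !pos); fn <- sum(!pred & pos)
  structure(list(
    acc = (tp + tn) / length(scores),
    mcc = mcc_score(tp, tn, fp, fn),
    auc = auc_rank(scores, labels),
    confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
    n = length(scores),
    scores = scores, labels = labels, threshold = threshold
  ), class = "srp_eval")
}

#' @export
print.srp_eval <- function(x, ...) {
  cat(sprintf("<srp_eval> n=%d  ACC %.3f  MCC %.3f  AUC %s\n", x$n, x$acc,
              x$mcc, if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  cat(sprintf("  confusion: TP %d  TN %d  FP %d  FN %d\n",
              x$confusion["tp"], x$confusion["tn"],
              x$confusion["fp"], x$confusion["fn"]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy srp_eval
#' @export
tidy.srp_eval <- function(x, ...) {
  tibble::tibble(
    cell = names(x$confusion),
    count = as.integer(x$confusion)
  )
}

#' @method glance srp_eval
#' @export
glance.srp_eval <- function(x, ...) {
  tibble::tibble(acc = x$acc, mcc = x$mcc, auc = x$auc, n = x$n,
                 threshold = x$threshold)
}

#' ROC curve of an evaluation
#'
#' @param object An `srp_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot srp_eval
#' @export
autoplot.srp_eval <- function(object, ...) {
  ord <- order(object$scores, decreasing = TRUE)
  pos <- object$labels[ord] == "ES"
  df <- tibble::tibble(
    tpr = c(0, cumsum(pos) / max(1, sum(pos))),
    fpr = c(0, cumsum(!pos) / max(1, sum(!pos)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %s)",
                      if (is.na(object$auc)) "NA" else sprintf("%.3f", object$auc))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
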
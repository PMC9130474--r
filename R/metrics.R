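#' Binary confusion matrix
#'
#' Tallies TP/FN/FP/TN counts for a binary task under an explicit
#' positive-class convention. The four counts always sum to the number of
#' records.
#'
#' @param pred Predicted labels.
#' @param truth True labels, same length.
#' @param positive The label counted as positive.
#' @return An object of class `ctg_confusion` with fields `tp`, `fn`, `fp`,
#'   `tn`, `positive`.
#' @export
confusion_matrix <- function(pred, truth, positive) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  p <- pred == positive
  t <- truth == positive
  structure(list(tp = sum(p & t), fn = sum(!p & t),
                 fp = sum(p & !t), tn = sum(!p & !t),
                 positive = positive),
            class = "ctg_confusion")
}

#' @export
print.ctg_confusion <- function(x, ...) {
  cat("<ctg_confusion> positive =", x$positive, "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("truth: positive", "truth: negative"),
                              c("pred: positive", "pred: negative")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes the positive-predictive metrics used throughout this package:
#' `paper_accuracy = TP/(TP+FP)` (precision in standard terminology, but
#' reported under the name the CTG literature uses for it),
#' `sensitivity = TP/(TP+FN)`, their harmonic mean `f1`, and
#' `standard_accuracy = (TP+TN)/total`. A metric whose denominator is zero is
#' reported as `NA` and listed in `undefined` rather than silently zeroed.
#'
#' @param cm A `ctg_confusion`.
#' @return An object of class `metrics_report` with fields `paper_accuracy`,
#'   `sensitivity`, `f1`, `standard_accuracy`, `undefined` (character vector
#'   of metric names whose denominator was zero).
#' @export
paper_metrics <- function(cm) {
  stopifnot(inherits(cm, "ctg_confusion"))
  undefined <- character(0)
  total <- cm$tp + cm$fn + cm$fp + cm$tn

  pa <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else {
    undefined <- c(undefined, "paper_accuracy"); NA_real_
  }
  se <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  f1 <- if (!is.na(pa) && !is.na(se) && pa + se > 0) {
    2 * pa * se / (pa + se)
  } else {
    undefined <- c(undefined, "f1"); NA_real_
  }
  sa <- if (total > 0) (cm$tp + cm$tn) / total else {
    undefined <- c(undefined, "standard_accuracy"); NA_real_
  }
  structure(list(paper_accuracy = pa, sensitivity = se, f1 = f1,
                 standard_accuracy = sa, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (m in c("paper_accuracy", "sensitivity", "f1", "standard_accuracy")) {
    cat(sprintf("  %-18s %s\n", m,
                if (is.na(x[[m]])) "undefined" else sprintf("%.4f", x[[m]])))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = c("paper_accuracy", "sensitivity", "f1", "standard_accuracy"),
    value = c(x$paper_accuracy, x$sensitivity, x$f1, x$standard_accuracy),
    defined = !c("paper_accuracy", "sensitivity", "f1", "standard_accuracy")
      %in% x$undefined
  )
}

#' ROC curve and AUC
#'
#' AUC is the tie-corrected Mann-Whitney rank statistic: the probability
#' that a random positive scores above a random negative, ties counting one
#' half. The ROC curve is traced over the distinct score thresholds;
#' both coordinates are non-decreasing along it.
#'
#' @param scores Real-valued confidence for the positive class.
#' @param truth Binary vector (logical, or 0/1) marking positives; both
#'   classes must be present.
#' @return A list with `roc` (tibble: `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_and_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) {
    stop("scores and truth must have equal length", call. = FALSE)
  }
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks for ties
  auc <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  tp <- cumsum(t); fp <- cumsum(!t)
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  roc <- tibble::tibble(
    threshold = c(Inf, s[last_of_block]),
    fpr = c(0, fp[last_of_block] / n_neg),
    tpr = c(0, tp[last_of_block] / n_pos)
  )
  list(roc = roc, auc = auc)
}
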
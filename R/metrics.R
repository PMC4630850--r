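#' Confusion matrix from consensus calls and truth labels
#'
#' The four counts every benchmark metric is built from: a damaging call on
#' a pathogenic variant is a true positive, a tolerated call on a benign
#' variant a true negative, and so on. Masked variants are not counted.
#'
#' @param calls Character vector of \code{"damaging"}/\code{"tolerated"}
#'   (NA allowed only where masked).
#' @param truths Character vector of \code{"pathogenic"}/\code{"benign"},
#'   same length.
#' @param mask Logical vector selecting the evaluable variants (default:
#'   all non-NA calls).
#' @return Object of class \code{confusion_matrix}: list with integer
#'   fields \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @seealso [confusion_matrix()] for direct construction from counts.
#' @export
confusion <- function(calls, truths, mask = !is.na(calls)) {
  if (length(calls) != length(truths) || length(mask) != length(calls)) {
    stop("calls, truths and mask must have equal length", call. = FALSE)
  }
  calls <- calls[mask]; truths <- truths[mask]
  confusion_matrix(
    tp = sum(calls == "damaging"  & truths == "pathogenic"),
    fp = sum(calls == "damaging"  & truths == "benign"),
    tn = sum(calls == "tolerated" & truths == "benign"),
    fn = sum(calls == "tolerated" & truths == "pathogenic")
  )
}

#' Confusion matrix from explicit counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Object of class \code{confusion_matrix}.
#' @examples
#' cm <- confusion_matrix(tp = 94, fp = 0, tn = 8, fn = 7)
#' mcc(cm)
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy, as percentages
#'
#' Sensitivity is the true-positive rate \eqn{TP/(TP+FN) \times 100}: the
#' probability of identifying a truly damaging variant. Specificity is the
#' true-negative rate \eqn{TN/(TN+FP) \times 100}. Accuracy is
#' \eqn{(TP+TN)/n \times 100}. A zero denominator yields \code{NA} (an
#' undefined-sentinel rendered as \code{"NA"} in reports), never an error,
#' so strata with a single truth class flow through rankings.
#'
#' @param cm A [confusion_matrix()].
#' @return Percentage in \[0, 100\], or \code{NA}.
#' @export
sensitivity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  den <- cm$tp + cm$fn
  if (den == 0) NA_real_ else 100 * cm$tp / den
}

#' @rdname sensitivity
#' @export
specificity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  den <- cm$tn + cm$fp
  if (den == 0) NA_real_ else 100 * cm$tn / den
}

#' @rdname sensitivity
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0) NA_real_ else 100 * (cm$tp + cm$tn) / n
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#'
#' +1 means predictions are always correct, -1 always false, 0 no better
#' than chance. MCC equals the Pearson correlation of the binary
#' prediction and truth vectors, which makes it robust to the strong
#' class imbalance of clinical variant panels (few benign variants) and is
#' why combinations are ranked by it. When any of the four marginal sums is
#' zero the coefficient is undefined as a ratio; the conventional value 0
#' is returned then, with attribute \code{degenerate = TRUE}.
#'
#' @param cm A [confusion_matrix()].
#' @return Numeric in \[-1, 1\]; attribute \code{degenerate} set when a
#'   marginal sum is zero.
#' @examples
#' mcc(confusion_matrix(tp = 86, fp = 7, tn = 7, fn = 13))
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(marg == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  # products kept in log space would be overkill: counts here are panel-sized
  (tp * tn - fp * fn) / sqrt(prod(marg))
}

#' Full metric battery for one confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class \code{metric_set}: list with \code{accuracy},
#'   \code{sensitivity}, \code{specificity} (percent) and \code{mcc}.
#' @export
metric_set <- function(cm) {
  structure(
    list(accuracy = accuracy(cm), sensitivity = sensitivity(cm),
         specificity = specificity(cm), mcc = as.numeric(mcc(cm))),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  fmt_pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", v)
  cat(sprintf("accuracy %s, sensitivity %s, specificity %s, MCC %s\n",
              fmt_pct(x$accuracy), fmt_pct(x$sensitivity),
              fmt_pct(x$specificity),
              if (is.na(x$mcc)) "NA" else sprintf("%.2f", x$mcc)))
  invisible(x)
}
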
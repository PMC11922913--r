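#' Confusion counts for binary predictions
#'
#' Cross-tabulates true labels against predicted labels (1 = malignant, the
#' positive class; 0 = benign).
#'
#' @param labels integer/logical vector of true labels in `{0, 1}`.
#' @param predictions equal-length vector of predicted labels in `{0, 1}`.
#' @return An object of class `confusion_counts`: a list with `TP`, `TN`,
#'   `FP`, `FN` and `total`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) != length(predictions)) {
    stopf("labels (%d) and predictions (%d) differ in length",
          length(labels), length(predictions))
  }
  if (!all(labels %in% c(0L, 1L)) || !all(predictions %in% c(0L, 1L))) {
    stopf("labels and predictions must be binary (0 = benign, 1 = malignant)")
  }
  structure(list(TP = sum(labels == 1L & predictions == 1L),
                 TN = sum(labels == 0L & predictions == 0L),
                 FP = sum(labels == 0L & predictions == 1L),
                 FN = sum(labels == 1L & predictions == 0L),
                 total = length(labels)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(format_confusion(x), sep = "\n")
  invisible(x)
}

#' Render a confusion matrix as a 2x2 text table
#'
#' Rows are the true class, columns the predicted class.
#'
#' @param cc a [confusion_counts()].
#' @return character vector of table lines.
#' @export
format_confusion <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  w <- max(9L, nchar(c(cc$TP, cc$TN, cc$FP, cc$FN)))
  pad <- function(s) formatC(s, width = w)
  c(sprintf("%-16s%s%s", "", pad("benign"), pad("malignant")),
    sprintf("%-16s%s%s", "true benign", pad(cc$TN), pad(cc$FP)),
    sprintf("%-16s%s%s", "true malignant", pad(cc$FN), pad(cc$TP)))
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall
#' (sensitivity) `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the F1 score
#' (the harmonic mean of precision and recall).  A metric whose denominator
#' is zero is reported as `NA` — an explicit "undefined" marker, never a
#' silent zero or an error.  Values are fractions in `[0, 1]`; multiply by
#' 100 for presentation as percentages.
#'
#' @param cc a [confusion_counts()], or a list/vector with elements
#'   `TP`, `TN`, `FP`, `FN`.
#' @return An object of class `metric_set`: a list with `accuracy`,
#'   `precision`, `recall`, `specificity`, `f1`.
#' @examples
#' compute_metrics(list(TP = 5, TN = 3, FP = 1, FN = 1))
#' @export
compute_metrics <- function(cc) {
  cc <- as.list(cc)
  for (f in c("TP", "TN", "FP", "FN")) {
    v <- cc[[f]]
    if (is.null(v) || !is_count(v) || v < 0) stopf("`%s` must be a non-negative integer", f)
  }
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  total <- TP + TN + FP + FN
  if (total == 0) stopf("cannot compute metrics from zero evaluated samples")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(TP, TP + FP)
  recall <- ratio(TP, TP + FN)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(accuracy = (TP + TN) / total,
                 precision = precision,
                 recall = recall,
                 specificity = ratio(TN, TN + FP),
                 f1 = f1),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("%-12s %s\n", nm,
                if (is.na(v)) "undefined" else formatC(v, digits = digits, format = "f")))
  }
  invisible(x)
}
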
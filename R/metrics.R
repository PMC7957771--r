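#' Confusion counts for a binary task
#'
#' @param truth,pred Vectors of class labels (any two-level coding).
#' @param positive The label treated as the positive class.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  stopifnot(length(truth) == length(pred))
  t_pos <- truth == positive; p_pos <- pred == positive
  structure(list(TP = sum(t_pos & p_pos), TN = sum(!t_pos & !p_pos),
                 FP = sum(!t_pos & p_pos), FN = sum(t_pos & !p_pos)),
            class = "confusion_counts")
}

counts_total <- function(counts) counts$TP + counts$TN + counts$FP + counts$FN

add_counts <- function(a, b) {
  structure(list(TP = a$TP + b$TP, TN = a$TN + b$TN,
                 FP = a$FP + b$FP, FN = a$FN + b$FN),
            class = "confusion_counts")
}

#' Classification accuracy (percent)
#'
#' `100 * (TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param counts A [confusion_counts()] object (or list with TP/TN/FP/FN).
#' @return Accuracy in percent.
#' @export
accuracy <- function(counts) {
  total <- counts_total(counts)
  if (total <= 0) stop("accuracy undefined for empty confusion counts")
  100 * (counts$TP + counts$TN) / total
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`.
#' When any factor of the denominator is zero (e.g. a constant one-class
#' predictor) the chance-level value 0 is returned.
#'
#' @param counts A [confusion_counts()] object.
#' @return MCC value.
#' @export
mcc <- function(counts) {
  if (counts_total(counts) <= 0) stop("MCC undefined for empty confusion counts")
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}
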
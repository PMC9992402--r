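#' Confusion counts from truth and predicted labels
#'
#' @param truth binary 0/1 vector of true labels (1 = BCE).
#' @param predicted binary 0/1 vector of predicted labels.
#' @return named integer vector TP, TN, FP, FN.
#' @export
confusionCounts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(all(truth %in% 0:1), all(predicted %in% 0:1))
  c(TP = sum(truth == 1L & predicted == 1L),
    TN = sum(truth == 0L & predicted == 0L),
    FP = sum(truth == 0L & predicted == 1L),
    FN = sum(truth == 1L & predicted == 0L))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Computes Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC = (TP+TN)/n and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FN)(TP+FP)(TN+FP)).
#' Any metric whose denominator is zero (e.g. no negatives evaluated) is
#' reported as 0 and flagged in the `degenerate` slot so that fold
#' aggregation stays total.
#'
#' @param counts named integer vector with elements TP, TN, FP, FN (as from
#'   [confusionCounts()]), or the TP count if the remaining three are given.
#' @param tn,fp,fn individual counts when `counts` is scalar TP.
#' @return a [MetricsReport-class].
#' @examples
#' computeMetrics(confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1)))
#' @export
computeMetrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!is.null(tn)) counts <- c(TP = counts, TN = tn, FP = fp, FN = fn)
  counts <- as.integer(counts[c("TP", "TN", "FP", "FN")])
  names(counts) <- c("TP", "TN", "FP", "FN")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative TP, TN, FP, FN", call. = FALSE)
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  if (total == 0L) stop("no samples counted", call. = FALSE)
  degenerate <- character(0)
  safeDiv <- function(num, den, what) {
    if (den == 0) { degenerate <<- c(degenerate, what); 0 }
    else num / den
  }
  sn <- safeDiv(tp, tp + fn, "Sn")
  sp <- safeDiv(tn, tn + fp, "Sp")
  acc <- (tp + tn) / total
  mccDen <- sqrt(as.numeric(tp + fn) * (tn + fn) * (tp + fp) * (tn + fp))
  mcc <- if (mccDen == 0) { degenerate <- c(degenerate, "MCC"); 0 }
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mccDen
  new("MetricsReport", sn = sn, sp = sp, acc = acc, mcc = mcc,
      counts = counts, degenerate = degenerate)
}

#' Evaluate a trained model on a labelled batch
#'
#' @param model an [LBCEModel-class].
#' @param batch a labelled [EncodedBatch-class].
#' @param threshold decision threshold (ties classify positive).
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, batch, threshold = 0.5) {
  if (!length(batch@labels))
    stop("batch carries no labels", call. = FALSE)
  p <- predictProbs(model, batch)
  computeMetrics(confusionCounts(batch@labels, as.integer(p >= threshold)))
}
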
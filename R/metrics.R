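#' Construct confusion counts
#'
#' Either directly from the four totals, or aggregated from label vectors
#' via [confusionFromPredictions()].
#'
#' @param tp,tn,fp,fn non-negative counts
#' @return a [ConfusionCounts-class]
#' @export
confusionCounts <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Aggregate confusion counts from predicted labels
#'
#' Binary problems (`nClasses = 2`) use the standard 2x2 table with class 1
#' as positive. Multiclass problems are micro-aggregated: each class in
#' turn is treated as positive in a one-vs-rest 2x2 table and the four
#' counts are summed over classes (so `tp + fn` equals the number of items,
#' since every item is a positive exactly once).
#'
#' @param yTrue,yPred integer class labels in `0..nClasses-1`, equal length
#' @param nClasses number of classes, >= 2
#' @return a [ConfusionCounts-class]
#' @export
confusionFromPredictions <- function(yTrue, yPred, nClasses) {
  if (length(yTrue) != length(yPred))
    stop("label vectors must have equal length", call. = FALSE)
  if (any(c(yTrue, yPred) < 0) || any(c(yTrue, yPred) >= nClasses))
    stop("labels must lie in 0..nClasses-1", call. = FALSE)
  if (nClasses == 2) {
    confusionCounts(tp = sum(yTrue == 1 & yPred == 1),
                    tn = sum(yTrue == 0 & yPred == 0),
                    fp = sum(yTrue == 0 & yPred == 1),
                    fn = sum(yTrue == 1 & yPred == 0))
  } else {
    tp <- tn <- fp <- fn <- 0
    for (k in seq_len(nClasses) - 1) {
      tp <- tp + sum(yTrue == k & yPred == k)
      tn <- tn + sum(yTrue != k & yPred != k)
      fp <- fp + sum(yTrue != k & yPred == k)
      fn <- fn + sum(yTrue == k & yPred != k)
    }
    confusionCounts(tp, tn, fp, fn)
  }
}

#' Confusion-matrix metric suite
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' specificity `TN/(TN+FP)`, recall (sensitivity) `TP/(TP+FN)`, the Dice
#' coefficient `2TP/(2TP+FP+FN)` and F1 `2PR/(P+R)`. Computed from the same
#' hard counts, Dice and F1 are algebraically identical. A metric whose
#' denominator is zero is reported as `NA` (undefined), never silently 0.
#' Values are kept at full precision; use [metricTable()] for half-up
#' percent formatting.
#'
#' @param x a [ConfusionCounts-class]
#' @param ... unused
#' @return named numeric vector with elements `accuracy`, `precision`,
#'   `specificity`, `recall`, `dice`, `f1`, each in `[0, 1]` or `NA`
#' @examples
#' computeMetrics(confusionCounts(10363, 10363, 241, 241))
#' @export
setMethod("computeMetrics", "ConfusionCounts", function(x, ...) {
  validObject(x)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  p <- rat(x@tp, x@tp + x@fp)
  r <- rat(x@tp, x@tp + x@fn)
  c(accuracy = rat(x@tp + x@tn, x@tp + x@tn + x@fp + x@fn),
    precision = p,
    specificity = rat(x@tn, x@tn + x@fp),
    recall = r,
    dice = rat(2 * x@tp, 2 * x@tp + x@fp + x@fn),
    f1 = if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r))
})

#' Per-model metric report table
#'
#' One row per model, the six metric columns expressed as percentages
#' rounded half-up to two decimals (presentation rounding only; use
#' [computeMetrics()] for full precision).
#'
#' @param countsByModel named list of [ConfusionCounts-class]
#' @return data.frame with columns model, accuracy, precision, specificity,
#'   recall, dice, f1 (percent)
#' @export
metricTable <- function(countsByModel) {
  if (length(countsByModel) == 0) stop("empty counts collection", call. = FALSE)
  if (is.null(names(countsByModel)) || any(names(countsByModel) == ""))
    stop("counts collection must be named by model", call. = FALSE)
  rows <- lapply(names(countsByModel), function(m) {
    v <- computeMetrics(countsByModel[[m]])
    data.frame(model = m, t(halfUpRound(100 * v, 2)))
  })
  do.call(rbind, rows)
}

#' Read confusion counts from a CSV file
#'
#' Expects columns `model, tp, tn, fp, fn` (header required).
#'
#' @param path CSV path
#' @return named list of [ConfusionCounts-class]
#' @export
readConfusionCsv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot parse '%s': file not found", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                                  conditionMessage(e)), call. = FALSE))
  need <- c("model", "tp", "tn", "fp", "fn")
  if (!all(need %in% names(df)))
    stop("counts CSV needs columns: model, tp, tn, fp, fn", call. = FALSE)
  if (nrow(df) == 0) stop("counts CSV has no rows", call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(confusionCounts(df$tp[i], df$tn[i], df$fp[i], df$fn[i]),
             error = function(e) stop(sprintf("invalid counts at line %d: %s",
                                              i + 1, conditionMessage(e)), call. = FALSE))
  })
  names(out) <- df$model
  out
}

#' @describeIn ConfusionCounts-class print the four totals and accuracy
#' @param object a `ConfusionCounts`
#' @export
setMethod("show", "ConfusionCounts", function(object) {
  m <- computeMetrics(object)
  cat(sprintf("ConfusionCounts: TP=%g TN=%g FP=%g FN=%g (accuracy %.2f%%)\n",
              object@tp, object@tn, object@fp, object@fn, 100 * m[["accuracy"]]))
})
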
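#' Confusion matrix
#'
#' Counts with rows = true class and columns = predicted class, in the
#' order given by \code{labelOrder}.
#'
#' @param yTrue,yPred equal-length label vectors, each a subset of
#'   \code{labelOrder}.
#' @param labelOrder class label order.
#' @return integer matrix with \code{labelOrder} dimnames.
#' @export
confusionMatrix <- function(yTrue, yPred, labelOrder) {
  stopIf(length(yTrue) != length(yPred),
         "yTrue and yPred must have equal length")
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  unknown <- setdiff(unique(c(yTrue, yPred)), labelOrder)
  stopIf(length(unknown) > 0, "unknown label(s): %s",
         paste(unknown, collapse = ", "))
  k <- length(labelOrder)
  cm <- matrix(0L, k, k, dimnames = list(true = labelOrder,
                                         predicted = labelOrder))
  if (length(yTrue)) {
    tab <- table(factor(yTrue, levels = labelOrder),
                 factor(yPred, levels = labelOrder))
    cm[] <- as.integer(tab)
  }
  cm
}

#' Per-class one-vs-rest metrics
#'
#' TP, FP, TN, FN per class plus the per-class binary accuracy
#' \code{(TP+TN)/total}, precision \code{TP/(TP+FP)}, sensitivity
#' \code{TP/(TP+FN)} and F1 (harmonic mean of the two). Any 0/0 is
#' defined as 0.
#'
#' @param cm a confusion matrix (rows true, columns predicted).
#' @return data.frame with one row per class.
#' @export
perClassMetrics <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safeDiv <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- safeDiv(tp, tp + fp)
  sensitivity <- safeDiv(tp, tp + fn)
  f1 <- safeDiv(2 * precision * sensitivity, precision + sensitivity)
  data.frame(class = rownames(cm), TP = tp, FP = fp, TN = tn, FN = fn,
             accuracy = safeDiv(tp + tn, total),
             precision = precision, sensitivity = sensitivity, f1 = f1,
             row.names = NULL)
}

#' Overall accuracy
#'
#' Ratio of correctly classified instances (the confusion-matrix trace)
#' to the total number of instances.
#'
#' @param cm a confusion matrix.
#' @return accuracy in [0, 1].
#' @export
overallAccuracy <- function(cm) {
  stopIf(sum(cm) == 0, "empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

#' Evaluate predictions
#'
#' Builds the confusion matrix, computes overall accuracy and the
#' per-class precision/sensitivity/F1, and macro-averages them
#' (unweighted mean over classes, so every subject counts equally
#' regardless of beat count).
#'
#' @inheritParams confusionMatrix
#' @return an \linkS4class{EvalReport}.
#' @export
evaluatePredictions <- function(yTrue, yPred, labelOrder) {
  cm <- confusionMatrix(yTrue, yPred, labelOrder)
  pc <- perClassMetrics(cm)
  if (any(pc$TP + pc$FP == 0 | pc$TP + pc$FN == 0))
    warning("some classes have undefined (0/0) metrics; reported as 0",
            call. = FALSE)
  new("EvalReport", confusion = cm, accuracy = overallAccuracy(cm),
      macroPrecision = mean(pc$precision),
      macroSensitivity = mean(pc$sensitivity),
      macroF1 = mean(pc$f1), perClass = pc)
}

#' Serialize an EvalReport to a plain list
#'
#' @param report an \linkS4class{EvalReport}.
#' @return a list suitable for JSON serialization.
#' @export
reportAsList <- function(report) {
  list(
    accuracy = report@accuracy,
    macro_precision = report@macroPrecision,
    macro_sensitivity = report@macroSensitivity,
    macro_f1 = report@macroF1,
    confusion = unname(report@confusion),
    labels = rownames(report@confusion),
    per_class = report@perClass
  )
}
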
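#' @include AllClasses.R AllGenerics.R
NULL

#' Build a multiclass confusion matrix
#'
#' Tallies counts[i, j] = number of samples with true class i predicted as
#' class j, over a fixed class order.
#'
#' @param trueLabels,predictedLabels equal-length vectors of labels, all
#'   contained in \code{classOrder}.
#' @param classOrder character vector fixing the class order; defaults to
#'   the union of observed labels in order of appearance in
#'   \code{trueLabels} then \code{predictedLabels}.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
#' @examples
#' cm <- confusionCounts(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
#' confusionTable(cm)
confusionCounts <- function(trueLabels, predictedLabels, classOrder = NULL) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) != length(predictedLabels))
    stop("true and predicted label vectors must have equal length")
  if (is.null(classOrder))
    classOrder <- unique(c(trueLabels, predictedLabels))
  unknown <- setdiff(unique(c(trueLabels, predictedLabels)), classOrder)
  if (length(unknown))
    stop(sprintf("labels not in classOrder: %s", paste(unknown, collapse = ", ")))
  counts <- table(factor(trueLabels, levels = classOrder),
                  factor(predictedLabels, levels = classOrder))
  counts <- matrix(as.integer(counts), nrow = length(classOrder),
                   dimnames = list(true = classOrder, predicted = classOrder))
  new("ConfusionMatrix", counts = counts, classOrder = classOrder)
}

#' Build a confusion matrix directly from counts
#'
#' @param counts K x K matrix, rows = true class, columns = predicted.
#' @param classOrder the K class names (defaults to rownames).
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
confusionFromCounts <- function(counts, classOrder = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(classOrder)) classOrder <- paste0("class", seq_len(nrow(counts)))
  dimnames(counts) <- list(true = classOrder, predicted = classOrder)
  new("ConfusionMatrix", counts = counts, classOrder = classOrder)
}

#' @rdname confusionCounts
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @export
confusionTable <- function(cm) cm@counts

#' Per-class metrics from a confusion matrix
#'
#' One-vs-rest reduction per class c: TP = counts[c, c], FN = row c minus
#' TP, FP = column c minus TP, TN = total minus TP, FP and FN. Reported as
#' fractions: sensitivity (recall) TP/(TP+FN), precision TP/(TP+FP) and
#' their harmonic mean F1 = 2*P*S/(P+S). A class with no true samples has
#' undefined sensitivity, reported as NA rather than 0; likewise precision
#' for a class never predicted.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return data.frame with columns class, support, tp, sensitivity,
#'   precision, f1.
#' @name classMetrics
#' @export
setMethod("classMetrics", "ConfusionMatrix", function(cm) {
  counts <- cm@counts
  tp <- diag(counts)
  rowS <- rowSums(counts)
  colS <- colSums(counts)
  sens <- ifelse(rowS > 0, tp / rowS, NA_real_)
  prec <- ifelse(colS > 0, tp / colS, NA_real_)
  f1 <- ifelse(!is.na(sens) & !is.na(prec) & (sens + prec) > 0,
               2 * prec * sens / (prec + sens), NA_real_)
  data.frame(class = cm@classOrder, support = as.integer(rowS),
             tp = as.integer(tp), sensitivity = sens, precision = prec,
             f1 = f1, row.names = NULL, stringsAsFactors = FALSE)
})

#' Overall accuracy of a confusion matrix
#'
#' Trace over total: the multiclass reading of the accuracy equation. The
#' misclassification rate is its complement.
#'
#' @param cm a \linkS4class{ConfusionMatrix} with at least one sample.
#' @return accuracy as a fraction in [0, 1].
#' @name overallAccuracy
#' @export
setMethod("overallAccuracy", "ConfusionMatrix", function(cm) {
  total <- sum(cm@counts)
  if (total == 0) stop("confusion matrix is empty")
  sum(diag(cm@counts)) / total
})

#' Full metrics report
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return a \linkS4class{MetricsReport} with per-class sensitivity,
#'   precision and F1, overall accuracy and misclassification rate.
#' @export
metricsReport <- function(cm) {
  acc <- overallAccuracy(cm)
  new("MetricsReport", perClass = classMetrics(cm), accuracy = acc,
      misclassificationRate = 1 - acc)
}

#' Render a fraction as a printed percentage
#'
#' Percentages are stored as fractions throughout the package; reports
#' render them to one decimal place (trailing ".0" dropped), the precision
#' used in the field's published tables.
#'
#' @param x fraction(s) in [0, 1].
#' @param digits decimal places (default 1).
#' @return numeric percentage(s), e.g. 0.985 -> 98.5.
#' @export
#' @examples
#' percent(196 / 200)
percent <- function(x, digits = 1) round(100 * x, digits)

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: %d classes, %d samples\n",
              length(object@classOrder), sum(object@counts)))
  print(object@counts)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.1f%% (misclassification %.1f%%)\n",
              100 * object@accuracy, 100 * object@misclassificationRate))
  df <- object@perClass
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-22s sens %5.1f%%  prec %5.1f%%  F1 %5.1f%%\n",
                df$class[i], 100 * df$sensitivity[i], 100 * df$precision[i],
                100 * df$f1[i]))
  }
})
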
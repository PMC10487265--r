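#' @include AllClasses.R AllGenerics.R utils.R classify.R
NULL

#' Build a frozen-fold fitness evaluator
#'
#' Constructs the objective that the metaheuristic weighting maximizes: the
#' mean out-of-fold accuracy of a classifier trained on column-weighted
#' features. The stratified fold assignment is drawn once here and frozen,
#' and per-fold standardization is precomputed on the training part of each
#' fold, so every subsequent evaluation is a pure, deterministic function
#' of the weight vector. Weights are applied multiplicatively per column
#' after standardization.
#'
#' @param x a \linkS4class{FeatureTable} (typically the selected columns)
#'   or n x d numeric matrix.
#' @param labels factor of class labels (taken from the table when omitted).
#' @param classifier a \code{\link{classifierSpec}}; default polynomial SVM.
#' @param k number of frozen folds (default 5).
#' @param seed integer seed fixing the folds and any classifier randomness.
#' @param groups optional grouping vector: all samples of a group share a
#'   fold (see \code{\link{kfoldPredict}}).
#' @return a \linkS4class{FitnessEvaluator}.
#' @export
fitnessEvaluator <- function(x, labels = NULL,
                             classifier = classifierSpec(), k = 5L,
                             seed = 1L, groups = NULL) {
  if (is(x, "FeatureTable")) {
    if (is.null(labels)) labels <- cellLabels(x)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  folds <- makeStratifiedFolds(labels, k, stageSeed(seed, "fitness-folds"),
                               groups = groups)
  new("FitnessEvaluator", values = x, labels = labels,
      classifier = unclass(classifier), folds = folds,
      parts = .foldScaleSplit(x, labels, folds),
      seed = as.integer(stageSeed(seed, "fitness-classifier")))
}

#' Evaluate the classification fitness of a weight vector
#'
#' Returns the mean over the evaluator's frozen folds of the accuracy of
#' the classifier trained on column-weighted training features and tested
#' on identically weighted held-out features. Pure: the same weights always
#' give the same value.
#'
#' @param weights numeric vector in [0, 1]^d matching the evaluator's
#'   feature count.
#' @param evaluator a \linkS4class{FitnessEvaluator}.
#' @return accuracy in [0, 1].
#' @name evaluateFitness
#' @export
setMethod("evaluateFitness", signature("numeric", "FitnessEvaluator"),
  function(weights, evaluator) {
    d <- ncol(evaluator@values)
    if (length(weights) != d)
      stop(sprintf("weight vector has length %d; evaluator expects %d",
                   length(weights), d))
    spec <- structure(evaluator@classifier, class = "ClassifierSpec")
    parts <- evaluator@parts
    accs <- withr::with_seed(evaluator@seed, vapply(parts, function(p) {
      xt <- sweep(p$train, 2, weights, "*")
      xv <- sweep(p$test, 2, weights, "*")
      fit <- .trainClassifier(xt, p$trainLabels, spec)
      mean(predict(fit, xv) == p$testLabels)
    }, numeric(1)))
    mean(accs)
  })

#' Apply a weight vector to a feature table
#'
#' Multiplies feature column i by weight i, preserving provenance, labels
#' and sample ids.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param weights numeric vector, one weight per feature.
#' @return a weighted \linkS4class{FeatureTable}.
#' @export
applyWeights <- function(table, weights) {
  d <- nrow(table)
  if (length(weights) != d)
    stop(sprintf("weight vector has length %d; table has %d features",
                 length(weights), d))
  a <- SummarizedExperiment::assay(table, "features") * weights
  SummarizedExperiment::assay(table, "features") <- a
  table
}
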
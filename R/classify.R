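#' @include AllClasses.R AllGenerics.R utils.R features.R
NULL

#' Classifier specification
#'
#' The two classifiers of the pipeline: a polynomial-kernel support vector
#' machine (one-vs-one multiclass) and a random forest. Defaults: SVM with
#' degree 3, cost C = 1 and gamma scaled as 1/d; random forest with 100
#' trees and sqrt(d) features tried per split. Feature standardization is
#' not part of the classifier — it is fitted per training fold by the
#' cross-validation harness.
#'
#' @param kind "svm_poly" or "random_forest".
#' @param degree polynomial degree (>= 1), SVM only.
#' @param cost regularization parameter C, SVM only.
#' @param gamma kernel coefficient, SVM only; NULL = 1/d ("scaled").
#' @param coef0 polynomial kernel offset, SVM only.
#' @param nTrees number of trees (>= 1), random forest only.
#' @return a list of class "ClassifierSpec".
#' @export
classifierSpec <- function(kind = c("svm_poly", "random_forest"),
                           degree = 3, cost = 1, gamma = NULL, coef0 = 0,
                           nTrees = 100L) {
  kind <- match.arg(kind)
  stopifnot(degree >= 1, nTrees >= 1, cost > 0)
  structure(list(kind = kind, degree = degree, cost = cost, gamma = gamma,
                 coef0 = coef0, nTrees = as.integer(nTrees)),
            class = "ClassifierSpec")
}

# train on standardized features; any internal randomness is governed by
# the caller's RNG state
.trainClassifier <- function(x, y, spec) {
  if (spec$kind == "svm_poly") {
    gamma <- if (is.null(spec$gamma)) 1 / ncol(x) else spec$gamma
    e1071::svm(x, y, kernel = "polynomial", degree = spec$degree,
               cost = spec$cost, gamma = gamma, coef0 = spec$coef0,
               scale = FALSE)
  } else {
    randomForest::randomForest(x, y, ntree = spec$nTrees,
                               mtry = max(1L, floor(sqrt(ncol(x)))))
  }
}

#' Pooled out-of-fold predictions under stratified k-fold CV
#'
#' Assigns every sample to one of k stratified folds (deterministic given
#' \code{seed}), then for each fold trains the classifier on the remaining
#' folds and predicts the held-out fold. Column standardization is fitted
#' on the training part of each fold only, so no information leaks from
#' the held-out samples. Every sample receives exactly one prediction from
#' a model that never saw it.
#'
#' @param x a \linkS4class{FeatureTable} or n x d numeric matrix.
#' @param labels factor of n class labels (taken from the table when
#'   omitted). Every class must have at least k members.
#' @param spec a \code{\link{classifierSpec}}.
#' @param k number of folds (default 5).
#' @param seed integer seed fixing the fold assignment and any classifier
#'   randomness.
#' @param groups optional grouping vector (e.g. source-cell ids): all
#'   samples of a group are assigned to the same fold, so augmented copies
#'   of one original never straddle a train/test split.
#' @return data.frame with columns sampleId, trueLabel, predictedLabel and
#'   fold, in input sample order.
#' @export
kfoldPredict <- function(x, labels = NULL, spec = classifierSpec(),
                         k = 5L, seed = 1L, groups = NULL) {
  ids <- NULL
  if (is(x, "FeatureTable")) {
    if (is.null(labels)) labels <- cellLabels(x)
    ids <- as.character(sampleIds(x))
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(nrow(x)))
  folds <- makeStratifiedFolds(labels, k, stageSeed(seed, "cv-folds"),
                               groups = groups)
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(labels))
  for (part in .foldScaleSplit(x, labels, folds)) {
    fit <- withr::with_seed(stageSeed(seed, paste0("fold-", part$fold)),
                            .trainClassifier(part$train, part$trainLabels, spec))
    p <- predict(fit, part$test)
    pred[part$testIdx] <- as.character(p)
  }
  data.frame(sampleId = ids, trueLabel = labels, predictedLabel = pred,
             fold = folds, stringsAsFactors = FALSE)
}
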
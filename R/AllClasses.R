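#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.SCENARIOS <- c("whole", "nucleus_excluded", "nucleus_only")
.ORIGINS <- c("original", "augmented")

#' Labelled single-cell image collection
#'
#' Holds a set of single-channel 8-bit cell rasters with class labels,
#' optional binary nucleus masks aligned with each raster, a scenario tag
#' describing which cell region the pixels represent, and a per-image origin
#' flag (original vs. augmented).
#'
#' @slot images list of numeric matrices (row x col, intensities in [0, 255]).
#' @slot masks list of logical matrices (TRUE = nucleus) or NULL entries.
#' @slot labels factor of class labels, one per image.
#' @slot scenario length-one character: "whole", "nucleus_excluded" or
#'   "nucleus_only".
#' @slot origin character vector, one of "original"/"augmented" per image.
#' @slot sourceIndex integer vector identifying the source cell of every
#'   image: originals carry their own id, augmented copies the id of the
#'   original they were derived from. Used for leakage-free grouped fold
#'   assignment.
#' @exportClass CellImageSet
setClass("CellImageSet",
  representation(
    images = "list",
    masks = "list",
    labels = "factor",
    scenario = "character",
    origin = "character",
    sourceIndex = "integer"
  )
)

setValidity("CellImageSet", function(object) {
  n <- length(object@images)
  if (length(object@masks) != n) return("masks must have one entry per image")
  if (length(object@labels) != n) return("labels must have one entry per image")
  if (length(object@origin) != n) return("origin must have one entry per image")
  if (length(object@scenario) != 1L || !object@scenario %in% .SCENARIOS)
    return(sprintf("scenario must be one of %s", paste(.SCENARIOS, collapse = ", ")))
  if (!all(object@origin %in% .ORIGINS))
    return("origin values must be 'original' or 'augmented'")
  if (length(object@sourceIndex) != n)
    return("sourceIndex must have one entry per image")
  for (i in seq_len(n)) {
    m <- object@masks[[i]]
    if (!is.null(m) && !identical(dim(m), dim(object@images[[i]])))
      return(sprintf("mask %d does not match its image dimensions", i))
  }
  TRUE
})

#' Feature table with per-column provenance
#'
#' A \linkS4class{SummarizedExperiment} whose rows are features and columns
#' are samples. \code{rowData} records each feature's provenance (extractor
#' name and 1-based feature index within that extractor); \code{colData}
#' carries the class label and sample identifier.
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("extractor", "featureIndex") %in% colnames(rd)))
    return("rowData must contain 'extractor' and 'featureIndex'")
  if (!all(c("label", "sampleId") %in% colnames(cd)))
    return("colData must contain 'label' and 'sampleId'")
  v <- SummarizedExperiment::assay(object)
  if (length(v) && !all(is.finite(v)))
    return("feature values must all be finite")
  TRUE
})

#' Principal component model for variable importance
#'
#' Stores the standardized-PCA decomposition used for loading-magnitude
#' variable ranking: the d x m coefficient (rotation) matrix, the
#' explained-variance ratio of each component, and the column centring and
#' scaling applied before decomposition.
#'
#' @slot rotation d x m numeric matrix of component coefficients.
#' @slot explainedVarianceRatio m nonnegative values summing to <= 1,
#'   non-increasing.
#' @slot center,scale d-length numeric vectors used to standardize columns.
#' @exportClass PcaModel
setClass("PcaModel",
  representation(
    rotation = "matrix",
    explainedVarianceRatio = "numeric",
    center = "numeric",
    scale = "numeric"
  )
)

setValidity("PcaModel", function(object) {
  m <- length(object@explainedVarianceRatio)
  if (ncol(object@rotation) != m)
    return("rotation must have one column per explained-variance ratio")
  if (any(object@explainedVarianceRatio < -1e-12))
    return("explained-variance ratios must be nonnegative")
  if (m > 1 && any(diff(object@explainedVarianceRatio) > 1e-8))
    return("explained-variance ratios must be non-increasing")
  if (length(object@center) != nrow(object@rotation) ||
      length(object@scale) != nrow(object@rotation))
    return("center/scale must have one entry per variable")
  TRUE
})

#' Result of top-k feature selection
#'
#' @slot indices ordered integer vector of selected column indices
#'   (non-increasing importance; ties broken by lower index).
#' @slot scores importance score of every candidate variable.
#' @slot provenanceCounts named integer vector: number of selected features
#'   contributed by each extractor.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(
    indices = "integer",
    scores = "numeric",
    provenanceCounts = "integer"
  )
)

setValidity("SelectionResult", function(object) {
  if (anyDuplicated(object@indices)) return("selected indices must be distinct")
  if (any(object@indices < 1L) || any(object@indices > length(object@scores)))
    return("selected indices out of range")
  s <- object@scores[object@indices]
  if (length(s) > 1 && any(diff(s) > 1e-12))
    return("selected indices must be ordered by non-increasing importance")
  if (length(object@provenanceCounts) &&
      sum(object@provenanceCounts) != length(object@indices))
    return("provenance counts must sum to the number of selected features")
  TRUE
})

#' Frozen-fold fitness evaluator for feature weighting
#'
#' Wraps a feature matrix, its labels, a classifier specification and a fixed
#' stratified fold assignment. Evaluating a weight vector returns the mean
#' out-of-fold accuracy of the classifier trained on column-weighted,
#' per-fold-standardized features. Because the folds (and any classifier
#' randomness seed) are frozen at construction, the evaluation is a pure
#' function of the weight vector.
#'
#' @slot values n x d numeric matrix (samples x selected features).
#' @slot labels factor of n class labels.
#' @slot classifier classifier specification list (see
#'   \code{\link{classifierSpec}}).
#' @slot folds integer fold id per sample.
#' @slot parts per-fold precomputed standardized train/test splits.
#' @slot seed integer seed used for any classifier-internal randomness.
#' @exportClass FitnessEvaluator
setClass("FitnessEvaluator",
  representation(
    values = "matrix",
    labels = "factor",
    classifier = "list",
    folds = "integer",
    parts = "list",
    seed = "integer"
  )
)

setValidity("FitnessEvaluator", function(object) {
  n <- nrow(object@values)
  if (length(object@labels) != n || length(object@folds) != n)
    return("labels and folds must have one entry per sample")
  TRUE
})

#' Result of a metaheuristic optimization run
#'
#' @slot method "alo" or "pso".
#' @slot bestWeights best position found (in [0,1]^d).
#' @slot bestFitness fitness of the best position.
#' @slot fitnessHistory best-so-far fitness after initialization and after
#'   each iteration; non-decreasing by elitism.
#' @slot evaluations number of objective evaluations performed.
#' @slot seed integer seed of the run.
#' @exportClass OptimizationResult
setClass("OptimizationResult",
  representation(
    method = "character",
    bestWeights = "numeric",
    bestFitness = "numeric",
    fitnessHistory = "numeric",
    evaluations = "integer",
    seed = "integer"
  )
)

setValidity("OptimizationResult", function(object) {
  h <- object@fitnessHistory
  if (length(h) && any(diff(h) < -1e-12))
    return("fitness history must be non-decreasing (elitism)")
  if (length(h) && abs(object@bestFitness - h[length(h)]) > 1e-12)
    return("bestFitness must equal the last history entry")
  TRUE
})

#' Multiclass confusion matrix
#'
#' K x K counts with rows = true class and columns = predicted class, in a
#' fixed class order. One-vs-rest TP/FN/FP/TN reductions and all derived
#' metrics are computed by \code{\link{classMetrics}} and
#' \code{\link{overallAccuracy}}.
#'
#' @slot counts K x K nonnegative integer matrix.
#' @slot classOrder character vector of the K class names.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", classOrder = "character")
)

setValidity("ConfusionMatrix", function(object) {
  k <- length(object@classOrder)
  if (!identical(dim(object@counts), c(k, k)))
    return("counts must be K x K for K classes")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  TRUE
})

#' Per-class and overall classification metrics
#'
#' @slot perClass data.frame with one row per class: sensitivity, precision
#'   and F1 as fractions (NA where a denominator is empty), plus support.
#' @slot accuracy overall accuracy (trace / total), a fraction.
#' @slot misclassificationRate 1 - accuracy.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    perClass = "data.frame",
    accuracy = "numeric",
    misclassificationRate = "numeric"
  )
)

setValidity("MetricsReport", function(object) {
  if (abs(object@misclassificationRate - (1 - object@accuracy)) > 1e-12)
    return("misclassificationRate must equal 1 - accuracy")
  TRUE
})
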
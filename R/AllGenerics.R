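#' @include AllClasses.R
NULL

#' Accessors for cytoweight containers
#'
#' \code{cellImages}, \code{cellMasks}, \code{cellLabels},
#' \code{imageScenario} and \code{imageOrigin} access the slots of a
#' \linkS4class{CellImageSet}; \code{cellLabels} also works on a
#' \linkS4class{FeatureTable}. \code{featureMatrix} returns a samples x
#' features numeric matrix, \code{featureProvenance} the per-column
#' provenance, and \code{sampleIds} the sample identifiers.
#'
#' @param x a cytoweight object.
#' @return the corresponding slot, in user-facing orientation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellImages", function(x) standardGeneric("cellImages"))

#' @rdname accessors
#' @export
setGeneric("cellMasks", function(x) standardGeneric("cellMasks"))

#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname accessors
#' @export
setGeneric("imageScenario", function(x) standardGeneric("imageScenario"))

#' @rdname accessors
#' @export
setGeneric("imageOrigin", function(x) standardGeneric("imageOrigin"))

#' @rdname accessors
#' @export
setGeneric("sourceIndex", function(x) standardGeneric("sourceIndex"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureProvenance", function(x) standardGeneric("featureProvenance"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname scoreVariables
#' @export
setGeneric("scoreVariables", function(model) standardGeneric("scoreVariables"))

#' @rdname scoreVariables
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname evaluateFitness
#' @export
setGeneric("evaluateFitness", function(weights, evaluator)
  standardGeneric("evaluateFitness"))

#' @rdname classMetrics
#' @export
setGeneric("classMetrics", function(cm) standardGeneric("classMetrics"))

#' @rdname overallAccuracy
#' @export
setGeneric("overallAccuracy", function(cm) standardGeneric("overallAccuracy"))

#' @rdname selectTop
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))

#' @rdname selectTop
#' @export
setGeneric("importanceScores", function(x) standardGeneric("importanceScores"))

#' @rdname selectTop
#' @export
setGeneric("provenanceCounts", function(x) standardGeneric("provenanceCounts"))

#' @rdname optimizers
#' @export
setGeneric("bestWeights", function(x) standardGeneric("bestWeights"))

#' @rdname optimizers
#' @export
setGeneric("bestFitness", function(x) standardGeneric("bestFitness"))

#' @rdname optimizers
#' @export
setGeneric("fitnessHistory", function(x) standardGeneric("fitnessHistory"))
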
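#' @include AllClasses.R AllGenerics.R features.R
NULL

#' Fit a PCA for variable ranking
#'
#' Centres every column and computes the principal component decomposition
#' of the covariance (the default, matching the convention that a
#' variable's variance contribution is part of its importance; set
#' \code{scale. = TRUE} to z-score columns first when features live on
#' incommensurate scales — constant columns are then left unscaled). All
#' min(n - 1, d) components are retained; coefficients are unit-length per
#' component and deterministic up to component sign, which the downstream
#' importance score is invariant to.
#'
#' @param x a \linkS4class{FeatureTable} or an n x d numeric matrix with at
#'   least 2 rows.
#' @param scale. standardize columns before decomposition (default FALSE).
#' @return a \linkS4class{PcaModel}.
#' @export
fitPca <- function(x, scale. = FALSE) {
  if (is(x, "FeatureTable")) x <- featureMatrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA requires at least 2 samples")
  scale_ <- FALSE
  if (isTRUE(scale.)) {
    sds <- apply(x, 2, stats::sd)
    scale_ <- ifelse(sds == 0 | !is.finite(sds), 1, sds)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale_)
  evr <- p$sdev^2 / sum(p$sdev^2)
  m <- min(nrow(x) - 1L, ncol(x))
  new("PcaModel",
      rotation = p$rotation[, seq_len(m), drop = FALSE],
      explainedVarianceRatio = evr[seq_len(m)],
      center = unname(p$center),
      scale = if (isFALSE(p$scale)) rep(1, ncol(x)) else unname(p$scale))
}

#' @rdname scoreVariables
#' @export
setMethod("explainedVariance", "PcaModel",
          function(x) x@explainedVarianceRatio)

#' Variable importance from PCA loadings
#'
#' Scores variable i as the sum over components j of
#' \code{explainedVarianceRatio[j] * |rotation[i, j]|}: the absolute
#' coefficient magnitudes, weighted by how much variance each component
#' explains. Scores are nonnegative and invariant to component sign flips.
#'
#' @param model a fitted \linkS4class{PcaModel}.
#' @return named numeric vector of importance scores, one per variable.
#' @name scoreVariables
#' @export
setMethod("scoreVariables", "PcaModel", function(model) {
  drop(abs(model@rotation) %*% model@explainedVarianceRatio)
})

#' Select the top-k variables by importance
#'
#' Returns the k highest-scoring column indices, ordered by non-increasing
#' importance with ties broken by the lower column index, together with
#' per-extractor provenance counts (how many selected features each
#' extractor contributed). With the 21-feature concatenation of three
#' extractors and k = 10 this realizes the 21-to-10 reduction.
#'
#' @param scores numeric importance scores (from
#'   \code{\link{scoreVariables}}).
#' @param k number of variables to keep, 1 <= k <= length(scores).
#' @param provenance optional character vector giving each column's
#'   extractor, for the provenance counts.
#' @return a \linkS4class{SelectionResult}.
#' @export
selectTop <- function(scores, k, provenance = NULL) {
  d <- length(scores)
  if (k < 1 || k > d) stop(sprintf("k must be in [1, %d]", d))
  ord <- order(-scores, seq_len(d))
  idx <- as.integer(ord[seq_len(k)])
  counts <- if (is.null(provenance)) integer(0) else {
    tb <- table(factor(provenance[idx], levels = unique(provenance)))
    stats::setNames(as.integer(tb), names(tb))
  }
  new("SelectionResult", indices = idx, scores = as.numeric(scores),
      provenanceCounts = counts)
}

#' Rank and select features of a table in one step
#'
#' Convenience wrapper: fits the standardized PCA on the table, scores the
#' variables by variance-weighted absolute loadings and keeps the top k.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param k number of features to keep (default 10, the published
#'   reduction from 21).
#' @return a \linkS4class{SelectionResult}.
#' @export
selectFeatures <- function(table, k = 10L) {
  model <- fitPca(table)
  scores <- scoreVariables(model)
  selectTop(scores, k, provenance = featureProvenance(table)$extractor)
}

#' @rdname selectTop
#' @export
setMethod("selectedIndices", "SelectionResult", function(x) x@indices)

#' @rdname selectTop
#' @export
setMethod("importanceScores", "SelectionResult", function(x) x@scores)

#' @rdname selectTop
#' @export
setMethod("provenanceCounts", "SelectionResult", function(x) x@provenanceCounts)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d of %d features\n",
              length(object@indices), length(object@scores)))
  cat("  indices:", paste(object@indices, collapse = ", "), "\n")
  if (length(object@provenanceCounts)) {
    cat("  provenance:",
        paste(sprintf("%s=%d", names(object@provenanceCounts),
                      object@provenanceCounts), collapse = ", "), "\n")
  }
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d variables, %d components\n",
              nrow(object@rotation), ncol(object@rotation)))
  cat("  explained variance ratios:",
      paste(sprintf("%.3f", utils::head(object@explainedVarianceRatio, 5)),
            collapse = ", "),
      if (length(object@explainedVarianceRatio) > 5) "..." else "", "\n")
})
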
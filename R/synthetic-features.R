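#' @include AllClasses.R features.R
NULL

#' Specification for synthetic feature tables
#'
#' Describes a seeded tabular dataset with a planted informative/noise
#' column structure over the seven cell classes: informative columns get
#' class-dependent means and noise columns are class-independent standard
#' normals. The first informative column carries a centred ordinal
#' severity ramp (adjacent classes one separation unit apart, emulating a
#' feature that tracks dysplasia grade); further informative columns carry
#' the binary code bits of the class index, scaled by the separation. With
#' three or more informative columns the seven class means are distinct
#' and well spread, so a separation of a few noise SDs makes the classes
#' linearly separable.
#'
#' @param nPerClass samples per class (balanced design).
#' @param nInformative number of class-informative columns.
#' @param nNoise number of class-independent noise columns.
#' @param classSeparation distance between class means along each
#'   informative column, in units of the noise SD (>= 0).
#' @param seed integer seed.
#' @return a list of class "SyntheticFeatureSpec".
#' @export
syntheticFeatureSpec <- function(nPerClass = 50L, nInformative = 3L,
                                 nNoise = 7L, classSeparation = 4,
                                 seed = 1L) {
  stopifnot(nPerClass >= 1, nInformative >= 0, nNoise >= 0,
            classSeparation >= 0)
  if (nInformative == 0 && classSeparation > 0)
    stop("a positive class separation requires at least one informative column")
  if (nInformative + nNoise < 1) stop("table must have at least one column")
  structure(list(nPerClass = as.integer(nPerClass),
                 nInformative = as.integer(nInformative),
                 nNoise = as.integer(nNoise),
                 classSeparation = classSeparation,
                 seed = as.integer(seed)),
            class = "SyntheticFeatureSpec")
}

#' Simulate a feature table with planted signal columns
#'
#' @param spec a \code{\link{syntheticFeatureSpec}}.
#' @return a \linkS4class{FeatureTable} whose first \code{nInformative}
#'   columns carry provenance "informative" and the rest "noise"; labels
#'   are the seven canonical classes, balanced at \code{nPerClass}.
#' @export
#' @examples
#' ft <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 5, seed = 3))
#' dim(featureMatrix(ft))
simulateFeatureTable <- function(spec) {
  stopifnot(inherits(spec, "SyntheticFeatureSpec"))
  cls <- herlevClasses()$name
  K <- length(cls)
  labels <- factor(rep(cls, each = spec$nPerClass), levels = cls)
  n <- length(labels)
  ninf <- spec$nInformative; nnoi <- spec$nNoise
  withr::with_seed(spec$seed, {
    values <- matrix(stats::rnorm(n * (ninf + nnoi)), n, ninf + nnoi)
  })
  if (ninf > 0) {
    ci <- as.integer(labels) - 1L
    # column 1: centred severity ramp; columns 2+: class-index bits
    pattern <- vapply(seq_len(ninf), function(j) {
      if (j == 1) ci - (K - 1) / 2
      else (ci %/% 2^((j - 2) %% 3)) %% 2
    }, numeric(n))
    values[, seq_len(ninf)] <- values[, seq_len(ninf), drop = FALSE] +
      pattern * spec$classSeparation
  }
  FeatureTable(values,
               extractor = c(rep("informative", ninf), rep("noise", nnoi)),
               featureIndex = c(seq_len(ninf), seq_len(nnoi)),
               labels = labels)
}
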
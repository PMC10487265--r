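#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a FeatureTable
#'
#' @param values n x d numeric matrix, samples in rows, features in columns.
#' @param extractor character vector of length d: originating extractor of
#'   each feature column.
#' @param featureIndex integer vector of length d: 1-based index of the
#'   feature within its extractor.
#' @param labels factor (or coercible) of n class labels.
#' @param sampleIds character vector of n sample identifiers; defaults to
#'   "s0001", "s0002", ...
#' @return a \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(values, extractor, featureIndex, labels,
                         sampleIds = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); d <- ncol(values)
  stopifnot(length(extractor) == d, length(featureIndex) == d,
            length(labels) == n)
  if (is.null(sampleIds)) sampleIds <- sprintf("s%04d", seq_len(n))
  fnames <- paste0(extractor, "_f", featureIndex)
  a <- t(values)
  dimnames(a) <- list(fnames, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = a),
    rowData = S4Vectors::DataFrame(extractor = extractor,
                                   featureIndex = as.integer(featureIndex),
                                   row.names = fnames),
    colData = S4Vectors::DataFrame(label = as.factor(labels),
                                   sampleId = sampleIds,
                                   row.names = sampleIds))
  new("FeatureTable", se)
}

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname accessors
#' @export
setMethod("featureProvenance", "FeatureTable", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname accessors
#' @export
setMethod("cellLabels", "FeatureTable", function(x)
  SummarizedExperiment::colData(x)$label)

#' @rdname accessors
#' @export
setMethod("sampleIds", "FeatureTable", function(x)
  SummarizedExperiment::colData(x)$sampleId)

.KNOWN_EXTRACTORS <- list(
  "mock-alexnet" = list(inputSize = c(227L, 227L, 3L), darkThreshold = 128),
  "mock-darknet19" = list(inputSize = c(256L, 256L, 3L), darkThreshold = 110),
  "mock-nasnet" = list(inputSize = c(224L, 224L, 3L), darkThreshold = 140)
)

#' Deep-feature extractor specification
#'
#' The extractor contract: each extractor resizes its input to a fixed
#' size and emits exactly 7 features per image, mirroring a transfer-learned
#' backbone whose final fully connected layer is replaced by a 7-way head
#' (one neuron per cervical cell class). The package ships deterministic
#' mock extractors ("mock-alexnet", 227x227; "mock-darknet19", 256x256;
#' "mock-nasnet", 224x224 — the mobile variant size) that compute 7 fixed
#' image statistics instead of network activations; a real CNN backbone can
#' be plugged in by supplying \code{fun}.
#'
#' @param name extractor identifier; the mock names above get canonical
#'   input sizes and thresholds.
#' @param inputSize integer (height, width) or (height, width, channels)
#'   the image is resized to before extraction. Mock extractors operate on
#'   the single grey channel.
#' @param nFeatures number of features; fixed at 7 by the contract.
#' @param darkThreshold intensity below which a pixel counts as "dark" for
#'   the mock statistics.
#' @param fun optional custom extraction function(matrix) -> numeric(7);
#'   defaults to the mock statistics.
#' @return a list of class "ExtractorSpec".
#' @export
extractorSpec <- function(name, inputSize = NULL, nFeatures = 7L,
                          darkThreshold = NULL, fun = NULL) {
  if (nFeatures != 7L)
    stop("the extractor contract fixes nFeatures at 7 (one per class)")
  known <- .KNOWN_EXTRACTORS[[name]]
  if (is.null(inputSize)) {
    if (is.null(known)) stop("inputSize required for unknown extractor name")
    inputSize <- known$inputSize
  }
  if (is.null(darkThreshold))
    darkThreshold <- if (is.null(known)) 128 else known$darkThreshold
  if (any(inputSize[1:2] <= 0)) stop("inputSize must be positive")
  structure(list(name = name, inputSize = as.integer(inputSize[1:2]),
                 nFeatures = 7L, darkThreshold = darkThreshold, fun = fun),
            class = "ExtractorSpec")
}

#' The three canonical mock extractors
#'
#' @return list of three \code{\link{extractorSpec}}s, in the canonical
#'   concatenation order: mock-alexnet, mock-darknet19, mock-nasnet.
#' @export
mockExtractors <- function() {
  lapply(c("mock-alexnet", "mock-darknet19", "mock-nasnet"), extractorSpec)
}

# 7 deterministic image statistics, pure in the pixel content:
# mean, SD, dark-pixel fraction, darkness-weighted centroid offset from the
# image centre, darkness-weighted second moments along rows and columns,
# and the 10-90% intensity spread. Chosen so nucleus size and darkness
# (the class-varying properties) are linearly visible.
.mockStatistics <- function(px, darkThreshold) {
  n <- nrow(px)
  w <- 255 - px
  sw <- sum(w)
  if (sw <= 0) w <- matrix(1, n, ncol(px)); sw <- sum(w)
  R <- rep(seq_len(n), times = ncol(px))
  C <- rep(seq_len(ncol(px)), each = n)
  ctr <- c((n + 1) / 2, (ncol(px) + 1) / 2)
  rc <- sum(R * w) / sw
  cc <- sum(C * w) / sw
  q <- stats::quantile(px, c(0.1, 0.9), names = FALSE)
  c(mean(px) / 255,
    stats::sd(px) / 255,
    mean(px < darkThreshold),
    sqrt((rc - ctr[1])^2 + (cc - ctr[2])^2) / n,
    sqrt(sum(w * (R - rc)^2) / sw) / n,
    sqrt(sum(w * (C - cc)^2) / sw) / n,
    (q[2] - q[1]) / 255)
}

# resize a (row, col) raster to the extractor input size (bilinear)
.resizeTo <- function(px, size) {
  if (all(dim(px) == size)) return(px)
  img <- EBImage::Image(t(px))
  out <- EBImage::resize(img, w = size[2], h = size[1])
  t(EBImage::imageData(out))
}

#' Extract a 7-feature table from images
#'
#' Resizes every image to the extractor's input size, then applies the
#' extractor function (the deterministic mock statistics by default),
#' producing one row per image in input order. Deterministic: identical
#' pixels give identical features.
#'
#' @param x a \linkS4class{CellImageSet} with at least one image.
#' @param spec an \code{\link{extractorSpec}}.
#' @return a \linkS4class{FeatureTable} with 7 columns attributed to
#'   \code{spec$name}.
#' @export
extractFeatures <- function(x, spec) {
  stopifnot(is(x, "CellImageSet"), inherits(spec, "ExtractorSpec"))
  if (length(x) == 0) stop("cannot extract features from an empty image set")
  fun <- spec$fun
  if (is.null(fun)) fun <- function(px) .mockStatistics(px, spec$darkThreshold)
  rows <- lapply(x@images, function(px) {
    if (length(px) == 0) stop("zero-size image")
    fun(.resizeTo(px, spec$inputSize))
  })
  values <- do.call(rbind, rows)
  if (ncol(values) != 7L) stop("extractor must return exactly 7 features")
  FeatureTable(values, extractor = rep(spec$name, 7L),
               featureIndex = 1:7, labels = x@labels)
}

#' Concatenate feature tables column-wise
#'
#' Combines the 7-feature blocks of several extractors into one table,
#' preserving per-column provenance and block order (e.g. three extractors
#' give 21 columns). All tables must agree in sample identifiers, order and
#' labels.
#'
#' @param ... \linkS4class{FeatureTable}s over the same samples.
#' @return a single \linkS4class{FeatureTable}.
#' @export
concatFeatures <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1]]) &&
      !is(tables[[1]], "FeatureTable"))
    tables <- tables[[1]]
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  if (length(tables) == 1L) return(ref)
  for (tb in tables[-1]) {
    if (!identical(as.character(sampleIds(tb)), as.character(sampleIds(ref))) ||
        !identical(as.character(cellLabels(tb)), as.character(cellLabels(ref))))
      stop("feature tables must share identical samples (ids, order, labels)")
  }
  values <- do.call(cbind, lapply(tables, featureMatrix))
  prov <- do.call(rbind, lapply(tables, featureProvenance))
  FeatureTable(values, extractor = prov$extractor,
               featureIndex = prov$featureIndex,
               labels = cellLabels(ref),
               sampleIds = as.character(sampleIds(ref)))
}
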
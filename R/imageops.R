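#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a CellImageSet
#'
#' @param images list of numeric matrices, intensities in [0, 255].
#' @param labels factor (or coercible) of class labels, one per image.
#' @param masks optional list of logical nucleus masks (TRUE = nucleus),
#'   one per image; NULL entries allowed. Default: no masks.
#' @param scenario region tag: "whole", "nucleus_excluded" or "nucleus_only".
#' @param origin per-image origin, "original" or "augmented"; recycled.
#' @return a \linkS4class{CellImageSet}.
#' @export
CellImageSet <- function(images, labels, masks = NULL,
                         scenario = "whole", origin = "original",
                         sourceIndex = NULL) {
  n <- length(images)
  if (is.null(masks)) masks <- vector("list", n)
  if (is.null(sourceIndex)) sourceIndex <- seq_len(n)
  new("CellImageSet",
      images = images,
      masks = masks,
      labels = as.factor(labels),
      scenario = scenario,
      origin = rep_len(origin, n),
      sourceIndex = as.integer(sourceIndex))
}

#' @rdname accessors
#' @export
setMethod("cellImages", "CellImageSet", function(x) x@images)

#' @rdname accessors
#' @export
setMethod("cellMasks", "CellImageSet", function(x) x@masks)

#' @rdname accessors
#' @export
setMethod("cellLabels", "CellImageSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("imageScenario", "CellImageSet", function(x) x@scenario)

#' @rdname accessors
#' @export
setMethod("imageOrigin", "CellImageSet", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("sourceIndex", "CellImageSet", function(x) x@sourceIndex)

#' @export
setMethod("length", "CellImageSet", function(x) length(x@images))

#' @export
setMethod("[", "CellImageSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
    images = x@images[i],
    masks = x@masks[i],
    labels = factor(x@labels[i], levels = levels(x@labels)),
    origin = x@origin[i],
    sourceIndex = x@sourceIndex[i])
})

setMethod("show", "CellImageSet", function(object) {
  d <- if (length(object)) dim(object@images[[1]]) else c(0L, 0L)
  cat(sprintf("CellImageSet with %d image(s) [%dx%d], scenario '%s'\n",
              length(object), d[1], d[2], object@scenario))
  cat(sprintf("  masks: %d/%d present; augmented: %d\n",
              sum(!vapply(object@masks, is.null, TRUE)), length(object),
              sum(object@origin == "augmented")))
  print(table(object@labels))
})

#' Combine CellImageSets
#' @param x,... CellImageSets with identical scenario and label levels.
#' @export
setMethod("c", "CellImageSet", function(x, ...) {
  others <- list(...)
  for (o in others) {
    stopifnot(is(o, "CellImageSet"), identical(o@scenario, x@scenario))
    x <- initialize(x,
      images = c(x@images, o@images),
      masks = c(x@masks, o@masks),
      labels = factor(c(as.character(x@labels), as.character(o@labels)),
                      levels = union(levels(x@labels), levels(o@labels))),
      origin = c(x@origin, o@origin),
      sourceIndex = c(x@sourceIndex, o@sourceIndex))
  }
  x
})

#' Augmentation configuration
#'
#' Ranges for the random geometric augmentation: rotation angle in degrees,
#' multiplicative scale factor, and per-axis translation in pixels. The
#' defaults follow the augmentation protocol this package emulates: angles
#' in [-20, 20] degrees, scale factors in [0.1, 1] (shrink only), and
#' translations in [-1, 1] pixels on each axis. Translation units are
#' pixels; this is configurable because published augmentation ranges do
#' not always state the unit.
#'
#' @param rotationRange closed interval of angles (degrees).
#' @param scaleRange closed interval of strictly positive scale factors.
#' @param translationRange closed interval of per-axis offsets (pixels).
#' @param interpolation "bilinear" (default) or "nearest" for pixel
#'   resampling; masks always use nearest.
#' @param fillMode "constant" (default) or "replicate" for out-of-canvas
#'   regions.
#' @param fillValue intensity used with constant fill. The default, 235,
#'   is the bright slide-background intensity of the synthetic renderer:
#'   filling with background avoids inventing tissue where none exists
#'   (stained tissue is dark, the empty slide is bright).
#' @return a list of class "AugmentationConfig".
#' @export
augmentationConfig <- function(rotationRange = c(-20, 20),
                               scaleRange = c(0.1, 1),
                               translationRange = c(-1, 1),
                               interpolation = c("bilinear", "nearest"),
                               fillMode = c("constant", "replicate"),
                               fillValue = 235) {
  interpolation <- match.arg(interpolation)
  fillMode <- match.arg(fillMode)
  stopifnot(length(rotationRange) == 2, rotationRange[1] <= rotationRange[2],
            length(scaleRange) == 2, scaleRange[1] <= scaleRange[2],
            all(scaleRange > 0),
            length(translationRange) == 2,
            translationRange[1] <= translationRange[2])
  structure(list(rotationRange = rotationRange, scaleRange = scaleRange,
                 translationRange = translationRange,
                 interpolation = interpolation, fillMode = fillMode,
                 fillValue = fillValue),
            class = "AugmentationConfig")
}

# Backward-mapping affine resampler on a (row, col) raster.
# Forward model: out = A %*% (in - ctr) + ctr + shift, with ctr the image
# centre ((n+1)/2 in each axis). Out-of-canvas samples are filled per
# fillMode. Bilinear weights are exact at integer sample coordinates, so
# identity transforms reproduce the raster bit-for-bit.
.warp <- function(px, A, shift = c(0, 0),
                  interpolation = "bilinear",
                  fillMode = "constant", fillValue = 0) {
  nr <- nrow(px); nc <- ncol(px)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  Ainv <- solve(A)
  R <- rep(seq_len(nr), times = nc)
  C <- rep(seq_len(nc), each = nr)
  dr <- R - ctr[1] - shift[1]
  dc <- C - ctr[2] - shift[2]
  sr <- Ainv[1, 1] * dr + Ainv[1, 2] * dc + ctr[1]
  sc <- Ainv[2, 1] * dr + Ainv[2, 2] * dc + ctr[2]
  if (fillMode == "replicate") {
    sr <- .clip(sr, 1, nr)
    sc <- .clip(sc, 1, nc)
  }
  fillValue <- as.numeric(fillValue)
  gather <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- rep(fillValue, length(ri))
    v[ok] <- px[cbind(ri[ok], ci[ok])]
    v
  }
  if (interpolation == "nearest") {
    val <- gather(round(sr), round(sc))
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    val <- (1 - fr) * (1 - fc) * gather(r0, c0) +
           (1 - fr) * fc       * gather(r0, c0 + 1) +
           fr       * (1 - fc) * gather(r0 + 1, c0) +
           fr       * fc       * gather(r0 + 1, c0 + 1)
  }
  matrix(val, nr, nc)
}

# rotation by `angle` degrees, counter-clockwise when the raster is
# displayed with row 1 at the top (y axis pointing down)
.rotationMatrix <- function(angle) {
  th <- angle * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
}

# apply one affine transform to every image (bilinear or per-config) and
# jointly to every mask (nearest, FALSE fill), preserving labels/scenario
.transformSet <- function(x, A, shift, cfg) {
  images <- lapply(x@images, .warp, A = A, shift = shift,
                   interpolation = cfg$interpolation,
                   fillMode = cfg$fillMode, fillValue = cfg$fillValue)
  masks <- lapply(x@masks, function(m) {
    if (is.null(m)) return(NULL)
    .warp(m * 1, A, shift, interpolation = "nearest",
          fillMode = "constant", fillValue = 0) > 0.5
  })
  initialize(x, images = images, masks = masks)
}

#' Geometric transforms of a CellImageSet
#'
#' Rotate, scale or translate every raster about the image centre. The
#' output canvas keeps the input height and width; content moved off-canvas
#' is lost and uncovered regions are filled per the configuration. Masks,
#' when present, undergo the identical transform with nearest-neighbour
#' interpolation and remain binary. Labels, scenario and origin are
#' preserved.
#'
#' @param x a \linkS4class{CellImageSet}.
#' @param angle rotation angle in degrees (positive = counter-clockwise in
#'   top-down display).
#' @param factor strictly positive scale factor (< 1 shrinks).
#' @param dx,dy translation in pixels along columns (x) and rows (y, down).
#' @param cfg an \code{\link{augmentationConfig}} controlling interpolation
#'   and fill.
#' @return a transformed \linkS4class{CellImageSet}.
#' @export
rotateImages <- function(x, angle, cfg = augmentationConfig()) {
  stopifnot(is.finite(angle))
  .transformSet(x, .rotationMatrix(angle), c(0, 0), cfg)
}

#' @rdname rotateImages
#' @export
scaleImages <- function(x, factor, cfg = augmentationConfig()) {
  if (!is.finite(factor) || factor <= 0)
    stop("scale factor must be strictly positive")
  .transformSet(x, diag(2) * factor, c(0, 0), cfg)
}

#' @rdname rotateImages
#' @export
translateImages <- function(x, dx, dy, cfg = augmentationConfig()) {
  stopifnot(is.finite(dx), is.finite(dy))
  .transformSet(x, diag(2), c(dy, dx), cfg)
}

#' Draw one set of augmentation parameters
#'
#' Samples an angle, scale factor and per-axis translation uniformly from
#' the configured ranges, using the current RNG stream.
#'
#' @param cfg an \code{\link{augmentationConfig}}.
#' @return list with elements \code{angle}, \code{factor}, \code{dx},
#'   \code{dy}.
#' @export
sampleAugmentation <- function(cfg = augmentationConfig()) {
  list(angle = stats::runif(1, cfg$rotationRange[1], cfg$rotationRange[2]),
       factor = stats::runif(1, cfg$scaleRange[1], cfg$scaleRange[2]),
       dx = stats::runif(1, cfg$translationRange[1], cfg$translationRange[2]),
       dy = stats::runif(1, cfg$translationRange[1], cfg$translationRange[2]))
}

#' Randomly augment images
#'
#' For each image, draws angle ~ U(rotation range), factor ~ U(scale range)
#' and dx, dy ~ U(translation range), then applies rotation, scaling and
#' translation in that order. Masks are transformed jointly. The origin flag
#' of every output image is "augmented". Deterministic given \code{seed};
#' with \code{seed = NULL} the current RNG stream is used.
#'
#' @param x a \linkS4class{CellImageSet}.
#' @param cfg an \code{\link{augmentationConfig}}.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return an augmented \linkS4class{CellImageSet}.
#' @export
randomAugment <- function(x, cfg = augmentationConfig(), seed = NULL) {
  run <- function() {
    out <- x
    for (i in seq_len(length(x))) {
      p <- sampleAugmentation(cfg)
      one <- x[i]
      one <- rotateImages(one, p$angle, cfg)
      one <- scaleImages(one, p$factor, cfg)
      one <- translateImages(one, p$dx, p$dy, cfg)
      out@images[[i]] <- one@images[[1]]
      out@masks[i] <- list(one@masks[[1]])
    }
    out@origin <- rep("augmented", length(x))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Balance a dataset to a fixed per-class count
#'
#' Classes below \code{targetPerClass} keep all originals and are topped up
#' with randomly augmented copies of originals sampled uniformly with
#' replacement; classes above the target are subsampled uniformly without
#' replacement; classes exactly at target pass through unchanged. With the
#' Herlev class counts and a target of 200 this reproduces the published
#' 1400-image balanced design.
#'
#' @param x a \linkS4class{CellImageSet}; every class level must have at
#'   least one member.
#' @param targetPerClass target image count per class (>= 1).
#' @param cfg an \code{\link{augmentationConfig}} for the augmented copies.
#' @param seed integer seed controlling sampling and augmentation draws.
#' @return a \linkS4class{CellImageSet} with exactly \code{targetPerClass}
#'   images in every class.
#' @export
balanceDataset <- function(x, targetPerClass, cfg = augmentationConfig(),
                           seed = 1L) {
  stopifnot(targetPerClass >= 1)
  tab <- table(x@labels)
  if (any(tab == 0))
    stop(sprintf("class '%s' is empty: cannot augment from nothing",
                 names(tab)[which(tab == 0)[1]]))
  keep <- integer(0)
  augIdx <- integer(0)
  withr::with_seed(stageSeed(seed, "balance-sampling"), {
    for (cl in levels(x@labels)) {
      idx <- which(x@labels == cl)
      n <- length(idx)
      if (n >= targetPerClass) {
        keep <- c(keep, if (n == targetPerClass) idx else
                  sort(sample(idx, targetPerClass)))
      } else {
        keep <- c(keep, idx)
        augIdx <- c(augIdx, sample(idx, targetPerClass - n, replace = TRUE))
      }
    }
  })
  out <- x[keep]
  if (length(augIdx)) {
    aug <- randomAugment(x[augIdx], cfg, seed = stageSeed(seed, "balance-augment"))
    out <- c(out, aug)
  }
  out
}

#' Realize a scenario by masking
#'
#' Produces the pixel content for one of the three analysis scenarios:
#' \describe{
#'   \item{whole}{pixels unchanged;}
#'   \item{nucleus_excluded}{mask-interior (nucleus) pixels replaced by
#'     \code{fillValue}, leaving the cytoplasm;}
#'   \item{nucleus_only}{mask-exterior pixels replaced by \code{fillValue},
#'     leaving the nucleus.}
#' }
#' Labels and masks are preserved; the scenario tag of the result records
#' how the pixels were produced. Masked scenarios require a mask on every
#' image.
#'
#' @param x a \linkS4class{CellImageSet}.
#' @param scenario "whole", "nucleus_excluded" or "nucleus_only".
#' @param fillValue intensity written into the removed region.
#' @return a \linkS4class{CellImageSet} with the scenario applied.
#' @export
applyScenario <- function(x, scenario = c("whole", "nucleus_excluded",
                                          "nucleus_only"), fillValue = 0) {
  scenario <- match.arg(scenario)
  if (scenario == "whole") {
    x@scenario <- "whole"
    return(x)
  }
  missing <- vapply(x@masks, is.null, TRUE)
  if (any(missing))
    stop(sprintf("scenario '%s' requires a nucleus mask on every image (%d missing)",
                 scenario, sum(missing)))
  images <- mapply(function(px, m) {
    if (scenario == "nucleus_excluded") px[m] <- fillValue else px[!m] <- fillValue
    px
  }, x@images, x@masks, SIMPLIFY = FALSE)
  initialize(x, images = images, scenario = scenario)
}
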
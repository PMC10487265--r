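#' @include AllClasses.R imageops.R
NULL

.defaultNucleusFractions <- function() {
  c(normal_superficial = 0.04, normal_intermediate = 0.06,
    normal_columnar = 0.09, mild_dysplasia = 0.14, moderate_dysplasia = 0.20,
    severe_dysplasia = 0.27, carcinoma_in_situ = 0.34)
}

.defaultNucleusDarkness <- function() {
  c(normal_superficial = 35, normal_intermediate = 40,
    normal_columnar = 50, mild_dysplasia = 60, moderate_dysplasia = 75,
    severe_dysplasia = 90, carcinoma_in_situ = 105)
}

#' Specification for synthetic cell images
#'
#' Describes a seeded synthetic rendering of the seven-class single-cell
#' layout: each image holds one lighter ellipsoidal cytoplasm with one
#' darker ellipsoidal nucleus on a bright background, plus the ground-truth
#' nucleus mask. The per-class nucleus area fraction and darkness offsets
#' default to a monotone progression over the abnormal grades (mild <
#' moderate < severe < carcinoma), emulating the enlarged, darker nuclei of
#' higher dysplasia grades; the three normal classes get small, mildly
#' dark nuclei.
#'
#' @param countsPerClass named nonnegative integer vector of images per
#'   class (names must be the canonical class names); defaults to the
#'   Herlev class counts.
#' @param imageSize side length in pixels of the square rasters.
#' @param nucleusAreaFraction named vector of nucleus area as a fraction of
#'   total image area, per class, each in (0, 1).
#' @param nucleusDarkness named vector of intensity offsets (0-255 units)
#'   subtracted from the cytoplasm intensity inside the nucleus.
#' @param noiseSd standard deviation of the additive Gaussian pixel noise.
#' @param seed integer master seed; each class draws from an independent
#'   substream so adding a class never shifts another class's images.
#' @return a list of class "SyntheticImageSpec".
#' @export
syntheticImageSpec <- function(countsPerClass = herlevCounts(),
                               imageSize = 64L,
                               nucleusAreaFraction = .defaultNucleusFractions(),
                               nucleusDarkness = .defaultNucleusDarkness(),
                               noiseSd = 8,
                               seed = 1L) {
  if (length(countsPerClass) == 0) stop("countsPerClass must not be empty")
  if (is.null(names(countsPerClass)))
    stop("countsPerClass must be named by class")
  if (any(countsPerClass < 0)) stop("counts must be nonnegative")
  if (imageSize < 16) stop("imageSize must be at least 16 pixels")
  cls <- names(countsPerClass)
  if (!all(cls %in% names(nucleusAreaFraction)) ||
      !all(cls %in% names(nucleusDarkness)))
    stop("nucleusAreaFraction and nucleusDarkness must cover every class")
  fr <- nucleusAreaFraction[cls]
  if (any(fr <= 0 | fr >= 1))
    stop("nucleus area fractions must lie in (0, 1)")
  stopifnot(noiseSd >= 0)
  structure(list(countsPerClass = countsPerClass,
                 imageSize = as.integer(imageSize),
                 nucleusAreaFraction = nucleusAreaFraction,
                 nucleusDarkness = nucleusDarkness,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "SyntheticImageSpec")
}

# pixel-centre test of a rotated ellipse; returns a logical matrix
.ellipseMask <- function(size, centre, a, b, theta) {
  R <- rep(seq_len(size), times = size)
  C <- rep(seq_len(size), each = size)
  dr <- R - centre[1]; dc <- C - centre[2]
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  matrix((u / a)^2 + (v / b)^2 <= 1, size, size)
}

#' Simulate labelled cell images with nucleus masks
#'
#' Renders seeded single-channel 8-bit images per the specification: a
#' bright background (intensity ~235), a lighter cytoplasm ellipse
#' (~180), and one darker nucleus ellipse whose area fraction and darkness
#' are set per class, with additive Gaussian noise clipped to [0, 255].
#' Each image carries a ground-truth nucleus mask consisting of exactly one
#' connected (elliptical) region. Identical specifications produce
#' bit-identical rasters.
#'
#' @param spec a \code{\link{syntheticImageSpec}}.
#' @return a \linkS4class{CellImageSet} with scenario "whole" and one mask
#'   per image.
#' @export
#' @examples
#' spec <- syntheticImageSpec(countsPerClass = c(mild_dysplasia = 2,
#'                                               carcinoma_in_situ = 2),
#'                            imageSize = 32, seed = 7)
#' simulateCellImages(spec)
simulateCellImages <- function(spec) {
  stopifnot(inherits(spec, "SyntheticImageSpec"))
  s <- spec$imageSize
  images <- list(); masks <- list(); labels <- character(0)
  for (cl in names(spec$countsPerClass)) {
    n <- spec$countsPerClass[[cl]]
    if (n == 0) next
    frac <- spec$nucleusAreaFraction[[cl]]
    dark <- spec$nucleusDarkness[[cl]]
    withr::with_seed(stageSeed(spec$seed, paste0("class:", cl)), {
      for (i in seq_len(n)) {
        cytCentre <- (s + 1) / 2 + stats::runif(2, -0.03, 0.03) * s
        cytA <- s * 0.46 * stats::runif(1, 0.92, 1)
        cytB <- cytA * stats::runif(1, 0.82, 1)
        cytTheta <- stats::runif(1, 0, pi)
        cytInt <- 180 + stats::runif(1, -10, 10)

        area <- frac * s^2
        q <- stats::runif(1, 1, 1.25)
        nucB <- sqrt(area / (pi * q))
        nucA <- q * nucB
        nucCentre <- cytCentre + stats::runif(2, -0.03, 0.03) * s
        nucTheta <- stats::runif(1, 0, pi)

        cyt <- .ellipseMask(s, cytCentre, cytA, cytB, cytTheta)
        nuc <- .ellipseMask(s, nucCentre, nucA, nucB, nucTheta)

        px <- matrix(235, s, s)
        px[cyt] <- cytInt
        px[nuc] <- cytInt - dark
        px <- px + stats::rnorm(s * s, sd = spec$noiseSd)
        px <- round(.clip(px, 0, 255))
        storage.mode(px) <- "integer"
        images[[length(images) + 1L]] <- px
        masks[[length(masks) + 1L]] <- nuc
        labels <- c(labels, cl)
      }
    })
  }
  CellImageSet(images,
               factor(labels, levels = names(spec$countsPerClass)),
               masks = masks, scenario = "whole", origin = "original")
}
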
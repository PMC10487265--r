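test_that("image generator produces the requested counts with single-component masks", {
  counts <- stats::setNames(rep(10L, 7), herlevClasses()$name)
  spec <- syntheticImageSpec(countsPerClass = counts, imageSize = 32, seed = 7)
  imgs <- simulateCellImages(spec)

  expect_s4_class(imgs, "CellImageSet")
  expect_length(imgs, 70)
  expect_equal(unname(table(cellLabels(imgs))), rep(10L, 7),
               ignore_attr = TRUE)
  expect_true(all(!vapply(cellMasks(imgs), is.null, TRUE)))

  # every mask is one connected elliptical region (checked on a subset by
  # an independent flood fill)
  for (i in c(1, 15, 40, 70))
    expect_equal(nComponents(cellMasks(imgs)[[i]]), 1L)

  # pixel values are 8-bit
  rngs <- range(unlist(lapply(cellImages(imgs), range)))
  expect_gte(rngs[1], 0)
  expect_lte(rngs[2], 255)
})

test_that("image generation is bit-identical under a fixed seed", {
  counts <- stats::setNames(rep(3L, 7), herlevClasses()$name)
  spec <- syntheticImageSpec(countsPerClass = counts, imageSize = 32, seed = 42)
  a <- simulateCellImages(spec)
  b <- simulateCellImages(spec)
  expect_identical(cellImages(a), cellImages(b))
  expect_identical(cellMasks(a), cellMasks(b))

  # adding a class must not shift existing classes' substreams
  counts2 <- counts
  counts2["normal_superficial"] <- 5L
  c_ <- simulateCellImages(syntheticImageSpec(countsPerClass = counts2,
                                              imageSize = 32, seed = 42))
  idxB <- which(cellLabels(b) == "normal_columnar")
  idxC <- which(cellLabels(c_) == "normal_columnar")
  expect_identical(cellImages(b)[idxB], cellImages(c_)[idxC])
})

test_that("the full Herlev class distribution renders 917 images", {
  spec <- syntheticImageSpec(imageSize = 32, seed = 1)
  imgs <- simulateCellImages(spec)
  expect_length(imgs, 917)
  expect_equal(as.integer(table(cellLabels(imgs))),
               unname(herlevCounts()))
})

test_that("mask area tracks the requested per-class fraction within 10%", {
  counts <- stats::setNames(rep(8L, 7), herlevClasses()$name)
  spec <- syntheticImageSpec(countsPerClass = counts, imageSize = 64, seed = 3)
  imgs <- simulateCellImages(spec)
  fr <- spec$nucleusAreaFraction[as.character(cellLabels(imgs))]
  got <- vapply(cellMasks(imgs), mean, numeric(1))
  expect_true(all(abs(got - fr) / fr <= 0.10))

  # nucleus area fraction grows monotonically with dysplasia grade
  means <- tapply(got, cellLabels(imgs), mean)
  grades <- c("mild_dysplasia", "moderate_dysplasia", "severe_dysplasia",
              "carcinoma_in_situ")
  expect_true(all(diff(means[grades]) > 0))
})

test_that("invalid image specifications are rejected", {
  expect_error(syntheticImageSpec(countsPerClass = integer(0)), "empty")
  expect_error(syntheticImageSpec(imageSize = 0), "at least")
  expect_error(syntheticImageSpec(countsPerClass = c(normal_superficial = -1L)),
               "nonnegative")
  bad <- stats::setNames(rep(1.2, 7), herlevClasses()$name)
  expect_error(syntheticImageSpec(nucleusAreaFraction = bad), "\\(0, 1\\)")
})

test_that("feature tables plant separable signal and are seed-stable", {
  # no signal: a linear classifier sits at chance
  ft0 <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 30,
                                                   classSeparation = 0,
                                                   seed = 9))
  expect_lt(abs(linearCvAccuracy(ft0) - 1 / 7), 0.08)

  # strong planted signal: high accuracy
  ft4 <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 50,
                                                   nInformative = 3,
                                                   nNoise = 7,
                                                   classSeparation = 4,
                                                   seed = 9))
  expect_equal(dim(featureMatrix(ft4)), c(350L, 10L))
  expect_gt(linearCvAccuracy(ft4), 0.95)

  # determinism
  ft4b <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 50,
                                                    nInformative = 3,
                                                    nNoise = 7,
                                                    classSeparation = 4,
                                                    seed = 9))
  expect_identical(featureMatrix(ft4), featureMatrix(ft4b))

  # rejection: positive separation with no informative columns
  expect_error(syntheticFeatureSpec(nInformative = 0, classSeparation = 2),
               "informative")
})

test_that("downstream accuracy is monotone non-decreasing in class separation", {
  accs <- vapply(c(0, 1, 2, 4), function(sep) {
    ft <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 30,
                                                    classSeparation = sep,
                                                    seed = 5))
    linearCvAccuracy(ft, seed = 5)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})
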
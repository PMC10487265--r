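test_that("scenario masking replaces exactly the intended region", {
  imgs <- tinyImageSet(nPerClass = 1, size = 10, maskFraction = 0.25)
  px <- cellImages(imgs)[[1]]
  m <- cellMasks(imgs)[[1]]

  excl <- applyScenario(imgs, "nucleus_excluded", fillValue = 7)
  out <- cellImages(excl)[[1]]
  expect_identical(imageScenario(excl), "nucleus_excluded")
  expect_true(all(out[m] == 7))
  expect_identical(out[!m], px[!m])
  expect_equal(sum(out == 7), sum(m) + sum(px[!m] == 7))

  only <- applyScenario(imgs, "nucleus_only", fillValue = 7)
  out2 <- cellImages(only)[[1]]
  expect_true(all(out2[!m] == 7))
  expect_identical(out2[m], px[m])

  whole <- applyScenario(imgs, "whole")
  expect_identical(cellImages(whole)[[1]], px)
  expect_identical(cellLabels(excl), cellLabels(imgs))
})

test_that("degenerate masks make masked scenarios no-ops", {
  imgs <- tinyImageSet(nPerClass = 1, size = 6)
  px <- cellImages(imgs)[[1]]

  zeroMask <- CellImageSet(list(px), "a",
                           masks = list(matrix(FALSE, 6, 6)))
  expect_equal(cellImages(applyScenario(zeroMask, "nucleus_excluded"))[[1]], px)

  fullMask <- CellImageSet(list(px), "a",
                           masks = list(matrix(TRUE, 6, 6)))
  expect_equal(cellImages(applyScenario(fullMask, "nucleus_only"))[[1]], px)

  noMask <- CellImageSet(list(px), "a")
  expect_error(applyScenario(noMask, "nucleus_excluded"), "mask")
})

test_that("identity transforms reproduce the raster exactly", {
  imgs <- tinyImageSet(nPerClass = 1, size = 9, maskFraction = 0.2)
  px <- cellImages(imgs)[[1]]
  expect_equal(cellImages(rotateImages(imgs, 0))[[1]], px, ignore_attr = TRUE)
  expect_equal(cellImages(translateImages(imgs, 0, 0))[[1]], px,
               ignore_attr = TRUE)
  expect_equal(cellImages(scaleImages(imgs, 1))[[1]], px, ignore_attr = TRUE)
  expect_error(scaleImages(imgs, 0), "positive")
  expect_error(scaleImages(imgs, -2), "positive")
})

test_that("rotation maps a one-hot pixel to its analytic coordinate", {
  # hot pixel at (3, 2) in a 9x9 raster, centre (5, 5); a 90-degree
  # counter-clockwise rotation (top-down display) maps (r, c) to
  # (cr - (c - cc), cc + (r - cr)) = (8, 3)
  px <- matrix(0, 9, 9); px[3, 2] <- 255
  s <- CellImageSet(list(px), "a")
  cfg <- augmentationConfig(fillValue = 0)
  rot <- cellImages(rotateImages(s, 90, cfg))[[1]]
  expect_equal(which(rot > 128, arr.ind = TRUE)[1, ], c(row = 8, col = 3))
  expect_equal(sum(rot > 128), 1)

  # translation: dx shifts columns, dy shifts rows
  tr <- cellImages(translateImages(s, dx = 2, dy = 1, cfg))[[1]]
  expect_equal(which(tr > 128, arr.ind = TRUE)[1, ], c(row = 4, col = 4))
})

test_that("masks transform jointly, staying binary and aligned", {
  imgs <- tinyImageSet(nPerClass = 1, size = 16, maskFraction = 0.25)
  rot <- rotateImages(imgs, 33)
  m <- cellMasks(rot)[[1]]
  expect_type(m, "logical")
  expect_identical(dim(m), dim(cellImages(rot)[[1]]))
  # mask area approximately preserved by rotation (nearest resampling of
  # a blocky region can shift a few boundary pixels)
  expect_lt(abs(sum(m) - sum(cellMasks(imgs)[[1]])) / sum(cellMasks(imgs)[[1]]),
            0.25)

  # scenario and labels survive augmentation
  aug <- randomAugment(imgs, seed = 4)
  expect_identical(cellLabels(aug), cellLabels(imgs))
  expect_identical(imageScenario(aug), imageScenario(imgs))
  expect_true(all(imageOrigin(aug) == "augmented"))
})

test_that("augmentation draws stay inside the configured ranges", {
  cfg <- augmentationConfig()
  draws <- withr::with_seed(1, replicate(1000, sampleAugmentation(cfg),
                                         simplify = FALSE))
  angles <- vapply(draws, `[[`, numeric(1), "angle")
  factors <- vapply(draws, `[[`, numeric(1), "factor")
  dxs <- vapply(draws, `[[`, numeric(1), "dx")
  expect_true(all(angles >= -20 & angles <= 20))
  expect_true(all(factors >= 0.1 & factors <= 1))
  expect_true(all(dxs >= -1 & dxs <= 1))

  # collapsed ranges give the identity transform
  idCfg <- augmentationConfig(rotationRange = c(0, 0), scaleRange = c(1, 1),
                              translationRange = c(0, 0))
  imgs <- tinyImageSet(nPerClass = 1, size = 8)
  out <- randomAugment(imgs, idCfg, seed = 3)
  expect_equal(cellImages(out)[[1]], cellImages(imgs)[[1]],
               ignore_attr = TRUE)

  # determinism under a fixed seed
  a <- randomAugment(imgs, cfg, seed = 11)
  b <- randomAugment(imgs, cfg, seed = 11)
  expect_identical(cellImages(a), cellImages(b))
})

test_that("balancing reaches the target count per class from the Herlev distribution", {
  counts <- herlevCounts()
  images <- list(); labels <- character(0)
  withr::with_seed(2, {
    for (cl in names(counts)) {
      images <- c(images, replicate(counts[[cl]],
        matrix(round(runif(64, 0, 255)), 8, 8), simplify = FALSE))
      labels <- c(labels, rep(cl, counts[[cl]]))
    }
  })
  imgs <- CellImageSet(images, factor(labels, levels = names(counts)))
  bal <- balanceDataset(imgs, 200L, seed = 1)
  expect_length(bal, 1400)
  expect_true(all(table(cellLabels(bal)) == 200L))
})

test_that("balancing keeps originals, augments deficits and subsamples surpluses", {
  imgs <- tinyImageSet(nPerClass = 3, classes = c("a", "b"), size = 8)
  # class at target: unchanged, no augmented members
  bal3 <- balanceDataset(imgs, 3L, seed = 1)
  expect_true(all(imageOrigin(bal3) == "original"))
  expect_length(bal3, 6)

  # deficit: 3 originals + 2 augmented copies per class
  bal5 <- balanceDataset(imgs, 5L, seed = 1)
  expect_true(all(table(cellLabels(bal5)) == 5L))
  for (cl in c("a", "b")) {
    ori <- imageOrigin(bal5)[cellLabels(bal5) == cl]
    expect_equal(sum(ori == "original"), 3)
    expect_equal(sum(ori == "augmented"), 2)
  }
  # all originals retained
  origPx <- cellImages(imgs)
  keptPx <- cellImages(bal5)[imageOrigin(bal5) == "original"]
  expect_true(all(vapply(origPx, function(p)
    any(vapply(keptPx, identical, TRUE, p)), TRUE)))

  # surplus: subsampled without replacement
  bal2 <- balanceDataset(imgs, 2L, seed = 1)
  expect_true(all(table(cellLabels(bal2)) == 2L))
  expect_true(all(imageOrigin(bal2) == "original"))

  # empty class is an explicit error
  lv <- factor(rep("a", 3), levels = c("a", "ghost"))
  empty <- CellImageSet(cellImages(imgs)[1:3], lv)
  expect_error(balanceDataset(empty, 2L), "empty")
})
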
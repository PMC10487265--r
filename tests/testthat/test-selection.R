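test_that("the decomposition matches the analytic 2x2 eigensolution", {
  withr::with_seed(8, {
    x <- cbind(rnorm(200, sd = sqrt(10)), rnorm(200, sd = 1))
  })
  model <- fitPca(x)

  # closed-form eigenvalues of the sample covariance, computed directly
  S <- stats::cov(x)
  a <- S[1, 1]; b <- S[1, 2]; c_ <- S[2, 2]
  disc <- sqrt((a - c_)^2 + 4 * b^2)
  lambda <- c((a + c_ + disc) / 2, (a + c_ - disc) / 2)
  expect_equal(explainedVariance(model), lambda / sum(lambda),
               tolerance = 1e-10)

  # first component aligned with the high-variance column
  expect_gt(abs(model@rotation[1, 1]), 0.99)
  expect_lt(abs(model@rotation[2, 1]), 0.15)

  expect_error(fitPca(x[1, , drop = FALSE]), "at least 2")
})

test_that("duplicated columns share first-component weight equally", {
  withr::with_seed(2, z <- rnorm(100))
  model <- fitPca(cbind(z, z))
  expect_equal(abs(model@rotation[1, 1]), abs(model@rotation[2, 1]),
               tolerance = 1e-10)
  expect_equal(abs(model@rotation[1, 1]), 1 / sqrt(2), tolerance = 1e-10)
  # ratios sum to one and are non-increasing
  evr <- explainedVariance(model)
  expect_equal(sum(evr), 1, tolerance = 1e-10)
  expect_true(all(diff(evr) <= 1e-12))
})

test_that("importance scores equal the variance-weighted absolute loadings", {
  withr::with_seed(5, {
    x <- matrix(rnorm(60 * 3), 60, 3) %*%
      matrix(c(2, 0.5, 0, 0, 1, 0.3, 0, 0, 0.7), 3, 3)
  })
  model <- fitPca(x)
  scores <- scoreVariables(model)

  # independent oracle: eigendecomposition of the covariance via eigen()
  e <- eigen(stats::cov(x), symmetric = TRUE)
  evr <- e$values / sum(e$values)
  expected <- drop(abs(e$vectors) %*% evr)
  expect_equal(unname(scores), expected, tolerance = 1e-8)
  expect_true(all(scores >= 0))

  # sign flips of whole components leave the scores unchanged
  flipped <- model
  flipped@rotation[, 1] <- -flipped@rotation[, 1]
  expect_equal(scoreVariables(flipped), scores)

  # a variable with zero loading everywhere scores zero; with a single
  # component the ranking equals the |coefficient| ranking
  single <- new("PcaModel",
                rotation = matrix(c(0.8, 0, 0.6), 3, 1),
                explainedVarianceRatio = 1,
                center = rep(0, 3), scale = rep(1, 3))
  s1 <- scoreVariables(single)
  expect_equal(s1[2], 0)
  expect_equal(order(-s1), order(-abs(single@rotation[, 1])))
})

test_that("top-k selection is ordered, tie-stable and provenance-aware", {
  scores <- c(0.5, 0.9, 0.1, 0.9, 0.3)
  sel <- selectTop(scores, 3, provenance = c("a", "a", "b", "b", "b"))
  # ties broken by lower column index: 2 before 4
  expect_equal(selectedIndices(sel), c(2L, 4L, 1L))
  expect_equal(provenanceCounts(sel), c(a = 2L, b = 1L))

  # k = d keeps everything; equal scores give the first k indices
  expect_equal(selectedIndices(selectTop(scores, 5)), c(2L, 4L, 1L, 5L, 3L))
  expect_equal(selectedIndices(selectTop(rep(1, 5), 3)), 1:3)
  expect_error(selectTop(scores, 0), "k must be")
  expect_error(selectTop(scores, 6), "k must be")
})

test_that("21 candidate features reduce to 10 with provenance counts", {
  imgs <- smallSyntheticImages(nPerClass = 4, imageSize = 32)
  specs <- lapply(c("mock-alexnet", "mock-darknet19", "mock-nasnet"),
                  extractorSpec, inputSize = c(32, 32))
  full <- concatFeatures(lapply(specs, function(sp) extractFeatures(imgs, sp)))
  sel <- selectFeatures(full, k = 10)
  expect_length(selectedIndices(sel), 10L)
  expect_equal(sum(provenanceCounts(sel)), 10L)
  expect_length(importanceScores(sel), 21L)
})

test_that("planted informative columns outrank noise columns across seeds", {
  hits <- vapply(1:10, function(s) {
    ft <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 30,
                                                    nInformative = 3,
                                                    nNoise = 7,
                                                    classSeparation = 4,
                                                    seed = 100 + s))
    scores <- scoreVariables(fitPca(ft))
    all(rank(-scores)[1:3] <= 3)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("a negligible-variance noise column never displaces a selected column", {
  for (s in 1:5) {
    ft <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 20,
                                                    nInformative = 3,
                                                    nNoise = 4,
                                                    classSeparation = 4,
                                                    seed = 200 + s))
    x <- featureMatrix(ft)
    before <- selectedIndices(selectTop(scoreVariables(fitPca(x)), 3))
    withr::with_seed(s, tiny <- rnorm(nrow(x), sd = 1e-6))
    after <- selectedIndices(selectTop(scoreVariables(fitPca(cbind(x, tiny))), 3))
    expect_setequal(before, after)
  }
})
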
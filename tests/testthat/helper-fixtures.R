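# shared fixture builders; all generation is in-code and seeded

# a tiny balanced image set built directly from matrices (no rendering),
# optionally with rectangular nucleus masks of the given area fraction
tinyImageSet <- function(nPerClass = 2, classes = c("a", "b"), size = 8,
                         maskFraction = NULL, seed = 1) {
  withr::with_seed(seed, {
    n <- nPerClass * length(classes)
    images <- replicate(n, matrix(round(runif(size * size, 0, 255)),
                                  size, size), simplify = FALSE)
    masks <- NULL
    if (!is.null(maskFraction)) {
      side <- max(1, round(size * sqrt(maskFraction)))
      masks <- replicate(n, {
        m <- matrix(FALSE, size, size)
        m[seq_len(side), seq_len(side)] <- TRUE
        m
      }, simplify = FALSE)
    }
    CellImageSet(images, rep(classes, each = nPerClass), masks = masks)
  })
}

# small rendered synthetic set over all seven classes
smallSyntheticImages <- function(nPerClass = 6, imageSize = 48, seed = 11) {
  counts <- stats::setNames(rep(as.integer(nPerClass), 7),
                            herlevClasses()$name)
  simulateCellImages(syntheticImageSpec(countsPerClass = counts,
                                        imageSize = imageSize, seed = seed))
}

# cross-validated accuracy of a linear SVM, used as an independent check
# of planted signal strength (not the package's classification path)
linearCvAccuracy <- function(ft, k = 3, seed = 5) {
  x <- featureMatrix(ft)
  y <- cellLabels(ft)
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  accs <- vapply(seq_len(k), function(kk) {
    tr <- folds != kk
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear")
    mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(accs)
}

# number of connected components (4-connectivity) of a logical mask;
# plain flood fill, independent of the package's rendering code
nComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      comp <- comp + 1L
      queue <- list(c(i, j))
      lab[i, j] <- comp
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- comp
            queue <- c(queue, list(q))
          }
        }
      }
    }
  }
  comp
}
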
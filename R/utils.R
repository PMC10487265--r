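#' @include AllClasses.R
NULL

#' Derive a reproducible per-stage seed from a master seed
#'
#' Pipeline stages (augmentation, extraction, fold assignment, optimization)
#' draw their own seeds from one master seed, so that changing one stage's
#' name or adding a stage never shifts another stage's random stream. The
#' result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer in [0, 2^31 - 2].
#' @export
#' @examples
#' stageSeed(42, "augment")
stageSeed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  code <- utf8ToInt(paste(stage, collapse = "/"))
  h <- sum(code * seq_along(code) * 131)
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483629)
}

# clamp numeric values into [lo, hi]
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stratified fold assignment: shuffles within each class and deals fold ids
# round-robin, so every class is spread as evenly as possible across folds.
# With `groups`, assignment is made over groups (e.g. source cells) and
# every member of a group — such as an augmented copy of an original —
# shares its group's fold, preventing augmented train/test leakage.
makeStratifiedFolds <- function(labels, k, seed, groups = NULL) {
  labels <- as.factor(labels)
  if (is.null(groups)) {
    tab <- table(labels)
    if (any(tab < k))
      stop(sprintf("class '%s' has %d member(s); need at least k = %d for stratified folds",
                   names(tab)[which.min(tab)], min(tab), k))
    folds <- integer(length(labels))
    withr::with_seed(seed, {
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    })
    return(folds)
  }
  stopifnot(length(groups) == length(labels))
  first <- !duplicated(groups)
  groupFolds <- makeStratifiedFolds(labels[first], k, seed)
  groupFolds[match(groups, groups[first])]
}

# per-fold column standardization fitted on the training part only;
# zero-variance columns are left unscaled (divide by 1)
.foldScaleSplit <- function(x, labels, folds) {
  lapply(sort(unique(folds)), function(kk) {
    tr <- folds != kk
    mu <- colMeans(x[tr, , drop = FALSE])
    sd_ <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    list(
      fold = kk,
      train = sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sd_, "/"),
      trainLabels = labels[tr],
      test = sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sd_, "/"),
      testLabels = labels[!tr],
      testIdx = which(!tr)
    )
  })
}
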
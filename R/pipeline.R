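#' @include AllClasses.R imageops.R features.R selection.R weighting.R optimizers.R classify.R metrics.R
NULL

#' Pipeline configuration
#'
#' Bundles every stage's settings for one end-to-end run: data source,
#' scenario, augmentation/balancing, extractors, selection size, weighting
#' optimizer, classifier and cross-validation. A single master seed spawns
#' deterministic per-stage seeds, so the whole run is reproducible with the
#' mock extractors.
#'
#' @param images a \linkS4class{CellImageSet}, or NULL to simulate from
#'   \code{imageSpec}.
#' @param imageSpec a \code{\link{syntheticImageSpec}} used when
#'   \code{images} is NULL.
#' @param scenario "whole", "nucleus_excluded" or "nucleus_only".
#' @param targetPerClass balanced per-class image count (default 200, the
#'   published design); NULL skips balancing.
#' @param augmentation an \code{\link{augmentationConfig}}.
#' @param extractors list of \code{\link{extractorSpec}}s (default: the
#'   three canonical mock extractors, giving 21 features).
#' @param selectK number of features kept by PCA selection (default 10).
#' @param optimizer "alo", "pso" or "none" (all-ones weights).
#' @param optimizerControl an \code{\link{optimControl}}.
#' @param classifier a \code{\link{classifierSpec}} used for the final
#'   cross-validated evaluation and for the weighting fitness.
#' @param cvFolds folds for both the fitness evaluator and the final
#'   evaluation (default 5).
#' @param augmentWithinFolds when TRUE, fold assignment is grouped by
#'   source cell, so augmented copies of one original never straddle a
#'   train/test split. Default FALSE: the emulated protocol augments
#'   before fold splitting (which inflates absolute accuracies; the
#'   weighted-vs-baseline comparison is unaffected since both sides share
#'   folds).
#' @param scenarioFill intensity written into masked-out regions.
#' @param seed master seed.
#' @return a list of class "PipelineConfig".
#' @export
pipelineConfig <- function(images = NULL, imageSpec = NULL,
                           scenario = "whole", targetPerClass = 200L,
                           augmentation = augmentationConfig(),
                           extractors = mockExtractors(),
                           selectK = 10L,
                           optimizer = c("alo", "pso", "none"),
                           optimizerControl = optimControl(),
                           classifier = classifierSpec("svm_poly"),
                           cvFolds = 5L,
                           augmentWithinFolds = FALSE,
                           scenarioFill = 0,
                           seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (is.null(images) && is.null(imageSpec))
    stop("provide either images or an imageSpec")
  structure(list(images = images, imageSpec = imageSpec,
                 scenario = scenario, targetPerClass = targetPerClass,
                 augmentation = augmentation, extractors = extractors,
                 selectK = as.integer(selectK), optimizer = optimizer,
                 optimizerControl = optimizerControl,
                 classifier = classifier, cvFolds = as.integer(cvFolds),
                 augmentWithinFolds = isTRUE(augmentWithinFolds),
                 scenarioFill = scenarioFill, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full weighting pipeline
#'
#' Executes the end-to-end workflow: obtain images (given or simulated),
#' realize the scenario by masking, balance classes by augmentation,
#' extract and concatenate the per-extractor 7-feature blocks, select the
#' top-k features by PCA loading magnitude, learn per-feature weights by
#' maximizing frozen-fold classifier accuracy (ALO or PSO; "none" uses
#' all-ones weights), then evaluate the weighted features with pooled
#' out-of-fold predictions and the confusion-matrix metric suite.
#'
#' The all-ones weight vector is injected into the optimizer's initial
#' population, so the optimized frozen-fold fitness can never fall below
#' the unweighted baseline on the same folds. Both fitnesses are reported.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return a list of class "RunReport": images/balanced counts, the
#'   feature table, selection result, optimization result (or NULL),
#'   baseline and weighted fitness, predictions, confusion matrix and
#'   metrics report, plus the config echo.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- config$seed
  images <- config$images
  if (is.null(images))
    images <- stage("simulate", simulateCellImages(config$imageSpec))

  images <- stage("scenario",
                  applyScenario(images, config$scenario,
                                fillValue = config$scenarioFill))
  if (!is.null(config$targetPerClass)) {
    images <- stage("balance",
                    balanceDataset(images, config$targetPerClass,
                                   config$augmentation,
                                   seed = stageSeed(seed, "augment")))
  }

  full <- stage("extract", concatFeatures(
    lapply(config$extractors, function(sp) extractFeatures(images, sp))))

  sel <- stage("select", selectFeatures(full, k = config$selectK))
  selected <- full[selectedIndices(sel), ]

  groups <- if (config$augmentWithinFolds) sourceIndex(images) else NULL
  ev <- stage("fitness", fitnessEvaluator(selected,
                                          classifier = config$classifier,
                                          k = config$cvFolds,
                                          seed = stageSeed(seed, "fitness"),
                                          groups = groups))
  d <- length(selectedIndices(sel))
  baseline <- evaluateFitness(rep(1, d), ev)

  opt <- NULL
  weights <- rep(1, d)
  if (config$optimizer != "none") {
    optFun <- if (config$optimizer == "alo") aloOptimize else psoOptimize
    opt <- stage("weight", optFun(ev, control = config$optimizerControl,
                                  seed = stageSeed(seed, "optimizer"),
                                  init = rep(1, d)))
    weights <- bestWeights(opt)
  }

  weighted <- applyWeights(selected, weights)
  predictions <- stage("classify",
                       kfoldPredict(weighted, spec = config$classifier,
                                    k = config$cvFolds,
                                    seed = stageSeed(seed, "final-cv"),
                                    groups = groups))
  cm <- confusionCounts(predictions$trueLabel, predictions$predictedLabel,
                        classOrder = levels(predictions$trueLabel))
  report <- metricsReport(cm)

  structure(list(
    config = config,
    nImages = length(images),
    classCounts = table(cellLabels(images)),
    featureTable = full,
    selection = sel,
    optimization = opt,
    weights = weights,
    baselineFitness = baseline,
    weightedFitness = if (is.null(opt)) baseline else bestFitness(opt),
    predictions = predictions,
    confusion = cm,
    metrics = report
  ), class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport: scenario '%s', optimizer '%s', classifier '%s'\n",
              x$config$scenario, x$config$optimizer, x$config$classifier$kind))
  cat(sprintf("  images: %d; features: %d -> %d selected\n",
              x$nImages, nrow(x$featureTable),
              length(selectedIndices(x$selection))))
  cat(sprintf("  frozen-fold fitness: baseline %.4f, weighted %.4f\n",
              x$baselineFitness, x$weightedFitness))
  cat(sprintf("  out-of-fold accuracy: %.1f%%\n", 100 * x$metrics@accuracy))
  invisible(x)
}

#' Compare scenarios, optimizers and classifiers
#'
#' Runs the pipeline once per combination of the requested scenarios,
#' optimizers and classifiers, holding everything else (including the
#' master seed, and hence the augmentation draws) fixed, and tabulates the
#' results.
#'
#' @param config a base \code{\link{pipelineConfig}}.
#' @param scenarios,optimizers,classifiers character vectors of settings to
#'   cross; defaults take the single setting from \code{config}.
#' @return data.frame with one row per run: scenario, optimizer,
#'   classifier, accuracy, misclassification rate, baseline and weighted
#'   fitness, and the minimum per-class sensitivity.
#' @export
compareScenarios <- function(config, scenarios = config$scenario,
                             optimizers = config$optimizer,
                             classifiers = config$classifier$kind) {
  grid <- expand.grid(scenario = scenarios, optimizer = optimizers,
                      classifier = classifiers,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$scenario <- grid$scenario[i]
    cfg$optimizer <- grid$optimizer[i]
    cfg$classifier$kind <- grid$classifier[i]
    rep_ <- runPipeline(cfg)
    data.frame(scenario = grid$scenario[i], optimizer = grid$optimizer[i],
               classifier = grid$classifier[i],
               accuracy = rep_$metrics@accuracy,
               misclassification = rep_$metrics@misclassificationRate,
               baselineFitness = rep_$baselineFitness,
               weightedFitness = rep_$weightedFitness,
               minSensitivity = min(rep_$metrics@perClass$sensitivity,
                                    na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
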
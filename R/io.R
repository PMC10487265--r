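#' @include AllClasses.R imageops.R features.R selection.R optimizers.R metrics.R
NULL

#' Write a CellImageSet as directory-per-class PNGs
#'
#' Writes 8-bit grayscale PNGs under \code{dir/<class>/}, nucleus masks
#' (0 background, 255 nucleus) under sibling \code{dir/<class>/masks/},
#' and a \code{manifest.csv} with columns path, label, has_mask, origin.
#'
#' @param x a \linkS4class{CellImageSet}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
writeImageSet <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(length(x)), function(i) {
    cl <- as.character(x@labels[i])
    clDir <- file.path(dir, cl)
    dir.create(clDir, showWarnings = FALSE)
    path <- file.path(clDir, sprintf("img%04d.png", i))
    png::writePNG(x@images[[i]] / 255, path)
    hasMask <- !is.null(x@masks[[i]])
    if (hasMask) {
      mDir <- file.path(clDir, "masks")
      dir.create(mDir, showWarnings = FALSE)
      png::writePNG(x@masks[[i]] * 1, file.path(mDir, sprintf("img%04d.png", i)))
    }
    data.frame(path = path, label = cl, has_mask = hasMask,
               origin = x@origin[i], stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a CellImageSet written by writeImageSet
#'
#' @param dir directory containing \code{manifest.csv}.
#' @return a \linkS4class{CellImageSet} (scenario "whole").
#' @export
readImageSet <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) {
    px <- round(png::readPNG(p) * 255)
    storage.mode(px) <- "integer"
    px
  })
  masks <- lapply(seq_len(nrow(manifest)), function(i) {
    if (!manifest$has_mask[i]) return(NULL)
    p <- file.path(dirname(manifest$path[i]), "masks", basename(manifest$path[i]))
    png::readPNG(p) > 0.5
  })
  CellImageSet(images, manifest$label, masks = masks,
               origin = manifest$origin)
}

#' Write/read a FeatureTable as CSV with provenance sidecar
#'
#' The CSV holds sample_id, label and one column per feature (named
#' extractor_fN); the sidecar JSON records each column's extractor and
#' feature index. The reader validates the 7-features-per-extractor
#' contract for extractor-derived tables when \code{checkContract} is TRUE.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param path CSV path; the sidecar is written at \code{path} with
#'   extension ".json".
#' @return invisibly, \code{path}.
#' @export
writeFeatureCSV <- function(x, path) {
  df <- data.frame(sample_id = as.character(sampleIds(x)),
                   label = as.character(cellLabels(x)),
                   featureMatrix(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  prov <- featureProvenance(x)
  jsonlite::write_json(list(extractor = prov$extractor,
                            featureIndex = prov$featureIndex),
                       sub("\\.csv$", ".json", path))
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @param checkContract validate that every extractor contributes exactly
#'   7 features.
#' @export
readFeatureCSV <- function(path, checkContract = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  prov <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  if (checkContract) {
    perExtractor <- table(prov$extractor)
    if (any(perExtractor != 7L))
      stop("feature file violates the 7-features-per-extractor contract")
  }
  FeatureTable(values, extractor = prov$extractor,
               featureIndex = prov$featureIndex, labels = df$label,
               sampleIds = df$sample_id)
}

#' Serialize selection and optimization results as JSON
#'
#' @param x a \linkS4class{SelectionResult} or
#'   \linkS4class{OptimizationResult}.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
writeResultJSON <- function(x, path) {
  obj <- if (is(x, "SelectionResult")) {
    list(type = "selection", indices = x@indices, scores = x@scores,
         provenanceCounts = as.list(x@provenanceCounts))
  } else if (is(x, "OptimizationResult")) {
    list(type = "optimization", method = x@method, weights = x@bestWeights,
         bestFitness = x@bestFitness, fitnessHistory = x@fitnessHistory,
         evaluations = x@evaluations, seed = x@seed)
  } else stop("unsupported object type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write run artifacts of a pipeline report
#'
#' Writes predictions CSV, confusion-matrix CSV and metrics JSON (plus
#' selection and weights JSON when present) under \code{dir}.
#'
#' @param report a RunReport from \code{\link{runPipeline}}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(confusionTable(report$confusion),
                   file.path(dir, "confusion.csv"))
  m <- report$metrics
  jsonlite::write_json(
    list(accuracy = m@accuracy,
         misclassificationRate = m@misclassificationRate,
         perClass = m@perClass),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  writeResultJSON(report$selection, file.path(dir, "selection.json"))
  if (!is.null(report$optimization))
    writeResultJSON(report$optimization, file.path(dir, "weights.json"))
  invisible(dir)
}
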
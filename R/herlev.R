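#' @include AllClasses.R
NULL

#' The seven Herlev cervical cell classes
#'
#' The Herlev Pap smear benchmark distinguishes three normal epithelial cell
#' types (superficial squamous, intermediate squamous, columnar) and four
#' abnormal grades (mild, moderate and severe squamous non-keratinizing
#' dysplasia, and squamous carcinoma in situ). The order returned here is
#' the canonical class order used throughout the package; the abnormal
#' grades are ordered by increasing dysplasia severity.
#'
#' @return data.frame with columns \code{name} and \code{abnormal}
#'   (3 normal, 4 abnormal classes).
#' @export
#' @examples
#' herlevClasses()
herlevClasses <- function() {
  data.frame(
    name = c("normal_superficial", "normal_intermediate", "normal_columnar",
             "mild_dysplasia", "moderate_dysplasia", "severe_dysplasia",
             "carcinoma_in_situ"),
    abnormal = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Per-class image counts of the Herlev dataset
#'
#' The published class distribution of the 917 single-cell Herlev images:
#' 74 superficial, 70 intermediate and 98 columnar normal cells, and 182
#' mild, 146 moderate, 197 severe dysplastic and 150 carcinoma-in-situ
#' abnormal cells. Used as the default synthetic image counts so the
#' class-imbalance structure of the benchmark is reproduced.
#'
#' @return named integer vector in canonical class order, summing to 917.
#' @export
#' @examples
#' sum(herlevCounts())
herlevCounts <- function() {
  c(normal_superficial = 74L, normal_intermediate = 70L,
    normal_columnar = 98L, mild_dysplasia = 182L, moderate_dysplasia = 146L,
    severe_dysplasia = 197L, carcinoma_in_situ = 150L)
}
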
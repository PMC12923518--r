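#' Score substance-use severity (ASI-X)
#'
#' Lifetime years of regular use (three or more times weekly) are summed
#' across substances per subject, then square-root transformed and z-scored
#' across the cohort. The square root is applied before standardisation,
#' which matters because the sum has a point mass at zero and a long right
#' tail.
#'
#' @param use_records either a numeric vector of already-summed years per
#'   subject, or a matrix / data frame with one row per subject and one
#'   column per substance (years of regular use, >= 0).
#' @return a data frame with columns `asix_years` (summed), `asix_sqrt` and
#'   `asix_z` (z-scored square root, sample SD). If the cohort has zero
#'   variance the z-score is 0 for all subjects, with a warning.
#' @examples
#' score_asix(c(0, 1, 4, 9))$asix_z
#' @export
score_asix <- function(use_records) {
  if (is.data.frame(use_records)) use_records <- as.matrix(use_records)
  if (is.matrix(use_records)) {
    if (any(use_records < 0)) stop("years of regular use must be >= 0")
    total <- rowSums(use_records)
  } else {
    if (any(use_records < 0)) stop("years of regular use must be >= 0")
    total <- as.numeric(use_records)
  }
  s <- sqrt(total)
  sdev <- stats::sd(s)
  if (length(total) < 2 || is.na(sdev) || sdev == 0) {
    if (length(total) >= 2) warning("zero variance in severity scores; z-scores set to 0")
    z <- rep(0, length(total))
  } else {
    z <- (s - mean(s)) / sdev
  }
  data.frame(asix_years = total, asix_sqrt = s, asix_z = z)
}
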
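#' Build the stay/shift trial table
#'
#' One row per analysable trial, coding whether the subject repeated the
#' previous trial's choice (`stay`) as a function of the previous trial's
#' outcome and the task context. The first trial of the session and the
#' first trial of each context block are excluded: the previous outcome is
#' only defined within a context block (a lag across the block boundary
#' would span a contingency regime the participant has not yet
#' experienced). On complete 200-trial data this leaves 198 rows per
#' subject.
#'
#' Factor coding follows the reference levels used throughout the package:
#' `previous_outcome` with `"avoided"` as reference (so its coefficient
#' contrasts incurred vs avoided), `context` with `"stable"` as reference,
#' `randomization` with `"stable_first"` as reference. The
#' chosen-minus-unchosen loss-magnitude difference on the *current* trial
#' (`mag_diff_c`) and age (`age_c`) are mean-centered once, over the pooled
#' analysable rows and over the cohort respectively.
#'
#' @param trials trial-level data frame (multiple subjects allowed) with
#'   columns `subject_id`, `trial`, `context`, `choice`, `outcome`,
#'   `mag_card1`, `mag_card2`.
#' @param covariates optional per-subject data frame with `subject_id` and
#'   any of `asix_z` (or `asix_years`, scored via [score_asix()]), `age`,
#'   `randomization`.
#' @return a data frame with columns `subject_id`, `trial`, `stay` (0/1),
#'   `previous_outcome`, `context`, `mag_diff_c`, plus covariate columns
#'   when supplied.
#' @export
build_stay_table <- function(trials, covariates = NULL) {
  need <- c("subject_id", "trial", "context", "choice", "outcome",
            "mag_card1", "mag_card2")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials is missing column(s): ",
                         paste(miss, collapse = ", "))
  trials <- trials[order(trials$subject_id, trials$trial), , drop = FALSE]

  rows <- lapply(split(trials, trials$subject_id), function(d) {
    keep <- !is.na(d$choice)
    if (any(!keep)) {
      message("dropping ", sum(!keep), " trial(s) with missing choices for ",
              d$subject_id[1])
      d <- d[keep, , drop = FALSE]
    }
    n <- nrow(d)
    if (n < 2) return(NULL)
    same_block <- c(FALSE, d$context[-1] == d$context[-n])
    idx <- which(same_block)
    mag_chosen <- ifelse(d$choice == 1, d$mag_card1, d$mag_card2)
    mag_unchosen <- ifelse(d$choice == 1, d$mag_card2, d$mag_card1)
    data.frame(subject_id = d$subject_id[idx],
               trial = d$trial[idx],
               stay = as.integer(d$choice[idx] == d$choice[idx - 1]),
               previous_outcome = ifelse(d$outcome[idx - 1] == 1,
                                         "incurred", "avoided"),
               context = d$context[idx],
               mag_diff = mag_chosen[idx] - mag_unchosen[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$previous_outcome <- factor(out$previous_outcome,
                                 levels = c("avoided", "incurred"))
  out$context <- factor(out$context, levels = c("stable", "volatile"))
  out$mag_diff_c <- out$mag_diff - mean(out$mag_diff)
  out$mag_diff <- NULL

  if (!is.null(covariates)) {
    cov <- covariates
    if (is.null(cov$asix_z) && !is.null(cov$asix_years))
      cov$asix_z <- score_asix(cov$asix_years)$asix_z
    if (!is.null(cov$age)) cov$age_c <- cov$age - mean(cov$age)
    keep <- intersect(c("subject_id", "asix_z", "age_c", "randomization"),
                      names(cov))
    out <- merge(out, cov[, keep, drop = FALSE], by = "subject_id",
                 sort = FALSE)
    if (!is.null(out$randomization))
      out$randomization <- factor(out$randomization,
                                  levels = c("stable_first", "volatile_first"))
  }
  out[order(out$subject_id, out$trial), , drop = FALSE]
}
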
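#' Read and write trial-level data
#'
#' Trial-level CSV schema (1-based trial indexing): `subject_id`, `trial`,
#' `context`, `block_order`, `p_loss_card1`, `mag_card1`, `mag_card2`,
#' `correct_card`, `choice`, `outcome`, `loss_amount`. Reading validates
#' the schema and value ranges, reporting every violation with its row
#' number, and canonicalises row order by (subject, trial) with a message
#' if the file was out of order.
#'
#' @param trials trial-level data frame.
#' @param path CSV file path.
#' @param validate check schema and ranges on read.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

trial_columns <- c("subject_id", "trial", "context", "block_order",
                   "p_loss_card1", "mag_card1", "mag_card2", "correct_card",
                   "choice", "outcome", "loss_amount")

#' @rdname write_trials
#' @export
read_trials <- function(path, validate = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!validate) return(d)
  miss <- setdiff(trial_columns, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  problems <- character(0)
  bad <- function(rows, col, why) {
    if (length(rows))
      problems <<- c(problems, paste0("rows ", paste(utils::head(rows, 5),
                                                     collapse = ","),
                                      if (length(rows) > 5) ",..." else "",
                                      ": ", col, " ", why))
  }
  bad(which(d$mag_card1 < 1 | d$mag_card1 > 5), "mag_card1", "outside [1,5]")
  bad(which(d$mag_card2 < 1 | d$mag_card2 > 5), "mag_card2", "outside [1,5]")
  bad(which(!d$choice %in% c(1, 2)), "choice", "not in {1,2}")
  bad(which(!d$correct_card %in% c(1, 2)), "correct_card", "not in {1,2}")
  bad(which(!d$outcome %in% c(0, 1)), "outcome", "not in {0,1}")
  bad(which(d$p_loss_card1 < 0 | d$p_loss_card1 > 1), "p_loss_card1",
      "outside [0,1]")
  bad(which(!d$context %in% c("stable", "volatile")), "context",
      "not stable/volatile")
  bad(which(d$outcome != as.integer(d$choice != d$correct_card)), "outcome",
      "inconsistent with choice vs correct_card")
  if (length(problems))
    stop("trial file validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  ord <- order(d$subject_id, d$trial)
  if (!identical(ord, seq_len(nrow(d)))) {
    message("trial file was out of order; sorted by (subject_id, trial)")
    d <- d[ord, , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

#' Read and write subject covariates
#'
#' Covariate CSV schema: `subject_id`, `asix_years`, `age`,
#' `randomization`, plus `true_*` parameter columns for synthetic cohorts.
#'
#' @param covariates per-subject data frame.
#' @param path CSV file path.
#' @return `read_covariates()` returns the data frame; `write_covariates()`
#'   returns `path` invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "asix_years", "age", "randomization"),
                  names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(d$asix_years < 0)) stop("asix_years must be >= 0")
  d
}

# regression result -> plain list for JSON export
regression_to_list <- function(result) {
  list(formula = paste(deparse(result$formula), collapse = " "),
       n_obs = result$n_obs,
       n_subjects = result$n_subjects,
       statistic = result$statistic,
       random_intercept_sd = if (is.na(result$random_intercept_sd)) NULL
                             else result$random_intercept_sd,
       converged = result$converged,
       terms = result$terms)
}

#' Write a regression result, BMS result, or generic list as JSON
#'
#' @param x object to serialise (`costlearn_regression`, `costlearn_bms`,
#'   or any list).
#' @param path output path.
#' @export
write_result_json <- function(x, path) {
  if (inherits(x, "costlearn_regression")) x <- regression_to_list(x)
  if (inherits(x, "costlearn_bms"))
    x <- list(alpha = as.list(x$alpha),
              expected_frequencies = as.list(x$expected_frequencies),
              exceedance = as.list(x$exceedance),
              prior_concentration = x$prior_concentration,
              n_samples = x$n_samples, seed = x$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
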
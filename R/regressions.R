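#' Mixed-effects logistic regressions on stay/shift behaviour
#'
#' Fits the two stay/shift models with a random intercept per subject by
#' Laplace-approximated maximum likelihood (lme4):
#'
#' * `"eq1"` (basic task effects):
#'   `stay ~ previous_outcome * context + mag_diff_c + randomization +
#'   age_c + (1 | subject_id)`
#' * `"eq2"` (individual differences):
#'   `stay ~ previous_outcome * context * asix_z + mag_diff_c +
#'   randomization + age_c + (1 | subject_id)`
#'
#' Wald z tests and 95% confidence intervals (estimate +- 1.96 SE) are
#' reported per fixed-effect term.
#'
#' @param stay_table data frame from [build_stay_table()] (with covariates
#'   for `"eq2"`).
#' @param formula_spec `"eq1"` or `"eq2"`, or a formula.
#' @param nAGQ integration setting passed to [lme4::glmer()]; 1 (Laplace)
#'   by default, 0 for the faster penalised-least-squares approximation
#'   used inside large simulation loops.
#' @param ... further arguments to [lme4::glmer()].
#' @return an object of class `costlearn_regression`: a list with `terms`
#'   (data frame: `term`, `estimate`, `se`, `ci_lower`, `ci_upper`,
#'   `statistic`, `p_value`), `vcov`, `random_intercept_sd`, `n_obs`,
#'   `n_subjects`, `formula`, `converged`, and the underlying `fit`.
#' @export
fit_mixed_logistic <- function(stay_table, formula_spec = c("eq1", "eq2"),
                               nAGQ = 1, ...) {
  if (is.character(formula_spec)) {
    formula_spec <- match.arg(formula_spec)
    f <- switch(formula_spec,
      eq1 = stay ~ previous_outcome * context + mag_diff_c + randomization +
        age_c + (1 | subject_id),
      eq2 = stay ~ previous_outcome * context * asix_z + mag_diff_c +
        randomization + age_c + (1 | subject_id))
  } else {
    f <- stats::as.formula(formula_spec)
  }
  vars <- setdiff(all.vars(f), "subject_id")
  miss <- setdiff(vars, names(stay_table))
  if (length(miss)) stop("stay table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (length(unique(stay_table$subject_id)) < 2)
    stop("need at least 2 subjects")
  if (length(unique(stay_table$stay)) < 2)
    stop("both stay and shift outcomes must be present")

  warnings <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(f, data = stay_table, family = stats::binomial(),
                nAGQ = nAGQ, ...),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv <- length(fit@optinfo$conv$lme4) == 0
  as_regression_result(fit, n_subjects = length(unique(stay_table$subject_id)),
                       converged = conv, warnings = warnings)
}

as_regression_result <- function(fit, n_subjects, converged = TRUE,
                                 warnings = character(0)) {
  if (inherits(fit, "merMod")) {
    co <- summary(fit)$coefficients
    vc <- as.matrix(stats::vcov(fit))
    ri <- sqrt(unname(lme4::VarCorr(fit)[[1]][1, 1]))
    n_obs <- stats::nobs(fit)
    stat_name <- "z"
  } else {
    co <- summary(fit)$coefficients
    vc <- stats::vcov(fit)
    ri <- NA_real_
    n_obs <- stats::nobs(fit)
    stat_name <- "t"
  }
  terms <- data.frame(term = rownames(co),
                      estimate = co[, 1],
                      se = co[, 2],
                      ci_lower = co[, 1] - 1.96 * co[, 2],
                      ci_upper = co[, 1] + 1.96 * co[, 2],
                      statistic = co[, 3],
                      p_value = co[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, vcov = vc, random_intercept_sd = ri,
                 n_obs = n_obs, n_subjects = n_subjects,
                 formula = stats::formula(fit), statistic = stat_name,
                 converged = converged, warnings = warnings, fit = fit),
            class = "costlearn_regression")
}

#' @export
print.costlearn_regression <- function(x, ...) {
  cat("costlearn regression:", deparse(x$formula), "\n")
  cat(x$n_obs, "observations,", x$n_subjects, "subjects")
  if (!is.na(x$random_intercept_sd))
    cat(", random-intercept SD", round(x$random_intercept_sd, 3))
  cat("\n\n")
  tt <- x$terms
  tt[, -1] <- round(tt[, -1], 4)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Extract a term from a regression result
#'
#' @param result a `costlearn_regression`.
#' @param term exact term name (as in `result$terms$term`).
#' @return the matching single row of the term table.
#' @export
regression_term <- function(result, term) {
  i <- match(term, result$terms$term)
  if (is.na(i)) stop("term '", term, "' not in model; available: ",
                     paste(result$terms$term, collapse = ", "))
  result$terms[i, , drop = FALSE]
}

#' Simple slopes of a focal predictor at fixed moderator values
#'
#' Conditional (simple) slope of a focal model column at chosen values of
#' the moderating columns, computed as a linear combination of fixed-effect
#' coefficients with a delta-method standard error from the coefficient
#' covariance. A coefficient contributes to the slope if its term contains
#' the focal column; its weight is the product of the `at` values of the
#' other columns in the term (so any interaction order is handled). Every
#' non-focal column appearing in an interaction with the focal column must
#' be given a value in `at`; for a treatment-coded binary factor these are
#' the dummy values 0/1, for continuous moderators conventional probe
#' values such as +-1 SD.
#'
#' @param result a `costlearn_regression`.
#' @param focal name of the focal model column (e.g.
#'   `"previous_outcomeincurred"` or `"asix_z"`).
#' @param at named list/vector of moderator model-column values.
#' @return a one-row data frame: `slope`, `se`, `ci_lower`, `ci_upper`,
#'   `statistic`, `p_value`, `odds_ratio` (`exp(slope)`, meaningful for
#'   logistic models).
#' @examples
#' \dontrun{
#' # stay-odds contrast avoided vs incurred in the stable context:
#' s <- simple_slopes(m1, "previous_outcomeincurred",
#'                    at = list(contextvolatile = 0))
#' exp(-s$slope)  # odds ratio, avoided relative to incurred
#' }
#' @export
simple_slopes <- function(result, focal, at = list()) {
  at <- as.list(at)
  terms <- result$terms$term
  est <- result$terms$estimate
  w <- numeric(length(terms))
  found_focal <- FALSE
  for (i in seq_along(terms)) {
    parts <- strsplit(terms[i], ":", fixed = TRUE)[[1]]
    if (!(focal %in% parts)) next
    found_focal <- TRUE
    others <- parts[parts != focal]
    wi <- 1
    for (o in others) {
      if (is.null(at[[o]]))
        stop("moderator column '", o, "' interacts with '", focal,
             "' but has no value in `at`")
      wi <- wi * at[[o]]
    }
    w[i] <- wi
  }
  if (!found_focal) stop("focal column '", focal, "' not found in model terms")
  slope <- sum(w * est)
  V <- result$vcov[terms, terms, drop = FALSE]
  se <- sqrt(drop(t(w) %*% V %*% w))
  z <- slope / se
  data.frame(slope = slope, se = se,
             ci_lower = slope - 1.96 * se, ci_upper = slope + 1.96 * se,
             statistic = z,
             p_value = 2 * stats::pnorm(-abs(z)),
             odds_ratio = exp(slope))
}

#' Linear regression of a fitted model parameter on covariates
#'
#' Ordinary least squares of a subject-level parameter estimate on the
#' severity score, randomisation arm and mean-centered age:
#' `parameter ~ asix_z + randomization + age_c`. Inverse temperature and
#' loss sensitivity enter on the log scale (with the inverse-temperature
#' outlier winsorized upstream, see [winsorize_extreme()]).
#'
#' @param cohort_table data frame with one row per subject: the parameter
#'   column plus `asix_z`, `randomization`, `age_c` (or `age`, centered
#'   internally).
#' @param parameter name of the outcome column.
#' @return a `costlearn_regression` with t statistics.
#' @export
fit_parameter_regression <- function(cohort_table, parameter) {
  if (!parameter %in% names(cohort_table))
    stop("no column '", parameter, "' in cohort table")
  if (is.null(cohort_table$age_c)) {
    if (is.null(cohort_table$age)) stop("cohort table needs age or age_c")
    cohort_table$age_c <- cohort_table$age - mean(cohort_table$age)
  }
  if (!is.factor(cohort_table$randomization))
    cohort_table$randomization <- factor(cohort_table$randomization,
                                         levels = c("stable_first",
                                                    "volatile_first"))
  f <- stats::reformulate(c("asix_z", "randomization", "age_c"),
                          response = parameter)
  fit <- stats::lm(f, data = cohort_table)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(aliased)[aliased], collapse = ", "))
  as_regression_result(fit, n_subjects = nrow(cohort_table))
}
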
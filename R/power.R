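#' Nuisance settings for the power simulation
#'
#' Generative values for the terms of the individual-differences stay/shift
#' model ("eq2") that are not the focal effect. Fixed effects sit at
#' magnitudes comparable to the basic-task-effects estimates (log-odds):
#' intercept 0.4, previous outcome (incurred vs avoided) -0.67, context
#' (volatile vs stable) -0.10, their interaction 0.12, severity main effect
#' -0.23, context x severity 0.08, three-way 0, magnitude-difference slope
#' -0.05, and null randomisation and age effects. Between-subject
#' heterogeneity has two components: a random intercept (SD 0.8) and a
#' random slope on previous outcome (SD 0.6, about 0.9 times the fixed
#' previous-outcome effect). The slope component matters: power for a
#' cross-level interaction (within-subject effect x between-subject
#' covariate) is governed by how much the within-subject effect varies
#' across subjects, and with ~200 trials per subject a model with a random
#' intercept alone would put power for any detectable interaction at
#' essentially 1. The fitted model remains the random-intercept "eq2"
#' exactly as analysed.
#'
#' @param intercept,b_previous,b_context,b_prev_context,b_asix,
#'   b_context_asix,b_threeway,b_mag_diff,b_randomization,b_age fixed
#'   effects (log-odds).
#' @param sd_intercept,sd_prev_slope random-effect SDs.
#' @param p_prev_incurred marginal probability that the previous trial's
#'   loss was incurred.
#' @return a named list of settings.
#' @export
power_nuisance <- function(intercept = 0.4, b_previous = -0.67,
                           b_context = -0.10, b_prev_context = 0.12,
                           b_asix = -0.23, b_context_asix = 0.08,
                           b_threeway = 0, b_mag_diff = -0.05,
                           b_randomization = 0, b_age = 0,
                           sd_intercept = 0.8, sd_prev_slope = 0.6,
                           p_prev_incurred = 0.5) {
  as.list(environment())
}

# one synthetic eq2 stay table drawn directly from the GLMM data-generating
# process (198 analysable rows per subject: 99 per context)
simulate_eq2_table <- function(n_subjects, effect_size, nuis,
                               n_rows_per_context = 99) {
  n_tr <- 2 * n_rows_per_context
  zero <- stats::runif(n_subjects) < 0.25
  asix_years <- ifelse(zero, 0, stats::rgamma(n_subjects, 1.5, scale = 8))
  asix_z <- score_asix(asix_years)$asix_z
  age <- stats::rnorm(n_subjects, 35, 10)
  age_c <- age - mean(age)
  rand <- ifelse(stats::runif(n_subjects) < 0.5, "stable_first",
                 "volatile_first")
  b0 <- stats::rnorm(n_subjects, 0, nuis$sd_intercept)
  b1 <- stats::rnorm(n_subjects, 0, nuis$sd_prev_slope)

  idx <- rep(seq_len(n_subjects), each = n_tr)
  ctx_stable_first <- rep(c("stable", "volatile"), each = n_rows_per_context)
  ctx_volatile_first <- rep(c("volatile", "stable"), each = n_rows_per_context)
  context <- ifelse(rep(rand == "stable_first", each = n_tr),
                    rep(ctx_stable_first, n_subjects),
                    rep(ctx_volatile_first, n_subjects))
  prev <- stats::rbinom(n_subjects * n_tr, 1, nuis$p_prev_incurred)
  mag_diff <- stats::runif(n_subjects * n_tr, 1, 5) -
    stats::runif(n_subjects * n_tr, 1, 5)
  mag_diff_c <- mag_diff - mean(mag_diff)

  ctx <- as.integer(context == "volatile")
  az <- asix_z[idx]
  eta <- nuis$intercept +
    (nuis$b_previous + b1[idx]) * prev +
    nuis$b_context * ctx +
    nuis$b_prev_context * prev * ctx +
    nuis$b_asix * az +
    effect_size * prev * az +
    nuis$b_context_asix * ctx * az +
    nuis$b_threeway * prev * ctx * az +
    nuis$b_mag_diff * mag_diff_c +
    nuis$b_randomization * (rand[idx] == "volatile_first") +
    nuis$b_age * age_c[idx] +
    b0[idx]
  data.frame(subject_id = sprintf("S%03d", idx),
             trial = rep(seq_len(n_tr), n_subjects),
             stay = stats::rbinom(length(eta), 1, stats::plogis(eta)),
             previous_outcome = factor(ifelse(prev == 1, "incurred", "avoided"),
                                       levels = c("avoided", "incurred")),
             context = factor(context, levels = c("stable", "volatile")),
             mag_diff_c = mag_diff_c,
             asix_z = az,
             age_c = age_c[idx],
             randomization = factor(rand[idx],
                                    levels = c("stable_first", "volatile_first")),
             stringsAsFactors = FALSE)
}

#' Simulation-based power for the previous-outcome x severity interaction
#'
#' Estimates the power of the individual-differences stay/shift model
#' ("eq2", mixed-effects logistic with a random intercept per subject) to
#' detect a previous-outcome x severity two-way interaction of a given
#' log-odds size. Each replicate simulates a cohort directly from the eq2
#' data-generating process with the interaction coefficient injected (all
#' other coefficients and the random-effect SDs at the documented
#' [power_nuisance()] defaults), fits eq2, and applies the Wald test of the
#' interaction at level `alpha`. Power is the rejection fraction across
#' converged replicates, with a Clopper-Pearson binomial confidence
#' interval.
#'
#' @param effect_size generative interaction coefficient (log-odds).
#' @param n_subjects cohort size per replicate (default 137).
#' @param n_replicates number of simulated cohorts (>= 50).
#' @param alpha two-sided test level.
#' @param seed integer seed.
#' @param nuisance settings from [power_nuisance()].
#' @param nAGQ passed to the mixed-model fit; default 0 (fast approximate
#'   integration, with Wald statistics nearly identical to the Laplace fit
#'   at this problem size).
#' @return a list: `power` (in [0,1]), `ci` (95% binomial CI), `rejections`,
#'   `n_effective`, `n_failed`, and the settings used.
#' @examples
#' \dontrun{
#' power_simulation(0.17, n_subjects = 137, n_replicates = 200, seed = 1)
#' }
#' @export
power_simulation <- function(effect_size, n_subjects = 137,
                             n_replicates = 200, alpha = 0.05, seed = NULL,
                             nuisance = power_nuisance(), nAGQ = 0) {
  stopifnot(n_replicates >= 50)
  if (!is.null(seed)) set.seed(seed)
  term <- "previous_outcomeincurred:asix_z"
  pvals <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    tab <- simulate_eq2_table(n_subjects, effect_size, nuisance)
    res <- tryCatch(
      suppressMessages(fit_mixed_logistic(tab, "eq2", nAGQ = nAGQ)),
      error = function(e) NULL)
    if (is.null(res) || !res$converged) next
    pvals[r] <- regression_term(res, term)$p_value
  }
  ok <- !is.na(pvals)
  rejections <- sum(pvals[ok] < alpha)
  bt <- stats::binom.test(rejections, sum(ok))
  list(power = rejections / sum(ok),
       ci = as.numeric(bt$conf.int),
       rejections = rejections,
       n_effective = sum(ok),
       n_failed = sum(!ok),
       effect_size = effect_size, n_subjects = n_subjects,
       alpha = alpha, nuisance = nuisance, nAGQ = nAGQ)
}
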
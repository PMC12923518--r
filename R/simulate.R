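#' Simulate an agent on a task schedule
#'
#' Plays one model through a schedule: on each trial the perceptual model's
#' current prediction and the two cards' magnitudes are mapped to a softmax
#' choice probability, a choice is sampled, and the outcome follows the
#' schedule's correct card (loss incurred iff the chosen card was
#' incorrect). The perceptual model is updated with the reference-card
#' outcome, which is fully observable from either card's feedback.
#'
#' @param model_spec model label, one of [costlearn_models()].
#' @param params native-scale parameter list (perceptual parameters plus
#'   `beta`, and `rho` for the `_loss` models).
#' @param schedule data frame from [generate_schedule()].
#' @param seed optional integer seed.
#' @param subject_id identifier stored in the output (default `"sim"`).
#' @return a subject dataset: the schedule columns plus `subject_id`,
#'   `choice` (1/2), `outcome` (1 = incurred loss) and `loss_amount`.
#' @examples
#' sched <- generate_schedule("stable_first", seed = 1)
#' dat <- simulate_agent("hgf2_loss",
#'                       list(omega = -3, beta = 2, rho = 1),
#'                       sched, seed = 2)
#' mean(dat$outcome)
#' @export
simulate_agent <- function(model_spec, params, schedule, seed = NULL,
                           subject_id = "sim") {
  model_spec <- match.arg(model_spec, costlearn_models())
  check_params(params, model_spec)
  if (!is.null(seed)) set.seed(seed)
  u <- as.integer(schedule$correct_card == 2)   # card 1 losing
  s_hat <- shat_series(model_spec, params, u)
  if (is.null(s_hat)) stop("trajectory diverged for the supplied parameters")
  has_rho <- model_spec %in% c("hgf2_loss", "hgf3_loss")
  rho <- if (has_rho) params$rho else 1
  p1 <- p_choose1(s_hat, schedule$mag_card1, schedule$mag_card2,
                  params$beta, rho)
  choice <- ifelse(stats::runif(nrow(schedule)) < p1, 1L, 2L)
  outcome <- as.integer(choice != schedule$correct_card)
  mag_chosen <- ifelse(choice == 1, schedule$mag_card1, schedule$mag_card2)
  out <- schedule
  out$subject_id <- subject_id
  out$choice <- choice
  out$outcome <- outcome
  out$loss_amount <- outcome * mag_chosen
  out[, c("subject_id", setdiff(names(out), "subject_id"))]
}

#' Cohort generation settings
#'
#' Settings for [generate_cohort()]. The defaults emulate the study sample:
#' 137 participants, about a quarter of whom report zero lifetime years of
#' regular substance use (a point mass at zero) while the rest follow a
#' right-skewed Gamma; ages roughly 18-65; context order randomised 50/50;
#' and generative model parameters drawn on their unconstrained scales with
#' a single covariate link -- more years of regular use predicting lower
#' log inverse temperature (slope -0.3 per z unit of the square-root,
#' z-scored severity score), with no links on volatility or loss
#' sensitivity.
#'
#' @param n_subjects cohort size.
#' @param model generative model label.
#' @param asix_zero_fraction probability of zero years of regular use.
#' @param asix_gamma_shape,asix_gamma_scale Gamma distribution (years) for
#'   subjects with any regular use.
#' @param age_mean,age_sd,age_range Normal age distribution, truncated.
#' @param param_means,param_sds named numeric vectors: unconstrained-scale
#'   mean and between-subject SD for each generative parameter.
#' @param param_links named numeric vector: linear coefficient from the
#'   z-scored transformed severity score to each parameter's unconstrained
#'   scale.
#' @param seed integer seed for the whole cohort.
#' @return a list of settings with class `costlearn_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 137,
                          model = "hgf2_loss",
                          asix_zero_fraction = 0.25,
                          asix_gamma_shape = 1.5,
                          asix_gamma_scale = 8,
                          age_mean = 35, age_sd = 10, age_range = c(18, 65),
                          param_means = c(omega = -3, beta = 0.5, rho = 0),
                          param_sds = c(omega = 1.5, beta = 1, rho = 0.5),
                          param_links = c(omega = 0, beta = -0.3, rho = 0),
                          seed = 1L) {
  stopifnot(asix_zero_fraction >= 0, asix_zero_fraction <= 1,
            n_subjects >= 1)
  structure(list(n_subjects = n_subjects, model = model,
                 asix_zero_fraction = asix_zero_fraction,
                 asix_gamma_shape = asix_gamma_shape,
                 asix_gamma_scale = asix_gamma_scale,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 param_means = param_means, param_sds = param_sds,
                 param_links = param_links, seed = seed),
            class = "costlearn_cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws covariates (years of regular substance use with a point mass at
#' zero, age, randomised context order), computes each subject's generative
#' parameters on the unconstrained scale as
#' `mean + link * asix_z + Normal(0, sd)` (mapped to the native scale by the
#' model's transforms, so native-scale constraints hold automatically),
#' simulates each subject through their own task schedule, and records the
#' true parameters for recovery checks.
#'
#' @param config settings from [cohort_config()].
#' @return a list with class `costlearn_cohort`:
#'   `trials` (row-bound subject datasets) and `covariates`
#'   (one row per subject: `subject_id`, `asix_years`, `asix_z`, `age`,
#'   `randomization`, plus `true_*` columns on both scales).
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 5, seed = 42))
#' coh$covariates[, c("subject_id", "asix_years", "true_beta")]
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "costlearn_cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  tab <- model_param_table(config$model)
  fitted_names <- tab$name[!tab$fixed]

  zero <- stats::runif(n) < config$asix_zero_fraction
  asix_years <- ifelse(zero, 0,
                       stats::rgamma(n, shape = config$asix_gamma_shape,
                                     scale = config$asix_gamma_scale))
  if (n > 1 && stats::var(asix_years) == 0)
    warning("degenerate severity distribution: zero variance in years of use")
  asix_z <- score_asix(asix_years)$asix_z

  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  randomization <- ifelse(stats::runif(n) < 0.5, "stable_first",
                          "volatile_first")

  # unconstrained generative parameters, covariate-linked
  theta <- sapply(fitted_names, function(p) {
    m <- config$param_means[[p]]
    s <- config$param_sds[[p]]
    l <- config$param_links[[p]]
    if (is.null(m) || is.null(s) || is.null(l))
      stop("param_means/param_sds/param_links must name parameter '", p, "'")
    m + l * asix_z + stats::rnorm(n, 0, s)
  })
  theta <- matrix(theta, nrow = n, dimnames = list(NULL, fitted_names))

  subject_seeds <- sample.int(.Machine$integer.max %/% 4, n)
  trials <- vector("list", n)
  ids <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    params <- theta_to_params(theta[i, ], tab[!tab$fixed, , drop = FALSE])
    for (j in which(tab$fixed)) params[[tab$name[j]]] <- tab$fixed_native[j]
    sched <- generate_schedule(randomization[i], seed = subject_seeds[i])
    trials[[i]] <- simulate_agent(config$model, params, sched,
                                  seed = subject_seeds[i] + 1L,
                                  subject_id = ids[i])
  }

  covariates <- data.frame(subject_id = ids, asix_years = asix_years,
                           asix_z = asix_z, age = age,
                           randomization = randomization,
                           stringsAsFactors = FALSE)
  for (p in fitted_names) {
    covariates[[paste0("true_", p, "_u")]] <- theta[, p]
    covariates[[paste0("true_", p)]] <-
      vapply(theta[, p], to_native, numeric(1),
             transform = tab$transform[tab$name == p])
  }
  structure(list(trials = do.call(rbind, trials), covariates = covariates,
                 config = config),
            class = "costlearn_cohort")
}

#' @export
print.costlearn_cohort <- function(x, ...) {
  cat("costlearn cohort:", nrow(x$covariates), "subjects x",
      nrow(x$trials) / nrow(x$covariates), "trials (model",
      x$config$model, ")\n")
  invisible(x)
}
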
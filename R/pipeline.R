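#' Pipeline configuration
#'
#' Resolved settings for [run_pipeline()]. Per-stage seeds are derived from
#' the global seed by fixed offsets (simulate +1, fit +2, compare +3,
#' analyze +4) so every source of randomness is named and reproducible.
#'
#' @param seed global integer seed.
#' @param n_subjects synthetic cohort size (ignored when `trials_file` is
#'   given).
#' @param models character vector of model labels to fit.
#' @param winning_model model whose parameters feed the parameter
#'   regressions.
#' @param n_restarts optimisation restarts per fit.
#' @param trials_file,covariates_file optional paths to existing data; when
#'   `NULL` a synthetic cohort is generated.
#' @param cohort arguments forwarded to [cohort_config()] for synthetic
#'   data.
#' @param nAGQ integration setting for the stay/shift models.
#' @param write_trajectories write per-subject belief-trajectory TSVs for
#'   the winning model.
#' @return a named list with class `costlearn_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 137,
                            models = c("rw", "k1", "hgf2", "hgf2_loss",
                                       "hgf3", "hgf3_loss"),
                            winning_model = "hgf2_loss",
                            n_restarts = 3,
                            trials_file = NULL, covariates_file = NULL,
                            cohort = list(), nAGQ = 1,
                            write_trajectories = FALSE) {
  if (!length(models)) stop("config invalid: empty model list")
  models <- vapply(models, match.arg, "", choices = costlearn_models())
  if (!winning_model %in% models)
    stop("config invalid: winning_model must be among models")
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 models = unname(models), winning_model = winning_model,
                 n_restarts = n_restarts, trials_file = trials_file,
                 covariates_file = covariates_file, cohort = cohort,
                 nAGQ = nAGQ, write_trajectories = write_trajectories),
            class = "costlearn_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `costlearn_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> fit -> compare -> analyze -> report:
#' generates or reads the cohort, fits the candidate models to every
#' subject, selects models by random-effects Bayesian model selection,
#' winsorizes the inverse-temperature estimates, builds the stay/shift
#' table, fits the two mixed-effects logistic models with simple-slopes
#' follow-ups, runs the three parameter regressions, and writes all outputs
#' under `out_dir` together with the resolved configuration, its MD5 hash
#' and the seed (manifest sidecar). Identical configurations give identical
#' outputs.
#'
#' @param config a `costlearn_config` (or YAML path).
#' @param out_dir output directory (created if needed).
#' @param progress print stage messages.
#' @return (invisibly) a list with the cohort, fits table, BMS result,
#'   regression results and output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("costlearn_"),
                         progress = TRUE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "costlearn_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (progress) message("[costlearn] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate / load ------------------------------------------------------
  say("stage simulate")
  if (is.null(config$trials_file)) {
    cohort_args <- utils::modifyList(
      list(n_subjects = config$n_subjects, seed = config$seed + 1L),
      config$cohort)
    cohort <- stage("simulate", generate_cohort(do.call(cohort_config, cohort_args)))
    trials <- cohort$trials
    covariates <- cohort$covariates
  } else {
    trials <- stage("simulate", read_trials(config$trials_file))
    covariates <- stage("simulate", read_covariates(config$covariates_file))
    cohort <- NULL
  }

  # --- fit ------------------------------------------------------------------
  say("stage fit (", length(config$models), " models x ",
      length(unique(trials$subject_id)), " subjects)")
  fits <- stage("fit", fit_cohort(trials, config$models,
                                  n_restarts = config$n_restarts,
                                  seed = config$seed + 2L,
                                  progress = FALSE))

  # --- compare --------------------------------------------------------------
  say("stage compare")
  lme <- evidence_matrix(fits$table)
  ok <- stats::complete.cases(lme)
  bms_res <- if (ncol(lme) >= 2) {
    stage("compare", bms(lme[ok, , drop = FALSE], seed = config$seed + 3L))
  } else NULL

  # --- analyze --------------------------------------------------------------
  say("stage analyze")
  win <- fits$table[fits$table$model == config$winning_model, , drop = FALSE]
  win <- win[match(covariates$subject_id, win$subject_id), , drop = FALSE]
  ctab <- covariates
  if (is.null(ctab$asix_z)) ctab$asix_z <- score_asix(ctab$asix_years)$asix_z
  ctab$age_c <- ctab$age - mean(ctab$age)
  ctab$omega <- win$omega
  wb <- winsorize_extreme(win$beta)
  ctab$log_beta <- log(wb$values)
  if (!is.null(win$rho)) ctab$log_rho <- log(win$rho)

  stay <- stage("analyze", build_stay_table(trials, covariates))
  eq1 <- stage("analyze", fit_mixed_logistic(stay, "eq1", nAGQ = config$nAGQ))
  eq2 <- stage("analyze", fit_mixed_logistic(stay, "eq2", nAGQ = config$nAGQ))
  slopes <- stage("analyze", list(
    prev_in_stable = simple_slopes(eq1, "previous_outcomeincurred",
                                   at = list(contextvolatile = 0)),
    prev_in_volatile = simple_slopes(eq1, "previous_outcomeincurred",
                                     at = list(contextvolatile = 1)),
    asix_after_avoided = simple_slopes(eq2, "asix_z",
                                       at = list(previous_outcomeincurred = 0,
                                                 contextvolatile = 0)),
    asix_after_incurred = simple_slopes(eq2, "asix_z",
                                        at = list(previous_outcomeincurred = 1,
                                                  contextvolatile = 0))))
  param_regs <- stage("analyze", list(
    volatility = fit_parameter_regression(ctab, "omega"),
    loss_aversion = if (!is.null(ctab$log_rho))
      fit_parameter_regression(ctab, "log_rho") else NULL,
    inverse_temperature = fit_parameter_regression(ctab, "log_beta")))

  # --- report ---------------------------------------------------------------
  say("stage report -> ", out_dir)
  paths <- list(
    config = file.path(out_dir, "config.yaml"),
    trials = file.path(out_dir, "trials.csv"),
    covariates = file.path(out_dir, "covariates.csv"),
    fits = file.path(out_dir, "fits.csv"),
    bms = file.path(out_dir, "bms.json"),
    eq1 = file.path(out_dir, "regression_eq1.json"),
    eq2 = file.path(out_dir, "regression_eq2.json"),
    slopes = file.path(out_dir, "simple_slopes.json"),
    params = file.path(out_dir, "parameter_regressions.json"),
    manifest = file.path(out_dir, "manifest.json"))
  cfg <- unclass(config)
  cfg$models <- as.list(cfg$models)
  yaml::write_yaml(cfg, paths$config)
  write_trials(trials, paths$trials)
  write_covariates(covariates, paths$covariates)
  utils::write.csv(fits$table, paths$fits, row.names = FALSE)
  if (!is.null(bms_res)) write_result_json(bms_res, paths$bms)
  write_result_json(eq1, paths$eq1)
  write_result_json(eq2, paths$eq2)
  write_result_json(slopes, paths$slopes)
  write_result_json(list(
    volatility = regression_to_list(param_regs$volatility),
    loss_aversion = if (!is.null(param_regs$loss_aversion))
      regression_to_list(param_regs$loss_aversion),
    inverse_temperature = regression_to_list(param_regs$inverse_temperature),
    winsorized = wb$flagged), paths$params)
  if (isTRUE(config$write_trajectories)) {
    tdir <- file.path(out_dir, "trajectories")
    dir.create(tdir, showWarnings = FALSE)
    for (sid in unique(trials$subject_id)) {
      f <- fits$fits[[sid]][[config$winning_model]]
      if (inherits(f, "costlearn_fit")) {
        d <- trials[trials$subject_id == sid, , drop = FALSE]
        tr <- run_trajectory(config$winning_model, f$estimates,
                             reference_outcome(d))
        write_trajectory(tr, file.path(tdir, paste0(sid, ".tsv")))
      }
    }
  }
  config_hash <- unname(tools::md5sum(paths$config))
  manifest <- list(config_hash = config_hash, seed = config$seed,
                   files = lapply(paths[names(paths) != "manifest"],
                                  basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(cohort = cohort, trials = trials, covariates = covariates,
                 fits = fits, bms = bms_res, eq1 = eq1, eq2 = eq2,
                 slopes = slopes, parameter_regressions = param_regs,
                 cohort_table = ctab, winsorized = wb, paths = paths,
                 config_hash = config_hash))
}
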
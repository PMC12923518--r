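# shared fixtures, built in code at test time

# a small deterministic subject dataset
quick_subject <- function(model = "hgf2_loss",
                          params = list(omega = -2, beta = 2, rho = 1),
                          seed = 11, block_order = "stable_first") {
  sched <- generate_schedule(block_order, seed = seed)
  simulate_agent(model, params, sched, seed = seed + 1)
}

# cohort sized for tests; generator defaults otherwise untouched
quick_cohort <- function(n_subjects, seed, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, seed = seed, ...))
}

# fast fitting settings used in recovery loops
FIT_RESTARTS <- 3

# build a costlearn_regression by hand (for closed-form slope oracles)
fake_regression <- function(terms, estimates, vcov) {
  structure(list(terms = data.frame(term = terms, estimate = estimates,
                                    se = sqrt(diag(vcov)),
                                    ci_lower = NA, ci_upper = NA,
                                    statistic = NA, p_value = NA),
                 vcov = `dimnames<-`(vcov, list(terms, terms)),
                 random_intercept_sd = NA_real_, n_obs = NA, n_subjects = NA,
                 formula = stay ~ 1, statistic = "z", converged = TRUE,
                 warnings = character(0), fit = NULL),
            class = "costlearn_regression")
}
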
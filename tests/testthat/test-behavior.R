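test_that("severity scoring sums, square-roots, then standardises", {
  s <- score_asix(c(0, 1, 4, 9))
  expect_equal(s$asix_sqrt, 0:3)
  expect_equal(s$asix_z, c(-1.1619, -0.3873, 0.3873, 1.1619),
               tolerance = 1e-4)
  # summing across substances
  m <- cbind(alcohol = c(0, 2), cannabis = c(0, 3))
  expect_equal(score_asix(m)$asix_years, c(0, 5))
  expect_error(score_asix(c(1, -2)), ">= 0")
  # all-zero cohort: zero floor is the minimum, zero variance warns
  expect_warning(z0 <- score_asix(rep(0, 5)), "variance")
  expect_equal(z0$asix_z, rep(0, 5))
  # transform order matters: sqrt is taken before z-scoring
  x <- c(0, 1, 4, 9)
  expect_false(isTRUE(all.equal(score_asix(x + 4)$asix_z,
                                score_asix(x)$asix_z)))
})

test_that("stay table codes lagged outcomes within context blocks", {
  trials <- data.frame(
    subject_id = "s1", trial = 1:6,
    context = c("stable", "stable", "stable", "volatile", "volatile", "volatile"),
    choice = c(1L, 1L, 2L, 2L, 1L, 1L),
    outcome = c(0L, 1L, 0L, 1L, 0L, 0L),
    mag_card1 = 2, mag_card2 = 3)
  st <- build_stay_table(trials)
  # first trial of the session and of the second block are absent
  expect_equal(st$trial, c(2, 3, 5, 6))
  expect_equal(st$stay, c(1L, 0L, 0L, 1L))
  expect_equal(as.character(st$previous_outcome),
               c("avoided", "incurred", "incurred", "avoided"))
  # an always-card-1 chooser always stays
  trials$choice <- 1L
  expect_true(all(build_stay_table(trials)$stay == 1))
})

test_that("a complete cohort yields 198 analysable rows per subject", {
  coh <- quick_cohort(3, seed = 13)
  st <- build_stay_table(coh$trials, coh$covariates)
  expect_equal(nrow(st), 3 * 198)
  expect_true(all(table(st$subject_id) == 198))
  expect_equal(mean(st$mag_diff_c), 0, tolerance = 1e-12)
  expect_true(all(c("asix_z", "age_c", "randomization") %in% names(st)))
  expect_false(any(st$trial %in% c(1, 101)))
})

test_that("the mixed logistic matches a direct numerical-integration fit", {
  # tiny instance: 3 subjects x 20 trials, stay ~ x + (1 | subject)
  set.seed(17)
  n_s <- 3; n_t <- 20
  subj <- factor(rep(1:n_s, each = n_t))
  x <- rnorm(n_s * n_t)
  b <- c(-0.8, 0.2, 1.0)[as.integer(subj)]
  stay <- rbinom(n_s * n_t, 1, plogis(0.3 + 0.8 * x + b))
  d <- data.frame(stay = stay, x = x, subject_id = subj)

  # independent oracle: marginal likelihood by brute-force grid integration
  # over the random intercept, maximised with optim
  grid <- seq(-8, 8, by = 0.02)
  neg_marg_ll <- function(par) {
    eta0 <- par[1] + par[2] * d$x
    sigma <- exp(par[3])
    w <- dnorm(grid, 0, sigma) * 0.02
    ll <- 0
    for (s in levels(d$subject_id)) {
      i <- d$subject_id == s
      lik_b <- vapply(grid, function(bb) {
        p <- plogis(eta0[i] + bb)
        exp(sum(dbinom(d$stay[i], 1, p, log = TRUE)))
      }, numeric(1))
      ll <- ll + log(sum(lik_b * w))
    }
    -ll
  }
  oracle <- optim(c(0, 0, 0), neg_marg_ll, method = "BFGS",
                  control = list(reltol = 1e-12))

  fit <- fit_mixed_logistic(d, stay ~ x + (1 | subject_id), nAGQ = 25)
  expect_equal(fit$terms$estimate, oracle$par[1:2], tolerance = 5e-4)
  expect_equal(fit$random_intercept_sd, exp(oracle$par[3]), tolerance = 1e-3)
})

test_that("mixed logistic input validation", {
  d <- data.frame(stay = c(0, 1), x = 1:2, subject_id = c("a", "a"))
  expect_error(fit_mixed_logistic(d, stay ~ x + (1 | subject_id)),
               "2 subjects")
  d2 <- data.frame(stay = 1, x = 1:4,
                   subject_id = rep(c("a", "b"), 2))
  expect_error(fit_mixed_logistic(d2, stay ~ x + (1 | subject_id)),
               "both stay and shift")
})

test_that("simple slopes are linear combinations with delta-method SEs", {
  V <- matrix(c(0.04, 0.01, 0.005,
                0.01, 0.09, 0.002,
                0.005, 0.002, 0.0625), 3, 3)
  r <- fake_regression(c("f", "m", "f:m"), c(0.5, 0.2, 0.3), V)
  s <- simple_slopes(r, "f", at = list(m = 2))
  expect_equal(s$slope, 0.5 + 2 * 0.3)
  w <- c(1, 0, 2)
  expect_equal(s$se, sqrt(drop(t(w) %*% V %*% w)))
  expect_equal(s$odds_ratio, exp(s$slope))

  # a zero interaction leaves the slope equal to the main effect at any level
  r0 <- fake_regression(c("f", "m", "f:m"), c(0.5, 0.2, 0), V)
  expect_equal(simple_slopes(r0, "f", at = list(m = 0))$slope, 0.5)
  expect_equal(simple_slopes(r0, "f", at = list(m = 1))$slope, 0.5)

  expect_error(simple_slopes(r, "f", at = list()), "no value")
  expect_error(simple_slopes(r, "nope", at = list(m = 0)), "not found")
})

test_that("parameter regression recovers a planted link and rejects collinearity", {
  set.seed(19)
  n <- 80
  tab <- data.frame(asix_z = rnorm(n),
                    randomization = sample(c("stable_first", "volatile_first"),
                                           n, TRUE),
                    age = rnorm(n, 35, 10))
  tab$log_beta <- 0.5 - 0.3 * tab$asix_z + rnorm(n, 0, 0.5)
  r <- fit_parameter_regression(tab, "log_beta")
  est <- regression_term(r, "asix_z")
  expect_lt(est$estimate, 0)
  expect_lt(est$p_value, 0.05)
  expect_equal(est$ci_upper - est$estimate, 1.96 * est$se)

  # permuted covariate: no signal
  tab$asix_perm <- sample(tab$asix_z)
  tab2 <- tab; tab2$asix_z <- tab$asix_perm
  r2 <- fit_parameter_regression(tab2, "log_beta")
  e2 <- regression_term(r2, "asix_z")
  expect_lt(abs(e2$estimate) / e2$se, 2.5)

  # exact collinearity is named
  tab3 <- tab; tab3$age <- NULL; tab3$age_c <- tab3$asix_z
  expect_error(fit_parameter_regression(tab3, "log_beta"), "age_c")
})

test_that("power is calibrated at the null and monotone in effect size", {
  # correctly specified null (no slope heterogeneity): rejection rate ~ alpha
  p0 <- power_simulation(0, n_subjects = 40, n_replicates = 60, seed = 23,
                         nuisance = power_nuisance(sd_prev_slope = 0))
  expect_lte(p0$power, 0.15)
  # monotone non-decreasing in effect size (within Monte Carlo error)
  p1 <- power_simulation(0.25, n_subjects = 40, n_replicates = 60, seed = 23)
  p2 <- power_simulation(1.0, n_subjects = 40, n_replicates = 60, seed = 23)
  expect_lte(p0$power, p1$power + 0.1)
  expect_lte(p1$power, p2$power + 0.1)
  expect_gt(p2$power, p0$power)
  expect_gt(p2$power, 0.9)   # large effects are asymptotically certain
})

test_that("the eq2 estimator recovers an injected interaction without bias", {
  set.seed(29)
  ests <- ses <- numeric(12)
  for (r in 1:12) {
    tab <- costlearn:::simulate_eq2_table(137, 0.3,
                                          power_nuisance(sd_prev_slope = 0))
    fit <- fit_mixed_logistic(tab, "eq2", nAGQ = 0)
    tt <- regression_term(fit, "previous_outcomeincurred:asix_z")
    ests[r] <- tt$estimate; ses[r] <- tt$se
  }
  expect_lt(abs(mean(ests) - 0.3), 0.05)
  covered <- abs(ests - 0.3) <= 2 * ses
  expect_gte(mean(covered), 0.8)
})
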
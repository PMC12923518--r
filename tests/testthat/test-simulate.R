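test_that("simulated datasets respect the payoff rules", {
  dat <- quick_subject(seed = 101)
  expect_equal(dat$outcome, as.integer(dat$choice != dat$correct_card))
  expect_true(all((dat$loss_amount == 0) == (dat$outcome == 0)))
  mag_chosen <- ifelse(dat$choice == 1, dat$mag_card1, dat$mag_card2)
  expect_equal(dat$loss_amount[dat$outcome == 1],
               mag_chosen[dat$outcome == 1])
  # cumulative loss is non-decreasing
  expect_true(all(diff(cumsum(dat$loss_amount)) >= 0))
})

test_that("agents are deterministic given a seed and random at beta = 0", {
  sched <- generate_schedule("stable_first", seed = 5)
  p <- list(omega = -2, beta = 2, rho = 1)
  expect_identical(simulate_agent("hgf2_loss", p, sched, seed = 9),
                   simulate_agent("hgf2_loss", p, sched, seed = 9))
  # beta = 0: uniform choices
  set.seed(10)
  choices <- unlist(lapply(1:20, function(i)
    simulate_agent("hgf2", list(omega = -2, beta = 0),
                   generate_schedule(seed = i), seed = 100 + i)$choice))
  expect_lt(abs(mean(choices == 1) - 0.5), 0.02)
})

test_that("deterministic agents prefer the safer card late in the stable block", {
  # high beta: the low-p_loss card should dominate the second half of the
  # stable block for most agents
  set.seed(11)
  prop_best <- replicate(100, {
    sched <- generate_schedule("stable_first")
    dat <- simulate_agent("hgf2", list(omega = -3, beta = 20), sched)
    best <- if (sched$p_loss_card1[1] > 0.5) 2L else 1L
    mean(dat$choice[51:100] == best)
  })
  expect_gt(mean(prop_best), 0.5)
  expect_gt(mean(prop_best > 0.5), 0.8)
})

test_that("cohorts link parameters to severity as configured", {
  # null links: parameters independent of severity
  coh0 <- quick_cohort(200, seed = 41,
                       param_links = c(omega = 0, beta = 0, rho = 0))
  expect_lt(abs(cor(coh0$covariates$asix_z, coh0$covariates$true_beta_u)),
            0.15)
  # negative link to log beta shows up in the generative parameters
  coh1 <- quick_cohort(500, seed = 42)
  expect_lt(cor(coh1$covariates$asix_z, coh1$covariates$true_beta_u), 0)
  # ~25% zero-severity subjects (binomial +- 3 SD around 34.25 at n = 137)
  coh2 <- quick_cohort(137, seed = 43)
  n_zero <- sum(coh2$covariates$asix_years == 0)
  expect_true(abs(n_zero - 137 * 0.25) <= 3 * sqrt(137 * 0.25 * 0.75))
  expect_true(all(coh2$covariates$asix_years >= 0))
  expect_equal(nrow(coh2$trials), 137 * 200)
})

test_that("trajectory export is lossless", {
  tr <- run_trajectory("hgf2", list(omega = -2, beta = 1),
                       rbinom(30, 1, 0.7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- utils::read.delim(path)
  expect_equal(back, tr, tolerance = 1e-12, ignore_attr = TRUE)
})
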
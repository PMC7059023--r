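test_that("invalid scenario configurations are rejected with the offending field named", {
  expect_error(scenario_config(n_patients = 0), "n_patients",
               class = "ccw_config_error")
  expect_error(scenario_config(horizon = 2, grace = 3), "grace",
               class = "ccw_config_error")
  expect_error(scenario_config(timevarying_ar_coef = 1), "timevarying_ar_coef",
               class = "ccw_config_error")
  expect_error(scenario_config(admin_censor_fraction = 1.2),
               "admin_censor_fraction", class = "ccw_config_error")
  expect_error(
    scenario_config(init_model_coefs = c("(Intercept)" = -2, nosuch = 1)),
    "nosuch", class = "ccw_config_error")
  expect_error(generate_cohort(scenario_config()), "seed",
               class = "ccw_config_error")
})

test_that("generation is deterministic given config and seed", {
  cfg <- scenario_config(n_patients = 150, horizon = 10, seed = 33)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$panel, b$panel)
  c <- generate_cohort(cfg, seed = 34)
  expect_false(identical(a$patients, c$patients))
})

test_that("patient records satisfy the follow-up invariants", {
  cfg <- scenario_config(n_patients = 400, horizon = 15, seed = 5,
                         admin_censor_fraction = 0.3)
  cohort <- generate_cohort(cfg)
  p <- cohort$patients
  # at most one of event/censor marks the end of follow-up
  expect_false(any(!is.na(p$event_interval) & !is.na(p$censor_interval)))
  end <- pmin(ifelse(is.na(p$event_interval), cfg$horizon - 1, p$event_interval),
              ifelse(is.na(p$censor_interval), cfg$horizon - 1, p$censor_interval))
  # initiation, when observed, does not postdate the end of follow-up
  expect_true(all(is.na(p$initiation_interval) | p$initiation_interval <= end))
  # no covariate values after the end of follow-up, none missing before
  lens <- table(factor(cohort$panel$patient_id, levels = p$patient_id))
  expect_equal(as.integer(lens), end + 1L)
})

test_that("marginal initiation frequency matches the closed-form geometric probability", {
  # constant per-interval initiation hazard p: P(initiate within the
  # 3-interval grace window among survivors) ~ 1 - (1-p)^3; death is kept
  # rare so survival barely perturbs the comparison
  p <- 0.1
  cfg <- scenario_config(
    n_patients = 10000, horizon = 12, grace = 3,
    init_model_coefs = c("(Intercept)" = qlogis(p)),
    death_model_coefs = c("(Intercept)" = -8),
    admin_censor_fraction = 0, seed = 21
  )
  cohort <- generate_cohort(cfg)
  frac <- mean(!is.na(cohort$patients$initiation_interval) &
                 cohort$patients$initiation_interval < 3)
  expected <- 1 - (1 - p)^3
  mc_se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(frac - expected), 3 * mc_se)
})

test_that("marginal death frequency matches its closed form in a no-covariate scenario", {
  pd <- 0.08
  cfg <- flat_scenario(n = 10000, horizon = 12, p_init = 0.5, p_death = pd)
  cfg$init_model_coefs <- c("(Intercept)" = -30) # effectively never initiate
  cohort <- generate_cohort(cfg, seed = 8)
  frac_dead <- mean(!is.na(cohort$patients$event_interval))
  expected <- 1 - (1 - pd)^12
  mc_se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(frac_dead - expected), 3 * mc_se)
})

test_that("forced-arm oracle curves coincide under the null and separate under a protective effect", {
  cfg <- flat_scenario(n = 100, horizon = 12, p_init = 0.3, p_death = 0.08)
  cfg$seed <- 17L
  n_o <- 50000
  rt <- simulate_counterfactual_risks(cfg, "treat", n_oracle = n_o)
  rc <- simulate_counterfactual_risks(cfg, "control", n_oracle = n_o)
  se <- sqrt(rt$risk * (1 - rt$risk) / n_o) + sqrt(rc$risk * (1 - rc$risk) / n_o)
  expect_true(all(abs(rt$risk - rc$risk) <= 3 * pmax(se, 1e-4)))

  cfg2 <- flat_scenario(n = 100, horizon = 12, p_init = 0.3, p_death = 0.08,
                        true_log_hr = log(0.7))
  cfg2$seed <- 17L
  rt2 <- simulate_counterfactual_risks(cfg2, "treat", n_oracle = n_o)
  rc2 <- simulate_counterfactual_risks(cfg2, "control", n_oracle = n_o)
  H <- cfg2$horizon
  se_h <- sqrt(rt2$risk[H] * (1 - rt2$risk[H]) / n_o) +
    sqrt(rc2$risk[H] * (1 - rc2$risk[H]) / n_o)
  expect_lt(rt2$risk[H], rc2$risk[H] - 3 * se_h)
})

test_that("the oracle ignores administrative censoring and yields monotone risks in [0, 1]", {
  cfg_a <- flat_scenario(n = 100, admin_censor_fraction = 0)
  cfg_b <- flat_scenario(n = 100, admin_censor_fraction = 0.9)
  cfg_a$seed <- cfg_b$seed <- 3L
  ra <- simulate_counterfactual_risks(cfg_a, "treat", n_oracle = 2000)
  rb <- simulate_counterfactual_risks(cfg_b, "treat", n_oracle = 2000)
  expect_identical(ra, rb)
  expect_true(all(diff(ra$risk) >= 0))
  expect_true(all(ra$risk >= 0 & ra$risk <= 1))
  expect_error(simulate_counterfactual_risks(cfg_a, "placebo", 100),
               class = "ccw_config_error")
})

test_that("cohorts round-trip through the CSV pair", {
  cfg <- scenario_config(n_patients = 60, horizon = 8, seed = 12)
  cohort <- generate_cohort(cfg)
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, wide, long)
  back <- read_cohort(wide, long)
  expect_equal(back$baseline_covariates, cohort$baseline_covariates)
  expect_equal(back$timevarying_covariates, cohort$timevarying_covariates)
  expect_equal(as.data.frame(back$patients), as.data.frame(cohort$patients))
  expect_equal(as.data.frame(back$panel), as.data.frame(cohort$panel))
})
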
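test_that("the strategy coefficient is zero when the arms carry identical data", {
  cfg <- flat_scenario(n = 300, horizon = 8, p_init = 0.2, p_death = 0.1)
  cohort <- generate_cohort(cfg, seed = 41)
  protocol <- trial_protocol(grace = 3, horizon = 8)
  pp <- expand_person_periods(cohort, protocol)
  cl <- make_clones(pp, protocol) # both arms are exact copies, no censoring
  fit <- fit_pooled_logistic(cl, outcome_model_config(
    time_quadratic(), include_treatment_time_products = FALSE, horizon = 8))
  expect_equal(unname(fit$coefficients[["arm"]]), 0, tolerance = 1e-8)
})

test_that("a saturated unweighted model reproduces empirical cell hazards", {
  cfg <- flat_scenario(n = 200, horizon = 6, p_init = 0.3, p_death = 0.15)
  cohort <- generate_cohort(cfg, seed = 58)
  protocol <- trial_protocol(grace = 3, horizon = 6)
  pp <- expand_person_periods(cohort, protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)
  fit <- fit_pooled_logistic(cl, outcome_model_config(
    time_indicator(), include_treatment_time_products = TRUE, horizon = 6))
  for (a in c("treat", "control")) {
    for (t in 0:5) {
      rows <- cl$arm == a & cl$interval == t
      if (!any(rows)) next
      emp <- sum(cl$event[rows]) / sum(rows)
      pred <- predict_hazard(fit, a, t)
      expect_equal(pred, emp, tolerance = 1e-7)
    }
  }
})

test_that("known hazard-model coefficients are recovered from simulated data", {
  cfg <- scenario_config(
    n_patients = 5000, horizon = 12, grace = 3, true_log_hr = log(0.8),
    init_model_coefs = c("(Intercept)" = qlogis(0.25)),
    death_model_coefs = c("(Intercept)" = -2.6, time = 0.05, age = 0.3,
                          stage2 = 0.4),
    admin_censor_fraction = 0
  )
  cohort <- generate_cohort(cfg, seed = 70)
  protocol <- trial_protocol(grace = 3, horizon = 12,
                             baseline_covariates = c("age", "stage2"))
  pp <- expand_person_periods(cohort, protocol)
  # treatment as actually received, unit weights: the generating model
  pp$arm <- ifelse(pp$initiated_by_t, "treat", "control")
  pp$weight <- 1
  fit <- fit_pooled_logistic(pp, outcome_model_config(
    time_quadratic(), include_treatment_time_products = FALSE,
    baseline_adjustment_covariates = c("age", "stage2"), horizon = 12))
  td <- tidy(fit)
  truth <- c("(Intercept)" = -2.6, arm = log(0.8), time = 0.05,
             age = 0.3, stage2 = 0.4)
  for (nm in names(truth)) {
    est <- td$estimate[td$term == nm]
    se <- td$std.error[td$term == nm]
    expect_lt(abs(est - truth[[nm]]), 2 * se)
  }
})

test_that("standardized risk equals the counting product-limit in the saturated unweighted case", {
  cfg <- flat_scenario(n = 120, horizon = 6, p_init = 0.35, p_death = 0.12)
  cohort <- generate_cohort(cfg, seed = 13)
  protocol <- trial_protocol(grace = 3, horizon = 6)
  pp <- expand_person_periods(cohort, protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)
  fit <- fit_pooled_logistic(cl, outcome_model_config(
    time_indicator(), include_treatment_time_products = TRUE, horizon = 6))
  surv <- standardized_survival(fit, cohort$patients)
  for (a in c("treat", "control")) {
    pl <- counting_product_limit(cl, a, 6)
    got <- surv$curves$risk[surv$curves$arm == a]
    expect_lt(max(abs(got - pl)), 1e-10)
  }
})

test_that("identical fitted hazards give a zero risk difference at every horizon", {
  cfg <- flat_scenario(n = 300, horizon = 8, p_init = 0.2, p_death = 0.1)
  cohort <- generate_cohort(cfg, seed = 41)
  protocol <- trial_protocol(grace = 3, horizon = 8)
  pp <- expand_person_periods(cohort, protocol)
  cl <- make_clones(pp, protocol)
  fit <- fit_pooled_logistic(cl, outcome_model_config(
    time_quadratic(), include_treatment_time_products = TRUE, horizon = 8))
  for (h in c(2, 5, 8)) {
    surv <- standardized_survival(fit, cohort$patients, rd_horizon = h)
    expect_equal(surv$risk_difference$estimate, 0, tolerance = 1e-6)
  }
})

test_that("an arm without events is reported as unidentifiable, naming the arm", {
  protocol <- trial_protocol(grace = 3, horizon = 8)
  # the patient initiates at t=0, so the control clone is censored at t=0
  # and the control arm retains no person-time at all
  pp <- pp_for(one_patient(init = 0L, event = 6L), protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)
  expect_error(fit_pooled_logistic(cl, outcome_model_config(
    time_quadratic(), horizon = 8)), "control", class = "ccw_estimation_error")
})

test_that("the pooled-logistic marginal HR agrees with direct tabulation and the Cox backend on rare events", {
  cfg <- flat_scenario(n = 4000, horizon = 10, p_init = 0.4, p_death = 0.01,
                       true_log_hr = log(0.6))
  cohort <- generate_cohort(cfg, seed = 91)
  protocol <- trial_protocol(grace = 3, horizon = 10)
  pp <- expand_person_periods(cohort, protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)
  cl$weight <- 1
  hr_pl <- marginal_hazard_ratio(cl, time_terms = time_indicator(),
                                 horizon = 10)$hazard_ratio

  # brute-force 2 x T event/at-risk tabulation, identical time structure:
  # conditional ML on the saturated 2xT table via glm as the oracle
  tab <- dplyr::summarise(dplyr::group_by(cl, .data$arm, .data$interval),
                          events = sum(.data$event), atrisk = dplyr::n(),
                          .groups = "drop")
  oracle <- stats::glm(cbind(events, atrisk - events) ~ arm + factor(interval),
                       family = stats::binomial(), data = tab)
  # "control" is the reference level, so the armtreat coefficient is the
  # treat-vs-control log odds ratio
  hr_tab <- exp(unname(stats::coef(oracle)[["armtreat"]]))
  expect_equal(hr_pl, hr_tab, tolerance = 1e-6)

  skip_if_not_installed("survival")
  hr_cox <- marginal_hazard_ratio(cl, backend = "cox")$hazard_ratio
  expect_equal(hr_pl, hr_cox, tolerance = 0.01)
})

test_that("adjustment flavors are labelled, distinct, and agree under no confounding", {
  cfg <- protective_adherent_scenario(n = 3000, horizon = 12)
  cohort <- generate_cohort(cfg, seed = 27)
  ac <- analysis_configs_for(cfg)
  est <- estimate_all_hr_flavors(cohort, ac$protocol, ac$weight_config,
                                 ac$outcome_config)
  expect_setequal(est$method,
                  c("unadjusted", "baseline-adjusted", "baseline+postbaseline"))
  # without confounding, all three flavors estimate the same quantity
  expect_lt(max(est$hazard_ratio) - min(est$hazard_ratio), 0.1)
})
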
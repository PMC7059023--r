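# A hand-built initiation model with known constant probability, used to
# check the weight arithmetic exactly.
constant_init_model <- function(p, grace = 3) {
  structure(list(
    coefficients = c("(Intercept)" = qlogis(p),
                     setNames(rep(0, grace - 1), paste0("time_", 1:(grace - 1)))),
    vcov = NULL, covariates = character(),
    time_terms = structure(list(kind = "indicator", levels = 0:(grace - 1)),
                           class = "ccw_time_spec"),
    role = "denominator", grace = grace, n = 0L, n_events = 0L,
    converged = TRUE, deviance = 0
  ), class = "ccw_initiation_model")
}

test_that("the initiation model recovers a constant hazard and known coefficients", {
  protocol <- trial_protocol(grace = 3, horizon = 12,
                             timevarying_covariates = "frailty")
  wcfg <- weight_model_config(denominator_covariates = "frailty")

  # no-covariate model on constant-hazard data: intercept ~ logit(p-hat)
  cfg <- flat_scenario(n = 3000, horizon = 12, p_init = 0.15, p_death = 0.05)
  cohort <- generate_cohort(cfg, seed = 31)
  pp <- expand_person_periods(cohort,
                              trial_protocol(grace = 3, horizon = 12))
  fit0 <- fit_initiation_model(pp, weight_model_config(character()),
                               trial_protocol(grace = 3, horizon = 12))
  rs <- pp[pp$interval < 3 & (!pp$initiated_by_t | pp$initiates_at_t), ]
  phat <- mean(rs$initiates_at_t[rs$interval == 0])
  expect_equal(unname(fit0$coefficients[["(Intercept)"]]), qlogis(phat),
               tolerance = 1e-6)

  # data generated with initiation log-odds -2 + 1 * frailty: coefficients
  # recovered within 2 estimated standard errors
  cfg2 <- scenario_config(
    n_patients = 5000, horizon = 12, grace = 3,
    init_model_coefs = c("(Intercept)" = -2, frailty = 1),
    death_model_coefs = c("(Intercept)" = -4),
    timevarying_mean_coefs = c("(Intercept)" = 0),
    admin_censor_fraction = 0
  )
  cohort2 <- generate_cohort(cfg2, seed = 77)
  pp2 <- expand_person_periods(cohort2,
                               trial_protocol(grace = 3, horizon = 12,
                                              timevarying_covariates = "frailty"))
  fit2 <- fit_initiation_model(pp2, wcfg, protocol)
  td <- tidy(fit2)
  est <- td$estimate[td$term == "frailty"]
  se <- td$std.error[td$term == "frailty"]
  expect_lt(abs(est - 1), 2 * se)
  est0 <- td$estimate[td$term == "(Intercept)"]
  se0 <- td$std.error[td$term == "(Intercept)"]
  expect_lt(abs(est0 - (-2)), 2 * se0)
})

test_that("degenerate initiation responses raise estimation errors", {
  cfg <- flat_scenario(n = 100, horizon = 8, p_init = 0.5, p_death = 0.05)
  cfg$init_model_coefs <- c("(Intercept)" = -30)
  cohort <- generate_cohort(cfg, seed = 4)
  protocol <- trial_protocol(grace = 3, horizon = 8)
  pp <- expand_person_periods(cohort, protocol)
  expect_error(fit_initiation_model(pp, weight_model_config(character()), protocol),
               class = "ccw_estimation_error")
})

test_that("numerator equal to denominator cancels exactly to unit weights", {
  cfg <- null_confounded_scenario(n = 400, horizon = 10)
  cohort <- generate_cohort(cfg, seed = 19)
  base <- names(cfg$baseline_covariate_spec)
  protocol <- trial_protocol(grace = 3, horizon = 10,
                             baseline_covariates = base,
                             timevarying_covariates = "frailty")
  # both models conditioned on baseline covariates only
  wcfg <- weight_model_config(denominator_covariates = base,
                              numerator_covariates = base)
  pp <- expand_person_periods(cohort, protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)
  den <- fit_initiation_model(pp, wcfg, protocol)
  num <- fit_initiation_model(pp, wcfg, protocol, use_numerator = TRUE)
  clw <- compute_stabilized_weights(cl, num, den, protocol,
                                    truncation_percentile = 1)
  expect_equal(clw$weight, rep(1, nrow(clw)), tolerance = 1e-12)

  d <- weight_diagnostics(clw)
  expect_true(all(abs(d$mean - 1) < 1e-12))
  expect_true(all(d$max <= 1 + 1e-12))
  expect_false(any(d$flag))
})

test_that("unstabilized control-arm weights reproduce the closed-form product", {
  # constant denominator probability 0.2, numerator = 1: an uncensored
  # control clone accumulates 1 / 0.8^min(t+1, grace) by direct arithmetic
  protocol <- trial_protocol(grace = 3, horizon = 8)
  pp <- pp_for(one_patient(event = 6L), protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)
  den <- constant_init_model(0.2)
  clw <- compute_stabilized_weights(cl, NULL, den, protocol,
                                    truncation_percentile = 1)
  ctrl <- clw[clw$arm == "control", ]
  expect_equal(ctrl$weight[ctrl$interval == 0], 1 / 0.8)
  expect_equal(ctrl$weight[ctrl$interval == 1], 1 / 0.8^2)
  expect_equal(ctrl$weight[ctrl$interval >= 2], rep(1 / 0.8^3, 5))
})

test_that("a denominator probability of one trips the positivity guard", {
  protocol <- trial_protocol(grace = 3, horizon = 8)
  pp <- pp_for(one_patient(event = 6L), protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)
  den <- constant_init_model(0.2)
  den$coefficients[["(Intercept)"]] <- 60 # p numerically 1
  expect_error(compute_stabilized_weights(cl, NULL, den, protocol, 1),
               class = "ccw_positivity_error")
})

test_that("weight truncation caps at the requested percentile", {
  cfg <- null_confounded_scenario(n = 800, horizon = 10)
  cohort <- generate_cohort(cfg, seed = 23)
  ac <- analysis_configs_for(cfg, truncation_percentile = 1)
  pp <- expand_person_periods(cohort, ac$protocol)
  cl <- apply_censoring(make_clones(pp, ac$protocol), ac$protocol)
  den <- fit_initiation_model(pp, ac$weight_config, ac$protocol)
  num <- fit_initiation_model(pp, ac$weight_config, ac$protocol,
                              use_numerator = TRUE)
  raw <- compute_stabilized_weights(cl, num, den, ac$protocol, 1)
  trunc <- compute_stabilized_weights(cl, num, den, ac$protocol, 0.995)
  cap <- quantile(raw$weight, 0.995, names = FALSE)
  expect_equal(max(trunc$weight), cap)
  expect_true(all(trunc$weight <= cap + 1e-12))
  expect_equal(trunc$weight[raw$weight <= cap], raw$weight[raw$weight <= cap])
})

test_that("stabilized weights from a correctly specified model stay near mean one", {
  cfg <- null_confounded_scenario(n = 5000, horizon = 16)
  cohort <- generate_cohort(cfg, seed = 55)
  ac <- analysis_configs_for(cfg)
  pp <- expand_person_periods(cohort, ac$protocol)
  cl <- apply_censoring(make_clones(pp, ac$protocol), ac$protocol)
  den <- fit_initiation_model(pp, ac$weight_config, ac$protocol)
  num <- fit_initiation_model(pp, ac$weight_config, ac$protocol,
                              use_numerator = TRUE)
  clw <- compute_stabilized_weights(cl, num, den, ac$protocol, 0.995)
  d <- weight_diagnostics(clw)
  expect_true(all(abs(d$mean - 1) < 0.05))
  # weighted pseudo-population size ~ retained person-time per arm
  by_arm <- dplyr::summarise(dplyr::group_by(clw, .data$arm),
                             n = dplyr::n(), w = sum(.data$weight))
  expect_true(all(abs(by_arm$w / by_arm$n - 1) < 0.05))
})
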
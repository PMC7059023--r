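test_that("cloning duplicates every person-period once per arm", {
  protocol <- trial_protocol(grace = 3, horizon = 60)
  pp <- pp_for(one_patient(event = 4L), protocol)
  cl <- make_clones(pp, protocol)
  expect_equal(nrow(cl), 10)
  expect_equal(sum(cl$arm == "treat"), 5)
  expect_equal(sum(cl$arm == "control"), 5)
  expect_true(all(cl$weight == 1))
  expect_false(any(cl$artificial_censor))

  empty <- make_clones(pp[0, ], protocol)
  expect_equal(nrow(empty), 0)

  expect_error(make_clones(dplyr::bind_rows(pp, pp[1, ]), protocol),
               class = "ccw_data_error")
})

test_that("clone-period count is twice the person-period count on synthetic data", {
  cfg <- scenario_config(n_patients = 100, horizon = 12, seed = 2)
  cohort <- generate_cohort(cfg)
  protocol <- trial_protocol(grace = 3, horizon = 12)
  pp <- expand_person_periods(cohort, protocol)
  cl <- make_clones(pp, protocol)
  expect_equal(nrow(cl), 2 * nrow(pp))
})

test_that("compatibility implements the grace-window censoring rules", {
  # control clones are censored the moment they initiate inside the grace
  # window, but initiation afterwards is protocol-compatible
  expect_equal(compatibility("control", TRUE, TRUE, t = 1, grace = 3),
               "censor-now")
  expect_equal(compatibility("control", TRUE, TRUE, t = 5, grace = 3),
               "compatible")
  # treat clones are censored at the close of the final grace interval if
  # still untreated
  expect_equal(compatibility("treat", FALSE, FALSE, t = 2, grace = 3),
               "censor-now")
  expect_equal(compatibility("treat", FALSE, FALSE, t = 1, grace = 3),
               "compatible")
  expect_equal(compatibility("treat", TRUE, FALSE, t = 2, grace = 3),
               "compatible")
  expect_error(compatibility("placebo", TRUE, TRUE, 0, 3),
               class = "ccw_config_error")
  expect_error(compatibility("treat", TRUE, TRUE, -1, 3),
               class = "ccw_config_error")
})

test_that("artificial censoring retains exactly the hand-enumerated periods", {
  protocol <- trial_protocol(grace = 3, horizon = 60)

  # initiates at t=1: the control clone keeps only its pre-initiation row,
  # the treat clone keeps full follow-up
  cl <- apply_censoring(make_clones(pp_for(one_patient(init = 1L, event = 9L),
                                           protocol), protocol), protocol)
  ctrl <- cl[cl$arm == "control", ]
  trt <- cl[cl$arm == "treat", ]
  expect_equal(ctrl$interval, 0L)
  expect_true(all(ctrl$artificial_censor))
  expect_false(any(ctrl$event))
  expect_equal(trt$interval, 0:9)
  expect_true(trt$event[10])

  # never initiates: the treat clone keeps t=0,1 and is censored at the
  # close of interval 2; the control clone keeps full follow-up
  cl2 <- apply_censoring(make_clones(pp_for(one_patient(event = 7L),
                                            protocol), protocol), protocol)
  expect_equal(cl2$interval[cl2$arm == "treat"], 0:1)
  expect_true(cl2$artificial_censor[cl2$arm == "treat"][2])
  expect_equal(cl2$interval[cl2$arm == "control"], 0:7)

  # death at t=0 before any initiation: both clones retain the death
  cl3 <- apply_censoring(make_clones(pp_for(one_patient(event = 0L),
                                            protocol), protocol), protocol)
  expect_equal(nrow(cl3), 2)
  expect_true(all(cl3$event))

  # control clone initiating and dying in the same grace interval is
  # censored there and its death excluded from the control risk set
  cl4 <- apply_censoring(make_clones(pp_for(one_patient(init = 2L, event = 2L),
                                            protocol), protocol), protocol)
  expect_equal(cl4$interval[cl4$arm == "control"], 0:1)
  expect_false(any(cl4$event[cl4$arm == "control"]))
  expect_true(any(cl4$event[cl4$arm == "treat"]))
})

test_that("person-time is conserved and no clone-period outlives its censoring", {
  cfg <- scenario_config(n_patients = 300, horizon = 15, seed = 6)
  cohort <- generate_cohort(cfg)
  protocol <- trial_protocol(grace = 3, horizon = 15)
  pp <- expand_person_periods(cohort, protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)

  # every observed person-period appears in at least one arm
  key_pp <- paste(pp$patient_id, pp$interval)
  key_cl <- paste(cl$patient_id, cl$interval)
  expect_true(all(key_pp %in% key_cl))

  # pre-initiation periods inside the grace window appear in both arms
  both <- pp[pp$interval < 2 & !pp$initiated_by_t, ]
  key_both <- paste(both$patient_id, both$interval)
  expect_true(all(table(key_cl[key_cl %in% key_both]) == 2))

  # artificial censoring only at grace-window intervals
  cens <- cl[cl$artificial_censor, ]
  expect_true(all(cens$interval <= protocol$grace - 1))
})

test_that("when everyone initiates at t=0 the control arm keeps nothing and the treat arm everything", {
  cfg <- flat_scenario(n = 200, horizon = 10, p_init = 1 - 1e-9, p_death = 0.1)
  cohort <- generate_cohort(cfg, seed = 14)
  stopifnot(all(cohort$patients$initiation_interval == 0, na.rm = TRUE))
  protocol <- trial_protocol(grace = 3, horizon = 10)
  pp <- expand_person_periods(cohort, protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)
  # initiation at t=0 is evaluated before outcomes, so control clones are
  # censored at t=0 and retain no rows
  expect_equal(sum(cl$arm == "control"), 0)
  expect_equal(sum(cl$arm == "treat"), nrow(pp))
  expect_false(any(cl$artificial_censor[cl$arm == "treat"]))
})
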
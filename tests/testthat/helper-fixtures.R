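# Minimal hand-built records for exact, enumerable checks.

one_patient <- function(init = NA_integer_, event = NA_integer_,
                        censor = NA_integer_, id = "A") {
  tibble::tibble(patient_id = id, initiation_interval = init,
                 event_interval = event, censor_interval = censor,
                 eligible = TRUE)
}

pp_for <- function(patients, protocol) {
  ev <- ifelse(is.na(patients$event_interval), Inf, patients$event_interval)
  cv <- ifelse(is.na(patients$censor_interval), Inf, patients$censor_interval)
  end <- pmin(ev, cv, 200)
  panel <- tibble::tibble(
    patient_id = rep(patients$patient_id, end + 1),
    interval = unlist(lapply(end + 1, function(k) 0:(k - 1)))
  )
  cohort <- ccwtte:::new_cohort(patients, panel, character(), character())
  expand_person_periods(cohort, protocol)
}
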
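#' Encode a target-trial protocol
#'
#' The machine form of a target-trial protocol table for a two-arm
#' initiation contrast: eligibility rules, the two strategies ("initiate
#' within the grace period" vs "do not initiate within the grace period"),
#' the grace-period length, and the follow-up horizon. After the grace
#' period both strategies leave treatment decisions unrestricted, so
#' artificial censoring can only happen during the grace window.
#'
#' @param grace Grace-period length in intervals (default 3, e.g. 3 months).
#' @param horizon Follow-up horizon in intervals (default 60 months).
#' @param baseline_covariates Names of baseline covariate columns.
#' @param timevarying_covariates Names of time-varying covariate columns.
#' @param arm_labels Named character vector `c(treat = ..., control = ...)`
#'   giving display labels for the two strategies.
#' @param interval_unit Free-text unit of one interval (e.g. "month").
#' @param eligibility List of [eligibility_rule()] objects, applied in order.
#' @return A `ccw_protocol` object.
#' @examples
#' protocol <- trial_protocol(
#'   grace = 3, horizon = 24,
#'   baseline_covariates = c("age", "stage2"),
#'   timevarying_covariates = "frailty",
#'   eligibility = list(rule_no_prior_initiation())
#' )
#' @export
trial_protocol <- function(grace = 3,
                           horizon = 60,
                           baseline_covariates = character(),
                           timevarying_covariates = character(),
                           arm_labels = c(treat = "initiate_within_grace",
                                          control = "never_initiate_in_grace"),
                           interval_unit = "month",
                           eligibility = list()) {
  assert_count(grace, "grace")
  assert_count(horizon, "horizon")
  if (grace > horizon) {
    abort("`grace` must not exceed `horizon`.", class = "ccw_config_error")
  }
  if (length(arm_labels) != 2 || !setequal(names(arm_labels), ARM_ROLES) ||
      arm_labels[1] == arm_labels[2]) {
    abort("`arm_labels` must be c(treat = ..., control = ...) with distinct labels.",
          class = "ccw_config_error")
  }
  reserved <- c("patient_id", "interval", "arm", "event", "admin_censored",
                "artificial_censor", "weight", "initiated_by_t",
                "initiates_at_t", "initiation_interval", "event_interval",
                "censor_interval", "eligible")
  clash <- intersect(c(baseline_covariates, timevarying_covariates), reserved)
  if (length(clash) > 0) {
    abort(sprintf("Covariate names clash with reserved columns: %s",
                  paste(clash, collapse = ", ")), class = "ccw_config_error")
  }
  if (anyDuplicated(c(baseline_covariates, timevarying_covariates))) {
    abort("Baseline and time-varying covariate names must be disjoint.",
          class = "ccw_config_error")
  }
  for (r in eligibility) {
    if (!inherits(r, "ccw_rule")) {
      abort("All `eligibility` entries must be eligibility_rule() objects.",
            class = "ccw_config_error")
    }
  }
  structure(list(
    grace = as.integer(grace),
    horizon = as.integer(horizon),
    baseline_covariates = baseline_covariates,
    timevarying_covariates = timevarying_covariates,
    arm_labels = arm_labels[ARM_ROLES],
    interval_unit = interval_unit,
    eligibility = eligibility
  ), class = "ccw_protocol")
}

#' @export
print.ccw_protocol <- function(x, ...) {
  cat("<ccw_protocol>\n")
  cat(sprintf("  arms: %s vs %s\n", x$arm_labels["treat"], x$arm_labels["control"]))
  cat(sprintf("  grace: %d %ss | horizon: %d %ss | %d eligibility rule(s)\n",
              x$grace, x$interval_unit, x$horizon, x$interval_unit,
              length(x$eligibility)))
  invisible(x)
}

#' Eligibility rules
#'
#' An eligibility rule names a predicate over the wide patient table; rules
#' are applied in the declared order and each excluded patient is tallied
#' under the first rule that fails (flow-diagram style accounting).
#'
#' @param name Short rule label used in the exclusion tally.
#' @param keep A function taking the patient tibble and returning a logical
#'   vector, `TRUE` for patients the rule retains.
#' @return A `ccw_rule`.
#' @examples
#' rule <- eligibility_rule("no interval-0 deaths",
#'   function(p) is.na(p$event_interval) | p$event_interval > 0)
#' @export
eligibility_rule <- function(name, keep) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort("`name` must be a non-empty string.", class = "ccw_config_error")
  }
  if (!is.function(keep)) {
    abort("`keep` must be a function of the patient table.", class = "ccw_config_error")
  }
  structure(list(name = name, keep = keep), class = "ccw_rule")
}

#' @rdname eligibility_rule
#' @export
rule_no_prior_initiation <- function() {
  eligibility_rule("no prior treatment", function(p) {
    is.na(p$initiation_interval) | p$initiation_interval >= 0
  })
}

#' @rdname eligibility_rule
#' @param k Minimum number of observed intervals.
#' @export
rule_min_followup <- function(k) {
  assert_count(k, "k")
  eligibility_rule(sprintf("followed for at least %d intervals", k), function(p) {
    end <- pmin(ifelse(is.na(p$event_interval), Inf, p$event_interval),
                ifelse(is.na(p$censor_interval), Inf, p$censor_interval))
    end + 1 >= k
  })
}

#' Apply eligibility rules to a cohort
#'
#' @param cohort A `ccw_cohort`.
#' @param protocol A `ccw_protocol`; its `eligibility` rules are applied in
#'   order with first-failing-rule attribution.
#' @return A list with `cohort` (the eligible subset, panel filtered to
#'   match) and `exclusions`, a tibble with one row per rule giving the
#'   number excluded by that rule.
#' @export
apply_eligibility <- function(cohort, protocol) {
  stopifnot(inherits(cohort, "ccw_cohort"), inherits(protocol, "ccw_protocol"))
  patients <- cohort$patients
  in_play <- rep(TRUE, nrow(patients))
  tally <- tibble::tibble(rule = character(), excluded = integer())
  for (r in protocol$eligibility) {
    keep <- r$keep(patients)
    if (!is.logical(keep) || length(keep) != nrow(patients)) {
      abort(sprintf("Rule '%s' must return one logical per patient.", r$name),
            class = "ccw_config_error")
    }
    keep[is.na(keep)] <- FALSE
    dropped <- in_play & !keep
    tally <- dplyr::bind_rows(tally,
      tibble::tibble(rule = r$name, excluded = sum(dropped)))
    in_play <- in_play & keep
  }
  patients$eligible <- in_play
  kept <- patients[in_play, , drop = FALSE]
  panel <- cohort$panel[cohort$panel$patient_id %in% kept$patient_id, , drop = FALSE]
  out <- new_cohort(kept, panel, cohort$baseline_covariates,
                    cohort$timevarying_covariates, cohort$config)
  list(cohort = out, exclusions = tally)
}

#' Expand patient records into discrete person-periods
#'
#' One row per patient per 0-based interval `[t, t + 1)` from 0 through the
#' end of follow-up: the earliest of the death interval, the administrative
#' censoring interval, and `horizon - 1`. Death during the interval is
#' attributed to that interval's row; events at or beyond the horizon are
#' administratively truncated and do not appear.
#'
#' @param cohort A `ccw_cohort` (typically the eligible subset).
#' @param protocol A `ccw_protocol`.
#' @return A person-period tibble with columns `patient_id`, `interval`,
#'   `initiated_by_t`, `initiates_at_t`, `event`, `admin_censored`, the
#'   baseline covariates and the time-varying covariates.
#' @examples
#' cfg <- scenario_config(n_patients = 50, horizon = 12, seed = 3)
#' cohort <- generate_cohort(cfg)
#' protocol <- trial_protocol(grace = 3, horizon = 12,
#'   baseline_covariates = cohort$baseline_covariates,
#'   timevarying_covariates = cohort$timevarying_covariates)
#' pp <- expand_person_periods(cohort, protocol)
#' @export
expand_person_periods <- function(cohort, protocol) {
  stopifnot(inherits(cohort, "ccw_cohort"), inherits(protocol, "ccw_protocol"))
  p <- cohort$patients
  H <- protocol$horizon
  ev <- ifelse(is.na(p$event_interval), Inf, p$event_interval)
  cv <- ifelse(is.na(p$censor_interval), Inf, p$censor_interval)
  end <- pmin(ev, cv, H - 1)
  n_per <- as.integer(end) + 1L

  idx <- rep(seq_len(nrow(p)), n_per)
  interval <- unlist(lapply(n_per, function(k) 0:(k - 1L)), use.names = FALSE)
  init <- p$initiation_interval[idx]
  out <- tibble::tibble(
    patient_id = p$patient_id[idx],
    interval = interval,
    initiates_at_t = !is.na(init) & interval == init,
    initiated_by_t = !is.na(init) & interval >= init,
    event = interval == ev[idx] & interval <= (H - 1),
    admin_censored = interval == cv[idx] & interval != ev[idx]
  )
  for (nm in protocol$baseline_covariates) {
    if (is.null(p[[nm]])) {
      abort(sprintf("Baseline covariate '%s' not found in cohort.", nm),
            class = "ccw_data_error")
    }
    out[[nm]] <- p[[nm]][idx]
  }
  if (length(protocol$timevarying_covariates) > 0) {
    key_pp <- paste(out$patient_id, out$interval)
    key_panel <- paste(cohort$panel$patient_id, cohort$panel$interval)
    pos <- match(key_pp, key_panel)
    if (anyNA(pos)) {
      bad <- unique(out$patient_id[is.na(pos)])
      abort(sprintf("Covariate path shorter than follow-up for patient(s): %s",
                    paste(head(bad, 5), collapse = ", ")),
            class = "ccw_data_error")
    }
    for (nm in protocol$timevarying_covariates) {
      if (is.null(cohort$panel[[nm]])) {
        abort(sprintf("Time-varying covariate '%s' not found in panel.", nm),
              class = "ccw_data_error")
      }
      out[[nm]] <- cohort$panel[[nm]][pos]
    }
  }
  out
}
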
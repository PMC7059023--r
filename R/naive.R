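#' Naive ever/never-treated hazard ratio (immortal-time-biased comparator)
#'
#' The flawed analysis the clone-censor-weight design replaces: patients are
#' assigned to the treated group if they initiated at any time during
#' follow-up and to the untreated group otherwise, follow-up for both groups
#' starts at time zero, and a proportional-hazards model with the group
#' indicator and baseline covariates is fit. Person-time before initiation
#' is misclassified as treated, so treated patients are guaranteed to
#' survive until their initiation ("immortal time") and the estimate is
#' biased toward protection even under a null effect.
#'
#' @param cohort A `ccw_cohort` of eligible patients.
#' @param protocol A `ccw_protocol`.
#' @param baseline_covariates Baseline covariates adjusted for.
#' @param time_terms Time basis for the pooled-logistic backend.
#' @param backend `"pooled-logistic"` (default) or `"cox"`.
#' @return A one-row `ccw_effect` tibble with `method = "naive"`.
#' @export
naive_ever_never_hr <- function(cohort, protocol,
                                baseline_covariates = protocol$baseline_covariates,
                                time_terms = time_quadratic(),
                                backend = c("pooled-logistic", "cox")) {
  backend <- match.arg(backend)
  stopifnot(inherits(cohort, "ccw_cohort"), inherits(protocol, "ccw_protocol"))
  pp <- expand_person_periods(cohort, protocol)
  ever_ids <- unique(pp$patient_id[pp$initiated_by_t])
  pp$ever <- pp$patient_id %in% ever_ids

  n_ever <- length(ever_ids)
  n_never <- length(unique(pp$patient_id)) - n_ever
  if (n_ever == 0 || n_never == 0) {
    abort(sprintf(
      "Naive analysis needs both groups populated (ever-treated: %d, never-treated: %d).",
      n_ever, n_never), class = "ccw_estimation_error")
  }
  for (g in c(TRUE, FALSE)) {
    if (sum(pp$event[pp$ever == g]) < 1) {
      abort(sprintf("No events in the %s-treated group.",
                    if (g) "ever" else "never"),
            class = "ccw_estimation_error")
    }
  }

  if (backend == "cox") {
    if (!requireNamespace("survival", quietly = TRUE)) {
      abort("The cox backend needs the survival package.", class = "ccw_config_error")
    }
    fml <- stats::as.formula(paste(
      "survival::Surv(interval, interval + 1, event) ~ ever",
      if (length(baseline_covariates) > 0)
        paste("+", paste(baseline_covariates, collapse = " + ")) else ""
    ))
    fit <- survival::coxph(fml, data = pp, ties = "breslow",
                           control = survival::coxph.control(timefix = FALSE))
    return(effect_estimate(unname(exp(stats::coef(fit)[["everTRUE"]])),
                           method = "naive"))
  }

  cfg <- outcome_model_config(
    time_terms = time_terms,
    include_treatment_time_products = FALSE,
    baseline_adjustment_covariates = baseline_covariates,
    horizon = protocol$horizon
  )
  # reuse the hazard-model machinery with "arm" standing for the ever flag
  pp$arm <- ifelse(pp$ever, "treat", "control")
  pp$weight <- 1
  fit <- fit_pooled_logistic(pp, cfg)
  effect_estimate(unname(exp(fit$coefficients[["arm"]])), method = "naive")
}
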
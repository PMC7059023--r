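#' Configure the discrete-time outcome model
#'
#' The outcome model is a weighted pooled logistic regression of death on
#' the assigned-strategy indicator, a function of follow-up time, optional
#' strategy-by-time product terms, and baseline covariates -- a
#' discrete-time hazard model whose fitted values are per-interval
#' conditional probabilities of death.
#'
#' @param time_terms A `ccw_time_spec`: [time_rcs()] (default, knots at
#'   3, 16, 30, 44, 57), [time_quadratic()], or [time_indicator()] for a
#'   saturated time effect.
#' @param include_treatment_time_products Include strategy-by-time product
#'   terms so the two arms have separate hazard shapes.
#' @param baseline_adjustment_covariates Baseline covariate names entering
#'   the model linearly.
#' @param horizon Follow-up horizon in intervals.
#' @return A `ccw_outcome_config`.
#' @export
outcome_model_config <- function(time_terms = time_rcs(),
                                 include_treatment_time_products = TRUE,
                                 baseline_adjustment_covariates = character(),
                                 horizon = 60) {
  assert_count(horizon, "horizon")
  if (!inherits(time_terms, "ccw_time_spec")) {
    abort("`time_terms` must be a ccw_time_spec.", class = "ccw_config_error")
  }
  structure(list(
    time_terms = time_terms,
    include_treatment_time_products = isTRUE(include_treatment_time_products),
    baseline_adjustment_covariates = baseline_adjustment_covariates,
    horizon = as.integer(horizon)
  ), class = "ccw_outcome_config")
}

# Design matrix for the outcome hazard model. `arm01` is the treat
# indicator; covariate columns are taken from `data`.
build_outcome_design <- function(data, arm01, config, spec) {
  n <- length(arm01)
  tb <- time_basis(data$interval, spec)
  x <- cbind("(Intercept)" = rep(1, n), arm = arm01, tb)
  if (config$include_treatment_time_products) {
    inter <- tb * arm01
    colnames(inter) <- paste0("arm:", colnames(tb))
    x <- cbind(x, inter)
  }
  for (nm in config$baseline_adjustment_covariates) {
    if (is.null(data[[nm]])) {
      abort(sprintf("Baseline covariate '%s' not found in clone-period data.", nm),
            class = "ccw_data_error")
    }
    x <- cbind(x, data[[nm]])
    colnames(x)[ncol(x)] <- nm
  }
  x
}

#' Fit the weighted pooled logistic discrete-time hazard model
#'
#' @param clone_periods Weighted, censored clone-period tibble (a `weight`
#'   column of 1s is used if absent).
#' @param config A `ccw_outcome_config`.
#' @return A `ccw_hazard_model` with coefficients, `vcov` (unit dispersion),
#'   the resolved time basis and the fitting configuration; supports
#'   [tidy()], [glance()] and [predict_hazard()].
#' @export
fit_pooled_logistic <- function(clone_periods, config) {
  stopifnot(is.data.frame(clone_periods), inherits(config, "ccw_outcome_config"))
  if (is.null(clone_periods$weight)) clone_periods$weight <- 1
  spec <- resolve_time_spec(config$time_terms, config$horizon)
  for (a in ARM_ROLES) {
    ev <- sum(clone_periods$event[clone_periods$arm == a])
    if (is.na(ev) || ev < 1) {
      abort(sprintf("No events in the %s arm: hazard model is not identifiable.", a),
            class = "ccw_estimation_error")
    }
  }
  arm01 <- as.numeric(clone_periods$arm == "treat")
  x <- build_outcome_design(clone_periods, arm01, config, spec)
  fit <- pooled_logit(x, clone_periods$event, weights = clone_periods$weight,
                      epsilon = 1e-12, maxit = 200L)
  if (!fit$converged) {
    abort(sprintf("Outcome model did not converge (deviance %.4g).", fit$deviance),
          class = "ccw_estimation_error")
  }
  structure(list(
    coefficients = fit$coefficients,
    vcov = fit$vcov,
    config = config,
    time_terms = spec,
    n = fit$n,
    n_events = sum(clone_periods$event),
    person_time = sum(clone_periods$weight),
    converged = fit$converged,
    deviance = fit$deviance
  ), class = "ccw_hazard_model")
}

#' @export
print.ccw_hazard_model <- function(x, ...) {
  cat("<ccw_hazard_model> weighted pooled logistic discrete-time hazard\n")
  cat(sprintf("  %d clone-periods (weighted person-time %.1f), %d events\n",
              x$n, x$person_time, x$n_events))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.ccw_hazard_model <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  est <- x$coefficients
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se)))
  )
}

#' @export
glance.ccw_hazard_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 person_time = x$person_time,
                 deviance = x$deviance, converged = x$converged)
}

#' Predicted discrete-time hazard
#'
#' @param model A `ccw_hazard_model`.
#' @param arm `"treat"` or `"control"`.
#' @param t Vector of 0-based intervals.
#' @param baseline One-row data frame (or `NULL`) with the baseline
#'   covariates used in the fit.
#' @return Per-interval conditional death probabilities.
#' @export
predict_hazard <- function(model, arm, t, baseline = NULL) {
  stopifnot(inherits(model, "ccw_hazard_model"))
  arm <- match_arm(arm)
  data <- tibble::tibble(interval = as.numeric(t))
  for (nm in model$config$baseline_adjustment_covariates) {
    if (is.null(baseline) || is.null(baseline[[nm]])) {
      abort(sprintf("`baseline` must supply covariate '%s'.", nm),
            class = "ccw_data_error")
    }
    data[[nm]] <- baseline[[nm]][1]
  }
  x <- build_outcome_design(data, rep(as.numeric(arm == "treat"), nrow(data)),
                            model$config, model$time_terms)
  plogis(design_eta(x, model$coefficients))
}

#' Standardized survival and risk curves (g-formula)
#'
#' Averages model-based conditional survival curves over the eligible
#' cohort's baseline-covariate distribution (each patient once, regardless
#' of cloning): for arm `a` and patient `i`,
#' `S_a(t | V_i) = prod_{k < t} (1 - h_a(k | V_i))`, and the standardized
#' survival at `t` is the mean over patients. Risk is `1 - survival`;
#' the risk difference is treat minus control at the stated horizon.
#'
#' @param model A `ccw_hazard_model`.
#' @param baseline_rows Tibble of eligible patients' baseline covariates,
#'   one row per patient.
#' @param rd_horizon Interval at which the risk difference is reported
#'   (defaults to the model horizon).
#' @return A `ccw_survival_result`: `curves` (arm, interval 1..horizon,
#'   risk, survival), `risk_difference`, and the horizon used.
#' @export
standardized_survival <- function(model, baseline_rows,
                                  rd_horizon = NULL) {
  stopifnot(inherits(model, "ccw_hazard_model"))
  H <- model$config$horizon
  rd_horizon <- rd_horizon %||% H
  if (rd_horizon < 1 || rd_horizon > H) {
    abort("`rd_horizon` must lie in 1..horizon.", class = "ccw_config_error")
  }
  covs <- model$config$baseline_adjustment_covariates
  cov_values <- matrix(numeric(0), nrow = max(1L, nrow(baseline_rows)), ncol = 0)
  for (nm in covs) {
    if (is.null(baseline_rows[[nm]])) {
      abort(sprintf("`baseline_rows` lacks covariate '%s'.", nm),
            class = "ccw_data_error")
    }
    cov_values <- cbind(cov_values, baseline_rows[[nm]])
    colnames(cov_values)[ncol(cov_values)] <- nm
  }
  std <- std_curves_from_beta(model$coefficients, model$config,
                              model$time_terms, cov_values)
  s_treat <- std$treat
  s_control <- std$control
  curves <- tibble::tibble(
    arm = rep(ARM_ROLES, each = H),
    interval = rep(seq_len(H), 2),
    survival = c(s_treat, s_control),
    risk = 1 - c(s_treat, s_control)
  )
  new_survival_result(curves, rd_horizon = rd_horizon)
}

# Standardization core shared by standardized_survival() and the
# resampling engine. The linear predictor splits additively into a patient
# part (intercept + baseline covariates) and an arm/time part, so hazards
# form an n x H outer sum; survival is the row-wise cumulative product.
std_curves_from_beta <- function(beta, config, spec, cov_values) {
  beta[is.na(beta)] <- 0
  H <- config$horizon
  n <- nrow(cov_values)
  cov_part <- rep(beta[["(Intercept)"]], n)
  if (ncol(cov_values) > 0) {
    cov_part <- cov_part + drop(cov_values %*% beta[colnames(cov_values)])
  }
  if (any(!is.finite(cov_part))) {
    abort("Non-finite linear predictor in standardization.",
          class = "ccw_numerical_error")
  }
  tb <- time_basis(0:(H - 1), spec)
  time_part <- drop(tb %*% beta[colnames(tb)])
  arm_part <- function(a01) {
    part <- time_part + a01 * beta[["arm"]]
    if (config$include_treatment_time_products) {
      part <- part + a01 * drop(tb %*% beta[paste0("arm:", colnames(tb))])
    }
    part
  }
  curve_for <- function(a01) {
    h <- plogis(outer(cov_part, arm_part(a01), `+`))
    surv <- matrix(1, n, H)
    acc <- rep(1, n)
    for (k in seq_len(H)) {
      acc <- acc * (1 - h[, k])
      surv[, k] <- acc
    }
    colMeans(surv)
  }
  list(treat = curve_for(1), control = curve_for(0))
}

new_survival_result <- function(curves, rd_horizon,
                                rd_ci = c(NA_real_, NA_real_)) {
  rt <- curves$risk[curves$arm == "treat" & curves$interval == rd_horizon]
  rc <- curves$risk[curves$arm == "control" & curves$interval == rd_horizon]
  structure(list(
    curves = curves,
    risk_difference = tibble::tibble(
      horizon = rd_horizon,
      estimate = rt - rc,
      ci_lower = rd_ci[1],
      ci_upper = rd_ci[2]
    ),
    horizon = max(curves$interval)
  ), class = "ccw_survival_result")
}

#' @export
print.ccw_survival_result <- function(x, ...) {
  cat("<ccw_survival_result> standardized survival by strategy\n")
  rd <- x$risk_difference
  last <- x$curves[x$curves$interval == x$horizon, ]
  cat(sprintf("  survival at %d: treat %.3f | control %.3f\n", x$horizon,
              last$survival[last$arm == "treat"],
              last$survival[last$arm == "control"]))
  cat(sprintf("  risk difference at %d: %+.4f", rd$horizon, rd$estimate))
  if (!is.na(rd$ci_lower)) {
    cat(sprintf(" (95%% CI %+.4f to %+.4f)", rd$ci_lower, rd$ci_upper))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.ccw_survival_result <- function(x, ...) x$curves

#' Effect estimates (hazard ratios)
#'
#' @param hazard_ratio Point estimate.
#' @param ci_lower,ci_upper Optional confidence bounds.
#' @param method One of `"unadjusted"`, `"baseline-adjusted"`,
#'   `"baseline+postbaseline"`, `"naive"`.
#' @return A one-row `ccw_effect` tibble.
#' @export
effect_estimate <- function(hazard_ratio, ci_lower = NA_real_,
                            ci_upper = NA_real_, method = "unadjusted") {
  if (!is.na(ci_lower) && !(ci_lower <= hazard_ratio && hazard_ratio <= ci_upper)) {
    abort("CI bounds must bracket the hazard ratio.", class = "ccw_config_error")
  }
  out <- tibble::tibble(
    method = method,
    hazard_ratio = hazard_ratio,
    ci_lower = ci_lower,
    ci_upper = ci_upper
  )
  class(out) <- c("ccw_effect", class(out))
  out
}

#' Marginal hazard ratio from weighted cloned person-time
#'
#' The trial-style marginal HR: a weighted pooled logistic model with the
#' strategy indicator and a time basis only (no products, no covariates),
#' whose exponentiated strategy coefficient approximates the weighted Cox
#' partial-likelihood estimate when per-interval hazards are small. A Cox
#' backend (via the survival package, counting-process form) is available
#' behind the same contract for cross-checking.
#'
#' @param clone_periods Weighted clone-period tibble.
#' @param time_terms Time basis for the pooled-logistic backend.
#' @param horizon Follow-up horizon (for resolving saturated bases).
#' @param backend `"pooled-logistic"` (default) or `"cox"`.
#' @param method Method label stored on the estimate.
#' @return A `ccw_effect` tibble with the hazard ratio.
#' @export
marginal_hazard_ratio <- function(clone_periods,
                                  time_terms = time_quadratic(),
                                  horizon = max(clone_periods$interval) + 1,
                                  backend = c("pooled-logistic", "cox"),
                                  method = "baseline+postbaseline") {
  backend <- match.arg(backend)
  if (is.null(clone_periods$weight)) clone_periods$weight <- 1
  if (backend == "cox") {
    if (!requireNamespace("survival", quietly = TRUE)) {
      abort("The cox backend needs the survival package.", class = "ccw_config_error")
    }
    d <- clone_periods
    d$arm01 <- as.numeric(d$arm == "treat")
    fit <- survival::coxph(
      survival::Surv(interval, interval + 1, event) ~ arm01,
      data = d, weights = d$weight, ties = "breslow",
      control = survival::coxph.control(timefix = FALSE)
    )
    return(effect_estimate(unname(exp(stats::coef(fit)[1])), method = method))
  }
  cfg <- outcome_model_config(
    time_terms = time_terms,
    include_treatment_time_products = FALSE,
    baseline_adjustment_covariates = character(),
    horizon = horizon
  )
  fit <- fit_pooled_logistic(clone_periods, cfg)
  effect_estimate(unname(exp(fit$coefficients[["arm"]])), method = method)
}

#' Hazard-ratio estimates under three adjustment strategies
#'
#' Runs the clone-censor pipeline three ways and returns the labelled
#' estimates: (1) unadjusted -- unit weights, no covariates; (2)
#' baseline-adjusted -- unit weights, baseline covariates in the outcome
#' model; (3) baseline + postbaseline -- stabilized
#' inverse-probability-of-censoring weights plus baseline covariates.
#'
#' @param cohort A `ccw_cohort`.
#' @param protocol A `ccw_protocol`.
#' @param weight_config A `ccw_weight_config`.
#' @param outcome_config A `ccw_outcome_config` (its
#'   `baseline_adjustment_covariates` are used for the adjusted flavors).
#' @return A three-row `ccw_effect` tibble.
#' @export
estimate_all_hr_flavors <- function(cohort, protocol, weight_config,
                                    outcome_config) {
  elig <- apply_eligibility(cohort, protocol)$cohort
  pp <- expand_person_periods(elig, protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)

  hr_for <- function(clones, covs, method) {
    cfg <- outcome_model_config(
      time_terms = outcome_config$time_terms,
      include_treatment_time_products = FALSE,
      baseline_adjustment_covariates = covs,
      horizon = outcome_config$horizon
    )
    fit <- fit_pooled_logistic(clones, cfg)
    effect_estimate(unname(exp(fit$coefficients[["arm"]])), method = method)
  }

  unadj <- hr_for(cl, character(), "unadjusted")
  badj <- hr_for(cl, outcome_config$baseline_adjustment_covariates,
                 "baseline-adjusted")
  den <- fit_initiation_model(pp, weight_config, protocol)
  num <- fit_initiation_model(pp, weight_config, protocol, use_numerator = TRUE)
  clw <- compute_stabilized_weights(cl, num, den, protocol,
                                    weight_config$truncation_percentile)
  full <- hr_for(clw, outcome_config$baseline_adjustment_covariates,
                 "baseline+postbaseline")
  out <- dplyr::bind_rows(unadj, badj, full)
  class(out) <- c("ccw_effect", class(out))
  out
}
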
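#' Configure the censoring-weight models
#'
#' Stabilized inverse-probability-of-censoring weights are built from two
#' pooled logistic models of treatment initiation fitted on the original
#' (un-cloned) person-periods still at risk of initiating inside the grace
#' window: a denominator model conditioning on baseline and time-varying
#' covariates, and a numerator model conditioning on baseline covariates
#' only. Because both arms' artificial-censoring processes are deterministic
#' functions of the single observed initiation process, one pair of models
#' weights both arms.
#'
#' @param denominator_covariates Covariate names for the denominator model
#'   (baseline + time-varying).
#' @param numerator_covariates Covariate names for the numerator model
#'   (baseline only); must be a subset of the denominator set.
#' @param time_terms A `ccw_time_spec` for the within-grace time effect.
#'   Defaults to interval indicators (a saturated time effect over the
#'   grace window).
#' @param truncation_percentile Cumulative weights are capped at this
#'   percentile of their distribution; `1` disables truncation.
#' @return A `ccw_weight_config`.
#' @export
weight_model_config <- function(denominator_covariates,
                                numerator_covariates = character(),
                                time_terms = time_indicator(),
                                truncation_percentile = 0.995) {
  if (!all(numerator_covariates %in% denominator_covariates)) {
    abort("`numerator_covariates` must be a subset of `denominator_covariates`.",
          class = "ccw_config_error")
  }
  assert_prob(truncation_percentile, "truncation_percentile", 0.5 + 1e-9, 1)
  if (!inherits(time_terms, "ccw_time_spec")) {
    abort("`time_terms` must be a ccw_time_spec.", class = "ccw_config_error")
  }
  structure(list(
    denominator_covariates = denominator_covariates,
    numerator_covariates = numerator_covariates,
    time_terms = time_terms,
    truncation_percentile = truncation_percentile
  ), class = "ccw_weight_config")
}

# Design matrix for an initiation model: intercept + covariates + grace-window
# time basis. `spec` must already be resolved (indicator levels fixed).
build_initiation_design <- function(data, covariates, spec) {
  n <- nrow(data)
  x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (nm in covariates) {
    if (is.null(data[[nm]])) {
      abort(sprintf("Covariate '%s' not found in person-period data.", nm),
            class = "ccw_data_error")
    }
    x <- cbind(x, data[[nm]])
    colnames(x)[ncol(x)] <- nm
  }
  cbind(x, time_basis(data$interval, spec))
}

# Risk set for the initiation models: original person-periods inside the
# grace window whose patient had not initiated before the interval started.
initiation_risk_set <- function(periods, grace) {
  periods$interval < grace &
    (!periods$initiated_by_t | periods$initiates_at_t)
}

#' Fit a pooled logistic model of treatment initiation
#'
#' Maximum-likelihood logistic regression of `initiates_at_t` on the
#' configured covariates and a grace-window time basis, fitted on the
#' original person-periods at risk of initiation (untreated at interval
#' start, interval before the end of the grace period).
#'
#' @param periods Person-period tibble from [expand_person_periods()]
#'   (un-cloned).
#' @param config A `ccw_weight_config`.
#' @param protocol A `ccw_protocol` (supplies the grace period).
#' @param use_numerator If `TRUE`, fit the numerator (baseline-only) model;
#'   otherwise the denominator model.
#' @return A `ccw_initiation_model` with `coefficients`, `vcov`, the risk-set
#'   size and event count; supports [tidy()], [glance()] and `predict()`
#'   (returning per-interval initiation probabilities).
#' @export
fit_initiation_model <- function(periods, config, protocol,
                                 use_numerator = FALSE) {
  stopifnot(inherits(config, "ccw_weight_config"),
            inherits(protocol, "ccw_protocol"))
  spec <- resolve_time_spec(config$time_terms, protocol$grace)
  if (spec$kind == "indicator" && length(spec$levels) > protocol$grace) {
    spec$levels <- 0:(protocol$grace - 1)
  }
  covs <- if (use_numerator) config$numerator_covariates else config$denominator_covariates
  rs <- periods[initiation_risk_set(periods, protocol$grace), , drop = FALSE]
  if (nrow(rs) == 0) {
    abort("Empty initiation risk set: no untreated person-time inside the grace window.",
          class = "ccw_estimation_error")
  }
  y <- rs$initiates_at_t
  if (all(y) || !any(y)) {
    abort(sprintf(
      "Degenerate initiation response: %s of %d risk-set rows initiate.",
      if (any(y)) "all" else "none", length(y)),
      class = "ccw_estimation_error")
  }
  x <- build_initiation_design(rs, covs, spec)
  fit <- pooled_logit(x, y)
  if (!fit$converged) {
    abort(sprintf(
      "Initiation model did not converge (deviance %.4g, %d rows, %d events).",
      fit$deviance, fit$n, sum(y)), class = "ccw_estimation_error")
  }
  if (max(abs(fit$coefficients), na.rm = TRUE) > 15) {
    abort("Initiation model shows signs of separation (|coefficient| > 15).",
          class = "ccw_estimation_error")
  }
  structure(list(
    coefficients = fit$coefficients,
    vcov = fit$vcov,
    covariates = covs,
    time_terms = spec,
    role = if (use_numerator) "numerator" else "denominator",
    grace = protocol$grace,
    n = fit$n,
    n_events = sum(y),
    converged = fit$converged,
    deviance = fit$deviance
  ), class = "ccw_initiation_model")
}

#' @export
predict.ccw_initiation_model <- function(object, newdata, ...) {
  x <- build_initiation_design(newdata, object$covariates, object$time_terms)
  plogis(design_eta(x, object$coefficients))
}

#' @export
print.ccw_initiation_model <- function(x, ...) {
  cat(sprintf("<ccw_initiation_model: %s>\n", x$role))
  cat(sprintf("  %d person-periods at risk, %d initiations, grace %d\n",
              x$n, x$n_events, x$grace))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Per-interval stabilized weight contribution of each retained clone row.
# Control arm, inside grace (necessarily still untreated): ratio of the
# probabilities of NOT initiating. Treat arm: 1 except at the final grace
# interval, where clones initiating exactly then contribute the ratio of
# initiation probabilities; clones that initiated earlier contribute 1.
weight_contributions <- function(arm, interval, initiates_at_t, initiated_by_t,
                                 grace, p_num, p_den) {
  contrib <- rep(1, length(arm))
  is_c <- arm == "control" & interval < grace
  is_t <- arm == "treat" & interval == grace - 1 & initiates_at_t
  bad <- (is_c & p_den >= 1 - 1e-12) | (is_t & p_den <= 1e-12)
  if (any(bad)) {
    abort(sprintf(
      "Positivity violation: initiation probability numerically 0 or 1 on %d retained row(s) (first offending rows: %s).",
      sum(bad), paste(head(which(bad), 5), collapse = ", ")),
      class = "ccw_positivity_error")
  }
  contrib[is_c] <- (1 - p_num[is_c]) / (1 - p_den[is_c])
  contrib[is_t] <- p_num[is_t] / p_den[is_t]
  contrib
}

#' Attach stabilized inverse-probability-of-censoring weights to clones
#'
#' Computes each clone-period's stabilized weight contribution from the
#' fitted numerator and denominator initiation models, accumulates them
#' multiplicatively within each clone, and truncates the cumulative weights
#' at the configured percentile.
#'
#' Passing `num_model = NULL` yields unstabilized weights (numerator
#' probability of remaining uncensored taken as 1).
#'
#' @param clone_periods Censored clone-period tibble from [apply_censoring()].
#' @param num_model,den_model `ccw_initiation_model`s from
#'   [fit_initiation_model()].
#' @param protocol A `ccw_protocol`.
#' @param truncation_percentile Cap for cumulative weights; defaults to no
#'   truncation when `NULL` config is given here.
#' @return `clone_periods` with the `weight` column replaced by cumulative
#'   stabilized weights.
#' @export
compute_stabilized_weights <- function(clone_periods, num_model, den_model,
                                       protocol, truncation_percentile = 0.995) {
  stopifnot(inherits(protocol, "ccw_protocol"),
            inherits(den_model, "ccw_initiation_model"))
  if (!is.null(num_model)) stopifnot(inherits(num_model, "ccw_initiation_model"))
  assert_prob(truncation_percentile, "truncation_percentile", 0.5 + 1e-9, 1)
  cp <- dplyr::arrange(clone_periods, .data$patient_id, .data$arm, .data$interval)
  if (nrow(cp) == 0) return(cp)
  grace <- protocol$grace
  need <- (cp$arm == "control" & cp$interval < grace) |
    (cp$arm == "treat" & cp$interval == grace - 1 & cp$initiates_at_t)
  p_den <- rep(NA_real_, nrow(cp))
  p_num <- rep(NA_real_, nrow(cp))
  if (any(need)) {
    p_den[need] <- predict(den_model, cp[need, , drop = FALSE])
    p_num[need] <- if (is.null(num_model)) {
      # unstabilized: numerator remains-uncensored probability is 1, i.e.
      # p_num = 0 for the control contribution and 1 for the treat ratio
      ifelse(cp$arm[need] == "treat", 1, 0)
    } else {
      predict(num_model, cp[need, , drop = FALSE])
    }
  }
  contrib <- weight_contributions(cp$arm, cp$interval, cp$initiates_at_t,
                                  cp$initiated_by_t, grace, p_num, p_den)
  starts <- !duplicated(cp[c("patient_id", "arm")])
  w <- group_cumprod(contrib, starts)
  if (truncation_percentile < 1) {
    cap <- quantile(w, truncation_percentile, names = FALSE, type = 7)
    w <- pmin(w, cap)
  }
  cp$weight <- w
  cp
}

#' Summarize cumulative weights by arm and interval
#'
#' Standard inverse-probability-weight diagnostics: stabilized cumulative
#' weights should have mean close to 1 in every interval when the
#' initiation models are correctly specified.
#'
#' @param clone_periods Weighted clone-period tibble.
#' @param tolerance Mean deviation from 1 beyond which an interval is
#'   flagged.
#' @return A tibble with per-arm, per-interval `n`, `mean`, `sd`, `p50`,
#'   `p99`, `max` of the cumulative weights and a `flag` column.
#' @export
weight_diagnostics <- function(clone_periods, tolerance = 0.05) {
  stopifnot(is.data.frame(clone_periods))
  clone_periods |>
    dplyr::group_by(.data$arm, .data$interval) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$weight),
      sd = sd(.data$weight),
      p50 = quantile(.data$weight, 0.5, names = FALSE),
      p99 = quantile(.data$weight, 0.99, names = FALSE),
      max = max(.data$weight),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = abs(.data$mean - 1) > tolerance)
}

#' @export
tidy.ccw_initiation_model <- function(x, ...) {
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
glance.ccw_initiation_model <- function(x, ...) {
  tibble::tibble(
    role = x$role, n = x$n, n_events = x$n_events,
    deviance = x$deviance, converged = x$converged
  )
}
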
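#' Configure the nonparametric bootstrap
#'
#' Confidence intervals for risks, risk differences and hazard ratios are
#' obtained by resampling patients with replacement (both clones of a
#' resampled patient enter together) and re-running the entire pipeline --
#' artificial censoring, weight-model fitting, outcome fitting and
#' standardization -- inside every resample, so the intervals reflect
#' weight-estimation uncertainty. Percentile intervals are reported.
#'
#' @param n_resamples Number of bootstrap resamples (default 500).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling stream.
#' @return A `ccw_boot_config`.
#' @export
bootstrap_config <- function(n_resamples = 500, ci_level = 0.95, seed = NULL) {
  assert_count(n_resamples, "n_resamples", min = 2L)
  assert_prob(ci_level, "ci_level", 1e-6, 1 - 1e-6)
  if (!is.null(seed)) assert_count(seed, "seed", min = 0L)
  structure(list(
    n_resamples = as.integer(n_resamples),
    ci_level = ci_level,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "ccw_boot_config")
}

#' Bootstrap confidence intervals for the clone-censor-weight pipeline
#'
#' @param cohort A `ccw_cohort` (eligibility is applied internally).
#' @param protocol A `ccw_protocol`.
#' @param weight_config A `ccw_weight_config`.
#' @param outcome_config A `ccw_outcome_config`.
#' @param boot_config A `ccw_boot_config`.
#' @param estimands Subset of `c("hr", "hr_adjusted", "risk_difference",
#'   "survival")`: `"hr"` is the marginal weighted hazard ratio (strategy +
#'   time only), `"hr_adjusted"` additionally conditions the outcome model
#'   on the baseline covariates.
#' @param rd_horizon Interval for the risk difference (default: horizon).
#' @return A `ccw_boot` list: `hr` (a `ccw_effect` with CI), `survival`
#'   (a `ccw_survival_result` with CI columns when curves were requested),
#'   `resamples` (per-resample estimates), `n_failed`, and the config.
#'   Resamples where estimation fails are dropped and counted; more than
#'   20% failures is an error.
#' @export
bootstrap_ci <- function(cohort, protocol, weight_config, outcome_config,
                         boot_config = bootstrap_config(),
                         estimands = c("hr", "hr_adjusted", "risk_difference",
                                       "survival"),
                         rd_horizon = NULL) {
  stopifnot(inherits(boot_config, "ccw_boot_config"))
  estimands <- match.arg(estimands, several.ok = TRUE)
  if (is.null(boot_config$seed)) {
    abort("`boot_config$seed` is required for a reproducible bootstrap.",
          class = "ccw_config_error")
  }
  engine <- build_ccw_engine(cohort, protocol, weight_config, outcome_config)
  point <- run_ccw_engine(engine, NULL, estimands = estimands,
                          rd_horizon = rd_horizon)
  B <- boot_config$n_resamples
  n <- engine$n
  H <- outcome_config$horizon
  want_curves <- any(c("risk_difference", "survival") %in% estimands)

  hr_b <- rep(NA_real_, B)
  hra_b <- rep(NA_real_, B)
  rd_b <- rep(NA_real_, B)
  rt_b <- if (want_curves) matrix(NA_real_, B, H) else NULL
  rc_b <- if (want_curves) matrix(NA_real_, B, H) else NULL
  n_failed <- 0L
  with_seed(boot_config$seed, {
    for (b in seq_len(B)) {
      pids <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(
        run_ccw_engine(engine, pids, estimands = estimands,
                       rd_horizon = rd_horizon),
        error = function(e) NULL
      )
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      if ("hr" %in% estimands) hr_b[b] <- res$hr
      if ("hr_adjusted" %in% estimands) hra_b[b] <- res$hr_adjusted
      if (want_curves) {
        rd_b[b] <- res$risk_difference
        rt_b[b, ] <- res$risk_treat
        rc_b[b, ] <- res$risk_control
      }
    }
  })
  if (n_failed > 0.2 * B) {
    abort(sprintf("Bootstrap failed in %d of %d resamples (> 20%%).",
                  n_failed, B), class = "ccw_inference_error")
  }
  lvl <- boot_config$ci_level

  hr <- NULL
  if ("hr" %in% estimands) {
    ci <- percentile_ci(hr_b, lvl)
    hr <- effect_estimate(point$hr, ci[1], ci[2],
                          method = "baseline+postbaseline")
  }
  hr_adjusted <- NULL
  if ("hr_adjusted" %in% estimands) {
    ci <- percentile_ci(hra_b, lvl)
    hr_adjusted <- effect_estimate(point$hr_adjusted, ci[1], ci[2],
                                   method = "baseline+postbaseline")
  }
  surv <- NULL
  if (want_curves) {
    rd_ci <- percentile_ci(rd_b, lvl)
    curves <- tibble::tibble(
      arm = rep(ARM_ROLES, each = H),
      interval = rep(seq_len(H), 2),
      risk = c(point$risk_treat, point$risk_control),
      survival = 1 - c(point$risk_treat, point$risk_control),
      risk_ci_lower = c(apply(rt_b, 2, function(z) percentile_ci(z, lvl)[1]),
                        apply(rc_b, 2, function(z) percentile_ci(z, lvl)[1])),
      risk_ci_upper = c(apply(rt_b, 2, function(z) percentile_ci(z, lvl)[2]),
                        apply(rc_b, 2, function(z) percentile_ci(z, lvl)[2]))
    )
    surv <- new_survival_result(curves, rd_horizon = point$rd_horizon,
                                rd_ci = rd_ci)
    if (!is.na(surv$risk_difference$estimate) &&
        (surv$risk_difference$estimate < rd_ci[1] ||
         surv$risk_difference$estimate > rd_ci[2])) {
      warn("Percentile CI does not contain the point risk difference; inspect the resample distribution.")
    }
  }
  if (!is.null(hr) && !is.na(hr$ci_lower) &&
      (hr$hazard_ratio < hr$ci_lower || hr$hazard_ratio > hr$ci_upper)) {
    warn("Percentile CI does not contain the point hazard ratio; inspect the resample distribution.")
  }
  structure(list(
    hr = hr,
    hr_adjusted = hr_adjusted,
    survival = surv,
    resamples = tibble::tibble(resample = seq_len(B), hr = hr_b,
                               hr_adjusted = hra_b,
                               risk_difference = rd_b),
    n_failed = n_failed,
    config = boot_config
  ), class = "ccw_boot")
}

#' @export
print.ccw_boot <- function(x, ...) {
  cat(sprintf("<ccw_boot> %d resamples (%d failed), %.0f%% percentile CIs\n",
              x$config$n_resamples, x$n_failed, 100 * x$config$ci_level))
  if (!is.null(x$hr)) {
    cat(sprintf("  HR %.3f (%.3f to %.3f)\n", x$hr$hazard_ratio,
                x$hr$ci_lower, x$hr$ci_upper))
  }
  if (!is.null(x$survival)) print(x$survival)
  invisible(x)
}
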
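#' Baseline covariate distributions for the synthetic cohort generator
#'
#' Small descriptor objects used in `baseline_covariate_spec`:
#' `cov_normal()` draws a Gaussian covariate (e.g. a standardized age or
#' comorbidity score), `cov_binary()` a Bernoulli indicator (e.g. advanced
#' stage, poor performance status), `cov_uniform()` a uniform covariate.
#'
#' @param mean,sd,p,min,max Distribution parameters.
#' @return A covariate-distribution descriptor.
#' @export
cov_normal <- function(mean = 0, sd = 1) {
  structure(list(dist = "normal", mean = mean, sd = sd), class = "ccw_cov_spec")
}

#' @rdname cov_normal
#' @export
cov_binary <- function(p = 0.5) {
  assert_prob(p, "p")
  structure(list(dist = "binary", p = p), class = "ccw_cov_spec")
}

#' @rdname cov_normal
#' @export
cov_uniform <- function(min = 0, max = 1) {
  structure(list(dist = "uniform", min = min, max = max), class = "ccw_cov_spec")
}

draw_covariate <- function(spec, n) {
  switch(spec$dist,
    normal = rnorm(n, spec$mean, spec$sd),
    binary = rbinom(n, 1, spec$p),
    uniform = runif(n, spec$min, spec$max),
    abort(sprintf("Unknown covariate distribution '%s'.", spec$dist),
          class = "ccw_config_error")
  )
}

#' Configure a synthetic claims-like cohort scenario
#'
#' Defines the data-generating process for a discrete-time observational
#' cohort of the kind the clone-censor-weight design targets: baseline
#' confounders, one autoregressive time-varying prognostic covariate (a
#' declining-health / performance-status proxy), confounded treatment
#' initiation concentrated early in follow-up, and death from a per-interval
#' logistic hazard with a constant multiplicative treatment effect on the
#' death odds from initiation onward.
#'
#' Per-interval models are logistic. The initiation model (while still
#' untreated) has linear predictor
#' `intercept + time * t + coefficients on baseline and time-varying covariates`;
#' the death model adds the treatment indicator times `true_log_hr`.
#' Coefficient vectors are named: `"(Intercept)"`, optionally `"time"`, and
#' covariate names. The time-varying covariate follows an AR(1) process
#' around a baseline-shifted, slowly drifting mean.
#'
#' @param n_patients Number of patients to simulate.
#' @param horizon Number of discrete follow-up intervals (months by default
#'   elsewhere in the package).
#' @param grace Grace-period length in intervals (default 3).
#' @param true_log_hr True log multiplicative effect of treatment on the
#'   per-interval death odds; 0 is the null.
#' @param baseline_covariate_spec Named list of covariate descriptors
#'   (`cov_normal()`, `cov_binary()`, `cov_uniform()`).
#' @param init_model_coefs Named coefficients of the per-interval
#'   treatment-initiation log-odds.
#' @param death_model_coefs Named coefficients of the per-interval death
#'   log-odds (before the treatment term).
#' @param timevarying_name Name of the time-varying covariate column.
#' @param timevarying_ar_coef AR(1) autocorrelation in `[0, 1)`.
#' @param timevarying_mean_coefs Named coefficients (`"(Intercept)"` +
#'   baseline names) of the covariate's long-run mean.
#' @param timevarying_sd Innovation standard deviation.
#' @param timevarying_drift Additive drift of the long-run mean per interval
#'   (positive = health worsens over time).
#' @param admin_censor_fraction Fraction of patients given a uniformly drawn
#'   administrative censoring interval.
#' @param seed Integer seed making `generate_cohort()` deterministic.
#' @return A `ccw_scenario` configuration object.
#' @examples
#' cfg <- scenario_config(n_patients = 200, horizon = 12, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
scenario_config <- function(n_patients = 2000,
                            horizon = 24,
                            grace = 3,
                            true_log_hr = 0,
                            baseline_covariate_spec = list(
                              age = cov_normal(0, 1),
                              stage2 = cov_binary(0.35),
                              comorbidity = cov_normal(0, 1),
                              poorperf = cov_binary(0.2)
                            ),
                            init_model_coefs = c(
                              "(Intercept)" = -2.0, time = -0.5,
                              age = -0.4, stage2 = 0.4, comorbidity = 0.2,
                              poorperf = -0.5, frailty = -0.3
                            ),
                            death_model_coefs = c(
                              "(Intercept)" = -3.5, time = 0.02,
                              age = 0.35, stage2 = 0.6, comorbidity = 0.3,
                              poorperf = 0.5, frailty = 0.4
                            ),
                            timevarying_name = "frailty",
                            timevarying_ar_coef = 0.7,
                            timevarying_mean_coefs = c(
                              "(Intercept)" = 0, age = 0.2, stage2 = 0.3,
                              comorbidity = 0.3, poorperf = 0.4
                            ),
                            timevarying_sd = 0.5,
                            timevarying_drift = 0.03,
                            admin_censor_fraction = 0.1,
                            seed = NULL) {
  assert_count(n_patients, "n_patients")
  assert_count(horizon, "horizon")
  assert_count(grace, "grace")
  if (grace > horizon) {
    abort("`grace` must not exceed `horizon`.", class = "ccw_config_error")
  }
  if (!is.numeric(true_log_hr) || length(true_log_hr) != 1 || !is.finite(true_log_hr)) {
    abort("`true_log_hr` must be a single finite number.", class = "ccw_config_error")
  }
  if (length(baseline_covariate_spec) == 0 ||
      is.null(names(baseline_covariate_spec)) ||
      any(names(baseline_covariate_spec) == "")) {
    abort("`baseline_covariate_spec` must be a non-empty named list.",
          class = "ccw_config_error")
  }
  if (!all(vapply(baseline_covariate_spec, inherits, logical(1), "ccw_cov_spec"))) {
    abort("`baseline_covariate_spec` entries must be cov_normal()/cov_binary()/cov_uniform().",
          class = "ccw_config_error")
  }
  assert_prob(timevarying_ar_coef, "timevarying_ar_coef", 0, 1 - 1e-12)
  assert_prob(admin_censor_fraction, "admin_censor_fraction")
  valid_names <- c("(Intercept)", "time", names(baseline_covariate_spec),
                   timevarying_name)
  for (nm in c("init_model_coefs", "death_model_coefs", "timevarying_mean_coefs")) {
    v <- get(nm)
    if (!is.numeric(v) || is.null(names(v)) || !all(is.finite(v))) {
      abort(sprintf("`%s` must be a named, finite numeric vector.", nm),
            class = "ccw_config_error")
    }
    bad <- setdiff(names(v), valid_names)
    if (length(bad) > 0) {
      abort(sprintf("`%s` refers to unknown covariates: %s", nm,
                    paste(bad, collapse = ", ")),
            class = "ccw_config_error")
    }
  }
  if (!is.numeric(timevarying_sd) || timevarying_sd < 0) {
    abort("`timevarying_sd` must be a non-negative number.", class = "ccw_config_error")
  }
  if (!is.null(seed)) assert_count(seed, "seed", min = 0L)
  structure(list(
    n_patients = as.integer(n_patients),
    horizon = as.integer(horizon),
    grace = as.integer(grace),
    true_log_hr = true_log_hr,
    baseline_covariate_spec = baseline_covariate_spec,
    init_model_coefs = init_model_coefs,
    death_model_coefs = death_model_coefs,
    timevarying_name = timevarying_name,
    timevarying_ar_coef = timevarying_ar_coef,
    timevarying_mean_coefs = timevarying_mean_coefs,
    timevarying_sd = timevarying_sd,
    timevarying_drift = timevarying_drift,
    admin_censor_fraction = admin_censor_fraction,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "ccw_scenario")
}

#' @export
print.ccw_scenario <- function(x, ...) {
  cat("<ccw_scenario>\n")
  cat(sprintf("  patients: %d | horizon: %d | grace: %d | true log HR: %.3f\n",
              x$n_patients, x$horizon, x$grace, x$true_log_hr))
  cat(sprintf("  baseline covariates: %s\n",
              paste(names(x$baseline_covariate_spec), collapse = ", ")))
  cat(sprintf("  time-varying: %s (AR %.2f) | admin censoring: %.0f%%\n",
              x$timevarying_name, x$timevarying_ar_coef,
              100 * x$admin_censor_fraction))
  invisible(x)
}
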
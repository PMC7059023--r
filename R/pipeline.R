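#' Run the full clone-censor-weight emulation on a cohort
#'
#' Orchestrates eligibility, person-period expansion, cloning, artificial
#' censoring, stabilized weighting, the weighted pooled logistic outcome
#' model, standardization, the marginal hazard ratio, the naive ever/never
#' comparator, and (optionally) the patient-level bootstrap.
#'
#' @param cohort A `ccw_cohort`.
#' @param protocol A `ccw_protocol`.
#' @param weight_config A `ccw_weight_config`.
#' @param outcome_config A `ccw_outcome_config`.
#' @param boot_config Optional `ccw_boot_config` for confidence intervals.
#' @param naive Include the naive ever/never comparator estimate.
#' @param rd_horizon Interval at which the risk difference is reported.
#' @return A `ccw_emulation` list: `survival` (standardized curves and risk
#'   difference), `marginal_hr` (the trial-style weighted hazard ratio from
#'   the strategy-plus-time model), `estimates` (a `ccw_effect` tibble:
#'   unadjusted, baseline-adjusted, baseline+postbaseline, and optionally
#'   naive), `hazard_model`, initiation models, `weight_diagnostics`, stage
#'   row counts, `exclusions`, and the component tables.
#' @examples
#' cfg <- scenario_config(n_patients = 300, horizon = 12, seed = 11)
#' cohort <- generate_cohort(cfg)
#' protocol <- trial_protocol(grace = 3, horizon = 12,
#'   baseline_covariates = cohort$baseline_covariates,
#'   timevarying_covariates = cohort$timevarying_covariates)
#' wcfg <- weight_model_config(
#'   denominator_covariates = c(cohort$baseline_covariates,
#'                              cohort$timevarying_covariates),
#'   numerator_covariates = cohort$baseline_covariates)
#' ocfg <- outcome_model_config(time_terms = time_quadratic(),
#'   baseline_adjustment_covariates = cohort$baseline_covariates,
#'   horizon = 12)
#' fit <- ccw_emulate(cohort, protocol, wcfg, ocfg)
#' fit$estimates
#' @export
ccw_emulate <- function(cohort, protocol, weight_config, outcome_config,
                        boot_config = NULL, naive = TRUE, rd_horizon = NULL) {
  elig <- apply_eligibility(cohort, protocol)
  pp <- expand_person_periods(elig$cohort, protocol)
  clones <- make_clones(pp, protocol)
  cl <- apply_censoring(clones, protocol)
  den <- fit_initiation_model(pp, weight_config, protocol)
  num <- fit_initiation_model(pp, weight_config, protocol, use_numerator = TRUE)
  clw <- compute_stabilized_weights(cl, num, den, protocol,
                                    weight_config$truncation_percentile)
  diagnostics <- weight_diagnostics(clw)
  hazard_model <- fit_pooled_logistic(clw, outcome_config)
  survival <- standardized_survival(hazard_model, elig$cohort$patients,
                                    rd_horizon = rd_horizon)
  marginal_hr <- marginal_hazard_ratio(clw, time_terms = outcome_config$time_terms,
                                       horizon = outcome_config$horizon)
  estimates <- estimate_all_hr_flavors(cohort, protocol, weight_config,
                                       outcome_config)
  if (isTRUE(naive)) {
    estimates <- dplyr::bind_rows(
      estimates,
      naive_ever_never_hr(elig$cohort, protocol,
                          outcome_config$baseline_adjustment_covariates)
    )
  }
  boot <- NULL
  if (!is.null(boot_config)) {
    boot <- bootstrap_ci(cohort, protocol, weight_config, outcome_config,
                         boot_config, rd_horizon = rd_horizon)
    survival <- boot$survival %||% survival
    estimates$ci_lower[estimates$method == "baseline+postbaseline"] <-
      boot$hr_adjusted$ci_lower
    estimates$ci_upper[estimates$method == "baseline+postbaseline"] <-
      boot$hr_adjusted$ci_upper
    marginal_hr$ci_lower <- boot$hr$ci_lower
    marginal_hr$ci_upper <- boot$hr$ci_upper
  }
  class(estimates) <- c("ccw_effect", class(tibble::tibble()))
  structure(list(
    survival = survival,
    estimates = estimates,
    marginal_hr = marginal_hr,
    hazard_model = hazard_model,
    initiation_models = list(numerator = num, denominator = den),
    weight_diagnostics = diagnostics,
    bootstrap = boot,
    exclusions = elig$exclusions,
    person_periods = pp,
    clone_periods = clw,
    counts = list(
      patients_in = nrow(cohort$patients),
      eligible = nrow(elig$cohort$patients),
      person_periods = nrow(pp),
      clone_periods = nrow(clones),
      clone_periods_censored = nrow(cl)
    ),
    protocol = protocol
  ), class = "ccw_emulation")
}

#' @export
print.ccw_emulation <- function(x, ...) {
  cat("<ccw_emulation> clone-censor-weight target trial emulation\n")
  cat(sprintf("  %d patients in, %d eligible; %d person-periods -> %d retained clone-periods\n",
              x$counts$patients_in, x$counts$eligible,
              x$counts$person_periods, x$counts$clone_periods_censored))
  print(x$survival)
  m <- x$marginal_hr
  cat(sprintf("  marginal HR (strategy-only weighted model): %.3f", m$hazard_ratio))
  if (!is.na(m$ci_lower)) cat(sprintf(" (%.3f to %.3f)", m$ci_lower, m$ci_upper))
  cat("\n  hazard ratios by adjustment:\n")
  df <- as.data.frame(x$estimates)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("    %-24s %.3f", df$method[i], df$hazard_ratio[i]))
    if (!is.na(df$ci_lower[i])) {
      cat(sprintf(" (%.3f to %.3f)", df$ci_lower[i], df$ci_upper[i]))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
glance.ccw_emulation <- function(x, ...) {
  tibble::tibble(
    patients = x$counts$patients_in,
    eligible = x$counts$eligible,
    clone_periods = x$counts$clone_periods_censored,
    events = x$hazard_model$n_events,
    hr_marginal = x$marginal_hr$hazard_ratio,
    hr_adjusted = x$estimates$hazard_ratio[x$estimates$method == "baseline+postbaseline"],
    risk_difference = x$survival$risk_difference$estimate
  )
}

#' Analysis configurations implied by a simulation scenario
#'
#' Convenience constructor for analysing a synthetic cohort under the
#' scenario that generated it: a protocol on the scenario's interval grid
#' and grace period, a weight model with denominator = baseline +
#' time-varying covariates and numerator = baseline covariates, and an
#' outcome model adjusted for the baseline covariates (quadratic follow-up
#' time by default, suited to short horizons).
#'
#' @param scenario A `ccw_scenario`.
#' @param time_terms Outcome-model time basis.
#' @param truncation_percentile Weight truncation percentile.
#' @return A list with `protocol`, `weight_config`, `outcome_config`.
#' @export
default_analysis_configs <- function(scenario,
                                     time_terms = time_quadratic(),
                                     truncation_percentile = 0.995) {
  base_names <- names(scenario$baseline_covariate_spec)
  tv <- scenario$timevarying_name
  list(
    protocol = trial_protocol(
      grace = scenario$grace, horizon = scenario$horizon,
      baseline_covariates = base_names, timevarying_covariates = tv
    ),
    weight_config = weight_model_config(
      denominator_covariates = c(base_names, tv),
      numerator_covariates = base_names,
      truncation_percentile = truncation_percentile
    ),
    outcome_config = outcome_model_config(
      time_terms = time_terms,
      include_treatment_time_products = TRUE,
      baseline_adjustment_covariates = base_names,
      horizon = scenario$horizon
    )
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or the path to a YAML file.",
          class = "ccw_config_error")
  }
  config
}

#' Configuration-driven end-to-end run
#'
#' Executes the whole pipeline from a single structured configuration
#' (a list or a YAML file): either `scenario` (simulate-then-analyze) or
#' `cohort` (paths to the wide/long CSV pair), plus optional `protocol`,
#' `weight_model`, `outcome_model` and `bootstrap` sections, an
#' `output_dir`, and a global `seed` from which per-stage seeds are derived.
#' All artifacts (person-periods, weighted clone-periods, weight
#' diagnostics, survival curves, estimates JSON and a manifest with stage
#' row counts) are written to `output_dir` when given.
#'
#' @param config List or YAML path. Recognized top-level keys: `scenario`,
#'   `cohort`, `protocol`, `weight_model`, `outcome_model`, `bootstrap`,
#'   `naive`, `rd_horizon`, `output_dir`, `seed`.
#' @param quiet Suppress progress messages.
#' @return The `ccw_emulation` (invisibly when writing artifacts).
#' @export
run_emulation <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  has_scenario <- !is.null(config$scenario)
  has_cohort <- !is.null(config$cohort)
  if (has_scenario == has_cohort) {
    abort("Exactly one of `scenario` and `cohort` must be present.",
          class = "ccw_config_error")
  }
  if (!is.null(config$bootstrap)) {
    # validate before any computation
    boot_config <- do.call(bootstrap_config, config$bootstrap)
  } else {
    boot_config <- NULL
  }
  seed <- config$seed
  if (is.null(seed)) {
    abort("`seed` is required.", class = "ccw_config_error")
  }

  if (has_scenario) {
    sc_args <- config$scenario
    if (!is.null(sc_args$baseline_covariate_spec)) {
      sc_args$baseline_covariate_spec <-
        lapply(sc_args$baseline_covariate_spec, function(s) {
          do.call(match.fun(paste0("cov_", s$dist)), s[setdiff(names(s), "dist")])
        })
    }
    for (nm in c("init_model_coefs", "death_model_coefs", "timevarying_mean_coefs")) {
      if (!is.null(sc_args[[nm]])) sc_args[[nm]] <- unlist(sc_args[[nm]])
    }
    scenario <- do.call(scenario_config, sc_args)
    say("simulating %d patients (seed %d)", scenario$n_patients,
        stage_seed(seed, "simulate"))
    cohort <- generate_cohort(scenario, seed = stage_seed(seed, "simulate"))
    defaults <- default_analysis_configs(scenario)
  } else {
    cohort <- read_cohort(config$cohort$wide, config$cohort$long,
                          baseline_covariates = config$cohort$baseline_covariates,
                          timevarying_covariates = config$cohort$timevarying_covariates)
    defaults <- NULL
  }

  protocol <- if (!is.null(config$protocol)) {
    do.call(trial_protocol, c(config$protocol, list(
      baseline_covariates = cohort$baseline_covariates,
      timevarying_covariates = cohort$timevarying_covariates
    )))
  } else if (!is.null(defaults)) defaults$protocol else {
    abort("A `protocol` section is required with cohort input.",
          class = "ccw_config_error")
  }
  weight_config <- if (!is.null(config$weight_model)) {
    do.call(weight_model_config, config$weight_model)
  } else if (!is.null(defaults)) defaults$weight_config else {
    weight_model_config(
      denominator_covariates = c(cohort$baseline_covariates,
                                 cohort$timevarying_covariates),
      numerator_covariates = cohort$baseline_covariates
    )
  }
  outcome_config <- if (!is.null(config$outcome_model)) {
    oc <- config$outcome_model
    if (!is.null(oc$time_terms)) {
      oc$time_terms <- switch(oc$time_terms$kind,
        rcs = time_rcs(unlist(oc$time_terms$knots)),
        quadratic = time_quadratic(),
        indicator = time_indicator(),
        abort("Unknown outcome time_terms kind.", class = "ccw_config_error"))
    }
    oc$horizon <- oc$horizon %||% protocol$horizon
    do.call(outcome_model_config, oc)
  } else if (!is.null(defaults)) defaults$outcome_config else {
    outcome_model_config(baseline_adjustment_covariates = cohort$baseline_covariates,
                         horizon = protocol$horizon)
  }
  if (!is.null(boot_config) && is.null(boot_config$seed)) {
    boot_config$seed <- stage_seed(seed, "bootstrap")
  }

  say("emulating: grace %d, horizon %d, %d patients", protocol$grace,
      protocol$horizon, nrow(cohort$patients))
  fit <- ccw_emulate(cohort, protocol, weight_config, outcome_config,
                     boot_config = boot_config,
                     naive = !isFALSE(config$naive),
                     rd_horizon = config$rd_horizon)

  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(fit$person_periods, file.path(out_dir, "person_periods.csv"))
    readr::write_csv(fit$clone_periods, file.path(out_dir, "clone_periods.csv"))
    readr::write_csv(fit$weight_diagnostics,
                     file.path(out_dir, "weight_diagnostics.csv"))
    readr::write_csv(fit$survival$curves, file.path(out_dir, "survival_curves.csv"))
    est <- as.data.frame(fit$estimates)
    jsonlite::write_json(
      list(estimates = est,
           marginal_hr = as.data.frame(fit$marginal_hr),
           risk_difference = as.data.frame(fit$survival$risk_difference),
           seed = seed),
      file.path(out_dir, "estimates.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    manifest <- list(
      package = "ccwtte",
      version = as.character(utils::packageVersion("ccwtte")),
      seed = seed,
      config = config,
      counts = fit$counts,
      exclusions = as.data.frame(fit$exclusions),
      bootstrap_failed = if (!is.null(fit$bootstrap)) fit$bootstrap$n_failed else NULL
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null", null = "null")
    say("artifacts written to %s", out_dir)
    return(invisible(fit))
  }
  fit
}

#' Benchmark the estimator across simulation scenarios
#'
#' Runs the clone-censor-weight estimator and the naive ever/never
#' comparator over replicated draws of each scenario and summarizes their
#' sampling distributions next to the forced-arm oracle risks.
#'
#' @param scenarios Named list of `ccw_scenario` objects.
#' @param replicates Replicates per scenario.
#' @param seed Global seed; per-replicate seeds are derived from it.
#' @param n_oracle Patients per arm in the oracle simulation.
#' @param bootstrap_resamples If positive, a percentile CI is computed per
#'   replicate and coverage of the true marginal HR is reported.
#' @param out_csv Optional path to write the summary table.
#' @return A tibble with one row per scenario: mean/SD of the
#'   clone-censor-weight and naive HRs, oracle risks at the horizon, and
#'   CI coverage (NA when no bootstrap was requested).
#' @export
run_benchmark_suite <- function(scenarios, replicates = 2, seed = 1,
                                n_oracle = 20000, bootstrap_resamples = 0,
                                out_csv = NULL) {
  if (!is.list(scenarios) || is.null(names(scenarios)) ||
      any(names(scenarios) == "")) {
    abort("`scenarios` must be a named list of ccw_scenario objects.",
          class = "ccw_config_error")
  }
  assert_count(replicates, "replicates")
  rows <- purrr::imap(scenarios, function(sc, nm) {
    if (!inherits(sc, "ccw_scenario")) {
      abort(sprintf("Scenario '%s' is not a ccw_scenario.", nm),
            class = "ccw_config_error")
    }
    cfgs <- default_analysis_configs(sc)
    i <- match(nm, names(scenarios))
    hr_ccw <- hr_naive <- covered <- rep(NA_real_, replicates)
    for (r in seq_len(replicates)) {
      s_r <- (seed + 7919L * i + r) %% 2147483647L
      cohort <- generate_cohort(sc, seed = s_r)
      engine <- build_ccw_engine(cohort, cfgs$protocol, cfgs$weight_config,
                                 cfgs$outcome_config)
      hr_ccw[r] <- run_ccw_engine(engine, NULL,
                                  estimands = "hr_adjusted")$hr_adjusted
      hr_naive[r] <- naive_ever_never_hr(cohort, cfgs$protocol)$hazard_ratio
      if (bootstrap_resamples > 0) {
        bt <- bootstrap_ci(cohort, cfgs$protocol, cfgs$weight_config,
                           cfgs$outcome_config,
                           bootstrap_config(bootstrap_resamples, seed = s_r + 1L),
                           estimands = "hr_adjusted")
        covered[r] <- as.numeric(
          bt$hr_adjusted$ci_lower <= exp(sc$true_log_hr) &&
            exp(sc$true_log_hr) <= bt$hr_adjusted$ci_upper)
      }
    }
    oracle_t <- simulate_counterfactual_risks(sc, "treat", n_oracle,
                                              seed = seed + 7919L * i)
    oracle_c <- simulate_counterfactual_risks(sc, "control", n_oracle,
                                              seed = seed + 7919L * i)
    tibble::tibble(
      scenario = nm,
      replicates = replicates,
      true_hr = exp(sc$true_log_hr),
      mean_ccw_hr = mean(hr_ccw), sd_ccw_hr = sd(hr_ccw),
      mean_naive_hr = mean(hr_naive), sd_naive_hr = sd(hr_naive),
      oracle_risk_treat = oracle_t$risk[sc$horizon],
      oracle_risk_control = oracle_c$risk[sc$horizon],
      ci_coverage = if (bootstrap_resamples > 0) mean(covered) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) readr::write_csv(out, out_csv)
  out
}
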
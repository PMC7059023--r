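#' Generate a synthetic claims-like cohort
#'
#' Simulates the scenario interval by interval on the same discrete grid the
#' estimator uses. Within each interval the ordering is: time-varying
#' covariate draw, then (if still untreated) the initiation draw, then the
#' death draw with the treatment indicator active from the initiation
#' interval onward. Administrative censoring is applied afterwards to the
#' configured fraction of patients at uniformly drawn intervals; surviving
#' patients are truncated at the horizon.
#'
#' @param config A `ccw_scenario` from [scenario_config()].
#' @param seed Seed for the simulation; defaults to `config$seed`.
#' @return A `ccw_cohort`: a list with `patients` (one row per patient:
#'   `patient_id`, baseline covariates, `initiation_interval`,
#'   `event_interval`, `censor_interval`, `eligible`) and `panel` (one row
#'   per observed patient-interval with the time-varying covariate).
#'   Intervals are 0-based; `NA` interval columns mean "did not occur during
#'   observed follow-up".
#' @examples
#' cohort <- generate_cohort(scenario_config(n_patients = 100, seed = 7))
#' cohort$patients
#' @export
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "ccw_scenario")) {
    abort("`config` must be a ccw_scenario.", class = "ccw_config_error")
  }
  if (is.null(seed)) {
    abort("A seed is required: set `seed` in scenario_config() or pass it here.",
          class = "ccw_config_error")
  }
  with_seed(seed, {
    sim <- simulate_paths(config, n = config$n_patients, arm = NULL)
    n <- config$n_patients
    H <- config$horizon

    # administrative censoring: a uniform interval for a random fraction;
    # a death at or before the censoring draw is still observed
    cens_flag <- runif(n) < config$admin_censor_fraction
    cens_draw <- sample.int(H, n, replace = TRUE) - 1L
    event_interval <- sim$event_interval
    censor_interval <- ifelse(cens_flag, cens_draw, NA_integer_)
    observed_death <- !is.na(event_interval) &
      (is.na(censor_interval) | event_interval <= censor_interval)
    event_interval[!observed_death] <- NA_integer_
    censor_interval[observed_death] <- NA_integer_

    end_t <- pmin(
      ifelse(is.na(event_interval), H - 1L, event_interval),
      ifelse(is.na(censor_interval), H - 1L, censor_interval)
    )
    initiation_interval <- sim$initiation_interval
    initiation_interval[!is.na(initiation_interval) &
                          initiation_interval > end_t] <- NA_integer_

    ids <- sprintf("P%05d", seq_len(n))
    patients <- tibble::tibble(patient_id = ids)
    for (nm in names(config$baseline_covariate_spec)) {
      patients[[nm]] <- sim$V[, nm]
    }
    patients$initiation_interval <- as.integer(initiation_interval)
    patients$event_interval <- as.integer(event_interval)
    patients$censor_interval <- as.integer(censor_interval)
    patients$eligible <- TRUE

    keep_len <- end_t + 1L
    panel <- tibble::tibble(
      patient_id = rep(ids, keep_len),
      interval = unlist(lapply(keep_len, function(k) 0:(k - 1L)), use.names = FALSE)
    )
    panel[[config$timevarying_name]] <-
      sim$L[cbind(rep(seq_len(n), keep_len), panel$interval + 1L)]

    new_cohort(patients, panel,
               baseline_covariates = names(config$baseline_covariate_spec),
               timevarying_covariates = config$timevarying_name,
               config = config)
  })
}

# Core interval-by-interval simulation, vectorized over patients.
# arm = NULL: observational initiation. arm = "treat"/"control": forced
# adherence to the strategy (used by the counterfactual oracle).
simulate_paths <- function(config, n, arm = NULL) {
  H <- config$horizon
  grace <- config$grace
  specs <- config$baseline_covariate_spec
  V <- vapply(names(specs), function(nm) draw_covariate(specs[[nm]], n),
              numeric(n))
  V <- matrix(V, nrow = n, dimnames = list(NULL, names(specs)))

  coef_part <- function(coefs, exclude = c("(Intercept)", "time")) {
    nm <- setdiff(names(coefs), exclude)
    nm_v <- intersect(nm, colnames(V))
    base <- if (length(nm_v)) drop(V[, nm_v, drop = FALSE] %*% coefs[nm_v]) else rep(0, n)
    list(base = base,
         icpt = unname(coefs["(Intercept)"] %||% 0) %|NA|% 0,
         time = unname(coefs["time"] %||% 0) %|NA|% 0,
         tv = unname(coefs[config$timevarying_name] %||% 0) %|NA|% 0)
  }
  ini <- coef_part(config$init_model_coefs)
  dea <- coef_part(config$death_model_coefs)
  mu0 <- {
    mc <- config$timevarying_mean_coefs
    nm_v <- intersect(names(mc), colnames(V))
    (unname(mc["(Intercept)"] %||% 0) %|NA|% 0) +
      (if (length(nm_v)) drop(V[, nm_v, drop = FALSE] %*% mc[nm_v]) else rep(0, n))
  }
  rho <- config$timevarying_ar_coef
  sdv <- config$timevarying_sd
  drift <- config$timevarying_drift

  L <- matrix(NA_real_, n, H)
  alive <- rep(TRUE, n)
  initiated <- rep(FALSE, n)
  init_t <- rep(NA_integer_, n)
  event_t <- rep(NA_integer_, n)

  for (t in 0:(H - 1)) {
    mean_t <- mu0 + drift * t
    eps <- rnorm(n, 0, sdv)
    if (t == 0) {
      L[, 1] <- mean_t + eps
    } else {
      L[, t + 1] <- mean_t + rho * (L[, t] - (mu0 + drift * (t - 1))) + eps
    }
    Lt <- L[, t + 1]

    u_init <- runif(n)
    if (is.null(arm)) {
      can_init <- alive & !initiated
    } else if (arm == "treat") {
      can_init <- alive & !initiated & (t < grace)
    } else {
      can_init <- alive & !initiated & (t >= grace)
    }
    if (any(can_init)) {
      p_init <- plogis(ini$icpt + ini$time * t + ini$base + ini$tv * Lt)
      new_init <- can_init & (u_init < p_init)
      init_t[new_init] <- t
      initiated[new_init] <- TRUE
    }
    if (!is.null(arm) && arm == "treat" && t == grace - 1) {
      force_now <- alive & !initiated
      init_t[force_now] <- t
      initiated[force_now] <- TRUE
    }

    u_death <- runif(n)
    treated_now <- initiated
    p_death <- plogis(dea$icpt + dea$time * t + dea$base + dea$tv * Lt +
                        config$true_log_hr * as.numeric(treated_now))
    dies <- alive & (u_death < p_death)
    event_t[dies] <- t
    alive[dies] <- FALSE
  }
  list(V = V, L = L, initiation_interval = init_t, event_interval = event_t)
}

# replace NA scalar with default (used for absent named coefficients)
`%|NA|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Counterfactual risk curves under forced adherence (ground-truth oracle)
#'
#' Simulates a large cohort with treatment forced to follow one strategy --
#' for the treat arm, initiation at its natural interval when that falls
#' inside the grace period and otherwise at the final grace interval; for
#' the control arm, initiation suppressed during the grace period and
#' natural afterwards -- with no administrative censoring. The empirical
#' cumulative-risk curve is the per-protocol ground truth the
#' clone-censor-weight estimator targets.
#'
#' @param config A `ccw_scenario`.
#' @param arm `"treat"`/`"control"` (or a protocol arm label).
#' @param n_oracle Number of forced-arm patients to simulate.
#' @param seed Seed; defaults to `config$seed`.
#' @return A tibble with `interval` (1..horizon) and `risk`, where
#'   `risk[t]` is the probability of death before the start of interval `t`.
#' @examples
#' cfg <- scenario_config(n_patients = 100, horizon = 12, seed = 1)
#' simulate_counterfactual_risks(cfg, "treat", n_oracle = 1000)
#' @export
simulate_counterfactual_risks <- function(config, arm, n_oracle = 50000,
                                          seed = config$seed) {
  if (!inherits(config, "ccw_scenario")) {
    abort("`config` must be a ccw_scenario.", class = "ccw_config_error")
  }
  arm <- match_arm(arm)
  assert_count(n_oracle, "n_oracle")
  if (is.null(seed)) {
    abort("A seed is required for the oracle simulation.", class = "ccw_config_error")
  }
  with_seed(seed + ifelse(arm == "treat", 1L, 2L), {
    sim <- simulate_paths(config, n = n_oracle, arm = arm)
    ev <- sim$event_interval
    risk <- vapply(seq_len(config$horizon),
                   function(t) mean(!is.na(ev) & ev < t), numeric(1))
    tibble::tibble(interval = seq_len(config$horizon), risk = risk)
  })
}

new_cohort <- function(patients, panel, baseline_covariates,
                       timevarying_covariates, config = NULL) {
  structure(list(
    patients = patients,
    panel = panel,
    baseline_covariates = baseline_covariates,
    timevarying_covariates = timevarying_covariates,
    config = config
  ), class = "ccw_cohort")
}

#' @export
print.ccw_cohort <- function(x, ...) {
  p <- x$patients
  cat("<ccw_cohort>\n")
  cat(sprintf("  %d patients, %d observed person-intervals\n",
              nrow(p), nrow(x$panel)))
  cat(sprintf("  baseline: %s | time-varying: %s\n",
              paste(x$baseline_covariates, collapse = ", "),
              paste(x$timevarying_covariates, collapse = ", ")))
  cat(sprintf("  initiated: %d | deaths: %d | admin censored: %d\n",
              sum(!is.na(p$initiation_interval)),
              sum(!is.na(p$event_interval)),
              sum(!is.na(p$censor_interval))))
  invisible(x)
}

#' Read and write cohorts as CSV pairs
#'
#' A cohort is stored as two plain CSV files: a wide table (one row per
#' patient with baseline covariates and the 0-based initiation, event and
#' censoring intervals) and a long table (one row per observed
#' patient-interval with the time-varying covariates).
#'
#' @param cohort A `ccw_cohort`.
#' @param wide_path,long_path File paths for the two tables.
#' @return `write_cohort()` returns the cohort invisibly; `read_cohort()`
#'   returns a `ccw_cohort`.
#' @export
write_cohort <- function(cohort, wide_path, long_path) {
  stopifnot(inherits(cohort, "ccw_cohort"))
  readr::write_csv(cohort$patients, wide_path)
  readr::write_csv(cohort$panel, long_path)
  invisible(cohort)
}

#' @rdname write_cohort
#' @param baseline_covariates,timevarying_covariates Covariate column names;
#'   inferred from the non-reserved columns when omitted.
#' @export
read_cohort <- function(wide_path, long_path,
                        baseline_covariates = NULL,
                        timevarying_covariates = NULL) {
  patients <- readr::read_csv(wide_path, show_col_types = FALSE)
  panel <- readr::read_csv(long_path, show_col_types = FALSE)
  reserved_w <- c("patient_id", "initiation_interval", "event_interval",
                  "censor_interval", "eligible")
  reserved_l <- c("patient_id", "interval")
  missing_w <- setdiff(setdiff(reserved_w, "eligible"), names(patients))
  if (length(missing_w) > 0) {
    abort(sprintf("Wide cohort file lacks required columns: %s",
                  paste(missing_w, collapse = ", ")), class = "ccw_data_error")
  }
  if (!all(reserved_l %in% names(panel))) {
    abort("Long cohort file needs `patient_id` and `interval` columns.",
          class = "ccw_data_error")
  }
  if (is.null(patients$eligible)) patients$eligible <- TRUE
  baseline_covariates <- baseline_covariates %||%
    setdiff(names(patients), reserved_w)
  timevarying_covariates <- timevarying_covariates %||%
    setdiff(names(panel), reserved_l)
  new_cohort(patients, panel, baseline_covariates, timevarying_covariates)
}
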
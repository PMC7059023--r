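# Precomputed design-matrix engine for the full clone-censor-weight
# pipeline. The tidy pipeline functions (expand_person_periods,
# make_clones, apply_censoring, the design builders) are run ONCE to build
# patient-indexed row blocks; each bootstrap resample then only re-indexes
# rows and re-fits the initiation and outcome models with glm.fit. Because
# a resampled patient's clone structure is a deterministic function of that
# patient's own record, re-indexing reproduces exactly what re-running the
# pipeline on the resampled cohort would produce.

build_ccw_engine <- function(cohort, protocol, weight_config, outcome_config,
                             marginal_time_terms = outcome_config$time_terms) {
  elig <- apply_eligibility(cohort, protocol)
  pp <- expand_person_periods(elig$cohort, protocol)
  cl <- apply_censoring(make_clones(pp, protocol), protocol)

  patients <- elig$cohort$patients
  n <- nrow(patients)
  pid_levels <- patients$patient_id

  wspec <- resolve_time_spec(weight_config$time_terms, protocol$grace)
  if (wspec$kind == "indicator" && length(wspec$levels) > protocol$grace) {
    wspec$levels <- 0:(protocol$grace - 1)
  }
  rs_mask <- initiation_risk_set(pp, protocol$grace)
  rs <- pp[rs_mask, , drop = FALSE]
  x_den <- build_initiation_design(rs, weight_config$denominator_covariates, wspec)
  x_num <- build_initiation_design(rs, weight_config$numerator_covariates, wspec)
  y_init <- as.numeric(rs$initiates_at_t)
  rs_pid <- match(rs$patient_id, pid_levels)

  ospec_full <- resolve_time_spec(outcome_config$time_terms, outcome_config$horizon)
  marg_config <- outcome_model_config(
    time_terms = marginal_time_terms,
    include_treatment_time_products = FALSE,
    baseline_adjustment_covariates = character(),
    horizon = outcome_config$horizon
  )
  ospec_marg <- resolve_time_spec(marg_config$time_terms, outcome_config$horizon)

  adj_config <- outcome_model_config(
    time_terms = outcome_config$time_terms,
    include_treatment_time_products = FALSE,
    baseline_adjustment_covariates = outcome_config$baseline_adjustment_covariates,
    horizon = outcome_config$horizon
  )

  arm01 <- as.numeric(cl$arm == "treat")
  x_full <- build_outcome_design(cl, arm01, outcome_config, ospec_full)
  x_marg <- build_outcome_design(cl, arm01, marg_config, ospec_marg)
  x_adj <- build_outcome_design(cl, arm01, adj_config, ospec_full)
  y_out <- as.numeric(cl$event)
  cl_pid <- match(cl$patient_id, pid_levels)

  # clone rows needing a model probability for their weight contribution
  grace <- protocol$grace
  wtype <- integer(nrow(cl))
  wtype[cl$arm == "control" & cl$interval < grace] <- 1L
  wtype[cl$arm == "treat" & cl$interval == grace - 1 & cl$initiates_at_t] <- 2L
  x_w_den <- build_initiation_design(cl, weight_config$denominator_covariates, wspec)
  x_w_num <- build_initiation_design(cl, weight_config$numerator_covariates, wspec)

  # per-patient contiguous row blocks (tables are sorted by patient)
  rs_rows <- split(seq_len(nrow(rs)), factor(rs_pid, levels = seq_len(n)))
  cl_rows <- split(seq_len(nrow(cl)), factor(cl_pid, levels = seq_len(n)))
  # local positions (within a patient's clone block) where a new clone starts
  starts_all <- !duplicated(cl[c("patient_id", "arm")])
  pos_within <- ave(seq_len(nrow(cl)), cumsum(!duplicated(cl$patient_id)),
                    FUN = seq_along)
  local_starts <- split(pos_within[starts_all],
                        factor(cl_pid[starts_all], levels = seq_len(n)))
  cl_lens <- lengths(cl_rows)

  cov_values <- matrix(numeric(0), nrow = n, ncol = 0)
  for (nm in outcome_config$baseline_adjustment_covariates) {
    cov_values <- cbind(cov_values, patients[[nm]])
    colnames(cov_values)[ncol(cov_values)] <- nm
  }

  list(
    n = n,
    protocol = protocol,
    weight_config = weight_config,
    outcome_config = outcome_config,
    marg_config = marg_config,
    ospec_full = ospec_full,
    ospec_marg = ospec_marg,
    pp = pp, cl = cl, exclusions = elig$exclusions, patients = patients,
    x_den = x_den, x_num = x_num, y_init = y_init, rs_rows = rs_rows,
    x_full = x_full, x_marg = x_marg, x_adj = x_adj, y_out = y_out,
    wtype = wtype, x_w_den = x_w_den, x_w_num = x_w_num,
    cl_rows = cl_rows, cl_lens = cl_lens, local_starts = local_starts,
    cov_values = cov_values,
    arm01 = arm01
  )
}

# Run the pipeline for a patient multiset. pids = NULL means the full
# original sample. Returns the weighted marginal HR and, when requested,
# the standardized curves and risk difference from the covariate-adjusted
# model with treatment-time products.
run_ccw_engine <- function(engine, pids = NULL,
                           estimands = c("hr", "risk_difference"),
                           rd_horizon = NULL) {
  n <- engine$n
  if (is.null(pids)) pids <- seq_len(n)

  idx_rs <- unlist(engine$rs_rows[pids], use.names = FALSE)
  lens <- engine$cl_lens[pids]
  idx_cl <- unlist(engine$cl_rows[pids], use.names = FALSE)
  offs <- cumsum(lens) - lens
  ls <- engine$local_starts[pids]
  starts <- logical(length(idx_cl))
  starts[unlist(ls, use.names = FALSE) + rep(offs, lengths(ls))] <- TRUE

  if (length(idx_rs) == 0) {
    abort("Empty initiation risk set in resample.", class = "ccw_estimation_error")
  }
  y_rs <- engine$y_init[idx_rs]
  if (all(y_rs == 1) || all(y_rs == 0)) {
    abort("Degenerate initiation response in resample.",
          class = "ccw_estimation_error")
  }
  fit_den <- pooled_logit(engine$x_den[idx_rs, , drop = FALSE], y_rs)
  fit_num <- pooled_logit(engine$x_num[idx_rs, , drop = FALSE], y_rs)
  if (!fit_den$converged || !fit_num$converged) {
    abort("Initiation model did not converge in resample.",
          class = "ccw_estimation_error")
  }

  wt <- engine$wtype[idx_cl]
  p_den <- rep(NA_real_, length(idx_cl))
  p_num <- rep(NA_real_, length(idx_cl))
  sel <- wt > 0L
  if (any(sel)) {
    rows <- idx_cl[sel]
    p_den[sel] <- plogis(design_eta(engine$x_w_den[rows, , drop = FALSE],
                                    fit_den$coefficients))
    p_num[sel] <- plogis(design_eta(engine$x_w_num[rows, , drop = FALSE],
                                    fit_num$coefficients))
  }
  cl_sub_arm <- ifelse(engine$arm01[idx_cl] == 1, "treat", "control")
  contrib <- weight_contributions(
    arm = cl_sub_arm,
    interval = engine$cl$interval[idx_cl],
    initiates_at_t = engine$cl$initiates_at_t[idx_cl],
    initiated_by_t = engine$cl$initiated_by_t[idx_cl],
    grace = engine$protocol$grace,
    p_num = p_num, p_den = p_den
  )
  w <- group_cumprod(contrib, starts)
  tp <- engine$weight_config$truncation_percentile
  if (tp < 1) w <- pmin(w, quantile(w, tp, names = FALSE, type = 7))

  y <- engine$y_out[idx_cl]
  for (a in 0:1) {
    if (sum(y[engine$arm01[idx_cl] == a]) < 1) {
      abort(sprintf("No events in the %s arm in resample.",
                    if (a == 1) "treat" else "control"),
            class = "ccw_estimation_error")
    }
  }
  out <- list()
  if ("hr" %in% estimands) {
    fit_m <- pooled_logit(engine$x_marg[idx_cl, , drop = FALSE], y, weights = w,
                          epsilon = 1e-12, maxit = 200L)
    if (!fit_m$converged) {
      abort("Marginal hazard model did not converge in resample.",
            class = "ccw_estimation_error")
    }
    out$hr <- unname(exp(fit_m$coefficients[["arm"]]))
  }
  if ("hr_adjusted" %in% estimands) {
    fit_a <- pooled_logit(engine$x_adj[idx_cl, , drop = FALSE], y, weights = w,
                          epsilon = 1e-12, maxit = 200L)
    if (!fit_a$converged) {
      abort("Adjusted hazard model did not converge in resample.",
            class = "ccw_estimation_error")
    }
    out$hr_adjusted <- unname(exp(fit_a$coefficients[["arm"]]))
  }
  if (any(c("risk_difference", "survival") %in% estimands)) {
    fit_f <- pooled_logit(engine$x_full[idx_cl, , drop = FALSE], y, weights = w,
                          epsilon = 1e-12, maxit = 200L)
    if (!fit_f$converged) {
      abort("Adjusted hazard model did not converge in resample.",
            class = "ccw_estimation_error")
    }
    std <- std_curves_from_beta(fit_f$coefficients, engine$outcome_config,
                                engine$ospec_full,
                                engine$cov_values[pids, , drop = FALSE])
    H <- engine$outcome_config$horizon
    rdh <- rd_horizon %||% H
    out$risk_treat <- 1 - std$treat
    out$risk_control <- 1 - std$control
    out$risk_difference <- out$risk_treat[rdh] - out$risk_control[rdh]
    out$rd_horizon <- rdh
    out$beta_full <- fit_f$coefficients
  }
  out$weights <- w
  out
}
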
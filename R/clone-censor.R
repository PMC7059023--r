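#' Clone eligible person-time into one copy per strategy
#'
#' With a grace period, observed data at time zero cannot uniquely assign a
#' patient to either strategy, so every eligible patient contributes one
#' clone to each arm. The output duplicates each person-period row once per
#' arm with `artificial_censor = FALSE` and unit weight; censoring rules are
#' applied afterwards by [apply_censoring()].
#'
#' @param periods A person-period tibble from [expand_person_periods()].
#' @param protocol A `ccw_protocol`.
#' @return A clone-period tibble: the person-period columns plus `arm`
#'   (`"treat"`/`"control"`), `artificial_censor` and `weight`.
#' @export
make_clones <- function(periods, protocol) {
  stopifnot(is.data.frame(periods), inherits(protocol, "ccw_protocol"))
  if (nrow(periods) > 0 &&
      anyDuplicated(periods[c("patient_id", "interval")]) > 0) {
    abort("Duplicate (patient_id, interval) rows in person-period input.",
          class = "ccw_data_error")
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(periods, arm = "treat"),
    dplyr::mutate(periods, arm = "control")
  )
  out$artificial_censor <- FALSE
  out$weight <- 1
  dplyr::arrange(out, .data$patient_id, .data$arm, .data$interval)
}

#' Strategy compatibility of one clone-interval
#'
#' The artificial-censoring rule evaluated at a single interval. A
#' control-arm clone must be censored the moment it initiates treatment
#' inside the grace period (initiation afterwards is protocol-compatible);
#' a treat-arm clone must be censored at the close of the final grace
#' interval if it has still not initiated by then. No censoring can occur
#' after the grace window in either arm.
#'
#' @param arm `"treat"` or `"control"` (vectorized).
#' @param initiated_by_t Logical: initiation occurred at an interval `<= t`.
#' @param initiates_at_t Logical: initiation occurred exactly at `t`.
#' @param t 0-based interval index.
#' @param grace Grace-period length.
#' @return Character vector: `"compatible"` or `"censor-now"`.
#' @examples
#' compatibility("control", initiated_by_t = TRUE, initiates_at_t = TRUE,
#'               t = 1, grace = 3)
#' compatibility("treat", FALSE, FALSE, t = 2, grace = 3)
#' @export
compatibility <- function(arm, initiated_by_t, initiates_at_t, t, grace) {
  if (!all(arm %in% ARM_ROLES)) {
    bad <- setdiff(unique(arm), ARM_ROLES)
    abort(sprintf("Unknown arm label(s): %s", paste(bad, collapse = ", ")),
          class = "ccw_config_error")
  }
  if (any(t < 0)) abort("`t` must be >= 0.", class = "ccw_config_error")
  censor <- (arm == "control" & initiates_at_t & t < grace) |
    (arm == "treat" & t == grace - 1 & !initiated_by_t)
  ifelse(censor, "censor-now", "compatible")
}

#' Apply artificial censoring to cloned person-time
#'
#' For each clone, the first interval flagged `censor-now` by
#' [compatibility()] and everything after it are removed from the risk set
#' (the censoring interval's event, if any, does not count: initiation
#' decisions are evaluated before outcomes within an interval).
#' `artificial_censor` is set on the last retained row of censored clones
#' for diagnostics; clones censored at interval 0 retain no rows.
#'
#' @param clone_periods Output of [make_clones()].
#' @param protocol A `ccw_protocol`.
#' @return The censored clone-period tibble.
#' @export
apply_censoring <- function(clone_periods, protocol) {
  stopifnot(is.data.frame(clone_periods), inherits(protocol, "ccw_protocol"))
  if (nrow(clone_periods) == 0) return(clone_periods)
  grace <- protocol$grace
  cp <- dplyr::arrange(clone_periods, .data$patient_id, .data$arm, .data$interval)
  cn <- compatibility(cp$arm, cp$initiated_by_t, cp$initiates_at_t,
                      cp$interval, grace) == "censor-now"
  cp |>
    dplyr::mutate(.cn = cn) |>
    dplyr::group_by(.data$patient_id, .data$arm) |>
    dplyr::mutate(
      .censor_at = if (any(.data$.cn)) min(.data$interval[.data$.cn]) else Inf
    ) |>
    dplyr::filter(.data$interval < .data$.censor_at) |>
    dplyr::mutate(
      artificial_censor = is.finite(.data$.censor_at) &
        .data$interval == max(.data$interval)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".cn", -".censor_at")
}
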
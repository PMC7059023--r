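#' Follow-up time bases for pooled logistic hazard models
#'
#' Discrete-time hazard models in this package represent follow-up time
#' through a configurable basis expansion: a restricted cubic spline
#' (natural spline in the truncated-power parameterization, linear beyond
#' the boundary knots), a quadratic polynomial, or interval indicators
#' (a saturated time effect). The spline with knots at 3, 16, 30, 44 and
#' 57 months is the default for long-horizon emulations; the quadratic is
#' a light alternative for short horizons.
#'
#' @param knots Numeric vector of at least 3 strictly increasing knot
#'   locations, in interval units.
#' @param levels Optional integer vector of the interval values the
#'   indicator basis should span (typically `0:(horizon - 1)`). When `NULL`
#'   the levels are resolved from the protocol horizon at fit time.
#' @return A time-specification object of class `ccw_time_spec`.
#' @examples
#' time_basis(0:10, time_rcs(c(2, 5, 8)))
#' time_basis(4, time_quadratic())
#' @export
time_rcs <- function(knots = c(3, 16, 30, 44, 57)) {
  if (!is.numeric(knots) || length(knots) < 3) {
    abort("Restricted cubic spline needs at least 3 numeric knots.",
          class = "ccw_config_error")
  }
  if (is.unsorted(knots, strictly = TRUE)) {
    abort("Spline knots must be strictly increasing (sorted, no duplicates).",
          class = "ccw_config_error")
  }
  structure(list(kind = "rcs", knots = as.numeric(knots)),
            class = "ccw_time_spec")
}

#' @rdname time_rcs
#' @export
time_quadratic <- function() {
  structure(list(kind = "quadratic"), class = "ccw_time_spec")
}

#' @rdname time_rcs
#' @export
time_indicator <- function(levels = NULL) {
  structure(list(kind = "indicator", levels = levels), class = "ccw_time_spec")
}

# Fill in data-dependent pieces (indicator levels) so that fit-time and
# predict-time expansions agree.
resolve_time_spec <- function(spec, horizon) {
  if (!inherits(spec, "ccw_time_spec")) {
    abort("`time_terms` must be built with time_rcs(), time_quadratic() or time_indicator().",
          class = "ccw_config_error")
  }
  if (spec$kind == "indicator" && is.null(spec$levels)) {
    spec$levels <- 0:(horizon - 1)
  }
  spec
}

#' @rdname time_rcs
#' @param t Integer (or numeric) vector of 0-based interval indices.
#' @param spec A `ccw_time_spec`.
#' @return For `time_basis()`, a numeric matrix with one row per element of
#'   `t`: `k - 1` columns for a `k`-knot restricted cubic spline (the linear
#'   term plus `k - 2` nonlinear terms), 2 columns for the quadratic, and
#'   one indicator column per non-reference level for the saturated basis.
#' @export
time_basis <- function(t, spec) {
  if (!inherits(spec, "ccw_time_spec")) {
    abort("`spec` must be a ccw_time_spec.", class = "ccw_config_error")
  }
  t <- as.numeric(t)
  switch(spec$kind,
    quadratic = cbind(time = t, time_sq = t^2),
    rcs = rcs_basis(t, spec$knots),
    indicator = {
      lev <- spec$levels
      if (is.null(lev)) lev <- sort(unique(t))
      ref <- lev[-1] # first level is the reference
      if (length(ref) == 0) {
        matrix(numeric(0), nrow = length(t), ncol = 0)
      } else {
        m <- vapply(ref, function(l) as.numeric(t == l), numeric(length(t)))
        matrix(m, nrow = length(t),
               dimnames = list(NULL, paste0("time_", ref)))
      }
    },
    abort(sprintf("Unknown time basis kind '%s'.", spec$kind),
          class = "ccw_config_error")
  )
}

# Natural cubic spline, truncated-power form: linear term plus k-2 terms
#   [(t-k_j)+^3 - (t-k_{K-1})+^3 (k_K-k_j)/(k_K-k_{K-1})
#                + (t-k_K)+^3 (k_{K-1}-k_j)/(k_K-k_{K-1})] / (k_K-k_1)^2,
# which is linear below the first and above the last knot.
rcs_basis <- function(t, knots) {
  k <- knots
  K <- length(k)
  scl <- (k[K] - k[1])^2
  cub <- function(x) pmax(x, 0)^3
  nl <- vapply(seq_len(K - 2), function(j) {
    (cub(t - k[j]) -
       cub(t - k[K - 1]) * (k[K] - k[j]) / (k[K] - k[K - 1]) +
       cub(t - k[K]) * (k[K - 1] - k[j]) / (k[K] - k[K - 1])) / scl
  }, numeric(length(t)))
  nl <- matrix(nl, nrow = length(t))
  out <- cbind(t, nl)
  colnames(out) <- c("time", paste0("time_s", seq_len(K - 2)))
  out
}
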
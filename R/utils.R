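# Internal numerical helpers shared by the tidy pipeline functions and the
# resampling engine. All logistic fits in the package go through
# pooled_logit() so that the interactive path and the bootstrap path are the
# same estimator by construction.

# Evaluate code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage seed derived from one global seed; keeps stages
# reproducible independently of how many draws earlier stages consumed.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) %% 1000003L) * 2011L + match(
    stage,
    c("simulate", "oracle", "eligibility", "weights", "outcome", "bootstrap", "benchmark")
  )
}

# Maximum-likelihood logistic regression on an explicit design matrix.
# Wraps stats::glm.fit (IRLS); quasibinomial family so fractional
# inverse-probability weights do not trigger integer-count warnings
# (coefficients are identical to binomial ML).
pooled_logit <- function(x, y, weights = NULL, epsilon = 1e-10, maxit = 100L) {
  if (is.null(weights)) weights <- rep(1, length(y))
  fit <- suppressWarnings(stats::glm.fit(
    x = x, y = as.numeric(y), weights = weights,
    family = stats::quasibinomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)
  ))
  coefs <- fit$coefficients
  rank <- fit$rank
  p1 <- seq_len(rank)
  vcov <- matrix(NA_real_, length(coefs), length(coefs),
                 dimnames = list(names(coefs), names(coefs)))
  if (rank > 0) {
    covu <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    piv <- fit$qr$pivot[p1]
    vcov[piv, piv] <- covu
  }
  list(
    coefficients = coefs,
    vcov = vcov,
    converged = isTRUE(fit$converged),
    deviance = fit$deviance,
    rank = rank,
    aliased = is.na(coefs),
    n = length(y),
    fitted = fit$fitted.values
  )
}

# Linear predictor from a fitted coefficient vector; aliased (NA)
# coefficients are treated as zero contributions.
design_eta <- function(x, coefs) {
  b <- coefs
  b[is.na(b)] <- 0
  drop(x %*% b)
}

# Cumulative product within contiguous groups of a sorted vector.
# `starts` flags the first row of each group. Vectorized via log-cumsum,
# valid because weight contributions are strictly positive.
group_cumprod <- function(x, starts) {
  if (length(x) == 0) return(numeric(0))
  lx <- log(x)
  cs <- cumsum(lx)
  gid <- cumsum(starts)
  base <- (cs - lx)[starts]
  exp(cs - base[gid])
}

# Percentile bootstrap interval.
percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), na.rm = TRUE, names = FALSE, type = 7))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "ccw_config_error")
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", name, lo, hi),
          class = "ccw_config_error")
  }
  invisible(as.numeric(x))
}

# Canonical strategy roles used in clone tables: "treat" = initiate within
# the grace period, "control" = do not initiate within the grace period.
ARM_ROLES <- c("treat", "control")

match_arm <- function(arm, protocol = NULL) {
  if (length(arm) != 1 || is.na(arm)) {
    abort("`arm` must be a single arm label.", class = "ccw_config_error")
  }
  if (arm %in% ARM_ROLES) return(arm)
  if (!is.null(protocol) && arm %in% protocol$arm_labels) {
    return(names(protocol$arm_labels)[match(arm, protocol$arm_labels)])
  }
  abort(sprintf("Unknown arm label '%s' (expected one of: %s).", arm,
                paste(ARM_ROLES, collapse = ", ")),
        class = "ccw_config_error")
}
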
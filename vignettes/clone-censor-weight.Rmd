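---
title: "Clone-censor-weight target trial emulation: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-censor-weight target trial emulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccwtte)
```

## The estimation problem

Comparative-effectiveness questions about *initiating* a treatment are
awkward in observational cohorts because a realistic strategy allows a
grace period: "initiate drug X within 3 months of surgery" versus "do not
initiate within 3 months". During the grace window a patient who has not
yet initiated is behaving consistently with *both* strategies, so patients
cannot be assigned to a single arm at time zero. Classifying patients by
what they eventually did (the ever/never design) misclassifies
pre-initiation person-time as treated and guarantees that treated patients
survived long enough to initiate — immortal-time bias, which pushes the
treated group's apparent hazard down even when the treatment does nothing.

The clone-censor-weight design resolves this in three steps:

1. **Clone.** Every eligible patient contributes one copy to each strategy
   arm at time zero, so no assignment decision is ever made from future
   information.
2. **Censor.** A clone is artificially censored at the first time its
   patient's observed data become incompatible with the clone's assigned
   strategy: a control-arm clone when its patient initiates inside the
   grace window, and a treat-arm clone at the close of the final grace
   interval if its patient has still not initiated. After the grace window
   both strategies leave treatment to discretion, so no artificial
   censoring can occur there.
3. **Weight.** Artificial censoring is informative — it selects, for
   example, never-initiators into the control arm — so retained
   clone-periods are weighted by stabilized inverse probabilities of
   remaining uncensored, estimated from pooled logistic models of
   treatment initiation on the original (un-cloned) person-time at risk of
   initiation inside the grace window.

Outcomes are then analysed on the weighted cloned data with a
discrete-time hazard model: a pooled logistic regression of death on the
strategy indicator, a function of follow-up time, strategy-by-time
products, and baseline covariates. Standardizing the fitted
conditional survival curves over the eligible cohort's baseline covariate
distribution (the g-formula) yields marginal survival and risk curves per
strategy and their risk difference; a strategy-plus-time-only weighted
model gives a trial-style marginal hazard ratio, the discrete-time
analogue of a Cox model with treatment as the only covariate (the two
agree when per-interval hazards are small, roughly below 0.1).

The estimand throughout is the per-protocol effect: the contrast that
would have been observed had every patient adhered to their assigned
strategy, with treatment decisions after the grace window left free in
both arms.

## Time conventions

Follow-up is a grid of discrete intervals (months by default), 0-based and
half-open: interval `t` covers `[t, t + 1)`, and a death during the
interval is attributed to interval `t`'s row. Within an interval the
causal ordering is: covariates are measured at the interval start, then
the initiation decision, then the outcome. Two consequences follow and are
applied consistently by the simulator, the censoring rules and the weight
models:

* a control-arm clone whose patient initiates and dies in the same grace
  interval is censored at that interval and its death is excluded from the
  control risk set (the treatment decision precedes the outcome);
* a death during the grace window before any initiation is compatible with
  both strategies and is counted in both arms.

Treat-arm censoring sits at the close of the final grace interval
(`grace - 1`), so a treat-arm clone contributes outcome risk during the
whole window and is censored only when the window closes without
initiation. Loss to follow-up and the administrative end of data are
treated as noninformative end-of-follow-up, identically in both arms.

## The weight models

A single pair of initiation models serves both arms, because both arms'
censoring processes are deterministic functions of the one observed
initiation process. Both are maximum-likelihood logistic regressions on
the person-periods still untreated at the interval start with `t < grace`:

* the **denominator** model conditions on baseline and time-varying
  covariates (the full measured history relevant to initiation);
* the **numerator** model conditions on baseline covariates only.

Per-interval stabilized contributions are `(1 - p_num)/(1 - p_den)` for
control-arm clones inside the grace window, `p_num/p_den` for treat-arm
clones that initiate exactly at the final grace interval, and 1 everywhere
else (treat-arm clones face no censoring risk before the window closes;
nothing is censorable after it). Cumulative weights are the running
product within each clone.

Two deliberate defaults deserve comment.

**Time terms in the weight models are interval indicators.** The outcome
model defaults to a restricted cubic spline over the whole horizon, but
the weight models only ever see the grace window — typically three
intervals. A long-horizon spline basis restricted to `t < 3` is exactly
linear there (all nonlinear natural-spline terms vanish below the first
boundary knot), which makes the design rank-deficient. A saturated
indicator basis over the grace window is the richest well-posed choice and
costs at most `grace - 1` parameters.

**Which hazard ratio goes with which numerator.** Stabilizing with a
baseline-conditional numerator leaves the two weighted arms imbalanced in
those baseline covariates by construction: treat-arm clones that initiated
early carry weight 1, so the weighted treat arm represents the initiator
subcohort rather than the full eligible cohort. This is the standard IPW
trade-off — a covariate-conditional numerator shrinks weight variance but
requires those covariates in the outcome model. The package therefore
reports, from the same weighted data:

* the **covariate-adjusted hazard ratio** (strategy + time + baseline
  covariates), the headline "baseline + postbaseline adjusted" estimate,
  valid under the default baseline-conditional numerator; and
* the **marginal hazard ratio** (strategy + time only), which is unbiased
  when the numerator is covariate-free (`numerator_covariates =
  character()`) or weights are unstabilized, and in unconfounded settings.

The standardized curves are always computed from the covariate-adjusted
model with strategy-by-time products, so they remain valid either way.
In simulation this distinction is visible and reproducible: under a
confounded null, the strategy-only weighted model with a
baseline-conditional numerator retains a depressed hazard ratio, while the
covariate-adjusted estimate centres on 1 (the suite's null-recovery test
checks exactly this).

Cumulative weights are truncated at their 99.5th percentile by default
(`truncation_percentile = 1` disables truncation); mild truncation is
standard variance control and the suite's weight diagnostics are computed
with it in place. The mean cumulative weight per arm-interval is the
routine diagnostic — near 1 when the models are correctly specified —
via `weight_diagnostics()` and `plot_weight_diagnostics()`.

## The synthetic cohort generator

Restricted-access claims cohorts cannot ship with a package, so the
generator produces cohorts with the statistical structure the design
targets, plus a known ground truth:

* baseline confounders: a standardized age, an advanced-stage indicator, a
  standardized comorbidity score and a poor-performance-status indicator
  (configurable as named distribution specs);
* one autoregressive time-varying prognostic covariate ("frailty", AR(1)
  around a baseline-shifted mean with slow upward drift) — a
  declining-health proxy that confounds initiation and death beyond
  baseline;
* treatment initiation from a per-interval logistic hazard on baseline and
  time-varying covariates, with a negative time trend by default so
  initiation concentrates early (as adjuvant-therapy decisions do);
* death from a per-interval logistic hazard with a time trend; treatment
  multiplies the death *odds* by `exp(true_log_hr)` from the initiation
  interval onward — the simplest mechanism with a well-defined effect to
  recover;
* administrative censoring at a uniformly drawn interval for a configured
  fraction of patients, with everyone truncated at the horizon.

The generator runs on the same discrete grid as the estimator — there is
deliberately no finer-grained continuous-time layer, because the analysis
model is itself discrete-time and a mismatch would conflate discretization
error with estimator error.

`simulate_counterfactual_risks()` is the ground-truth oracle: it re-runs
the generator with treatment forced to follow one strategy (treat arm:
initiation at its natural time when that falls inside the grace window,
otherwise at the final grace interval; control arm: initiation suppressed
during the window, natural afterwards) and no administrative censoring,
returning empirical cumulative-risk curves. The forced-at-window-close
convention keeps the oracle well defined for natural never-initiators
while matching "initiate within the grace period".

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: unmeasured confounding (every confounder is
measurable and used), treatment-confounder feedback (treatment does not
alter the frailty path), claims artefacts (coding errors, enrollment
gaps, misdated initiation), competing risks, and multi-line therapy
sequencing. Tests against this generator certify the estimator under its
own assumptions, not the assumptions themselves.

## Inference

Confidence intervals come from a nonparametric bootstrap that resamples
*patients* with replacement — both clones of a resampled patient enter
together, since clones are dependent copies of one person — and re-runs
the entire pipeline (censoring, weight-model fits, outcome fits,
standardization) inside every resample, so the intervals carry
weight-estimation uncertainty. Intervals are percentile-based
(assumption-light, no symmetry imposed), 500 resamples and 95% by default.
Resamples in which estimation fails (e.g. an arm with no events in a small
resample) are dropped and counted; more than 20% failures aborts with a
diagnostic rather than returning a silently fragile interval.

Internally the bootstrap uses a precomputed design-matrix engine: because
a patient's clone structure and censoring times are deterministic
functions of that patient's own record, resampling only re-indexes
patient row blocks and re-fits the logistic models, reproducing exactly
what re-running the pipeline on the resampled cohort would produce (the
suite asserts engine/pipeline equality on the full sample).

## Numerical choices

* All logistic fits use iteratively reweighted least squares
  (`stats::glm.fit`) with a deviance tolerance of 1e-10 (1e-12 for
  outcome models, which may be saturated) and up to 100–200 iterations;
  non-convergence is an explicit error, never a silent result.
* The restricted cubic spline uses the truncated-power natural-spline
  parameterization with default knots at 3, 16, 30, 44 and 57 months:
  `k - 1` columns, linear beyond the boundary knots.
* Saturated (indicator) time bases can produce cells with no events;
  IRLS then drives those hazards to numerical zero, which is the correct
  maximum-likelihood limit, and the standardized curves reproduce the
  counting product-limit estimator to near machine precision.
* Initiation probabilities numerically at 0 or 1 on retained rows are a
  positivity violation and raise an error listing the offending rows.
* Degenerate inputs fail loudly: an empty initiation risk set, an
  all-zero/all-one initiation response, an arm with no events (named in
  the message), or a covariate path shorter than follow-up (named
  patient).

## Problem sizes used by the test suite

The packaged checks run, by choice, at sizes where the relevant
asymptotics are visible but a laptop run stays short: product-limit
equivalence on 50 patients; weight calibration on 5 000; null recovery
and effect recovery (true hazard ratio 0.7) as 20 replicates of 2 000
patients over a 24-interval horizon with a 3-interval grace window;
bootstrap coverage as 100 replicates of 100 resamples at 1 000 patients;
coefficient recovery as 20 replicates at 5 000. The acceptance script
reruns the same computations at matching sizes from a single seed.

## Known limitations

* Two arms only; dynamic (covariate-triggered) strategies, re-eligibility
  and sequential trial emulation are out of scope.
* Administrative and loss-to-follow-up censoring are assumed
  noninformative; only artificial (protocol-deviation) censoring is
  weighted.
* The marginal hazard ratio is a discrete-time odds-ratio approximation;
  with per-interval hazards above ~0.1 it drifts from the
  partial-likelihood Cox estimate (a `backend = "cox"` cross-check is
  provided).
* Percentile intervals only — no BCa or studentized bootstrap, no
  sandwich variance.
* No competing risks and no proportional-hazards diagnostics; the
  standardized curves, not the hazard ratio, are the primary summary when
  hazards cross.
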
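---
title: "Correcting for mismeasured exposure histories in longitudinal outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting for mismeasured exposure histories in longitudinal outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlong)
```

## The problem

Epidemiological studies of long-term exposures — air pollution and
cognitive decline is the canonical example — relate a continuous outcome
measured repeatedly over time to a *summary of the exposure history*, such
as the cumulative average of monthly exposure up to each assessment. The
individual exposure measurements feeding that summary are usually
error-prone (for instance, address-based model predictions standing in for
personal exposure). Regressing the outcome on the summary of the surrogate
history biases the effect estimates, and in the linearly divergent
difference (LDD) outcome model the attenuation hits exactly the coefficient
of scientific interest: the exposure-by-time interaction `beta3` that
measures how the outcome trajectory steepens with exposure.

`memlong` implements a two-stage correction for the
main-study/validation-study (MS/VS) design: the main study observes the
outcome `Y`, surrogate exposure `C` and covariates `W`; a (usually much
smaller) validation study observes pairs of the surrogate and the true
exposure `c`.

## Model and assumptions

Outcome model (occasions `t_ij`, history functional `g`,
`X(t_ij) = g(c(t_i1), ..., c(t_ij))`):

`E[Y] = beta0 + beta1 X + beta2 t + beta3 X t + beta4' W`.

Measurement error model (MEM), a calibration-type regression fitted in the
validation study:

`E[c(t) | C(t), t, W(t)] = alpha0 + alpha1 C + alpha2 t + alpha3 C t + alpha4' W`.

Three assumptions make the correction work:

* **Surrogacy** — given the true exposure history, the surrogate history
  carries no further information about the outcome. Testable under an
  internal design (`surrogacy_test()`), assumed under an external one.
* **Localized error** — the true exposure at an occasion depends on the
  current surrogate, time and covariates only, not on past surrogates.
  Testable with repeated validation measurements
  (`localized_error_test()`).
* **Transportability** — the MEM estimated in the validation study is the
  one governing the main study. Comparable across two validation sources
  with `mem_equality_test()`; not verifiable against an external-only VS.

Under surrogacy, iterated expectations give an induced outcome model in
which the unobserved `X` is replaced by `E[X | surrogate history]`; under
localized error that conditional expectation is the history functional
applied to the *pointwise calibrated* values `f(C, t, W; alpha)`
(regression calibration). For the cumulative average this is linear in the
MEM: with no interaction and no covariates, the calibrated history equals
`alpha0 + alpha1 * Z` exactly, where `Z` is the surrogate cumulative
average — which is also why the uncorrected estimator converges to
`alpha1 * beta3` (a 30% attenuation when `alpha1 = 0.7`).

## Exposure-history functionals

`history_spec()` selects the functional:

* `cumavg` — `X(t_j) = sum_{k<j} c_k (t_{k+1} - t_k) / (t_j - t_1)`, the
  gap-weighted average since the first occasion. The forward-gap weighting
  means the exposure at `t_j` itself never contributes to `X(t_j)`; the
  asymmetry is kept deliberately, matching the discrete approximation of a
  running integral.
* `movavg` / `cumsum` — indicator-weighted mean / sum over the closed
  window `[t - b, t]`, with the window length `b` in the units of the
  outcome time scale. Closed endpoints keep occasions falling exactly on
  the boundary.

Absent exposure records (missingness indicator `present = FALSE`) are
skipped by every functional; subjects keep ragged occasion counts and no
imputation is performed, which is valid when missingness is completely at
random.

The cumulative average is undefined at a subject's first occasion. Two
rules are provided because practice needs both: `baseline = "single"`
(default) uses the single exposure value at the first occasion — the
continuity limit of the formula, which keeps every outcome row usable —
and `baseline = "exclude"` drops first occasions from the outcome fit.
The simulator uses `"single"`.

## Estimation and the stacked sandwich

Stage 1 fits the MEM in the validation study: ordinary least squares when
each subject contributes one measurement (to which any working-correlation
choice reduces), GEE with a chosen working correlation otherwise. Stage 2
computes the calibrated history for every main-study subject and solves
the outcome GEE `sum_i X_i' V_i^-1 (Y_i - X_i beta) = 0`. Because the
stacked estimating system in `theta = (alpha, beta)` is block-triangular —
the MEM scores do not involve `beta` — the two-stage solution solves the
full system exactly, so no joint root-finding is needed.

Naive plug-in standard errors for `beta` would ignore that `alpha` was
estimated. The stacked sandwich `Var(theta) = B^-1 A (B^-1)'` restores
validity:

* `A = sum_i psi_i psi_i'`, the empirical outer product of per-subject
  stacked scores. Under an external design each subject contributes either
  `(psi_alpha_i, 0)` or `(0, psi_beta_i)`, so the cross block of `A` is
  zero; under an internal design the overlapping subjects contribute the
  concatenation, which is where the two stages' correlation enters.
* `B` is block lower-triangular with diagonal blocks from the two fits and
  the cross block `d sum(psi_beta) / d alpha` computed by central
  differences with step `1e-6 * (1 + |alpha_k|)`, holding `beta` and the
  working covariance fixed. A closed-form cross block exists for the
  linear no-interaction MEM and is used as an oracle in the test suite;
  numeric differentiation is the default because it covers every term
  combination through one interface.

Under an internal design the validation subjects' outcome rows are
included in the outcome stage by default (their calibrated history is
used, not the observed true exposure); `include_validation_outcomes =
FALSE` excludes them for sensitivity analysis. Point estimates do not
depend on the design label — only the assembly of `A` does.

Two time scales are carried throughout: the MEM always evaluates on
`t_mem` (e.g. age — often the only time variable an external validation
study has), the outcome model and the history weights on `t_outcome`.
When the user supplies a single time column it is copied into both and a
message says so.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `working` (outcome) | `"ar1"` | working correlation: `independence`, `ar1`, `exchangeable`, `unstructured`; affects efficiency, not consistency |
| `mem_working` | `"independence"` | validation-stage working correlation (irrelevant when each subject has one record) |
| `history` | cumulative average, `baseline = "single"` | functional `g`; window `b` in outcome-time units for `movavg`/`cumsum` |
| `maxit`, `tol` | 50, `1e-8` | GEE iteration cap and coefficient-change convergence tolerance |
| `threshold` (confounder screen) | 0.1 | flag covariate sets whose removal changes `beta3` by more than 10% |

Working-covariance nuisances are estimated by moments from standardized
residuals — `phi = sum(e^2) / (N_obs - p)` (the regression-style
denominator; the residual count alone would differ only at order `p/N`),
lag-1 products for AR(1), all-pairs products for exchangeable,
available-pairs moments on a declared occasion grid for unstructured —
and treated as fixed inside the scores and the sandwich, the standard GEE
treatment. Correlation estimates are clamped to `(-0.99, 0.99)`;
`phi` is floored at `1e-12` so that an exactly saturated fit (e.g. a
validation study with zero measurement error) still returns point
estimates, with a warning that the sandwich is unavailable if `B` is
singular. Confidence intervals are Wald z-intervals throughout; no
small-sample degrees-of-freedom correction is applied because coverage is
assessed against normal quantiles.

## The simulator

`scenario_config()` / `generate_scenario()` implement a 2 x 3 factorial
family of true MEMs: interaction present or not (`IP`/`NI`) crossed with a
covariate `W` absent (`NW`), present and independent of `C` (`WP`), or
present and correlated with `C` at 0.4 (`WC`), with
`alpha = (1.2, 0.7, 0.6, 0.5, 0.4)` for the terms present. Surrogates and
covariates are standard normal at each of five occasions; the true
exposure is drawn from the scenario MEM, so the calibration model holds by
construction; outcomes are multivariate normal around the LDD mean
(`beta0 = 0.5`, `beta2 = 3`, `beta4 = 1`, user-chosen `(beta1, beta3)`)
with AR(1) errors, `sigma2_Y = 1`, `rho_Y = 0.1`. Validation subjects keep
all five occasions (`li = 5`) or one uniformly chosen occasion (`li = 1`).

Two generator choices deserve comment:

* **Noise calibration.** Rather than fixing the MEM noise variance, it is
  calibrated so that the model-implied Corr(c, C) matches each scenario's
  target (0.60, 0.65, 0.57, 0.84, 0.85, 0.84) — closed form for the
  no-interaction scenarios, a one-dimensional root-find over the occasion
  grid moments otherwise. Targets at or above the noise-free bound raise a
  calibration error.
* **Occasion grid.** Occasions sit at `t = (1, 2, 3, 4, 5)` for all
  subjects. With standard-normal surrogates, the interaction scenarios'
  correlation targets are attainable on this grid (the noise-free bound
  under a grid starting at 0 falls just below 0.84, making those targets
  unreachable); a grid of strictly positive times also keeps the
  surrogate-by-time interaction informative at every occasion. The same
  variable serves as both time scales in simulation; the two-scale
  machinery is exercised separately in the test suite with an age-like
  offset.

Replication `r` of a Monte-Carlo study uses the seed
`(master * 1009 + r * 7919) mod (2^31 - 1)` (`substream_seed()`), so any
single replication can be regenerated in isolation. `run_sim_study()`
reports relative bias in percent, the empirical standard error (SD of
estimates, the gold standard for the sandwich SE), the mean sandwich SE,
and empirical coverage of nominal 95% intervals, with non-converged
replications excluded and counted. The acceptance band for empirical
coverage is the two-standard-error band `coverage_bounds(R)`, e.g.
[93.6, 96.4]% at 1000 replications.

What the simulator emulates — and what it does not: it produces balanced,
normally distributed exposures and outcomes with a correctly specified
calibration model (except where misspecification is requested by fitting
reduced MEM terms). Passing tests therefore demonstrate the estimator's
behaviour under the design assumptions: they do not speak to informative
dropout (MAR/MNAR), nonlinear calibration relationships, skewed exposure
distributions, or irregular visit schedules in real cohorts. The
diagnostics exist precisely because the assumptions need checking on real
data.

## Problem sizes used in the shipped checks

The test suite runs the factorial study at desk scale: 500 replications
for the headline no-interaction scenario (`n1 = 1000`, `n2 = 100` naive /
`n2 = 500` corrected), 400 for the interaction scenario, 150 per
misspecification arm, 400–500 null simulations for the diagnostic
p-value uniformity checks, and a 500-resample subject bootstrap on one
small dataset (`n1 = 300`, `n2 = 100`) against which the sandwich SE is
compared. `scripts/acceptance.R` uses 1000 replications per study.
Monte-Carlo tolerances in the tests are derived from each run's own
empirical standard error (three standard errors of the mean), not tuned
constants.

## Known limitations

* Identity link and linear-in-parameters models only; no logistic or
  log-link outcomes, and only linear predictors (with optional
  interaction) in the MEM.
* MCAR missingness only; no weighting for MAR dropout.
* The unstructured working correlation needs a common occasion grid;
  subjects missing occasions contribute available pairs.
* No spline or distributed-lag weighting of the exposure history.
* The confounder screen is a change-in-estimate heuristic on the
  uncorrected fit, intended to decide which covariates the MEM must carry,
  not a causal-inference procedure.
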
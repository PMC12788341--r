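---
title: "Classifying cognitive status from naturalistic driving telematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cognitive status from naturalistic driving telematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(telemci)
```

## The problem

Subtle cognitive decline — Pre-MCI and mild cognitive impairment (MCI) —
may show up in how older adults drive long before it is obvious clinically.
In-vehicle telematics units plugged into the OBD-II port record speed, engine
RPM, throttle position, fuel level and tri-axial acceleration every 1–5
seconds, which can be aggregated into trip-level driving behavior indices.
`telemci` implements, end to end, a pipeline that asks: *can a driver's
cognitive status (unimpaired vs Pre-MCI/MCI) be predicted from trip-level
driving behavior?*

The data structure is strongly hierarchical: a few dozen drivers each
contribute tens to hundreds of trips, and the outcome — the driver's
diagnostic group — is *constant within driver*. Everything difficult about
this analysis follows from that fact.

## Cohort labeling

Diagnostic labels combine the Clinical Dementia Rating Sum of Boxes
(CDR-SB, 0–18 in half-point steps) with a neuropsychological (NP) battery
flag ("abnormal in at least one test"):

| CDR-SB | NP normal | NP abnormal |
|--------|-----------|-------------|
| 0 | unimpaired | Pre-MCI |
| 0.5–4.0 | Pre-MCI | MCI |

`classify_cognitive_status()` implements exactly this table. Scores above
4.0 indicate dementia-range staging and are rejected (such participants are
excluded from the study population); scores strictly between 0 and 0.5 are
rejected as undefined — the algorithm has no cell for them, and the package
treats that as an error rather than inventing a rule.

## The synthetic cohort generator

No participant data are deposited, so the package ships a generator
(`cohort_spec()`, `generate_cohort()`) whose defaults emulate the published
cohort: 23 unimpaired, 10 Pre-MCI and 3 MCI drivers; age 75.4 ± 6.3 vs
77.3 ± 6.3 years; education 16.2 ± 3.1 vs 16.0 ± 2.8 years; MoCA
26.8 ± 1.8 vs 25.0 ± 2.2 points (truncated to the eligible 19–30 range);
30–635 trips per driver drawn uniformly (only the range is known; the
uniform is a deliberate, simple choice). Each driver receives

* a latent intercept on the log-odds scale, SD `random_intercept_sd`
  (default 1), and
* a per-feature *behavior offset* in standard-deviation units, SD
  `offset_sd` (default 0.6), plus a signed group shift `effect_vector`.

The default group shifts follow the marginal pattern reported for the
cohort: impaired drivers show higher mean RPM, shorter trips and greater
throttle variability; unimpaired drivers more hard braking and turning,
higher mean speed and steadier (higher) mean throttle.

Two generation modes are provided:

* **Raw streams** (`generate_trip_stream()`): ordered sensor samples with
  gaps uniform on [1, 5] s, a ramp–cruise–ramp speed profile, RPM and
  throttle linked to speed, and hard acceleration/braking/turn events
  injected as short supra-threshold runs at configurable per-minute rates.
  Baseline accelerometer noise is *truncated* strictly below the 0.3 g
  event threshold, so supra-threshold excursions arise only from injected
  events — which makes event-count contracts exactly testable. Two percent
  of trips (configurable) are emitted degenerate (shorter than one minute
  or all-zero speed) to exercise screening.
* **Feature level** (`generate_feature_table()`): trip features are drawn
  from a Gaussian copula around the driver offsets, and labels are drawn
  at the driver level from a logistic model with recorded true
  coefficients and the latent intercept, then driver resampling enforces
  the exact requested group counts. This is the fast path used for
  parameter-recovery experiments; the generating truth is stored alongside
  every dataset.

The copula's default correlation matrix reproduces the sign pattern of the
cohort's reported trip-level correlations. The printed matrix is not
positive semidefinite (its speed/max-speed/RPM triangle is jointly
impossible), so the generator uses the nearest usable matrix by eigenvalue
clipping; this caps the strongest entry near 0.40 while preserving all
signs.

What the generator does *not* emulate: routes and GPS structure, weather
and traffic, longitudinal drift in behavior across quarters, non-uniform
trip-count distributions, and any within-driver outcome variation. Tests
passing on synthetic data therefore demonstrate the *pipeline's*
correctness and calibration, not clinical validity on real streams.

## Trip screening and the ten indices

`screen_trip()` drops trips with fewer than two samples, missing or
non-monotone timestamps, duration under one minute, or all-zero average
speed, with a reason code per drop; `summarize_trip()` computes, per kept
trip: distance (trapezoidal time-integral of speed, km — no odometer
channel is assumed), duration (min), counts of hard accelerations
(longitudinal acceleration > 0.3 g), hard brakings (< −0.3 g) and hard
turns (|lateral| > 0.3 g, both signs by default; a signed-only mode
exists), mean and maximum speed, mean RPM, mean fuel level, mean throttle
and the per-trip sample standard deviation (n−1) of throttle. One
*maximal contiguous supra-threshold run* counts as one event: at 1–5 s
sampling, per-sample counting would double-count single maneuvers. The
0.3 threshold is interpreted as 0.3 g and is configurable.

`standardize()` z-scores features either globally (the primary pipeline,
matching the published analysis) or with training-fold parameters applied
to held-out drivers (the leakage-free scheme used by the stability
analysis).

## The penalized mixed model

The core model is a logistic random-intercept regression for trip-level
outcome $y_{ij}$ of driver $i$:

$$\mathrm{logit}\,P(y_{ij}=1) = \beta_0 + x_{ij}^\top\beta + b_i,\qquad
b_i \sim N(0, \sigma^2_b),$$

with an L1 penalty $\lambda\sum_j|\beta_j|$ on the fixed effects (never
the intercept or the variance). The marginal likelihood is approximated by
the Laplace method — with a single scalar random effect per driver the
per-driver integrand is log-concave and the approximation is accurate —
giving the objective

$$\sum_i\Big[-\ell_i(\hat b_i) + \tfrac{\hat b_i^2}{2\sigma_b^2}
+ \tfrac12\log(1+\sigma_b^2 W_i)\Big] + \lambda\|\beta\|_1,$$

where $\hat b_i$ maximizes the per-driver joint log-density and
$W_i = \sum_j \hat p_{ij}(1-\hat p_{ij})$. As $\sigma_b^2 \to 0$ this
reduces exactly to the plain penalized logistic negative log-likelihood,
which is why the `variance_fixed = 0` fit can be checked against a
brute-force grid minimizer of that objective.

**Optimization.** Block updates, each accepted only when the full
penalized objective decreases (so the recorded trace is non-increasing by
construction):

1. *Fixed effects*: penalized weighted coordinate descent with
   soft-thresholding on the IRLS working response — the same score
   equations used by penalized quasi-likelihood mixed-model software; the
   derivative of the log-determinant term is deliberately omitted from
   this score (its effect is a small systematic shift, about 0.02 on a
   well-behaved fixture when compared with `lme4::glmer`). Exact zeros
   come from the soft-threshold; nothing is rounded to zero afterwards.
2. *Random intercepts*: vectorized per-driver Newton steps.
3. *Variance*: a bounded one-dimensional profile search on the log scale,
   re-bracketed locally and frozen once its improvement stalls.
4. An exact reparameterization absorbs the mean random intercept into the
   fixed intercept (pure descent), and a *zero-polish* step proposes
   zeroing each small penalized coefficient, accepting only on objective
   decrease — the block alternation can otherwise stall with small
   nonzero coefficients that a joint move would remove.

Defaults: at most 500 outer iterations, tolerance $10^{-6}$ on the largest
parameter change (variance measured on the log scale), variance ceiling
$10^5$.

**Quasi-separation.** Because the outcome is constant within driver, the
random intercept can absorb the labels entirely. Under the Laplace
objective the variance then climbs to a very large but finite optimum
(each fully-absorbed driver contributes about $\log 2$ to the negative
log-likelihood), and every fixed-effect score collapses toward zero: at
the unbounded optimum the penalized model retains *nothing*. The fit
raises a loud diagnostic (`quasi_separation`) when outcomes are
driver-constant and the variance reaches its ceiling. The `model_spec`
default keeps the permissive ceiling of $10^5$ so the degeneracy is
visible; the *pipeline* configuration bounds the variance at 10
(random-intercept SD ≈ 3.2 on the log-odds scale — still enormous
heterogeneity) as an explicit regularization, so that penalties can be
compared meaningfully in cross-validation. This mirrors, rather than
hides, the situation in the study, whose reported random-intercept
variance (10,855) is exactly this pathology.

**Post-selection refit.** Predictors retained by the penalized fit enter
an unpenalized fit with the same random-effects structure
(`fit_unpenalized_glmm()`). Standard errors come from the inverse observed
information of the profiled Laplace objective (numerical Hessian over the
fixed effects with the variance at its estimate); a numerically singular
information matrix (relative condition below $10^{-6}$) yields `NA`
standard errors with a diagnostic, never fabricated values. No
post-selection correction is applied; the summaries are exploratory.
Wald tables report $z=\beta/\mathrm{SE}$, two-sided normal $p$, the
interval $\beta \pm 1.96\,\mathrm{SE}$ and its exact exponential transform
to odds ratios.

## Evaluation

Folds are defined *by driver* (`make_grouped_folds()`), stratified by
driver label by default — with 13 positive drivers among 36, unstratified
folds risk single-class held-out sets; infeasible stratification falls
back with a warning. Held-out drivers have no estimated intercept, so
held-out prediction is *marginal* (random effect 0); this is the only
coherent choice and is applied everywhere.

`cross_validate_lambda()` evaluates the study grid λ ∈ {1, 5, 10, 20, 50},
reporting per-penalty mean and SD of held-out AUC across folds and
selecting the maximizer, with exact ties resolved toward the larger
(sparser) penalty. The per-fold AUC can be computed at the trip level (the
default) or at the driver level; the latter is provided because an SD of
≈0.33 across five folds, as reported for the study, is only plausible for
driver-level AUCs on ~7 held-out drivers.

AUC itself is the midrank (Mann–Whitney) statistic — ties count one half —
verified in tests against exhaustive pair counting and against pROC.
Driver-level discrimination averages trip probabilities within driver
(unweighted, so drivers with many trips do not dominate) and ranks the 36
driver means. Confidence intervals come from a percentile bootstrap
resampling *drivers* with replacement (default 2000 replicates;
single-class replicates are redrawn and counted). The trip-level interval
uses the same driver-resampling scheme and may be optimistic; the
driver-level metric is primary.

## Stability selection

The sensitivity analysis (`run_stability()`) drops the random intercept
entirely — driver structure enters only through fold grouping and the
driver-level AUC — and repeats, 100 times by default: fresh driver-level
5-fold assignment; per fold, standardization fitted on training trips
only; an 80-value log-spaced penalty path on [10⁻⁴, 10] fit by coordinate
descent (warm-started from large to small); held-out trips scored and
pooled to one mean probability per driver; the penalty maximizing the
pooled driver-level AUC selected (ties to the sparser penalty); and a
full-data refit at that penalty recording the nonzero set. Selection
frequency is the percentage of successful repetitions in which a
predictor keeps a nonzero coefficient. Here the penalty multiplies the
*per-observation* negative log-likelihood (the convention of standard
lasso software): with ~5000–11000 trips, a grid reaching only 10 would
otherwise shrink nothing, and the study's reported chosen penalties
(median ≈ 0.09) sit exactly in this parameterization's active range.
Quartiles use linear interpolation between order statistics (R type 7).

**A genuine limitation worth knowing.** With the signal destroyed (label
permutation, or no-signal data), the driver-level AUC landscape over the
penalty grid is pure noise around one half, so the per-repetition argmax
often lands on an essentially arbitrary small penalty; the full-data refit
— which sees the *same* dataset every repetition — then re-selects
whatever predictor happens to be spuriously correlated in that dataset.
At small driver counts this can push a null predictor's selection
frequency far above 50%. Stability selection with proper error control
would resample the *refit* data as well; the frequency tabulation
implemented here follows the simpler published procedure, so null
selection frequencies should be interpreted against this behavior. At the
200-driver scale used in the calibration experiments the no-signal
frequencies stayed at or below 60%.

## Calibration of the recovery experiments

The parameter-recovery experiments use 200 drivers × 50 trips with true
log-odds coefficients (+1, −1, 0, 0, 0) and latent intercept SD 1. The
remaining free quantity is the scale of between-driver behavior
heterogeneity, `offset_sd`. Because labels are generated from driver-level
behavior through a logistic link, discrimination has a Bayes ceiling: with
`offset_sd = 1` even the true coefficient vector cannot exceed a
driver-level AUC of about 0.77. The experiments therefore set
`offset_sd = 2` — between-driver behavior variation twice the
within-driver trip noise, a "strongly separable cohort" — for which the
Bayes driver-level AUC is ≈ 0.89. This choice was fixed once, from that
closed-form-style calculation, before the recovery tests were run. Penalty
selection in these experiments uses the driver-level CV AUC, where exact
ties are common and the sparser-penalty tie rule does real work.

## Problem sizes used by the test suite

The unit tests run on small fixtures (tens of drivers, tens of trips);
the acceptance-style checks run the recovery experiments at 200 × 50 over
20 seeds, one 100-repetition stability run each on strong-signal and
no-signal data, and one full default-configuration pipeline run
(36 drivers, ~11,000 trips, the study penalty grid, 2000 bootstrap
replicates, 100 stability repetitions). Byte-identical reproducibility of
the report files is asserted on a scaled-down configuration; all other
determinism (generators, fits, bootstrap, stability) is asserted at full
fidelity through fixed seeds. A single master seed fans out to named
sub-seeds (cohort, streams, folds, bootstrap, stability) so stages are
independently reproducible.

## Known limitations

* The synthetic cohort is a statistical emulation; no claim is made that
  its stream waveforms resemble real vehicle dynamics beyond the aggregate
  indices and their correlation signs.
* With driver-constant outcomes the fixed effects are identified mainly
  through the penalty, the variance bound and cross-validation; Wald
  summaries from the post-selection refit are exploratory.
* The stability analysis's full-data refit re-uses one dataset across
  repetitions (see above); its selection frequencies are descriptive, not
  error-controlled.
* Quantities that depend on the undeposited study data (the exact
  reported AUCs and selection-frequency tables) are reproduced in
  *structure* and mechanism, not in value.
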
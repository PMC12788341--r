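# telemci

Telematics-based classification of cognitive status in older drivers.

Naturalistic driving studies equip older adults' vehicles with OBD-II
telematics units that sample speed, engine RPM, throttle position, fuel
level and tri-axial acceleration every 1–5 seconds. `telemci` implements a
complete analysis pipeline that asks whether a driver's cognitive status —
unimpaired versus Pre-MCI/MCI (pre-clinical or mild cognitive impairment)
— can be predicted from ten trip-level driving behavior indices: trip
distance, counts of hard accelerations, hard brakings and hard turns
(longitudinal/lateral acceleration beyond ±0.3 g), mean and maximum speed,
mean RPM, mean fuel level, mean throttle position and per-trip throttle
variability.

## The model

Trips are nested within drivers and the outcome is constant within driver,
so the core model is an L1-penalized logistic regression with a per-driver
random intercept. For trip *j* of driver *i*,

    logit P(y_ij = 1) = beta0 + x_ij' beta + b_i,    b_i ~ N(0, sigma_b^2),

fit by minimizing the Laplace-approximated negative marginal log-likelihood
plus `lambda * sum(|beta_j|)` (soft-thresholding gives exact zeros). The
penalty is tuned by 5-fold cross-validation **grouped by driver** — all of
a driver's trips are held out together — scoring held-out drivers in
marginal mode (no estimated intercept). Retained predictors are refit
unpenalized for Wald/odds-ratio summaries; discrimination is reported as
both trip-level and the more conservative driver-level AUC (one mean
predicted probability per driver) with driver-bootstrap percentile
intervals; and a repeated grouped-CV stability analysis (plain L1 logistic
regression, fold-wise standardization, per-repetition penalty choice by
driver-level AUC, full-data refit) tabulates how often each predictor
keeps a nonzero coefficient.

Because no participant data are deposited, the package includes a
synthetic cohort generator that emulates the study: 36 drivers (23
unimpaired, 10 Pre-MCI, 3 MCI), published demographic marginals, 30–635
trips per driver, raw sensor streams with injected hard events, the
diagnostic algorithm combining CDR-SB with neuropsychological testing, and
a feature-level fast path with recorded ground truth for
parameter-recovery experiments.

## Worked example

```r
library(telemci)
report <- run_pipeline(default_run_config(out_dir = "run1", seed = 123))
print(report)
#> telemci run report
#>   11017 trips from 36 drivers (13 Pre-MCI/MCI)
#>   selected lambda: 1
#>   trip-level AUC 0.863 [0.714, 0.969]; driver-level AUC 0.886 [0.743, 0.991]
#>   stability: top predictor throttle_mean (100%)
report$lambda_grid$table
#>   lambda  mean_auc     sd_auc folds_used
#> 1      1 0.8692927 0.05981912          5
#> 2      5 0.7513393 0.07702371          5
#> 3     10 0.5000000 0.00000000          5
#> 4     20 0.5000000 0.00000000          5
#> 5     50 0.5000000 0.00000000          5
```

This simulates the cohort, generates and screens ~11,000 raw trip streams
(trips shorter than one minute or with zero average speed are dropped),
computes and z-scores the ten indices, tunes the penalty on the grid
λ ∈ {1, 5, 10, 20, 50} (here λ = 1 maximizes mean held-out AUC; λ ≥ 10
shrinks every coefficient to zero, so held-out discrimination collapses to
0.5), refits the retained predictors, and evaluates discrimination at both
levels. The driver-level AUC of 0.886 with bootstrap interval
[0.743, 0.991] says the model ranks a randomly chosen impaired driver
above a randomly chosen unimpaired driver about 89% of the time on
held-in data scored without driver intercepts. The stability analysis
(100 repetitions, 80-penalty grid on [1e-4, 10]) found mean throttle and
throttle variability — the pedal-control features the generator plants as
the strongest group differences — selected in 100% of repetitions, with
every other index below 10%; chosen penalties had median 0.061.

The fitted random-intercept variance sits at its configured bound with a
loud quasi-separation diagnostic: outcomes are constant within driver, so
the random intercept could absorb the labels entirely — the package
documents and regularizes this degeneracy rather than hiding it (see the
methods vignette, `vignettes/telemci-methods.Rmd`).

All report tables (cohort descriptives, feature correlations, the penalty
grid, coefficient/odds-ratio tables, ROC summaries and curve points,
stability distributions and selection frequencies) are also written as
tab-separated files under the output directory, plus JSON fits and a YAML
echo of the fully-resolved configuration.

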
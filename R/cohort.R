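# ------------------------------------------------------------------------
# Synthetic study cohort: driver profiles, diagnostic labeling, raw sensor
# streams and a fast feature-level generator with known ground truth.
# ------------------------------------------------------------------------

#' Specify a synthetic driving-study cohort
#'
#' Defines the conditions under which drivers, diagnostic scores and trips
#' are simulated. Defaults emulate the published cohort: 23 cognitively
#' unimpaired drivers and 13 with Pre-MCI (10) or MCI (3), demographic
#' marginals per group (age 75.4 +/- 6.3 vs 77.3 +/- 6.3 years, education
#' 16.2 +/- 3.1 vs 16.0 +/- 2.8 years, MoCA 26.8 +/- 1.8 vs 25.0 +/- 2.2
#' with an eligibility floor of 19), and 30 to 635 trips per driver over a
#' three-month window.
#'
#' Group effects on driving behavior are expressed in standard-deviation
#' units of the ten trip-level indices via `effect_vector` (positive values
#' shift the impaired group upward). Driver-level heterogeneity enters
#' through a per-feature behavior offset with standard deviation
#' `offset_sd` and a latent log-odds intercept with standard deviation
#' `random_intercept_sd`.
#'
#' @param n_unimpaired,n_premci,n_mci Group sizes (non-negative counts).
#' @param age_mean,age_sd,edu_mean,edu_sd,moca_mean,moca_sd Length-2 numeric
#'   vectors `(unimpaired, impaired)` of per-group means and SDs.
#' @param p_male Length-2 probabilities of male sex per group.
#' @param trips_min,trips_max Range of trips per driver (uniform).
#' @param random_intercept_sd SD of the latent driver intercept (log-odds).
#' @param offset_sd SD of per-feature driver behavior offsets (SD units).
#' @param effect_vector Named numeric vector of signed group shifts in SD
#'   units, one per feature; names define the feature set.
#' @param true_fixed_effects Named numeric vector of log-odds coefficients
#'   used by the feature-level generator to tie features to labels.
#' @param true_intercept Log-odds intercept of the feature-level label model.
#' @param sampling_interval_range Inter-sample gap range in seconds, within
#'   `[1, 5]`.
#' @param event_rates Named rates per minute of driving for injected hard
#'   acceleration, braking and turning events: `c(accel=, brake=, turn=)`.
#' @param degenerate_rate Proportion of trips emitted degenerate (shorter
#'   than one minute or with all-zero speed) to exercise screening.
#' @param seed Integer master seed.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_unimpaired = 23, n_premci = 10, n_mci = 3,
                        age_mean = c(75.4, 77.3), age_sd = c(6.3, 6.3),
                        edu_mean = c(16.2, 16.0), edu_sd = c(3.1, 2.8),
                        moca_mean = c(26.8, 25.0), moca_sd = c(1.8, 2.2),
                        p_male = c(14 / 23, 9 / 13),
                        trips_min = 30, trips_max = 635,
                        random_intercept_sd = 1,
                        offset_sd = 0.6,
                        effect_vector = default_effect_vector(),
                        true_fixed_effects = default_true_fixed_effects(),
                        true_intercept = -0.6,
                        sampling_interval_range = c(1, 5),
                        event_rates = c(accel = 0.3, brake = 0.4, turn = 0.5),
                        degenerate_rate = 0.02,
                        seed = 20260101L) {
  stopifnot(
    n_unimpaired >= 0, n_premci >= 0, n_mci >= 0,
    trips_min >= 1, trips_max >= trips_min,
    random_intercept_sd >= 0, offset_sd >= 0,
    degenerate_rate >= 0, degenerate_rate < 1,
    length(sampling_interval_range) == 2
  )
  if (sampling_interval_range[1] < 1 || sampling_interval_range[2] > 5 ||
      diff(sampling_interval_range) < 0) {
    stop("sampling_interval_range must lie within [1, 5] seconds")
  }
  if (any(moca_mean < 19) || any(moca_mean > 30)) {
    stop("moca_mean outside the eligible range [19, 30]")
  }
  if (is.null(names(effect_vector))) {
    stop("effect_vector must be named by feature")
  }
  spec <- list(
    n_unimpaired = as.integer(n_unimpaired),
    n_premci = as.integer(n_premci), n_mci = as.integer(n_mci),
    age_mean = age_mean, age_sd = age_sd,
    edu_mean = edu_mean, edu_sd = edu_sd,
    moca_mean = moca_mean, moca_sd = moca_sd,
    p_male = p_male,
    trips_min = as.integer(trips_min), trips_max = as.integer(trips_max),
    random_intercept_sd = random_intercept_sd,
    offset_sd = offset_sd,
    effect_vector = effect_vector,
    true_fixed_effects = true_fixed_effects,
    true_intercept = true_intercept,
    sampling_interval_range = sampling_interval_range,
    event_rates = event_rates,
    degenerate_rate = degenerate_rate,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

# Marginal group shifts (impaired minus unimpaired, SD units): impaired
# drivers show higher RPM, shorter trips and greater throttle variability;
# unimpaired drivers more hard braking and turning, higher mean speed and
# steadier (higher) mean throttle.
default_effect_vector <- function() {
  c(distance = -0.4, n_hard_accel = 0, n_hard_brake = -0.4,
    n_hard_turn = -0.3, speed_mean = -0.4, speed_max = 0,
    rpm_mean = 0.5, fuel_mean = 0, throttle_mean = -0.5, throttle_sd = 0.6)
}

# Log-odds per SD used when labels are generated from features directly.
default_true_fixed_effects <- function() {
  c(distance = 0.28, n_hard_accel = 0, n_hard_brake = -0.72,
    n_hard_turn = 0.22, speed_mean = -0.67, speed_max = 0,
    rpm_mean = 0.68, fuel_mean = -0.19, throttle_mean = -0.64,
    throttle_sd = 0.58)
}

#' Classify cognitive status from CDR-SB and neuropsychological testing
#'
#' Implements the diagnostic algorithm combining the Clinical Dementia
#' Rating Sum of Boxes (CDR-SB) with the neuropsychological (NP) battery:
#' unimpaired requires CDR-SB = 0 and normal NP; MCI requires CDR-SB in
#' 0.5-4.0 and abnormal NP; Pre-MCI is either single abnormality.
#'
#' @param cdr_sb Numeric CDR-SB score(s), each 0 or in `[0.5, 4]`.
#' @param np_abnormal Logical: abnormal performance on at least one NP test.
#' @return Character vector with values `"unimpaired"`, `"pre_mci"`, `"mci"`.
#' @export
classify_cognitive_status <- function(cdr_sb, np_abnormal) {
  stopifnot(is.numeric(cdr_sb), is.logical(np_abnormal))
  if (length(np_abnormal) == 1) np_abnormal <- rep(np_abnormal, length(cdr_sb))
  stopifnot(length(cdr_sb) == length(np_abnormal), all(cdr_sb >= 0))
  if (any(cdr_sb > 4)) {
    stop("CDR-SB above 4.0: dementia-range staging, outside the diagnostic algorithm")
  }
  if (any(cdr_sb > 0 & cdr_sb < 0.5)) {
    stop("CDR-SB in (0, 0.5) is not a defined cell of the diagnostic algorithm")
  }
  cdr_flag <- cdr_sb >= 0.5
  out <- ifelse(cdr_flag & np_abnormal, "mci",
         ifelse(cdr_flag | np_abnormal, "pre_mci", "unimpaired"))
  out
}

# truncated normal by rejection; ranges here are wide so this is cheap
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower > upper) stop("impossible truncation range")
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1
    if (guard > 10000) stop("impossible truncation range: rejection sampling failed")
  }
  out
}

#' Generate a synthetic cohort of driver profiles
#'
#' Draws demographics from per-group truncated normals (age >= 65, MoCA in
#' `[19, 30]`), samples per-driver trip counts uniformly on
#' `[trips_min, trips_max]`, assigns diagnostic scores (CDR-SB in half-point
#' steps, NP abnormality flag) consistent with each requested group, and
#' regenerates the group label through [classify_cognitive_status()] as a
#' consistency check. Latent driver structure (behavior offsets, random
#' intercept) is drawn and recorded together with the generating truth.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `telemci_cohort` with elements `profiles` (one
#'   row per driver: identifiers, demographics, diagnostic scores, label,
#'   trip count, latent intercept and `off_*` behavior offsets) and `truth`
#'   (the generator's parameters, for parameter-recovery checks).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(c("unimpaired", "pre_mci", "mci"),
                times = c(spec$n_unimpaired, spec$n_premci, spec$n_mci))
  n <- length(groups)
  if (n == 0) stop("empty cohort requested")
  imp <- as.integer(groups != "unimpaired") + 1L  # 1 = unimpaired, 2 = impaired

  cdr <- numeric(n)
  np <- logical(n)
  cdr_levels <- seq(0.5, 4, by = 0.5)
  for (i in seq_len(n)) {
    if (groups[i] == "unimpaired") {
      cdr[i] <- 0; np[i] <- FALSE
    } else if (groups[i] == "mci") {
      cdr[i] <- sample(cdr_levels, 1); np[i] <- TRUE
    } else if (runif(1) < 0.5) {
      cdr[i] <- 0; np[i] <- TRUE
    } else {
      cdr[i] <- sample(cdr_levels, 1); np[i] <- FALSE
    }
  }
  relabel <- classify_cognitive_status(cdr, np)
  stopifnot(identical(relabel, groups))

  age <- rtrunc_norm(n, spec$age_mean[imp], spec$age_sd[imp], lower = 65)
  edu <- round(rtrunc_norm(n, spec$edu_mean[imp], spec$edu_sd[imp], lower = 6, upper = 24))
  moca <- round(rtrunc_norm(n, spec$moca_mean[imp], spec$moca_sd[imp], lower = 19, upper = 30))
  male <- rbinom(n, 1, spec$p_male[imp]) == 1
  n_trips <- spec$trips_min + floor(runif(n) * (spec$trips_max - spec$trips_min + 1))
  latent <- rnorm(n, 0, spec$random_intercept_sd)

  feats <- names(spec$effect_vector)
  offsets <- matrix(rnorm(n * length(feats), 0, spec$offset_sd),
                    nrow = n, dimnames = list(NULL, feats))
  offsets <- offsets + outer(as.numeric(imp == 2), spec$effect_vector)

  profiles <- data.frame(
    driver_id = sprintf("D%03d", seq_len(n)),
    group_label = groups,
    age = age, education = edu, moca = moca, male = male,
    cdr_sb = cdr, np_abnormal = np,
    n_trips = as.integer(n_trips),
    latent_intercept = latent,
    stringsAsFactors = FALSE
  )
  off_df <- as.data.frame(offsets)
  names(off_df) <- paste0("off_", feats)
  profiles <- cbind(profiles, off_df)

  truth <- list(
    features = feats,
    effect_vector = spec$effect_vector,
    true_fixed_effects = spec$true_fixed_effects,
    true_intercept = spec$true_intercept,
    true_random_intercept_sd = spec$random_intercept_sd,
    offset_sd = spec$offset_sd,
    seed = spec$seed
  )
  structure(list(profiles = profiles, truth = truth, spec = spec),
            class = "telemci_cohort")
}

#' @export
print.telemci_cohort <- function(x, ...) {
  tab <- table(x$profiles$group_label)
  cat("Synthetic driving cohort:", nrow(x$profiles), "drivers (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  cat("Trips per driver:", min(x$profiles$n_trips), "-", max(x$profiles$n_trips),
      "; total", sum(x$profiles$n_trips), "\n")
  invisible(x)
}

# clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate one raw sensor stream for a trip
#'
#' Emits ordered samples (timestamp, speed, RPM, throttle, fuel, tri-axial
#' acceleration in g) with inter-sample gaps drawn uniformly from the
#' configured sampling-interval range. The driver's latent behavior offsets
#' shift trip duration, cruise speed, mean RPM, mean throttle, throttle
#' variability and hard-event rates in the configured directions. Baseline
#' accelerometer noise is truncated below the event threshold so that
#' supra-threshold excursions occur only through injected events. A
#' configurable proportion of trips is emitted degenerate (shorter than one
#' minute, or with all-zero speed) to exercise screening.
#'
#' @param driver One row of a cohort's `profiles` table (or an equivalent
#'   list with `driver_id` and `off_*` entries).
#' @param trip_index Trip number for this driver (used in the trip id).
#' @param spec The [cohort_spec()] governing stream generation.
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return A data frame with columns `driver_id, trip_id, t_s, speed_kmh,
#'   rpm, throttle_pct, fuel_pct, accel_x_g, accel_y_g, accel_z_g`.
#' @export
generate_trip_stream <- function(driver, trip_index = 1, spec = cohort_spec(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  off <- function(f) {
    v <- driver[[paste0("off_", f)]]
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }
  lo <- spec$sampling_interval_range[1]
  hi <- spec$sampling_interval_range[2]

  degenerate <- runif(1) < spec$degenerate_rate
  deg_type <- if (degenerate) sample(c("too_short", "zero_speed"), 1) else "none"

  duration <- rlnorm(1, meanlog = log(420) + 0.4 * off("distance"), sdlog = 0.6)
  duration <- clamp(duration, 75, 3600)
  if (deg_type == "too_short") duration <- runif(1, 15, 55)

  gaps <- runif(ceiling(duration / lo) + 2, lo, hi)
  t <- c(0, cumsum(gaps))
  t <- t[t <= duration]
  if (length(t) < 2) t <- c(0, duration)
  m <- length(t)

  ramp <- min(60, duration / 4)
  cruise <- max(8, rnorm(1, 45 * exp(0.12 * off("speed_mean")), 8))
  shape <- pmin(1, pmin(t / ramp, (duration - t) / ramp))
  speed <- clamp(cruise * shape + rnorm(m, 0, 3), 0, 200)
  if (deg_type == "zero_speed") speed <- rep(0, m)

  rpm <- clamp(750 + speed * 32 * exp(0.10 * off("rpm_mean")) + rnorm(m, 0, 80),
               600, 7000)
  throttle <- clamp(18 + 0.45 * speed + 3 * off("throttle_mean") +
                      rnorm(m, 0, 6 * exp(0.35 * off("throttle_sd"))), 0, 100)
  f0 <- clamp(runif(1, 20, 95) + 2 * off("fuel_mean"), 5, 100)
  fuel <- clamp(f0 - t / 3600 * 3 + rnorm(m, 0, 0.2), 0, 100)

  # baseline accelerometer noise, truncated strictly below the 0.3 g threshold
  ax <- clamp(rnorm(m, 0, 0.05), -0.25, 0.25)
  ay <- clamp(rnorm(m, 0, 0.05), -0.25, 0.25)
  az <- 1 + clamp(rnorm(m, 0, 0.02), -0.1, 0.1)

  mins <- duration / 60
  inject <- function(base, n_events, sign) {
    if (n_events <= 0 || m < 2) return(base)
    for (k in seq_len(n_events)) {
      start <- sample.int(m, 1)
      len <- sample(1:3, 1)
      idx <- start:min(m, start + len - 1)
      base[idx] <- sign * runif(1, 0.32, 0.6)
    }
    base
  }
  rate <- spec$event_rates
  ax <- inject(ax, rpois(1, mins * rate[["accel"]] * exp(0.5 * off("n_hard_accel"))), +1)
  ax <- inject(ax, rpois(1, mins * rate[["brake"]] * exp(0.5 * off("n_hard_brake"))), -1)
  n_turn <- rpois(1, mins * rate[["turn"]] * exp(0.5 * off("n_hard_turn")))
  if (n_turn > 0) {
    for (k in seq_len(n_turn)) ay <- inject(ay, 1, sample(c(-1, 1), 1))
  }

  data.frame(
    driver_id = as.character(driver[["driver_id"]]),
    trip_id = sprintf("%s_T%04d", driver[["driver_id"]], trip_index),
    t_s = t, speed_kmh = speed, rpm = rpm, throttle_pct = throttle,
    fuel_pct = fuel, accel_x_g = ax, accel_y_g = ay, accel_z_g = az,
    stringsAsFactors = FALSE
  )
}

#' Generate raw sensor streams for a whole cohort
#'
#' Loops over drivers and trips, deriving one reproducible sub-seed per trip
#' from the cohort seed, and row-binds all samples.
#'
#' @param cohort A [generate_cohort()] result.
#' @param seed Master seed for the streams; defaults to the cohort seed + 1.
#' @return A long data frame in the stream schema (one row per sample).
#' @export
generate_streams <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "telemci_cohort"))
  seed <- seed %||% (cohort$spec$seed + 1L)
  prof <- cohort$profiles
  out <- vector("list", sum(prof$n_trips))
  k <- 0
  for (i in seq_len(nrow(prof))) {
    for (j in seq_len(prof$n_trips[i])) {
      k <- k + 1
      out[[k]] <- generate_trip_stream(prof[i, ], j, cohort$spec,
                                       seed = derive_seed(seed, k))
    }
  }
  do.call(rbind, out)
}

# positive-definite repair by eigenvalue clipping (preserves the large
# entries far better than shrinkage toward the identity)
make_pd <- function(R, eps = 1e-4) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) > eps) return(R)
  v <- pmax(e$values, eps)
  S <- e$vectors %*% (v * t(e$vectors))
  S <- stats::cov2cor(S)
  dimnames(S) <- dimnames(R)
  S
}

#' Default trip-level correlation pattern of the driving behavior indices
#'
#' The empirical Pearson correlations among the ten indices reported for
#' the study cohort (speed/max-speed strongly positive, mean throttle vs
#' throttle variability negative, etc.), repaired to the nearest usable
#' positive-definite matrix for copula sampling.
#'
#' @return A 10 x 10 correlation matrix named by [telemci_features()].
#' @export
default_feature_correlation <- function() {
  f <- TELEMCI_FEATURES
  R <- diag(10)
  dimnames(R) <- list(f, f)
  set_r <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_r("distance", "n_hard_accel", -0.03); set_r("distance", "n_hard_brake", -0.06)
  set_r("distance", "n_hard_turn", -0.02); set_r("distance", "speed_mean", -0.48)
  set_r("distance", "speed_max", 0.48); set_r("distance", "rpm_mean", 0.09)
  set_r("distance", "fuel_mean", -0.04); set_r("distance", "throttle_mean", -0.12)
  set_r("distance", "throttle_sd", 0.15)
  set_r("n_hard_accel", "n_hard_brake", -0.24); set_r("n_hard_accel", "n_hard_turn", -0.35)
  set_r("n_hard_accel", "speed_mean", 0.10); set_r("n_hard_accel", "speed_max", 0.29)
  set_r("n_hard_accel", "rpm_mean", -0.09); set_r("n_hard_accel", "fuel_mean", 0.05)
  set_r("n_hard_accel", "throttle_mean", -0.18); set_r("n_hard_accel", "throttle_sd", 0.04)
  set_r("n_hard_brake", "n_hard_turn", -0.38); set_r("n_hard_brake", "speed_mean", -0.06)
  set_r("n_hard_brake", "speed_max", 0.37); set_r("n_hard_brake", "rpm_mean", 0.03)
  set_r("n_hard_brake", "fuel_mean", -0.03); set_r("n_hard_brake", "throttle_mean", -0.05)
  set_r("n_hard_brake", "throttle_sd", -0.01)
  set_r("n_hard_turn", "speed_mean", -0.13); set_r("n_hard_turn", "speed_max", 0.45)
  set_r("n_hard_turn", "rpm_mean", 0.09); set_r("n_hard_turn", "fuel_mean", 0.06)
  set_r("n_hard_turn", "throttle_mean", 0.11); set_r("n_hard_turn", "throttle_sd", -0.16)
  set_r("speed_mean", "speed_max", 0.76); set_r("speed_mean", "rpm_mean", -0.63)
  set_r("speed_mean", "fuel_mean", 0.02); set_r("speed_mean", "throttle_mean", 0.18)
  set_r("speed_mean", "throttle_sd", -0.10)
  set_r("speed_max", "rpm_mean", 0.72); set_r("speed_max", "fuel_mean", -0.01)
  set_r("speed_max", "throttle_mean", 0.09); set_r("speed_max", "throttle_sd", 0.31)
  set_r("rpm_mean", "fuel_mean", 0.00); set_r("rpm_mean", "throttle_mean", -0.29)
  set_r("rpm_mean", "throttle_sd", -0.14)
  set_r("fuel_mean", "throttle_mean", 0.05); set_r("fuel_mean", "throttle_sd", -0.03)
  set_r("throttle_mean", "throttle_sd", -0.41)
  make_pd(R)
}

#' Generate a trip-level feature table directly (fast path)
#'
#' Skips raw streams: trip features are drawn from a Gaussian copula around
#' each driver's latent behavior offsets, and the binary outcome is assigned
#' at the driver level from a logistic model with the recorded true fixed
#' effects and the driver's latent intercept. All trips of a driver share
#' the driver's label. After labels are drawn, drivers are resampled (with
#' replacement within the realized classes) so the cohort hits the exact
#' requested group counts; clones receive fresh trip-level noise.
#'
#' Because labels are generated *from* the features here, the group-shift
#' `effect_vector` of the spec plays no role in this mode; the signal is
#' carried entirely by `true_fixed_effects` acting on the driver offsets.
#'
#' @param cohort A [generate_cohort()] result.
#' @param truth Optional override of the cohort's generator truth (a list
#'   with `true_fixed_effects`, `true_intercept`).
#' @param correlation Trip-noise correlation matrix across features;
#'   defaults to [default_feature_correlation()] when the feature set is the
#'   standard ten, otherwise the identity.
#' @param seed Integer seed; defaults to the cohort seed + 2.
#' @return A data frame of class `telemci_features` with one row per trip:
#'   `driver_id`, `trip_id`, the feature columns, and `outcome` (0/1). The
#'   generating truth is attached as attribute `"truth"`.
#' @export
generate_feature_table <- function(cohort, truth = NULL, correlation = NULL,
                                   seed = NULL) {
  stopifnot(inherits(cohort, "telemci_cohort"))
  truth <- truth %||% cohort$truth
  seed <- seed %||% (cohort$spec$seed + 2L)
  set.seed(seed)
  beta <- truth$true_fixed_effects
  feats <- names(beta)
  prof <- cohort$profiles
  offc <- paste0("off_", feats)
  if (!all(offc %in% names(prof))) {
    stop("cohort profiles lack behavior offsets for: ",
         paste(setdiff(offc, names(prof)), collapse = ", "))
  }
  if (is.null(correlation)) {
    correlation <- if (identical(feats, TELEMCI_FEATURES)) {
      default_feature_correlation()
    } else diag(length(feats))
  }
  stopifnot(nrow(correlation) == length(feats))
  L <- chol(make_pd(correlation))

  eta <- truth$true_intercept +
    as.matrix(prof[, offc, drop = FALSE]) %*% beta + prof$latent_intercept
  y <- rbinom(nrow(prof), 1, plogis(drop(eta)))

  n_pos <- cohort$spec$n_premci + cohort$spec$n_mci
  n_neg <- cohort$spec$n_unimpaired
  pos_pool <- which(y == 1)
  neg_pool <- which(y == 0)
  if (n_pos > 0 && length(pos_pool) == 0) {
    stop("no driver realized a positive label; cannot rebalance to requested counts")
  }
  if (n_neg > 0 && length(neg_pool) == 0) {
    stop("no driver realized a negative label; cannot rebalance to requested counts")
  }
  draw <- function(pool, k) {
    if (k == 0) return(integer(0))
    if (length(pool) >= k) sample(pool, k) else
      c(pool, sample(pool, k - length(pool), replace = TRUE))
  }
  sel <- c(draw(neg_pool, n_neg), draw(pos_pool, n_pos))
  lab <- rep(c(0L, 1L), c(n_neg, n_pos))

  # rebalanced profile table (clones keep their source's latent structure)
  newprof <- prof[sel, , drop = FALSE]
  newprof$driver_id <- sprintf("S%03d", seq_along(sel))
  newprof$group_label <- ifelse(lab == 1,
                                ifelse(newprof$group_label == "unimpaired",
                                       "pre_mci", newprof$group_label),
                                "unimpaired")
  # keep diagnostic scores consistent with the reassigned labels
  flip0 <- lab == 0L
  newprof$cdr_sb[flip0] <- 0
  newprof$np_abnormal[flip0] <- FALSE
  flip1 <- lab == 1L & newprof$cdr_sb == 0 & !newprof$np_abnormal
  newprof$np_abnormal[flip1] <- TRUE
  stopifnot(identical(classify_cognitive_status(newprof$cdr_sb,
                                                newprof$np_abnormal) != "unimpaired",
                      lab == 1L))
  rownames(newprof) <- NULL

  rows <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    src <- sel[i]
    nt <- prof$n_trips[src]
    Z <- matrix(rnorm(nt * length(feats)), nt) %*% L
    X <- sweep(Z, 2, as.numeric(prof[src, offc]), "+")
    colnames(X) <- feats
    rows[[i]] <- data.frame(
      driver_id = sprintf("S%03d", i),
      trip_id = sprintf("S%03d_T%04d", i, seq_len(nt)),
      X, outcome = lab[i],
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "cohort") <- structure(
    list(profiles = newprof, truth = truth, spec = cohort$spec),
    class = "telemci_cohort")
  class(out) <- c("telemci_features", class(out))
  out
}

# ---- delimited-text writers/readers (exact numeric round-trip) -----------

format_numeric_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write / read sensor streams and feature tables as delimited text
#'
#' Tab-separated text with a header row; doubles are written with 17
#' significant digits so that tables round-trip without loss.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_*` return the data frame; `write_*` return `path`
#'   invisibly.
#' @name stream_io
#' @export
write_trip_streams <- function(x, path) {
  utils::write.table(format_numeric_cols(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_trip_streams <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(driver_id = "character", trip_id = "character"),
                    stringsAsFactors = FALSE)
}

#' @rdname stream_io
#' @export
write_feature_table <- function(x, path) {
  utils::write.table(format_numeric_cols(as.data.frame(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_feature_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(driver_id = "character",
                                          trip_id = "character"),
                           stringsAsFactors = FALSE)
  class(out) <- c("telemci_features", class(out))
  out
}

#' @rdname stream_io
#' @export
write_generator_truth <- function(x, path) {
  for (f in c("effect_vector", "true_fixed_effects")) {
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_generator_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("effect_vector", "true_fixed_effects")) {
    if (!is.null(out[[f]])) out[[f]] <- unlist(out[[f]])
  }
  out
}
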
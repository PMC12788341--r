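test_that("diagnostic algorithm matches the truth table over all defined cells", {
  # (CDR-SB, NP) -> label, exhaustive over the four defined cells
  expect_identical(classify_cognitive_status(0, FALSE), "unimpaired")
  expect_identical(classify_cognitive_status(0, TRUE), "pre_mci")
  expect_identical(classify_cognitive_status(0.5, FALSE), "pre_mci")
  expect_identical(classify_cognitive_status(2.0, TRUE), "mci")
  # every half-point CDR-SB in the defined range behaves like its row
  for (cdr in seq(0.5, 4, by = 0.5)) {
    expect_identical(classify_cognitive_status(cdr, FALSE), "pre_mci")
    expect_identical(classify_cognitive_status(cdr, TRUE), "mci")
  }
})

test_that("diagnostic algorithm rejects out-of-range and undefined scores", {
  expect_error(classify_cognitive_status(4.5, TRUE), "dementia")
  expect_error(classify_cognitive_status(0.25, FALSE), "not a defined cell")
  expect_error(classify_cognitive_status(-1, FALSE))
})

test_that("generated cohorts hit requested group counts with consistent labels", {
  co <- generate_cohort(cohort_spec(seed = 5))
  tab <- table(co$profiles$group_label)
  expect_equal(unname(tab[c("unimpaired", "pre_mci", "mci")]),
               as.integer(c(23, 10, 3)), ignore_attr = TRUE)
  expect_equal(nrow(co$profiles), 36)
  # labels are reproducible from the sampled diagnostic scores
  expect_identical(
    classify_cognitive_status(co$profiles$cdr_sb, co$profiles$np_abnormal),
    co$profiles$group_label)
  expect_true(all(co$profiles$moca >= 19 & co$profiles$moca <= 30))
  expect_true(all(co$profiles$age >= 65))
  expect_true(all(co$profiles$n_trips >= 30 & co$profiles$n_trips <= 635))

  solo <- generate_cohort(cohort_spec(n_unimpaired = 1, n_premci = 0, n_mci = 0,
                                      seed = 9))
  expect_equal(nrow(solo$profiles), 1)
  expect_identical(solo$profiles$group_label, "unimpaired")
  expect_equal(solo$profiles$cdr_sb, 0)
})

test_that("cohort demographics track the requested group means at scale", {
  # 3-SE check on a large cohort (split evenly across the two groups)
  spec <- cohort_spec(n_unimpaired = 5000, n_premci = 5000, n_mci = 0,
                      trips_min = 1, trips_max = 1, seed = 31)
  co <- generate_cohort(spec)
  g0 <- co$profiles$group_label == "unimpaired"
  for (i in 1:2) {
    idx <- if (i == 1) g0 else !g0
    # closed-form mean of the normal truncated below at age 65
    a <- (65 - spec$age_mean[i]) / spec$age_sd[i]
    mu_trunc <- spec$age_mean[i] + spec$age_sd[i] * dnorm(a) / (1 - pnorm(a))
    se <- spec$age_sd[i] / sqrt(sum(idx))
    expect_lt(abs(mean(co$profiles$age[idx]) - mu_trunc), 3 * se)
  }
})

test_that("generation is reproducible bit-for-bit under a fixed seed", {
  s <- cohort_spec(n_unimpaired = 4, n_premci = 2, n_mci = 1,
                   trips_min = 3, trips_max = 6, seed = 77)
  expect_identical(generate_cohort(s), generate_cohort(s))
  co <- generate_cohort(s)
  st1 <- generate_trip_stream(co$profiles[1, ], 1, s, seed = 123)
  st2 <- generate_trip_stream(co$profiles[1, ], 1, s, seed = 123)
  expect_identical(st1, st2)
  ft1 <- generate_feature_table(co, seed = 11)
  ft2 <- generate_feature_table(co, seed = 11)
  expect_identical(ft1, ft2)
})

test_that("trip streams respect timing, positivity and event-injection contracts", {
  spec <- cohort_spec(degenerate_rate = 0, seed = 3)
  co <- generate_cohort(spec)
  for (k in 1:20) {
    st <- generate_trip_stream(co$profiles[1 + k %% 36, ], k, spec,
                               seed = 1000 + k)
    gaps <- diff(st$t_s)
    expect_true(all(gaps > 0))
    expect_true(all(gaps >= 1 - 1e-9 & gaps <= 5 + 1e-9))
    expect_true(all(st$speed_kmh >= 0) && all(st$rpm >= 0))
    expect_true(all(st$throttle_pct >= 0 & st$throttle_pct <= 100))
    expect_true(all(st$fuel_pct >= 0 & st$fuel_pct <= 100))
  }

  # zero offsets + zero event rates -> no supra-threshold samples at all
  quiet <- cohort_spec(event_rates = c(accel = 0, brake = 0, turn = 0),
                       degenerate_rate = 0, seed = 3)
  drv <- co$profiles[1, ]
  for (f in telemci_features()) drv[[paste0("off_", f)]] <- 0
  for (k in 1:10) {
    st <- generate_trip_stream(drv, k, quiet, seed = 2000 + k)
    expect_equal(count_threshold_events(st$accel_x_g, 0.3, "above"), 0)
    expect_equal(count_threshold_events(st$accel_x_g, 0.3, "below"), 0)
    expect_equal(count_threshold_events(st$accel_y_g, 0.3, "above", TRUE), 0)
  }
})

test_that("group duration shift is monotone in the generator's own parameters", {
  # large effect on trip distance/duration: impaired trips are shorter
  big <- cohort_spec(n_unimpaired = 1, n_premci = 1, n_mci = 0,
                     offset_sd = 0,
                     effect_vector = c(distance = -1.5, n_hard_accel = 0,
                                       n_hard_brake = 0, n_hard_turn = 0,
                                       speed_mean = 0, speed_max = 0,
                                       rpm_mean = 0, fuel_mean = 0,
                                       throttle_mean = 0, throttle_sd = 0),
                     degenerate_rate = 0, seed = 21)
  co <- generate_cohort(big)
  dur <- function(row, base) {
    vapply(seq_len(1000), function(k) {
      st <- generate_trip_stream(row, k, big, seed = base + k)
      max(st$t_s)
    }, numeric(1))
  }
  d_un <- dur(co$profiles[co$profiles$group_label == "unimpaired", ][1, ], 10000)
  d_im <- dur(co$profiles[co$profiles$group_label != "unimpaired", ][1, ], 20000)
  expect_lt(mean(d_im), mean(d_un))
})

test_that("feature tables have per-driver row counts, shared labels and exact group counts", {
  co <- generate_cohort(cohort_spec(trips_min = 5, trips_max = 12, seed = 13))
  ft <- generate_feature_table(co, seed = 14)
  counts <- table(ft$driver_id)
  expect_true(all(counts >= 5 & counts <= 12))
  # all trips of a driver share the driver's label
  per <- tapply(ft$outcome, ft$driver_id, function(v) length(unique(v)))
  expect_true(all(per == 1))
  lab <- tapply(ft$outcome, ft$driver_id, function(v) v[1])
  expect_equal(sum(lab == 1), 13)
  expect_equal(sum(lab == 0), 23)
  expect_gte(nrow(ft), 36 * 5)
  expect_lte(nrow(ft), 36 * 12)
})

test_that("feature-level correlations reproduce the configured sign pattern", {
  co <- generate_cohort(cohort_spec(n_unimpaired = 30, n_premci = 5, n_mci = 1,
                                    trips_min = 100, trips_max = 100,
                                    offset_sd = 0.1, seed = 41))
  ft <- generate_feature_table(co, seed = 42)
  cm <- feature_correlations(ft)
  expect_gt(cm["speed_mean", "speed_max"], 0.2)
  expect_lt(cm["throttle_mean", "throttle_sd"], -0.2)
})

test_that("strong group effects shift generated feature means in the stated directions", {
  beta <- c(a = 1, b = -1, c = 1)
  co <- generate_cohort(cohort_spec(
    n_unimpaired = 100, n_premci = 100, n_mci = 0,
    trips_min = 10, trips_max = 10, offset_sd = 1,
    effect_vector = c(a = 0, b = 0, c = 0),
    true_fixed_effects = beta, true_intercept = 0, seed = 55))
  ft <- generate_feature_table(co, seed = 56)
  for (f in names(beta)) {
    diff_mean <- mean(ft[[f]][ft$outcome == 1]) - mean(ft[[f]][ft$outcome == 0])
    expect_identical(sign(diff_mean), sign(beta[[f]]))
  }
})

test_that("streams, features and truth round-trip through the text formats without loss", {
  co <- generate_cohort(cohort_spec(n_unimpaired = 2, n_premci = 1, n_mci = 0,
                                    trips_min = 2, trips_max = 3, seed = 61))
  st <- generate_streams(co)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_trip_streams(st, p1)
  expect_equal(read_trip_streams(p1), st, ignore_attr = TRUE)

  ft <- generate_feature_table(co, seed = 62)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, p2)
  back <- read_feature_table(p2)
  expect_equal(as.data.frame(back), as.data.frame(ft), ignore_attr = TRUE)

  p3 <- withr::local_tempfile(fileext = ".json")
  write_generator_truth(co$truth, p3)
  tr <- read_generator_truth(p3)
  expect_equal(tr$true_fixed_effects, co$truth$true_fixed_effects)
  expect_equal(tr$true_random_intercept_sd, co$truth$true_random_intercept_sd)
})
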
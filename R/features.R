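# ------------------------------------------------------------------------
# Trip screening, hard-event detection, the ten trip-level driving behavior
# indices, standardization and descriptive tables.
# ------------------------------------------------------------------------

#' Screen a raw trip stream
#'
#' A trip is dropped when it has fewer than two samples, missing or
#' non-increasing timestamps, a duration below one minute, or an implausible
#' all-zero average speed; otherwise it is kept. The decision is pure: the
#' stream is never modified.
#'
#' @param stream Data frame in the stream schema for a single trip.
#' @param min_duration_s Minimum trip duration in seconds (default 60).
#' @return A list with `keep` (logical) and `reason` (`"kept"`,
#'   `"too_few_samples"`, `"missing_timestamps"`, `"too_short"`, or
#'   `"implausible_speed"`).
#' @export
screen_trip <- function(stream, min_duration_s = 60) {
  t <- stream$t_s
  if (is.null(t) || length(t) < 2) {
    return(list(keep = FALSE, reason = "too_few_samples"))
  }
  if (anyNA(t) || any(diff(t) <= 0)) {
    return(list(keep = FALSE, reason = "missing_timestamps"))
  }
  if (t[length(t)] - t[1] < min_duration_s) {
    return(list(keep = FALSE, reason = "too_short"))
  }
  sp <- stream$speed_kmh
  if (is.null(sp) || anyNA(sp) || mean(sp) <= 0) {
    return(list(keep = FALSE, reason = "implausible_speed"))
  }
  list(keep = TRUE, reason = "kept")
}

#' Count threshold-crossing events in an acceleration series
#'
#' An event is one maximal contiguous run of samples beyond the threshold in
#' the stated direction; at 1-5 s sampling, per-sample counting would
#' double-count single maneuvers. With `use_absolute = TRUE` the absolute
#' value is compared, so excursions of either sign count (used for hard
#' turns on the lateral axis).
#'
#' @param series Ordered numeric values (g).
#' @param threshold Positive threshold in g (0.3 by default elsewhere).
#' @param direction `"above"`: values `> threshold`; `"below"`: values
#'   `< -threshold`.
#' @param use_absolute Compare `abs(series)` instead of the raw values.
#' @return Integer event count (0 for an empty series).
#' @export
count_threshold_events <- function(series, threshold,
                                   direction = c("above", "below"),
                                   use_absolute = FALSE) {
  direction <- match.arg(direction)
  stopifnot(threshold > 0)
  if (length(series) == 0) return(0L)
  x <- if (use_absolute) abs(series) else series
  hit <- if (direction == "above") x > threshold else x < -threshold
  hit[is.na(hit)] <- FALSE
  r <- rle(hit)
  sum(r$values)
}

#' Event-detection thresholds
#'
#' @param accel_g Threshold in g for hard accelerations (longitudinal axis,
#'   positive excursions), hard brakings (longitudinal, negative) and hard
#'   turns (lateral axis).
#' @param turn_absolute Count lateral excursions of either sign as turns
#'   (default); `FALSE` restricts to positive lateral acceleration only.
#' @param min_duration_s Screening minimum trip duration, seconds.
#' @return A list of class `trip_thresholds`.
#' @export
trip_thresholds <- function(accel_g = 0.3, turn_absolute = TRUE,
                            min_duration_s = 60) {
  stopifnot(accel_g > 0, min_duration_s >= 0)
  structure(list(accel_g = accel_g, turn_absolute = turn_absolute,
                 min_duration_s = min_duration_s),
            class = "trip_thresholds")
}

#' Summarize one screened trip into the ten driving behavior indices
#'
#' Distance is the trapezoidal time-integral of speed (km); duration is the
#' elapsed time in minutes; speed, RPM, fuel and throttle are per-sample
#' arithmetic means; throttle variability is the per-trip sample standard
#' deviation (n-1 denominator); event counts use
#' [count_threshold_events()] on the longitudinal (accelerations, brakings)
#' and lateral (turns) axes.
#'
#' @param stream Data frame in the stream schema for a single trip; must
#'   pass [screen_trip()].
#' @param thresholds A [trip_thresholds()].
#' @return One-row data frame: `driver_id`, `trip_id`, `duration` (min), the
#'   ten feature columns of [telemci_features()].
#' @export
summarize_trip <- function(stream, thresholds = trip_thresholds()) {
  scr <- screen_trip(stream, thresholds$min_duration_s)
  if (!scr$keep) {
    stop("stream was screened out (", scr$reason, "); refusing to summarize")
  }
  t <- stream$t_s
  sp <- stream$speed_kmh
  dur_min <- (t[length(t)] - t[1]) / 60
  dist_km <- sum(diff(t) * (head(sp, -1) + sp[-1]) / 2) / 3600
  th <- thresholds$accel_g
  data.frame(
    driver_id = stream$driver_id[1],
    trip_id = stream$trip_id[1],
    duration = dur_min,
    distance = dist_km,
    n_hard_accel = count_threshold_events(stream$accel_x_g, th, "above"),
    n_hard_brake = count_threshold_events(stream$accel_x_g, th, "below"),
    n_hard_turn = count_threshold_events(stream$accel_y_g, th, "above",
                                         use_absolute = thresholds$turn_absolute),
    speed_mean = mean(sp),
    speed_max = max(sp),
    rpm_mean = mean(stream$rpm),
    fuel_mean = mean(stream$fuel_pct),
    throttle_mean = mean(stream$throttle_pct),
    throttle_sd = sd(stream$throttle_pct),
    stringsAsFactors = FALSE
  )
}

#' Screen and featurize a table of raw streams
#'
#' Splits a long stream table by trip, applies [screen_trip()] and
#' [summarize_trip()], and merges the driver's outcome label when a cohort
#' is supplied. Incomplete feature rows are removed (listwise deletion).
#'
#' @param streams Long data frame in the stream schema (many trips).
#' @param thresholds A [trip_thresholds()].
#' @param cohort Optional [generate_cohort()] result supplying outcome
#'   labels (`0` unimpaired, `1` Pre-MCI/MCI).
#' @return A list with `features` (a `telemci_features` data frame) and
#'   `screen_log` (a data frame of counts per screening outcome).
#' @export
summarize_trips <- function(streams, thresholds = trip_thresholds(),
                            cohort = NULL) {
  pieces <- split(streams, streams$trip_id)
  reasons <- character(length(pieces))
  rows <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    scr <- screen_trip(pieces[[i]], thresholds$min_duration_s)
    reasons[i] <- scr$reason
    if (scr$keep) rows[[i]] <- summarize_trip(pieces[[i]], thresholds)
  }
  feats <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(feats)) {
    feats <- data.frame()
  } else {
    complete <- stats::complete.cases(feats)
    if (any(!complete)) {
      reasons <- c(reasons, rep("incomplete_row", sum(!complete)))
    }
    feats <- feats[complete, , drop = FALSE]
    rownames(feats) <- NULL
  }
  if (!is.null(cohort) && nrow(feats) > 0) {
    prof <- cohort$profiles
    lab <- stats::setNames(as.integer(prof$group_label != "unimpaired"),
                           prof$driver_id)
    feats$outcome <- unname(lab[feats$driver_id])
  }
  log <- as.data.frame(table(reason = reasons), stringsAsFactors = FALSE)
  names(log) <- c("reason", "n_trips")
  class(feats) <- c("telemci_features", class(feats))
  list(features = feats, screen_log = log)
}

#' Standardize (z-score) feature columns
#'
#' In the global scheme (default) means and standard deviations are fitted
#' on the table itself; in the training-fold scheme they are fitted on the
#' rows given by `fit` (e.g. the training drivers of a cross-validation
#' fold) and applied to the target table, so no held-out information leaks
#' into the transform.
#'
#' @param table Data frame containing the feature columns.
#' @param features Character vector of columns to standardize.
#' @param params Optional previously fitted parameters (as returned in
#'   `$params`); when supplied, `fit` is ignored.
#' @param fit Data frame on which to fit means/SDs (defaults to `table`).
#' @return A list with `table` (z-scored copy) and `params` (a data frame
#'   with `feature`, `mean`, `sd`).
#' @export
standardize <- function(table, features = telemci_features(), params = NULL,
                        fit = table) {
  stopifnot(all(features %in% names(table)))
  if (is.null(params)) {
    mu <- vapply(features, function(f) mean(fit[[f]]), numeric(1))
    sg <- vapply(features, function(f) sd(fit[[f]]), numeric(1))
    bad <- features[is.na(sg) | sg <= 0]
    if (length(bad) > 0) {
      stop("degenerate feature(s) with zero standard deviation in the fitting set: ",
           paste(bad, collapse = ", "))
    }
    params <- data.frame(feature = features, mean = unname(mu), sd = unname(sg),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(features %in% params$feature))
  for (f in features) {
    p <- params[params$feature == f, ]
    table[[f]] <- (table[[f]] - p$mean) / p$sd
  }
  list(table = table, params = params)
}

#' Pearson correlations among the trip-level indices
#'
#' @param table Feature data frame (at least 3 rows).
#' @param features Columns to correlate.
#' @return Symmetric correlation matrix with unit diagonal. Constant
#'   columns yield `NA` entries and a warning naming them; they are never
#'   silently zeroed.
#' @export
feature_correlations <- function(table, features = telemci_features()) {
  stopifnot(nrow(table) >= 3, all(features %in% names(table)))
  X <- as.matrix(table[, features])
  const <- features[apply(X, 2, function(v) sd(v) == 0 || is.na(sd(v)))]
  if (length(const) > 0) {
    warning("constant feature column(s) give undefined correlations: ",
            paste(const, collapse = ", "))
  }
  suppressWarnings(cor(X))
}

#' Group descriptives in the style of a cohort table
#'
#' Per-group (unimpaired vs Pre-MCI/MCI) means and SDs of age, education,
#' MoCA and trips per driver with Welch two-sample t-test p-values, plus
#' counts and percentages for sex and total trips with Pearson chi-square
#' p-values. These comparisons are descriptive only.
#'
#' @param features A trip-level feature table with `driver_id`.
#' @param cohort A [generate_cohort()] result covering every driver present.
#' @return A list with `continuous` and `categorical` data frames, and
#'   `trip_share` (percentage of trips per group, group-0 first).
#' @export
describe_cohort <- function(features, cohort) {
  prof <- cohort$profiles
  stopifnot(all(features$driver_id %in% prof$driver_id))
  grp <- ifelse(prof$group_label == "unimpaired", "unimpaired", "pre_mci_mci")
  if (length(unique(grp)) < 2 || any(table(grp) < 2)) {
    stop("both groups must be present (with >= 2 drivers) for descriptives")
  }
  trips_per_driver <- as.data.frame(table(driver_id = features$driver_id),
                                    stringsAsFactors = FALSE)
  prof$obs_trips <- trips_per_driver$Freq[match(prof$driver_id,
                                                trips_per_driver$driver_id)]
  prof$obs_trips[is.na(prof$obs_trips)] <- 0
  g0 <- grp == "unimpaired"

  cont_row <- function(name, v) {
    p <- tryCatch(stats::t.test(v[g0], v[!g0])$p.value, error = function(e) NA_real_)
    data.frame(variable = name,
               mean_unimpaired = mean(v[g0]), sd_unimpaired = sd(v[g0]),
               mean_impaired = mean(v[!g0]), sd_impaired = sd(v[!g0]),
               p_value = p, stringsAsFactors = FALSE)
  }
  continuous <- rbind(
    cont_row("age", prof$age),
    cont_row("education", prof$education),
    cont_row("moca", prof$moca),
    cont_row("trips_per_driver", prof$obs_trips)
  )

  males <- c(sum(prof$male[g0]), sum(prof$male[!g0]))
  ns <- c(sum(g0), sum(!g0))
  p_sex <- tryCatch(
    suppressWarnings(stats::chisq.test(rbind(males, ns - males))$p.value),
    error = function(e) NA_real_)
  trips <- c(sum(prof$obs_trips[g0]), sum(prof$obs_trips[!g0]))
  categorical <- data.frame(
    variable = c("males", "n_trips"),
    n_unimpaired = c(males[1], trips[1]),
    pct_unimpaired = c(proportion_pct(males[1], ns[1]),
                       proportion_pct(trips[1], sum(trips))),
    n_impaired = c(males[2], trips[2]),
    pct_impaired = c(proportion_pct(males[2], ns[2]),
                     proportion_pct(trips[2], sum(trips))),
    p_value = c(p_sex, NA_real_),
    stringsAsFactors = FALSE
  )
  list(continuous = continuous, categorical = categorical,
       trip_share = c(unimpaired = proportion_pct(trips[1], sum(trips)),
                      pre_mci_mci = proportion_pct(trips[2], sum(trips))))
}

#' Percentage of a count over a total
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @param digits Rounding digits (default 1, matching reported tables).
#' @return `100 * count / total`, rounded.
#' @export
proportion_pct <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}
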
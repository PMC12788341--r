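# Fixtures built in code. The "recovery" conditions used across tests:
# 200 drivers x 50 trips, true log-odds beta = (+1, -1, 0, 0, 0) on five
# generic features, latent intercept SD 1, driver behavior-offset SD 2
# (between-driver behavior variation twice the within-driver trip noise,
# the package's calibration of a strongly separable cohort).

recovery_features <- c("f1", "f2", "f3", "f4", "f5")

recovery_spec <- function(seed, beta = c(f1 = 1, f2 = -1, f3 = 0, f4 = 0, f5 = 0),
                          n_drivers = c(100, 70, 30), trips = 50,
                          intercept_sd = 1, offset_sd = 2) {
  cohort_spec(
    n_unimpaired = n_drivers[1], n_premci = n_drivers[2], n_mci = n_drivers[3],
    trips_min = trips, trips_max = trips,
    random_intercept_sd = intercept_sd, offset_sd = offset_sd,
    effect_vector = stats::setNames(rep(0, length(beta)), names(beta)),
    true_fixed_effects = beta, true_intercept = 0, seed = seed
  )
}

recovery_table <- function(seed, ...) {
  co <- generate_cohort(recovery_spec(seed, ...))
  generate_feature_table(co, seed = seed + 1)
}

# no-signal data: zero coefficients and zero intercept SD
null_table <- function(seed, n_drivers = c(100, 70, 30), trips = 50) {
  co <- generate_cohort(recovery_spec(
    seed, beta = c(f1 = 0, f2 = 0, f3 = 0, f4 = 0, f5 = 0),
    n_drivers = n_drivers, trips = trips, intercept_sd = 0))
  generate_feature_table(co, seed = seed + 1)
}

# standardized design pieces from a feature table
design_of <- function(ft, features = recovery_features) {
  zs <- standardize(ft, features)
  list(X = as.matrix(zs$table[, features]),
       y = ft$outcome,
       id = as.character(ft$driver_id),
       labels = vapply(split(ft$outcome, as.character(ft$driver_id)),
                       function(v) v[1], numeric(1)))
}

# a small clustered logistic dataset whose outcome VARIES within driver,
# so the unpenalized mixed model is well behaved (no quasi-separation)
within_driver_fixture <- function(seed = 7, m = 40, n_per = 25,
                                  beta = c(x1 = 0.8, x2 = -0.5),
                                  sigma_b = 0.8) {
  set.seed(seed)
  id <- rep(sprintf("W%02d", seq_len(m)), each = n_per)
  b <- rep(rnorm(m, 0, sigma_b), each = n_per)
  X <- matrix(rnorm(m * n_per * length(beta)), ncol = length(beta),
              dimnames = list(NULL, names(beta)))
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  eta <- drop(X %*% beta) + b
  y <- rbinom(m * n_per, 1, plogis(eta))
  list(X = X, y = y, id = id)
}

# hand-built raw stream with fully controlled values
toy_stream <- function(t, speed, ax = NULL, ay = NULL, driver = "D1",
                       trip = "D1_T1") {
  n <- length(t)
  data.frame(
    driver_id = driver, trip_id = trip, t_s = t,
    speed_kmh = speed, rpm = rep(1500, n),
    throttle_pct = rep(20, n), fuel_pct = rep(50, n),
    accel_x_g = ax %||% rep(0, n), accel_y_g = ay %||% rep(0, n),
    accel_z_g = rep(1, n), stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
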
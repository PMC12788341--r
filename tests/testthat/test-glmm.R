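# brute-force oracle: hierarchical grid minimization of the penalized
# logistic objective (variance fixed at zero), final step 1e-3
grid_search_logistic <- function(X, y, lambda, scale = "sum") {
  nll <- function(b0, b1, b2) {
    eta <- b0 + X[, 1] * b1 + X[, 2] * b2
    s <- sum(pmax(eta, 0) - y * eta + log1p(exp(-abs(eta))))
    if (scale == "mean") s <- s / length(y)
    s + lambda * (abs(b1) + abs(b2))
  }
  best <- c(0, 0, 0)
  span <- 3; step <- 0.05
  for (round in 1:3) {
    g0 <- seq(best[1] - span, best[1] + span, by = step)
    g1 <- seq(best[2] - span, best[2] + span, by = step)
    g2 <- seq(best[3] - span, best[3] + span, by = step)
    vals <- array(NA_real_, c(length(g0), length(g1), length(g2)))
    for (i in seq_along(g0)) for (j in seq_along(g1)) for (k in seq_along(g2)) {
      vals[i, j, k] <- nll(g0[i], g1[j], g2[k])
    }
    w <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(g0[w[1]], g1[w[2]], g2[w[3]])
    span <- 2.5 * step; step <- step / 10
    if (step < 1e-3 / 2) break
  }
  best
}

test_that("penalized fit with variance fixed at zero matches a brute-force grid oracle", {
  set.seed(5)
  X <- cbind(a = c(-1.2, 0.4, 1.1, -0.3, 0.8, -1.5, 0.2, 0.9, -0.7, 1.4, -0.2, 0.6),
             b = c(0.3, -0.8, 0.5, 1.2, -0.4, 0.1, -1.1, 0.7, 0.2, -0.6, 1.0, -0.9))
  X <- scale(X); attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  y <- c(0, 0, 1, 0, 1, 0, 0, 1, 0, 1, 1, 0)
  id <- rep(c("d1", "d2", "d3", "d4"), each = 3)
  oracle <- grid_search_logistic(X, y, lambda = 0.5)
  fit <- suppressWarnings(fit_penalized_glmm(
    X, y, id, model_spec(c("a", "b"), lambda = 0.5, variance_fixed = 0)))
  expect_lt(abs(fit$intercept - oracle[1]), 2e-3)
  expect_lt(abs(fit$coefficients[["a"]] - oracle[2]), 2e-3)
  expect_lt(abs(fit$coefficients[["b"]] - oracle[3]), 2e-3)
})

test_that("a penalty above the null-model score zeroes every coefficient (KKT)", {
  fx <- within_driver_fixture(seed = 11, m = 20, n_per = 20)
  # null-model score: gradient of the unpenalized part at beta = 0 with the
  # intercept (and random effects) fitted
  null_fit <- suppressWarnings(fit_penalized_glmm(
    fx$X, fx$y, fx$id, model_spec(colnames(fx$X), lambda = 1e9)))
  p0 <- predict_probability(null_fit, fx$X, fx$id, "conditional")
  lam_max <- max(abs(drop(crossprod(fx$X, fx$y - p0))))
  fit <- suppressWarnings(fit_penalized_glmm(
    fx$X, fx$y, fx$id, model_spec(colnames(fx$X), lambda = lam_max * 1.05)))
  expect_true(all(fit$coefficients == 0))
  expect_identical(fit$nonzero_set, character(0))
  # and the KKT condition holds at the returned solution
  expect_lte(kkt_violation(fit, fx$X, fx$y, fx$id), 1e-6)
})

test_that("lambda = 0 penalized fit equals the unpenalized fit within 1e-4", {
  fx <- within_driver_fixture(seed = 13, m = 25, n_per = 20)
  sp <- model_spec(colnames(fx$X))
  pen0 <- fit_penalized_glmm(fx$X, fx$y, fx$id, sp)
  unpen <- fit_unpenalized_glmm(fx$X, fx$y, fx$id, sp)
  expect_lt(max(abs(pen0$coefficients - unpen$coefficients)), 1e-4)
  expect_lt(abs(pen0$intercept - unpen$intercept), 1e-4)
})

test_that("the Laplace fit agrees with glmer on a well-behaved clustered fixture", {
  skip_if_not_installed("lme4")
  fx <- within_driver_fixture(seed = 19, m = 40, n_per = 25)
  ours <- fit_unpenalized_glmm(fx$X, fx$y, fx$id, model_spec(colnames(fx$X)))
  df <- data.frame(y = fx$y, fx$X, id = fx$id)
  ref <- lme4::glmer(y ~ x1 + x2 + (1 | id), data = df, family = binomial,
                     nAGQ = 1)
  # both are Laplace fits, but the fixed-effect update here solves the
  # penalized quasi-likelihood score (no log-determinant derivative), so
  # small systematic differences from glmer are expected
  fe <- lme4::fixef(ref)
  expect_lt(abs(ours$intercept - fe[["(Intercept)"]]), 0.05)
  expect_lt(max(abs(ours$coefficients - fe[c("x1", "x2")])), 0.05)
  vr <- as.numeric(lme4::VarCorr(ref)$id)
  expect_lt(abs(ours$random_intercept_variance - vr) / max(vr, 0.1), 0.1)
  # standard errors in the same ballpark as lme4's
  se_ref <- sqrt(diag(as.matrix(lme4::vcov.merMod(ref))))
  expect_lt(max(abs(ours$ses - se_ref) / se_ref), 0.15)
})

test_that("objective trace is non-increasing and zero coefficients are KKT-consistent", {
  fx <- within_driver_fixture(seed = 23, m = 30, n_per = 15)
  for (lam in c(2, 10, 30)) {
    fit <- suppressWarnings(fit_penalized_glmm(
      fx$X, fx$y, fx$id, model_spec(colnames(fx$X), lambda = lam)))
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
    expect_lte(kkt_violation(fit, fx$X, fx$y, fx$id), 1e-6)
  }
})

test_that("the nonzero count shrinks from the smallest to the largest penalty", {
  ft <- recovery_table(301)
  d <- design_of(ft)
  grid <- c(0.5, 2, 5, 20)
  nz <- vapply(grid, function(lam) {
    fit <- suppressWarnings(fit_penalized_glmm(
      d$X, d$y, d$id, model_spec(colnames(d$X), lambda = lam)))
    length(fit$nonzero_set)
  }, numeric(1))
  expect_lte(nz[length(grid)], nz[1])
})

test_that("null data yields calibrated Wald statistics", {
  # all true coefficients zero: |z| < 4 for every predictor across seeds
  worst <- 0
  for (s in 1:15) {
    fx <- within_driver_fixture(seed = 100 + s, m = 30, n_per = 20,
                                beta = c(x1 = 0, x2 = 0), sigma_b = 0.7)
    fit <- fit_unpenalized_glmm(fx$X, fx$y, fx$id, model_spec(colnames(fx$X)))
    worst <- max(worst, abs(fit$wald$z[fit$wald$name != "(Intercept)"]))
  }
  expect_lt(worst, 4)
})

test_that("driver-constant outcomes drive the variance to a configured ceiling", {
  # the study's design: every driver's trips share one label, so the random
  # intercept can absorb the outcome and the variance escalates
  ft <- recovery_table(401, n_drivers = c(12, 6, 2), trips = 10)
  d <- design_of(ft)
  expect_warning(
    fit <- fit_penalized_glmm(d$X, d$y, d$id,
                              model_spec(colnames(d$X), variance_ceiling = 50)),
    "quasi-separation")
  expect_equal(fit$random_intercept_variance, 50)
  expect_true(fit$quasi_separation)
  expect_true(fit$driver_constant_outcome)
  # escalation is monotone across iterations
  expect_true(all(diff(fit$variance_trace) >= 0))
  # without the tight ceiling the estimate is far above the generating
  # heterogeneity (latent intercept SD 1)
  free <- suppressWarnings(fit_penalized_glmm(
    d$X, d$y, d$id, model_spec(colnames(d$X))))
  expect_gt(free$random_intercept_variance, 100)
})

test_that("predictions follow the logistic closed form in both modes", {
  fake <- structure(list(
    intercept = 0,
    coefficients = c(u = 0, v = 0),
    random_intercepts = c(A = 1.5),
    penalize = c(TRUE, TRUE), lambda = 0
  ), class = "penalized_glmm_fit")
  X <- cbind(u = c(0.3, -0.2), v = c(1, 2))
  expect_equal(predict_probability(fake, X, c("A", "B"), "marginal"),
               c(0.5, 0.5))
  # known driver gets its intercept in conditional mode, unknown gets zero
  pc <- predict_probability(fake, X, c("A", "B"), "conditional")
  expect_equal(pc, c(plogis(1.5), 0.5))

  fake$intercept <- 4.25
  p <- predict_probability(fake, X, c("A", "B"), "marginal")
  expect_equal(p[1], exp(4.25) / (1 + exp(4.25)), tolerance = 1e-12)
  expect_equal(round(p[1], 3), 0.986)

  # monotonicity in a positive-coefficient feature
  fake$coefficients <- c(u = 0.8, v = 0)
  xs <- seq(-2, 2, by = 0.5)
  pm <- predict_probability(fake, cbind(u = xs, v = 0),
                            rep("B", length(xs)), "marginal")
  expect_true(all(diff(pm) > 0))

  expect_error(predict_probability(fake, cbind(v = xs, u = xs)), "match")
})

test_that("Wald summaries apply the definitional transforms", {
  fake <- list(intercept = 4.25,
               coefficients = c(rpm_mean = 0.68, n_hard_brake = -0.72,
                                throttle_sd = 0.58, distance = 0.28,
                                zero = 0))
  ses <- c(`(Intercept)` = 1.94, rpm_mean = 1.46, n_hard_brake = 1.74,
           throttle_sd = 0.12, distance = 1.14, zero = 1)
  w <- wald_summary(fake, ses)
  expect_equal(round(w$odds_ratio[w$name == "(Intercept)"], 2), 70.11)
  expect_equal(round(w$z[w$name == "(Intercept)"], 2), 2.19)
  expect_equal(round(w$odds_ratio[w$name == "rpm_mean"], 2), 1.97)
  expect_equal(round(w$odds_ratio[w$name == "n_hard_brake"], 2), 0.49)
  expect_equal(round(w$odds_ratio[w$name == "throttle_sd"], 2), 1.79)
  expect_equal(round(w$odds_ratio[w$name == "distance"], 2), 1.32)
  zr <- w[w$name == "zero", ]
  expect_equal(zr$odds_ratio, 1)
  expect_equal(zr$p, 1)
  # interval transforms are exact exponentials of the beta bounds
  expect_equal(w$or_low, exp(w$ci_low), tolerance = 1e-12)
  expect_equal(w$or_high, exp(w$ci_high), tolerance = 1e-12)
  expect_equal(w$ci_low, w$beta - 1.96 * w$se, tolerance = 1e-12)
})

test_that("information criteria follow their formulas", {
  # -2LL = 27.90 with 11 parameters on 4739 observations
  fs <- fit_statistics(-27.90 / 2, 11, 4739)
  expect_equal(round(fs$aic, 2), 49.90)
  expect_equal(round(fs$bic, 2), 121.00, tolerance = 0.0051)
  expect_equal(fs$minus_two_ll, 27.90)
})

test_that("singular information yields NA standard errors with a diagnostic", {
  fx <- within_driver_fixture(seed = 29, m = 15, n_per = 10)
  X <- cbind(fx$X, x3 = fx$X[, "x1"])  # exact duplicate column
  expect_warning(
    fit <- fit_unpenalized_glmm(X, fx$y, fx$id, model_spec(colnames(X))),
    "singular|not positive definite")
  expect_true(all(is.na(fit$ses)))
  expect_null(fit$wald)
})

test_that("non-standardized input triggers a warning signal", {
  fx <- within_driver_fixture(seed = 31, m = 10, n_per = 10)
  X <- fx$X * 7 + 2
  w <- capture_warnings(
    fit_penalized_glmm(X, fx$y, fx$id,
                       model_spec(colnames(X), lambda = 1, max_iterations = 5)))
  expect_true(any(grepl("z-scored", w)))
})

test_that("fits serialize to JSON with coefficients, variance and trace", {
  fx <- within_driver_fixture(seed = 37, m = 10, n_per = 8)
  fit <- suppressWarnings(fit_penalized_glmm(
    fx$X, fx$y, fx$id, model_spec(colnames(fx$X), lambda = 3)))
  p <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(unlist(back$coefficients), fit$coefficients)
  expect_equal(back$random_intercept_variance, fit$random_intercept_variance)
})
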
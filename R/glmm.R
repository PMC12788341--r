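# ------------------------------------------------------------------------
# L1-penalized and unpenalized random-intercept logistic models via the
# Laplace approximation to the marginal likelihood. Fixed effects are
# updated by penalized weighted coordinate descent (soft-thresholding gives
# exact zeros), driver intercepts by per-driver Newton steps, and the
# random-intercept variance by a bounded profile search. Every block update
# is accepted only if the full penalized objective decreases, so the
# objective trace is non-increasing by construction.
# ------------------------------------------------------------------------

#' Specify a random-intercept logistic model
#'
#' @param predictor_names Ordered names of the (z-scored) predictors.
#' @param lambda L1 penalty weight (>= 0) applied to the fixed effects on
#'   the unscaled negative log-likelihood; the intercept is never penalized.
#' @param penalize Logical vector (one per predictor) marking which
#'   coefficients the penalty applies to; defaults to all.
#' @param max_iterations Outer iteration cap.
#' @param convergence_tol Convergence tolerance on the maximum absolute
#'   parameter change.
#' @param variance_ceiling Upper bound for the random-intercept variance.
#'   With driver-constant outcomes the variance is unbounded without it;
#'   see the quasi-separation diagnostic on the fit.
#' @param variance_fixed Optional fixed value for the random-intercept
#'   variance (e.g. `0` for a plain penalized logistic model); `NULL`
#'   (default) estimates it.
#' @param prediction_mode Default prediction mode, `"conditional"` or
#'   `"marginal"`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(predictor_names, lambda = 0, penalize = NULL,
                       max_iterations = 500, convergence_tol = 1e-6,
                       variance_ceiling = 1e5, variance_fixed = NULL,
                       prediction_mode = c("conditional", "marginal")) {
  stopifnot(lambda >= 0, convergence_tol > 0, variance_ceiling > 0)
  penalize <- penalize %||% rep(TRUE, length(predictor_names))
  stopifnot(length(penalize) == length(predictor_names))
  structure(list(predictor_names = predictor_names, lambda = lambda,
                 penalize = penalize, max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 variance_ceiling = variance_ceiling,
                 variance_fixed = variance_fixed,
                 prediction_mode = match.arg(prediction_mode)),
            class = "model_spec")
}

# stable sum of log(1+exp(eta)) - y*eta
bernoulli_nll <- function(eta, y) {
  sum(pmax(eta, 0) - y * eta + log1p(exp(-abs(eta))))
}

# profile the per-driver intercepts: Newton on the strictly concave
# per-driver objective l_i(b) - b^2/(2 sigma2)
solve_ranef <- function(eta_fix, y, idx, m, sigma2, b) {
  if (sigma2 <= 0) return(list(b = numeric(m), W = ranef_weights(eta_fix, idx, m)))
  for (it in 1:200) {
    eta <- eta_fix + b[idx]
    p <- plogis(eta)
    g <- rowsum_vec(y - p, idx, m) - b / sigma2
    H <- rowsum_vec(p * (1 - p), idx, m) + 1 / sigma2
    step <- g / H
    step <- pmin(pmax(step, -5), 5)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- eta_fix + b[idx]
  p <- plogis(eta)
  list(b = b, W = rowsum_vec(p * (1 - p), idx, m))
}

ranef_weights <- function(eta_fix, idx, m) {
  p <- plogis(eta_fix)
  rowsum_vec(p * (1 - p), idx, m)
}

rowsum_vec <- function(x, idx, m) {
  out <- numeric(m)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# negative Laplace-approximated marginal log-likelihood (unpenalized part):
#   sum_i [ -l_i(b_hat) + b_hat^2/(2 s2) ] + 0.5 * sum_i log(1 + s2 * W_i)
# the last form reduces cleanly to the plain logistic NLL as s2 -> 0
laplace_nll <- function(beta0, beta, sigma2, X, y, idx, m, b_start) {
  eta_fix <- drop(beta0 + X %*% beta)
  re <- solve_ranef(eta_fix, y, idx, m, sigma2, b_start)
  nll <- bernoulli_nll(eta_fix + re$b[idx], y)
  if (sigma2 > 0) {
    nll <- nll + sum(re$b^2) / (2 * sigma2) + 0.5 * sum(log1p(sigma2 * re$W))
  }
  list(nll = nll, b = re$b, W = re$W)
}

#' Fit an L1-penalized random-intercept logistic model
#'
#' Minimizes the Laplace-approximated negative marginal log-likelihood plus
#' `lambda * sum(|beta_j|)` over the penalized fixed effects. Block updates:
#' penalized weighted coordinate descent (soft-thresholding, exact zeros)
#' on the quasi-likelihood working response for the fixed effects, per-driver
#' Newton steps for the random intercepts, and a bounded one-dimensional
#' profile search for the random-intercept variance. Each block is accepted
#' only when it decreases the full penalized Laplace objective (with a
#' halving line search), so the recorded objective trace is non-increasing.
#' The fixed-effect score omits the derivative of the Laplace
#' log-determinant term, the usual penalized-quasi-likelihood convention.
#'
#' @param X Numeric matrix of z-scored predictors (columns named).
#' @param y Binary trip outcomes (0 unimpaired, 1 Pre-MCI/MCI).
#' @param driver_ids Driver identifier per trip.
#' @param spec A [model_spec()].
#' @return An object of class `penalized_glmm_fit`: `intercept`,
#'   `coefficients` (named; exact zeros for shrunk predictors),
#'   `random_intercepts` (named by driver), `random_intercept_variance`,
#'   `objective_trace`, `converged`, `nonzero_set`, `lambda`,
#'   `quasi_separation` diagnostic flag, and bookkeeping needed for
#'   prediction.
#' @export
fit_penalized_glmm <- function(X, y, driver_ids, spec) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- spec$predictor_names
  stopifnot(identical(colnames(X), spec$predictor_names),
            all(y %in% c(0, 1)), length(y) == nrow(X),
            length(driver_ids) == nrow(X))
  mu <- colMeans(X); sg <- apply(X, 2, sd)
  if (any(abs(mu) > 0.01) || any(abs(sg - 1) > 0.01)) {
    warning("predictors do not look z-scored (|mean| > 0.01 or |sd - 1| > 0.01)")
  }
  drv <- factor(driver_ids)
  idx <- as.integer(drv)
  m <- nlevels(drv)
  n <- length(y)
  p <- ncol(X)
  lambda <- spec$lambda
  penalize <- spec$penalize
  tol <- spec$convergence_tol

  beta0 <- qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  beta <- numeric(p)
  sigma2 <- if (!is.null(spec$variance_fixed)) spec$variance_fixed else
    min(1, spec$variance_ceiling)
  est_var <- is.null(spec$variance_fixed)
  b <- numeric(m)

  pen <- function(beta) lambda * sum(abs(beta[penalize]))
  cur <- laplace_nll(beta0, beta, sigma2, X, y, idx, m, b)
  obj <- cur$nll + pen(beta)
  b <- cur$b
  trace <- obj
  s2_trace <- sigma2
  converged <- FALSE

  var_frozen <- FALSE
  for (iter in seq_len(spec$max_iterations)) {
    old <- c(beta0, beta, log1p(sigma2))
    obj_before <- obj

    # --- fixed-effects block: penalized IRLS/coordinate-descent proposal
    eta <- drop(beta0 + X %*% beta) + b[idx]
    pr <- plogis(pmin(pmax(eta, -30), 30))
    w <- pmax(pr * (1 - pr), 1e-6)
    z <- (eta - b[idx]) + (y - pr) / w
    prop <- cd_wls_l1_cpp(X, z, w, lambda, penalize,
                          c(beta0, beta), tol * 0.1, 200L)
    if (max(abs(prop - c(beta0, beta))) > tol / 10) {
      t_step <- 1
      for (half in 1:12) {
        nb0 <- beta0 + t_step * (prop[1] - beta0)
        nb <- beta + t_step * (prop[-1] - beta)
        cand <- laplace_nll(nb0, nb, sigma2, X, y, idx, m, b)
        cand_obj <- cand$nll + pen(nb)
        if (cand_obj <= obj + 1e-12) {
          beta0 <- nb0; beta <- nb; obj <- cand_obj; b <- cand$b
          break
        }
        t_step <- t_step / 2
      }
    }

    # exact reparameterization: absorb the mean random intercept into the
    # fixed intercept (likelihood and log-determinant terms are unchanged;
    # the prior term can only decrease, so this is a pure descent move)
    mb <- mean(b)
    if (sigma2 > 0 && abs(mb) > 0) {
      obj <- obj - (sum(b^2) - sum((b - mb)^2)) / (2 * sigma2)
      beta0 <- beta0 + mb
      b <- b - mb
    }

    # --- variance block: bounded profile search on the log scale. Once its
    # improvement stalls it is frozen until the fixed effects move again.
    if (est_var && !var_frozen) {
      fvar <- function(ls2) {
        laplace_nll(beta0, beta, exp(ls2), X, y, idx, m, b)$nll
      }
      lo_b <- log(1e-8); hi_b <- log(spec$variance_ceiling)
      if (iter > 1) {   # re-bracket locally around the current value
        lo_b <- max(lo_b, log(sigma2) - 2)
        hi_b <- min(hi_b, log(sigma2) + 2)
      }
      opt <- optimize(fvar, c(lo_b, hi_b), tol = 1e-3)
      # expand toward a bound the local bracket ran into
      while (opt$minimum > hi_b - 0.01 && hi_b < log(spec$variance_ceiling)) {
        lo_b <- hi_b; hi_b <- min(hi_b + 4, log(spec$variance_ceiling))
        opt <- optimize(fvar, c(lo_b, hi_b), tol = 1e-3)
      }
      while (opt$minimum < lo_b + 0.01 && lo_b > log(1e-8)) {
        hi_b <- lo_b; lo_b <- max(lo_b - 4, log(1e-8))
        opt <- optimize(fvar, c(lo_b, hi_b), tol = 1e-3)
      }
      cand_s2 <- exp(opt$minimum)
      # the ceiling itself can beat the interior optimum under divergence
      ceil_nll <- fvar(log(spec$variance_ceiling))
      if (ceil_nll < opt$objective) {
        cand_s2 <- spec$variance_ceiling
        opt$objective <- ceil_nll
      }
      if (opt$objective + pen(beta) <= obj + 1e-12) {
        improvement <- obj - (opt$objective + pen(beta))
        sigma2 <- cand_s2
        cur <- laplace_nll(beta0, beta, sigma2, X, y, idx, m, b)
        obj <- cur$nll + pen(beta)
        b <- cur$b
        if (improvement < 1e-8) var_frozen <- TRUE
      } else {
        var_frozen <- TRUE
      }
    } else if (est_var && obj_before - obj > 1e-6) {
      var_frozen <- FALSE  # fixed effects moved: revisit the variance later
    }

    trace <- c(trace, obj)
    s2_trace <- c(s2_trace, sigma2)
    if (max(abs(c(beta0, beta, log1p(sigma2)) - old)) < tol) {
      # the block alternation can stall with small nonzero coefficients that
      # a joint move would remove: propose zeroing each small penalized
      # coefficient and accept only when the full objective decreases
      polished <- FALSE
      if (lambda > 0) {
        for (j in order(abs(beta))) {
          if (beta[j] == 0 || !penalize[j] || abs(beta[j]) > 0.5) next
          nb <- beta
          nb[j] <- 0
          cand <- laplace_nll(beta0, nb, sigma2, X, y, idx, m, b)
          cand_obj <- cand$nll + pen(nb)
          if (cand_obj < obj - 1e-10) {
            beta <- nb; obj <- cand_obj; b <- cand$b
            polished <- TRUE
          }
        }
      }
      if (polished) {
        trace <- c(trace, obj)
        s2_trace <- c(s2_trace, sigma2)
        next
      }
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("penalized GLMM did not converge within max_iterations; returning current fit")
  }

  names(beta) <- colnames(X)
  names(b) <- levels(drv)
  driver_constant <- all(tapply(y, idx, function(v) length(unique(v)) == 1))
  quasi_sep <- driver_constant && est_var &&
    sigma2 >= 0.99 * spec$variance_ceiling
  if (quasi_sep) {
    warning("quasi-separation: outcomes are constant within drivers and the ",
            "random-intercept variance reached its ceiling (",
            format(spec$variance_ceiling), "); fixed effects are identified ",
            "mainly through the penalty and cross-validation")
  }

  structure(list(
    intercept = beta0,
    coefficients = beta,
    random_intercepts = b,
    random_intercept_variance = sigma2,
    objective_trace = trace,
    variance_trace = s2_trace,
    converged = converged,
    nonzero_set = names(beta)[beta != 0],
    lambda = lambda,
    penalize = penalize,
    quasi_separation = quasi_sep,
    driver_constant_outcome = driver_constant,
    n_obs = n, n_drivers = m,
    spec = spec
  ), class = "penalized_glmm_fit")
}

#' @export
print.penalized_glmm_fit <- function(x, ...) {
  cat("Random-intercept logistic fit (lambda =", format(x$lambda), ")\n")
  cat("  n =", x$n_obs, "trips,", x$n_drivers, "drivers;",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  intercept:", format(round(x$intercept, 4)), "\n")
  cat("  nonzero predictors:", if (length(x$nonzero_set)) {
    paste(x$nonzero_set, collapse = ", ")
  } else "(none)", "\n")
  cat("  random-intercept variance:", format(x$random_intercept_variance), "\n")
  if (x$quasi_separation) cat("  [quasi-separation diagnostic fired]\n")
  invisible(x)
}

#' Fit the unpenalized random-intercept logistic model
#'
#' The `lambda = 0` path of [fit_penalized_glmm()], typically on the
#' predictors retained by a prior penalized fit. Standard errors come from
#' the inverse of the observed information of the profiled Laplace
#' objective at the optimum (numerical Hessian over intercept and fixed
#' effects with the variance held at its estimate); a singular information
#' matrix yields `NA` standard errors with a diagnostic rather than
#' fabricated values.
#'
#' @inheritParams fit_penalized_glmm
#' @return A `penalized_glmm_fit` with extra fields `ses` (named standard
#'   errors), `wald` (the [wald_summary()] table) and `fit_statistics`
#'   (log-likelihood, -2LL, parameter count, AIC, BIC; the parameter count
#'   is the number of fixed effects plus one variance parameter).
#' @export
fit_unpenalized_glmm <- function(X, y, driver_ids, spec = NULL) {
  X <- as.matrix(X)
  if (is.null(spec)) spec <- model_spec(colnames(X))
  spec$lambda <- 0
  fit <- fit_penalized_glmm(X, y, driver_ids, spec)

  drv <- factor(driver_ids)
  idx <- as.integer(drv)
  m <- nlevels(drv)
  theta <- c(fit$intercept, fit$coefficients)
  s2 <- fit$random_intercept_variance
  b_hat <- fit$random_intercepts
  f <- function(th) {
    laplace_nll(th[1], th[-1], s2, X, y, idx, m, b_hat)$nll
  }
  H <- numeric_hessian(f, theta)
  ses <- rep(NA_real_, length(theta))
  se_note <- NULL
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  # finite-difference noise keeps truly null directions slightly positive,
  # so the singularity cut is on the relative condition of the information
  ok <- !is.null(ev) && min(ev) > 0 && min(ev) / max(ev) > 1e-6
  V <- if (ok) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
    ses <- sqrt(diag(V))
  } else {
    se_note <- "observed information matrix is singular or not positive definite; standard errors unavailable"
    warning(se_note)
  }
  names(ses) <- c("(Intercept)", colnames(X))

  ll <- -f(theta)
  k <- length(theta) + 1  # fixed effects + 1 variance parameter
  n_obs <- length(y)
  fit$ses <- ses
  fit$se_note <- se_note
  fit$fit_statistics <- fit_statistics(ll, k, n_obs)
  fit$wald <- if (all(is.finite(ses))) wald_summary(fit, ses) else NULL
  fit
}

# central finite-difference Hessian
numeric_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  h <- h %||% pmax(1e-4, 1e-4 * abs(x))
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Information criteria for a fitted model
#'
#' @param log_likelihood Maximized (marginal) log-likelihood.
#' @param n_parameters Number of estimated parameters (fixed effects plus
#'   variance components).
#' @param n_obs Number of observations (trips).
#' @return A list with `log_likelihood`, `minus_two_ll`, `n_parameters`,
#'   `aic` (`-2LL + 2k`), `bic` (`-2LL + k log n`), `n_obs`.
#' @export
fit_statistics <- function(log_likelihood, n_parameters, n_obs) {
  m2 <- -2 * log_likelihood
  list(log_likelihood = log_likelihood, minus_two_ll = m2,
       n_parameters = n_parameters,
       aic = m2 + 2 * n_parameters,
       bic = m2 + n_parameters * log(n_obs),
       n_obs = n_obs)
}

#' Predict per-trip probabilities of Pre-MCI/MCI membership
#'
#' Conditional predictions add the estimated random intercept of drivers
#' that were in the training data and 0 for unseen drivers; marginal
#' predictions always use 0 (the population-average driver), which is the
#' mode used for held-out drivers in cross-validation.
#'
#' @param fit A `penalized_glmm_fit`.
#' @param X Predictor matrix with columns matching the fit's predictors.
#' @param driver_ids Driver identifier per row (used in conditional mode).
#' @param mode `"conditional"` or `"marginal"`.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
predict_probability <- function(fit, X, driver_ids = NULL,
                                mode = c("conditional", "marginal")) {
  mode <- match.arg(mode, choices = c("conditional", "marginal"))
  X <- as.matrix(X)
  if (is.null(colnames(X)) || !identical(colnames(X), names(fit$coefficients))) {
    stop("predictor columns do not match the fitted model (order matters)")
  }
  eta <- drop(fit$intercept + X %*% fit$coefficients)
  if (mode == "conditional") {
    if (is.null(driver_ids)) stop("driver_ids required for conditional prediction")
    b <- fit$random_intercepts[as.character(driver_ids)]
    b[is.na(b)] <- 0
    eta <- eta + unname(b)
  }
  plogis(pmin(pmax(eta, -30), 30))
}

#' Wald and odds-ratio summary of fixed effects
#'
#' For each coefficient: `z = beta/se`, a two-sided normal p-value, a 95%
#' confidence interval `beta +/- 1.96 se`, the odds ratio `exp(beta)` and
#' the exponentiated interval bounds.
#'
#' @param fit A `penalized_glmm_fit` (or any list with `intercept` and
#'   `coefficients`).
#' @param ses Named standard errors for `(Intercept)` and each predictor.
#' @return Data frame with columns `name, beta, se, z, p, ci_low, ci_high,
#'   odds_ratio, or_low, or_high`.
#' @export
wald_summary <- function(fit, ses = fit$ses) {
  if (is.null(ses)) stop("standard errors unavailable")
  beta <- c(`(Intercept)` = fit$intercept, fit$coefficients)
  stopifnot(all(names(beta) %in% names(ses)))
  se <- ses[names(beta)]
  z <- beta / se
  data.frame(
    name = names(beta),
    beta = unname(beta),
    se = unname(se),
    z = unname(z),
    p = unname(2 * pnorm(-abs(z))),
    ci_low = unname(beta - 1.96 * se),
    ci_high = unname(beta + 1.96 * se),
    odds_ratio = unname(exp(beta)),
    or_low = unname(exp(beta - 1.96 * se)),
    or_high = unname(exp(beta + 1.96 * se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Karush-Kuhn-Tucker check for the penalized fit
#'
#' At a solution, every zero penalized coefficient must satisfy
#' `|score_j| <= lambda`, where the score is the gradient of the profiled
#' (unpenalized) objective, `-X_j'(y - p_hat)` at the fitted probabilities.
#'
#' @param fit A `penalized_glmm_fit`.
#' @param X,y,driver_ids The data the fit was produced from.
#' @return Maximum violation `max(|score_j|) - lambda` over zero penalized
#'   coefficients (negative or ~0 when KKT holds); `-Inf` when no
#'   coefficient is zero.
#' @export
kkt_violation <- function(fit, X, y, driver_ids) {
  X <- as.matrix(X)
  pr <- predict_probability(fit, X, driver_ids, "conditional")
  score <- abs(drop(crossprod(X, y - pr)))
  zero <- fit$coefficients == 0 & fit$penalize
  if (!any(zero)) return(-Inf)
  max(score[zero]) - fit$lambda
}

#' Serialize a fit to JSON
#'
#' @param fit A `penalized_glmm_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(
    intercept = fit$intercept,
    coefficients = as.list(fit$coefficients),
    random_intercepts = as.list(fit$random_intercepts),
    random_intercept_variance = fit$random_intercept_variance,
    lambda = fit$lambda,
    converged = fit$converged,
    quasi_separation = fit$quasi_separation,
    nonzero_set = fit$nonzero_set,
    objective_trace = fit$objective_trace
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
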
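# ------------------------------------------------------------------------
# Sensitivity analysis: repeated driver-grouped cross-validation with plain
# L1-penalized logistic regression (no random intercept; driver structure
# enters through fold grouping and the driver-level AUC), fold-wise
# standardization, per-repetition penalty selection, full-data refit and
# selection-frequency summaries.
# ------------------------------------------------------------------------

#' Configure the repeated grouped-CV stability analysis
#'
#' @param repetitions Number of repetitions (default 100).
#' @param k Folds per repetition (default 5, driver-grouped).
#' @param lambda_grid Ascending penalty grid; default 80 log-spaced values
#'   on `[1e-4, 10]` (the penalty multiplies the mean absolute-coefficient
#'   term against the per-observation negative log-likelihood).
#' @param seed Master seed; each repetition derives its own sub-seed.
#' @return A list of class `stability_config`.
#' @export
stability_config <- function(repetitions = 100, k = 5,
                             lambda_grid = default_lambda_grid(), seed = 1) {
  stopifnot(repetitions >= 1, k >= 2, length(lambda_grid) >= 1,
            !is.unsorted(lambda_grid))
  structure(list(repetitions = as.integer(repetitions), k = as.integer(k),
                 lambda_grid = lambda_grid, seed = as.integer(seed)),
            class = "stability_config")
}

#' @rdname stability_config
#' @export
default_lambda_grid <- function() {
  exp(seq(log(1e-4), log(10), length.out = 80))
}

#' L1-penalized logistic regression (coordinate descent)
#'
#' Minimizes the per-observation logistic negative log-likelihood plus
#' `lambda * sum(|beta_j|)` (intercept unpenalized) by iteratively
#' reweighted least squares with cyclic coordinate descent and
#' soft-thresholding, which produces exact zeros for excluded predictors.
#' A vector of penalties is solved in one call with warm starts from large
#' to small.
#'
#' @param X Numeric predictor matrix.
#' @param y Binary outcomes (0/1).
#' @param lambda Penalty value(s) >= 0.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iterations Outer (IRLS) iteration cap per penalty.
#' @return For a single penalty, a list with `intercept`, `coefficients`
#'   (named), `converged`; for several, a list with `lambda`,
#'   `intercepts`, `coefficients` (matrix, one column per penalty) and
#'   `converged`.
#' @export
fit_l1_logistic <- function(X, y, lambda, tol = 1e-7, max_iterations = 200) {
  X <- as.matrix(X)
  stopifnot(all(y %in% c(0, 1)), all(lambda >= 0), length(y) == nrow(X))
  ord <- order(lambda, decreasing = TRUE)  # warm starts: large to small
  res <- l1_logistic_path_cpp(X, as.numeric(y), lambda[ord], tol,
                              as.integer(max_iterations), 50L,
                              numeric(ncol(X)), 0)
  co <- res$coefficients[, order(ord), drop = FALSE]  # back to input order
  conv <- res$converged[order(ord)]
  rownames(co) <- c("(Intercept)", colnames(X))
  if (any(!conv)) {
    warning("L1 logistic fit did not converge for ", sum(!conv), " penalty value(s)")
  }
  if (length(lambda) == 1) {
    list(intercept = co[1, 1],
         coefficients = stats::setNames(co[-1, 1], colnames(X)),
         converged = conv[1])
  } else {
    list(lambda = lambda, intercepts = co[1, ],
         coefficients = co[-1, , drop = FALSE], converged = conv)
  }
}

#' Objective of the L1-penalized logistic model
#'
#' Per-observation negative log-likelihood plus `lambda * sum(|beta|)`;
#' used by tests to compare the solver against direct minimization.
#'
#' @param intercept,beta Coefficients.
#' @param X,y Data.
#' @param lambda Penalty.
#' @return Scalar objective value.
#' @export
l1_logistic_objective <- function(intercept, beta, X, y, lambda) {
  eta <- drop(intercept + as.matrix(X) %*% beta)
  bernoulli_nll(eta, y) / length(y) + lambda * sum(abs(beta))
}

#' Repeated grouped-CV stability selection
#'
#' Per repetition: a fresh driver-level fold plan is drawn from a derived
#' sub-seed; for every fold, predictors are standardized with
#' training-fold means and SDs and the L1 logistic path is fit on the
#' training trips; held-out trips are scored and pooled across folds to
#' one mean predicted probability per driver; the penalty maximizing the
#' pooled driver-level AUC is selected (exact ties to the larger, sparser,
#' penalty); the model is refit on the full, globally standardized data at
#' that penalty and its nonzero predictors recorded. Failed repetitions
#' are logged and excluded, never silently dropped.
#'
#' @param features Data frame or matrix of raw (unstandardized) trip-level
#'   predictors.
#' @param outcomes Binary trip outcomes.
#' @param driver_ids Driver id per trip.
#' @param driver_labels Named binary labels per driver (for fold
#'   stratification and the driver-level AUC).
#' @param config A [stability_config()].
#' @param feature_names Predictor columns (default [telemci_features()]
#'   intersected with the available columns).
#' @return A list of class `stability_result`: `outcomes` (one row per
#'   successful repetition: index, chosen lambda, driver-level AUC),
#'   `nonzero` (logical matrix repetitions x predictors), `n_failed`,
#'   `failures`, `config`.
#' @export
run_stability <- function(features, outcomes, driver_ids, driver_labels,
                          config = stability_config(),
                          feature_names = NULL) {
  stopifnot(inherits(config, "stability_config"))
  df <- as.data.frame(features)
  feature_names <- feature_names %||% intersect(telemci_features(), names(df))
  stopifnot(length(feature_names) >= 1)
  driver_ids <- as.character(driver_ids)
  grid <- config$lambda_grid
  rep_rows <- vector("list", config$repetitions)
  nonzero <- matrix(FALSE, config$repetitions, length(feature_names),
                    dimnames = list(NULL, feature_names))
  failures <- character(0)
  ok <- logical(config$repetitions)

  for (r in seq_len(config$repetitions)) {
    res <- tryCatch(
      stability_one_rep(df, outcomes, driver_ids, driver_labels, config,
                        feature_names, grid,
                        seed = derive_seed(config$seed, r)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("repetition %d: %s", r, conditionMessage(res)))
      next
    }
    ok[r] <- TRUE
    rep_rows[[r]] <- data.frame(repetition = r, chosen_lambda = res$chosen_lambda,
                                driver_level_auc = res$driver_level_auc)
    nonzero[r, ] <- res$nonzero
  }
  if (!any(ok)) stop("every stability repetition failed:\n",
                     paste(failures, collapse = "\n"))
  structure(list(
    outcomes = do.call(rbind, rep_rows[ok]),
    nonzero = nonzero[ok, , drop = FALSE],
    n_failed = sum(!ok),
    failures = failures,
    feature_names = feature_names,
    config = config
  ), class = "stability_result")
}

stability_one_rep <- function(df, outcomes, driver_ids, driver_labels, config,
                              feature_names, grid, seed) {
  plan <- make_grouped_folds(driver_labels, config$k, seed = seed,
                             stratified = TRUE)
  fold_of <- plan$assignment
  prob <- matrix(NA_real_, nrow(df), length(grid))
  for (f in seq_len(config$k)) {
    held <- names(fold_of)[fold_of == f]
    test_idx <- driver_ids %in% held
    train_idx <- !test_idx
    stopifnot(!any(train_idx & test_idx))
    # standardization fitted on training trips only, applied to held-out
    ztr <- standardize(df[train_idx, , drop = FALSE], feature_names)
    zte <- standardize(df[test_idx, , drop = FALSE], feature_names,
                       params = ztr$params)
    path <- fit_l1_logistic(as.matrix(ztr$table[, feature_names]),
                            outcomes[train_idx], grid, tol = 1e-5)
    co <- if (length(grid) == 1) cbind(path$coefficients) else path$coefficients
    ints <- if (length(grid) == 1) path$intercept else path$intercepts
    Xte <- as.matrix(zte$table[, feature_names])
    eta <- sweep(Xte %*% co, 2, ints, "+")
    prob[test_idx, ] <- plogis(pmin(pmax(eta, -30), 30))
  }
  # pooled driver-level AUC per penalty: aggregate the whole probability
  # matrix to driver means in one pass, then rank per column
  dm <- rowsum(prob, driver_ids)
  dm <- dm / as.vector(table(driver_ids)[rownames(dm)])
  lab <- driver_labels[rownames(dm)]
  aucs <- apply(dm, 2, auc, labels = lab)
  chosen <- select_lambda(grid, aucs)
  best_auc <- max(aucs)
  # refit on the full data, warm-starting down the path to the chosen value
  sub <- grid[grid >= chosen]
  refit <- fit_l1_logistic(
    as.matrix(standardize(df, feature_names)$table[, feature_names]),
    outcomes, sub)
  co <- if (length(sub) == 1) refit$coefficients else
    refit$coefficients[, which(sub == chosen)]
  list(chosen_lambda = chosen, driver_level_auc = best_auc,
       nonzero = co != 0)
}

#' Summarize a stability run
#'
#' @param result A [run_stability()] result.
#' @return A list of class `stability_report`: `selection_frequency`
#'   (data frame, percent of successful repetitions with a nonzero
#'   coefficient, sorted descending) and `distribution` (1st quartile,
#'   median, mean, 3rd quartile and maximum of the chosen penalty and of
#'   the driver-level AUC; quartiles use linear interpolation between
#'   order statistics).
#' @export
summarize_stability <- function(result) {
  stopifnot(inherits(result, "stability_result"))
  nz <- result$nonzero
  freq <- 100 * colMeans(nz)
  sel <- data.frame(predictor = colnames(nz),
                    selection_frequency_pct = unname(freq),
                    stringsAsFactors = FALSE)
  sel <- sel[order(-sel$selection_frequency_pct, sel$predictor), ]
  rownames(sel) <- NULL
  summarize_vec <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(q1 = q[1], median = q[2], mean = mean(v), q3 = q[3], max = max(v))
  }
  dist <- data.frame(
    statistic = c("1st quartile", "median", "mean", "3rd quartile", "maximum"),
    lambda = unname(summarize_vec(result$outcomes$chosen_lambda)),
    driver_level_auc = unname(summarize_vec(result$outcomes$driver_level_auc)),
    stringsAsFactors = FALSE
  )
  structure(list(selection_frequency = sel, distribution = dist,
                 n_repetitions = nrow(result$outcomes),
                 n_failed = result$n_failed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability selection over", x$n_repetitions, "repetitions",
      if (x$n_failed > 0) sprintf("(%d failed)", x$n_failed) else "", "\n")
  print(x$selection_frequency, row.names = FALSE)
  cat("\n")
  print(x$distribution, row.names = FALSE)
  invisible(x)
}

#' Write per-repetition outcomes as JSON lines
#'
#' @param result A [run_stability()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stability_jsonl <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(result$outcomes))) {
    row <- result$outcomes[i, ]
    rec <- list(repetition = row$repetition, chosen_lambda = row$chosen_lambda,
                driver_level_auc = row$driver_level_auc,
                nonzero_set = colnames(result$nonzero)[result$nonzero[i, ]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
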
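# ------------------------------------------------------------------------
# Driver-grouped cross-validation over the penalty grid, trip- and
# driver-level ROC/AUC, and driver-bootstrap confidence intervals.
# ------------------------------------------------------------------------

#' Build driver-grouped cross-validation folds
#'
#' Folds partition the driver set, so all trips of a driver are held out
#' together. Fold sizes differ by at most one driver. Stratified assignment
#' (the default caller choice) deals each outcome class round-robin into
#' the currently smallest folds, balancing class counts across folds to
#' within one; when a class has fewer drivers than folds stratification is
#' infeasible and the plan falls back to unstratified with a warning.
#'
#' @param driver_labels Named vector (names = driver ids) of binary driver
#'   labels, used for stratification.
#' @param k Number of folds (`k <=` number of drivers).
#' @param seed Integer seed for the shuffle.
#' @param stratified Balance class counts across folds.
#' @return An object of class `fold_plan`: `k`, `assignment` (named integer
#'   vector driver -> fold), `seed`, `stratified` (as realized).
#' @export
make_grouped_folds <- function(driver_labels, k = 5, seed = 1,
                               stratified = TRUE) {
  drivers <- names(driver_labels)
  stopifnot(!is.null(drivers), k >= 2, k <= length(drivers))
  set.seed(seed)
  assignment <- integer(length(drivers))
  names(assignment) <- drivers
  if (stratified && min(table(driver_labels)) < k) {
    warning("a class has fewer drivers than folds; falling back to unstratified assignment")
    stratified <- FALSE
  }
  if (stratified) {
    sizes <- integer(k)
    for (cl in unique(driver_labels)) {
      ids <- sample(drivers[driver_labels == cl])
      counts <- integer(k)  # this class's count per fold
      for (id in ids) {
        # balance this class first, then total fold size
        f <- which(counts == min(counts))
        if (length(f) > 1) f <- f[sizes[f] == min(sizes[f])]
        if (length(f) > 1) f <- sample(f, 1)
        assignment[id] <- f
        counts[f] <- counts[f] + 1
        sizes[f] <- sizes[f] + 1
      }
    }
  } else {
    ids <- sample(drivers)
    assignment[ids] <- rep_len(seq_len(k), length(ids))
  }
  structure(list(k = k, assignment = assignment, seed = seed,
                 stratified = stratified),
            class = "fold_plan")
}

#' Area under the ROC curve (midrank formula)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half; equivalent to trapezoidal
#' integration of the ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both outcome classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams auc
#' @return Data frame of `(fpr, tpr)` points, monotone non-decreasing from
#'   (0, 0) to (1, 1), with tied scores grouped.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tie group
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  data.frame(fpr = c(0, fp / sum(1 - labels)), tpr = c(0, tp / sum(labels)))
}

#' Driver-level ROC from trip probabilities
#'
#' Trip probabilities are averaged (unweighted) within driver to one mean
#' predicted probability per driver; the AUC is then computed over drivers.
#'
#' @param trip_probs Per-trip predicted probabilities.
#' @param trip_driver_ids Driver id per trip.
#' @param driver_labels Named binary labels, one per driver.
#' @return A list of class `roc_summary`: `level = "driver"`, `auc`,
#'   `driver_means`, `curve`.
#' @export
driver_level_auc <- function(trip_probs, trip_driver_ids, driver_labels) {
  means <- tapply(trip_probs, as.character(trip_driver_ids), mean)
  ids <- names(means)
  stopifnot(all(ids %in% names(driver_labels)))
  lab <- driver_labels[ids]
  structure(list(level = "driver", auc = auc(as.numeric(means), lab),
                 driver_means = stats::setNames(as.numeric(means), ids),
                 curve = roc_points(as.numeric(means), lab)),
            class = "roc_summary")
}

#' Driver-bootstrap confidence interval for the AUC
#'
#' Resamples drivers with replacement, keeping each driver's mean predicted
#' probability and label, and forms a percentile interval over replicate
#' AUCs. Replicates in which only one class is drawn are redrawn and
#' counted.
#'
#' @inheritParams driver_level_auc
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param level Which scores to resample: `"driver"` (one mean probability
#'   per driver, the primary metric) or `"trip"` (trip-level scores,
#'   resampled by driver; the resulting interval may be optimistic).
#' @param conf Confidence level (default 0.95).
#' @return A list of class `roc_summary` with `auc`, `ci_low`, `ci_high`,
#'   `n_bootstrap`, `n_redrawn`, `curve`.
#' @export
bootstrap_driver_auc_ci <- function(trip_probs, trip_driver_ids, driver_labels,
                                    n_boot = 2000, seed = 1,
                                    level = c("driver", "trip"),
                                    conf = 0.95) {
  level <- match.arg(level)
  stopifnot(n_boot >= 100)
  set.seed(seed)
  ids <- names(driver_labels)
  by_driver <- split(trip_probs, as.character(trip_driver_ids))
  stopifnot(all(names(by_driver) %in% ids))
  point <- if (level == "driver") {
    driver_level_auc(trip_probs, trip_driver_ids, driver_labels)
  } else {
    structure(list(level = "trip",
                   auc = auc(trip_probs, driver_labels[as.character(trip_driver_ids)]),
                   curve = roc_points(trip_probs,
                                      driver_labels[as.character(trip_driver_ids)])),
              class = "roc_summary")
  }
  stats_boot <- numeric(n_boot)
  n_redrawn <- 0L
  present <- intersect(ids, names(by_driver))
  for (r in seq_len(n_boot)) {
    repeat {
      take <- sample(present, length(present), replace = TRUE)
      lab <- driver_labels[take]
      if (length(unique(lab)) == 2) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100 * n_boot) stop("bootstrap cannot realize both classes")
    }
    if (level == "driver") {
      sc <- vapply(by_driver[take], mean, numeric(1))
      stats_boot[r] <- auc(sc, lab)
    } else {
      sc <- unlist(by_driver[take], use.names = FALSE)
      yl <- rep(lab, times = lengths(by_driver[take]))
      stats_boot[r] <- auc(sc, yl)
    }
  }
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(stats_boot, c(alpha, 1 - alpha), type = 7))
  point$ci_low <- ci[1]
  point$ci_high <- ci[2]
  point$n_bootstrap <- n_boot
  point$n_redrawn <- n_redrawn
  point
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("%s-level AUC = %.3f", x$level, x$auc))
  if (!is.null(x$ci_low)) {
    cat(sprintf(" (95%% CI %.3f-%.3f, %d bootstrap replicates)",
                x$ci_low, x$ci_high, x$n_bootstrap))
  }
  cat("\n")
  invisible(x)
}

#' Cross-validate the L1 penalty of the random-intercept model
#'
#' For each candidate penalty, fits the penalized GLMM on the training
#' drivers of each fold, predicts held-out trips in marginal mode (held-out
#' drivers have no estimated intercept) and computes the held-out AUC per
#' fold, either at the trip level (default) or aggregated to one mean
#' probability per held-out driver. The penalty attaining the maximum mean
#' AUC is selected; exact ties go to the larger (sparser) penalty. An
#' internal assertion verifies on every run that no driver appears in both
#' the training and held-out set of a fold.
#'
#' @param features Matrix or data frame of z-scored predictors.
#' @param outcomes Binary trip outcomes.
#' @param driver_ids Driver id per trip.
#' @param grid Numeric vector of candidate penalties (default the study
#'   grid 1, 5, 10, 20, 50).
#' @param plan A [make_grouped_folds()] plan.
#' @param spec Base [model_spec()] (its `lambda` is overridden per
#'   candidate).
#' @param level AUC level used for selection: `"trip"` or `"driver"`.
#' @return A list of class `lambda_grid_result`: `table` (per-lambda mean
#'   and SD of held-out AUC, folds used), `best_lambda`, `level`, `notes`
#'   (e.g. folds excluded for single-class outcomes).
#' @export
cross_validate_lambda <- function(features, outcomes, driver_ids,
                                  grid = c(1, 5, 10, 20, 50), plan,
                                  spec = NULL, level = c("trip", "driver")) {
  level <- match.arg(level)
  stopifnot(length(grid) >= 1, inherits(plan, "fold_plan"))
  X <- as.matrix(features)
  spec <- spec %||% model_spec(colnames(X))
  grid <- sort(grid)
  driver_ids <- as.character(driver_ids)
  fold_of <- plan$assignment
  notes <- character(0)

  fold_auc <- matrix(NA_real_, nrow = plan$k, ncol = length(grid))
  for (f in seq_len(plan$k)) {
    held <- names(fold_of)[fold_of == f]
    test_idx <- driver_ids %in% held
    train_idx <- !test_idx
    # leakage assertion: training and held-out driver sets must be disjoint
    stopifnot(length(intersect(unique(driver_ids[train_idx]),
                               unique(driver_ids[test_idx]))) == 0)
    if (length(unique(outcomes[test_idx])) < 2 && level == "trip") {
      notes <- c(notes, sprintf("fold %d excluded: single-class held-out trips", f))
      next
    }
    drv_lab <- tapply(outcomes[test_idx], driver_ids[test_idx],
                      function(v) v[1])
    if (level == "driver" && length(unique(drv_lab)) < 2) {
      notes <- c(notes, sprintf("fold %d excluded: single-class held-out drivers", f))
      next
    }
    for (g in rev(seq_along(grid))) {   # large to small: warm start ordering
      sp <- spec
      sp$lambda <- grid[g]
      fit <- suppressWarnings(
        fit_penalized_glmm(X[train_idx, , drop = FALSE], outcomes[train_idx],
                           driver_ids[train_idx], sp))
      pr <- predict_probability(fit, X[test_idx, , drop = FALSE],
                                driver_ids[test_idx], mode = "marginal")
      fold_auc[f, g] <- if (level == "trip") {
        auc(pr, outcomes[test_idx])
      } else {
        driver_level_auc(pr, driver_ids[test_idx],
                         stats::setNames(as.numeric(drv_lab), names(drv_lab)))$auc
      }
    }
  }
  mean_auc <- colMeans(fold_auc, na.rm = TRUE)
  sd_auc <- apply(fold_auc, 2, sd, na.rm = TRUE)
  folds_used <- colSums(!is.na(fold_auc))
  if (all(folds_used == 0)) stop("no fold produced a defined AUC")
  best <- select_lambda(grid, mean_auc)
  structure(list(
    table = data.frame(lambda = grid, mean_auc = mean_auc, sd_auc = sd_auc,
                       folds_used = folds_used),
    fold_auc = fold_auc,
    best_lambda = best, level = level, notes = notes
  ), class = "lambda_grid_result")
}

# maximum mean AUC; exact ties resolved toward the larger (sparser) penalty
select_lambda <- function(grid, mean_auc) {
  best_val <- max(mean_auc, na.rm = TRUE)
  cand <- grid[!is.na(mean_auc) & mean_auc == best_val]
  max(cand)
}

#' @export
print.lambda_grid_result <- function(x, ...) {
  cat("Driver-grouped CV over the penalty grid (", x$level, "-level AUC)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("best lambda:", format(x$best_lambda), "\n")
  if (length(x$notes)) cat(paste(x$notes, collapse = "\n"), "\n")
  invisible(x)
}
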
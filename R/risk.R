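# Risk-area binning, feature screening, and the regression-tree risk model.

#' Observation window
#'
#' @param start,end dates (anything `as.Date()` accepts); `end > start`.
#' @return list of class `observation_window` with `start`, `end` and
#'   `years` (days / 365.25; the denominator accommodates leap years).
#' @examples
#' observation_window("2018-10-07", "2024-05-28")$years  # about 5.64
#' @export
observation_window <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (!(end > start)) stop("observation window must satisfy end > start")
  structure(list(start = start, end = end,
                 years = as.numeric(end - start) / 365.25),
            class = "observation_window")
}

#' Average alerts per year
#'
#' @param count non-negative alert count(s).
#' @param window an [observation_window()] or a positive number of years.
#' @return `count / years`.
#' @export
alerts_per_year <- function(count, window) {
  years <- if (inherits(window, "observation_window")) window$years
           else as.numeric(window)
  if (!is.finite(years) || years <= 0) stop("observation window must be positive")
  if (any(count < 0)) stop("alert count must be >= 0")
  count / years
}

# Upper bounds of the alerts-per-year bins; level 1 is exactly zero, then
# half-open intervals (0,1], (1,2], (2,3], (3,4], (4,5], (5,10], (10,20],
# and everything above 20 is level 9.
RISK_BREAKS <- c(0, 1, 2, 3, 4, 5, 10, 20)

#' Bin an alerts-per-year rate into an ordinal risk area (1-9)
#'
#' Level 1 corresponds to no alerts at all; levels 2-8 to the half-open
#' intervals (0-1], (1-2], (2-3], (3-4], (4-5], (5-10], (10-20] alerts per
#' year; level 9 to more than 20. Vectorized.
#'
#' @param rate non-negative alerts-per-year rate(s).
#' @return integer risk level(s) in 1..9.
#' @export
bin_risk_area <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("rate must be finite and >= 0")
  }
  as.integer(findInterval(rate, RISK_BREAKS, left.open = TRUE) + 1L)
}

#' Screen features by collinearity (VIF) and a per-feature F-test
#'
#' Two stages. First, collinear features are removed iteratively: the
#' variance inflation factor of each remaining feature (1 / (1 - R^2) of its
#' regression on the others) is computed and the feature with the highest
#' VIF is dropped until all VIFs are at most `vif_cutoff`. Second, each
#' surviving feature is tested for association with the ordinal risk-area
#' target by a one-way ANOVA F-test; features with p below `alpha` are
#' retained. Zero-variance features are discarded up front. Deterministic
#' given the column order of `table`.
#'
#' @param table feature table with a `risk_area` column (see
#'   [build_feature_table()]).
#' @param features candidate feature columns; defaults to the canonical
#'   names present in `table`.
#' @param target name of the target column (default `"risk_area"`).
#' @param vif_cutoff VIF threshold (default 10).
#' @param alpha F-test significance level (default 0.05).
#' @return character vector of retained feature names, with attributes
#'   `dropped_constant`, `dropped_vif`, `p_values`.
#' @export
screen_features <- function(table, features = NULL, target = "risk_area",
                            vif_cutoff = 10, alpha = 0.05) {
  if (is.null(features)) {
    features <- intersect(aed_feature_names(include_age = TRUE), names(table))
  }
  stopifnot(length(features) >= 2, target %in% names(table))
  if (nrow(table) < 10) stop("need at least 10 rows to screen features")

  sds <- vapply(table[features], stats::sd, numeric(1))
  constant <- features[sds == 0 | is.na(sds)]
  feats <- setdiff(features, constant)
  if (length(feats) == 0) stop("all features are constant; degenerate inputs")

  dropped_vif <- character()
  while (length(feats) >= 2) {
    vifs <- vapply(feats, function(f) {
      # a perfect fit here just means an exactly collinear feature
      r2 <- suppressWarnings(summary(
        stats::lm(stats::reformulate(setdiff(feats, f), f),
                  data = table))$r.squared)
      1 / max(1 - r2, 1e-12)
    }, numeric(1))
    if (max(vifs) <= vif_cutoff) break
    worst <- feats[which.max(vifs)]
    dropped_vif <- c(dropped_vif, worst)
    feats <- setdiff(feats, worst)
  }

  y <- factor(table[[target]])
  if (nlevels(y) < 2) stop("target is constant; cannot screen features")
  pvals <- vapply(feats, function(f) {
    stats::anova(stats::lm(table[[f]] ~ y))[["Pr(>F)"]][1]
  }, numeric(1))
  retained <- feats[!is.na(pvals) & pvals < alpha]
  if (length(retained) == 0) {
    stop("all features eliminated during screening; degenerate inputs")
  }
  structure(retained, dropped_constant = constant, dropped_vif = dropped_vif,
            p_values = pvals)
}

.tree_cv_error <- function(data, formula, folds_id, depth, minbucket) {
  sq <- ab <- 0
  n <- 0
  for (k in sort(unique(folds_id))) {
    fit <- rpart::rpart(formula, data = data[folds_id != k, , drop = FALSE],
                        method = "anova",
                        control = rpart::rpart.control(
                          maxdepth = depth, minbucket = minbucket,
                          minsplit = max(2, 2 * minbucket),
                          cp = 0, xval = 0))
    pred <- stats::predict(fit, newdata = data[folds_id == k, , drop = FALSE])
    err <- pred - data[[all.vars(formula)[1]]][folds_id == k]
    sq <- sq + sum(err^2)
    ab <- ab + sum(abs(err))
    n <- n + length(err)
  }
  c(mse = sq / n, mae = ab / n)
}

#' Fit the regression-tree risk model
#'
#' The ordinal risk area (1-9) is regressed as a number. The data are split
#' 80/20 into training and test sets; tree depth and minimum leaf size are
#' chosen by five-fold cross-validation on the training set over a small
#' grid, ties broken toward the shallower tree (and, at equal depth, the
#' larger leaf size). A linear-regression baseline is fitted on the same
#' features for comparison only. Fully reproducible given `seed`.
#'
#' @param table screened feature table including the target column.
#' @param features feature names to use (typically [screen_features()]
#'   output).
#' @param target target column name (default `"risk_area"`).
#' @param split_fraction training fraction (default 0.8).
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for the split and fold assignment.
#' @param depth_grid,minbucket_grid hyperparameter grid (defaults 2:6 and
#'   c(5, 10, 20)).
#' @return object of class `risk_model`: the fitted `rpart` tree, the
#'   feature list, chosen hyperparameters, `cv_mse`/`cv_mae` (training CV)
#'   and `test_mse`/`test_mae` (held-out 20%), plus the linear baseline's
#'   test errors.
#' @export
fit_risk_tree <- function(table, features, target = "risk_area",
                          split_fraction = 0.8, folds = 5, seed = 1,
                          depth_grid = 2:6, minbucket_grid = c(5, 10, 20)) {
  stopifnot(all(features %in% names(table)), target %in% names(table))
  n <- nrow(table)
  if (n < 25) stop("need at least 25 rows to fit the risk model")
  set.seed(seed)
  train_idx <- sort(sample.int(n, round(split_fraction * n)))
  train <- table[train_idx, , drop = FALSE]
  test <- table[-train_idx, , drop = FALSE]
  fml <- stats::reformulate(features, target)
  y_train <- train[[target]]

  constant_target <- stats::var(y_train) == 0
  if (constant_target) {
    warning("constant target: fitting a single-leaf model")
    best <- list(depth = 1, minbucket = max(2, nrow(train)), cv = c(mse = 0, mae = 0))
  } else {
    folds_id <- sample(rep(seq_len(folds), length.out = nrow(train)))
    best <- NULL
    for (depth in sort(depth_grid)) {
      for (mb in sort(minbucket_grid, decreasing = TRUE)) {
        cv <- .tree_cv_error(train, fml, folds_id, depth, mb)
        if (is.null(best) || cv["mse"] < best$cv["mse"] - 1e-12) {
          best <- list(depth = depth, minbucket = mb, cv = cv)
        }
      }
    }
  }

  tree <- rpart::rpart(fml, data = train, method = "anova",
                       control = rpart::rpart.control(
                         maxdepth = best$depth, minbucket = best$minbucket,
                         minsplit = max(2, 2 * best$minbucket),
                         cp = 0, xval = 0))
  test_pred <- stats::predict(tree, newdata = test)
  test_err <- test_pred - test[[target]]

  baseline <- tryCatch({
    lmfit <- stats::lm(fml, data = train)
    pred <- stats::predict(lmfit, newdata = test)
    c(mse = mean((pred - test[[target]])^2),
      mae = mean(abs(pred - test[[target]])))
  }, error = function(e) c(mse = NA_real_, mae = NA_real_))

  structure(list(tree = tree, features = features, target = target,
                 depth = best$depth, minbucket = best$minbucket,
                 cv_mse = unname(best$cv["mse"]),
                 cv_mae = unname(best$cv["mae"]),
                 test_mse = mean(test_err^2), test_mae = mean(abs(test_err)),
                 baseline_test_mse = unname(baseline["mse"]),
                 baseline_test_mae = unname(baseline["mae"]),
                 n_train = nrow(train), n_test = nrow(test), seed = seed),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model (regression tree)\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  depth %d, minbucket %d | cv MSE %.3f MAE %.3f | test MSE %.3f MAE %.3f\n",
              x$depth, x$minbucket, x$cv_mse, x$cv_mae, x$test_mse, x$test_mae))
  invisible(x)
}

#' Predict risk areas for candidate locations
#'
#' @param model a [fit_risk_tree()] model.
#' @param newdata data.frame containing every model feature.
#' @param raw return the un-rounded tree output (used for tie-breaking in
#'   placement) instead of the integer level.
#' @return integer risk levels clamped to 1..9 (or numeric scores when
#'   `raw = TRUE`).
#' @export
predict_risk <- function(model, newdata, raw = FALSE) {
  stopifnot(inherits(model, "risk_model"))
  missing <- setdiff(model$features, names(newdata))
  if (length(missing) > 0) {
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  }
  score <- unname(stats::predict(model$tree, newdata = newdata))
  if (raw) return(score)
  as.integer(pmin(9, pmax(1, round(score))))
}

#' Export a risk-model summary as JSON
#'
#' @param model a `risk_model`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_risk_model_json <- function(model, path) {
  frame <- model$tree$frame
  summary <- list(
    type = "regression_tree",
    features = model$features,
    depth = model$depth,
    minbucket = model$minbucket,
    metrics = list(cv_mse = model$cv_mse, cv_mae = model$cv_mae,
                   test_mse = model$test_mse, test_mae = model$test_mae,
                   baseline_test_mse = model$baseline_test_mse,
                   baseline_test_mae = model$baseline_test_mae),
    nodes = data.frame(var = as.character(frame$var), n = frame$n,
                       value = frame$yval)
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
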
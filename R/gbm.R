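#' Fit the stage-2 gradient-boosted regressor with hyperparameter search
#'
#' Random search (seeded, hence reproducible and monotone in the explored
#' set) over a declared space — tree depth, learning rate, number of rounds
#' (early-stopped), row/column subsampling, minimum child weight and L2
#' regularization — selecting the configuration with minimal validation
#' RMSE. The validation rows are never part of the boosting training set, and
#' test rows must not be passed here at all (leakage guard: the returned
#' object records the index sets actually used).
#'
#' @param features numeric matrix of combined features (finite entries).
#' @param labels numeric vector of log10 K_M values.
#' @param val_rows indices of the validation rows within `features`.
#' @param search_budget number of hyperparameter draws (>= 1, default 20).
#' @param seed integer seed.
#' @param nthread xgboost threads (default 1, keeping runs deterministic).
#' @return an object of class `kmpred_gbm`: list with `model` (xgboost
#'   booster), `best_params`, `best_score` (validation RMSE), `best_nrounds`,
#'   `trials` (one row per draw), `train_rows`, `val_rows`.
#' @export
fit_gbm <- function(features, labels, val_rows, search_budget = 20L,
                    seed = 1L, nthread = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (search_budget < 1L) stop("search_budget must be >= 1")
  if (!all(is.finite(features))) stop("non-finite feature values")
  train_rows <- setdiff(seq_len(nrow(features)), val_rows)
  dtrain <- xgboost::xgb.DMatrix(features[train_rows, , drop = FALSE],
                                 label = labels[train_rows])
  dval <- xgboost::xgb.DMatrix(features[val_rows, , drop = FALSE],
                               label = labels[val_rows])

  # draws made trial-by-trial upfront, so a budget b explores exactly a
  # prefix of any larger budget under the same seed
  draws <- with_local_seed(seed, do.call(rbind, lapply(
    seq_len(search_budget), function(i) data.frame(
      max_depth = sample(3:9, 1),
      eta = 10^stats::runif(1, -1.7, -0.5),
      subsample = stats::runif(1, 0.6, 1),
      colsample_bytree = stats::runif(1, 0.5, 1),
      min_child_weight = sample(1:8, 1),
      lambda = 10^stats::runif(1, -0.3, 0.9)))))

  best <- list(score = Inf)
  trials <- draws
  trials$val_rmse <- NA_real_
  trials$nrounds <- NA_integer_
  for (i in seq_len(search_budget)) {
    params <- list(objective = "reg:squarederror",
                   max_depth = draws$max_depth[i], eta = draws$eta[i],
                   subsample = draws$subsample[i],
                   colsample_bytree = draws$colsample_bytree[i],
                   min_child_weight = draws$min_child_weight[i],
                   lambda = draws$lambda[i],
                   nthread = nthread, seed = seed)
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = 600L,
                              evals = list(val = dval),
                              early_stopping_rounds = 30L, verbose = 0)
    at <- xgboost::xgb.attributes(fit)
    score <- as.numeric(at$best_score)
    trials$val_rmse[i] <- score
    trials$nrounds[i] <- as.integer(at$best_iteration)
    if (score < best$score)
      best <- list(score = score, model = fit, params = params,
                   nrounds = as.integer(at$best_iteration), trial = i)
  }
  structure(list(model = best$model, best_params = best$params,
                 best_score = best$score, best_nrounds = best$nrounds,
                 trials = trials, train_rows = train_rows,
                 val_rows = val_rows),
            class = "kmpred_gbm")
}

#' @export
print.kmpred_gbm <- function(x, ...) {
  cat("<kmpred_gbm> ", nrow(x$trials), " search trials; best val RMSE ",
      signif(x$best_score, 4), " (depth ", x$best_params$max_depth,
      ", eta ", signif(x$best_params$eta, 3), ", ", x$best_nrounds,
      " rounds)\n", sep = "")
  invisible(x)
}

#' @export
predict.kmpred_gbm <- function(object, newdata, ...) {
  stats::predict(object$model, xgboost::xgb.DMatrix(newdata))
}
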
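#' Fit the two-stage K_M prediction model
#'
#' Stage 1 trains a message-passing graph encoder (GIN, GCN, GAT or GAT-GCN)
#' together with a two-layer fully connected head end to end on log10 K_M,
#' keeping the parameters of the epoch with minimal validation RMSE. Stage 2
#' fits gradient-boosted trees, with a seeded random hyperparameter search,
#' on the combined features (trained substrate embedding concatenated with
#' the protein embedding; 1,408-d with the defaults). Predictions come from
#' the stage-2 regressor.
#'
#' An internal validation split (`train_cfg$val_fraction` of the supplied
#' records) serves both the stage-1 epoch selection and the stage-2 search;
#' held-out test records must not be passed to `kmpred()` at all.
#'
#' @param data curated records (see [curate_records()]): a data frame with
#'   `canonical_smiles` (or `smiles`, canonicalized on the fly), `sequence`
#'   and `log10_km` (or positive `km_value`).
#' @param encoder encoder variant or a full [encoder_config()].
#' @param embedder a [protein_embedder()] (default [mock_embedder()]).
#' @param train_cfg a [train_config()].
#' @param gbm_budget stage-2 hyperparameter draws (default 20).
#' @param seed master seed; overrides `train_cfg$seed` and seeds the split
#'   and the stage-2 search.
#' @param quiet suppress progress output.
#' @return an object of class `kmpred` with components `encoder_cfg`,
#'   `stage1` (selected parameters, per-epoch log, `selected_epoch`), `gbm`
#'   (a `kmpred_gbm`), `embedder`, `val_rows`, `metrics` (validation-set
#'   [metrics_report()]), `data` (the training records), `seed`.
#' @seealso [predict.kmpred()], [summary.kmpred()], [run_training_pipeline()]
#' @export
kmpred <- function(data, encoder = c("gat_gcn", "gin", "gcn", "gat"),
                   embedder = mock_embedder(),
                   train_cfg = train_config(), gbm_budget = 20L,
                   seed = 1L, quiet = TRUE) {
  cl <- match.call()
  if (is.character(encoder))
    encoder <- encoder_config(match.arg(encoder))
  stopifnot(inherits(encoder, "encoder_config"),
            inherits(embedder, "protein_embedder"),
            inherits(train_cfg, "train_config"))
  if (is.null(data$canonical_smiles))
    data$canonical_smiles <- canonicalize_smiles(data$smiles, strict = TRUE)
  if (is.null(data$log10_km)) data <- log10_transform(data)
  train_cfg$seed <- as.integer(seed)

  n <- nrow(data)
  n_val <- max(2L, round(train_cfg$val_fraction * n))
  val_rows <- with_local_seed(seed + 1L, sort(sample.int(n, n_val)))

  feats <- featurize_records(data, embedder)
  stage1 <- train_stage1(feats, val_rows, encoder, train_cfg, quiet = quiet)
  combined <- extract_features(stage1, feats)
  gbm <- fit_gbm(combined, feats$y, val_rows, search_budget = gbm_budget,
                 seed = seed + 2L)

  val_pred <- predict(gbm, combined[val_rows, , drop = FALSE])
  metrics <- metrics_report(feats$y[val_rows], val_pred, label = "validation")

  structure(list(encoder_cfg = encoder, stage1 = stage1, gbm = gbm,
                 embedder = embedder, val_rows = val_rows,
                 metrics = metrics, data = data, seed = as.integer(seed),
                 call = cl),
            class = "kmpred")
}

#' Predict log10 K_M for enzyme-substrate pairs
#'
#' @param object a fitted [kmpred()] model.
#' @param newdata data frame with columns `smiles` (or `canonical_smiles`)
#'   and `sequence`; alternatively pass `smiles` and `sequence` vectors
#'   directly.
#' @param smiles,sequence used when `newdata` is missing.
#' @param ... unused.
#' @return numeric vector of predicted log10 K_M values.
#' @export
predict.kmpred <- function(object, newdata = NULL, smiles = NULL,
                           sequence = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(smiles) || is.null(sequence))
      stop("supply newdata or both smiles and sequence")
    newdata <- data.frame(smiles = smiles, sequence = sequence,
                          stringsAsFactors = FALSE)
  }
  bad <- !is_valid_sequence(newdata$sequence)
  if (any(bad))
    stop("invalid amino-acid sequence in row ", which(bad)[1],
         " (protein-embedding stage)")
  if (is.null(newdata$canonical_smiles))
    newdata$canonical_smiles <- canonicalize_smiles(newdata$smiles,
                                                    strict = TRUE)
  feats <- featurize_records(newdata, object$embedder)
  combined <- extract_features(object$stage1, feats)
  predict(object$gbm, combined)
}

#' Predict log10 K_M from one SMILES and one sequence
#'
#' Convenience wrapper around [predict.kmpred()]: the prediction equals the
#' stage-2 regressor applied to the concatenation of the trained encoder's
#' graph embedding and the protein embedding.
#'
#' @param bundle a fitted [kmpred()] model.
#' @param smiles substrate SMILES.
#' @param sequence amino-acid sequence.
#' @return predicted log10 K_M (scalar per input pair).
#' @export
predict_km <- function(bundle, smiles, sequence) {
  predict(bundle, smiles = smiles, sequence = sequence)
}

#' @export
print.kmpred <- function(x, ...) {
  cat("Two-stage K_M model (", toupper(x$encoder_cfg$variant),
      " encoder + gradient boosting)\n", sep = "")
  cat("  records: ", nrow(x$data), "  (", length(x$val_rows),
      " internal validation)\n", sep = "")
  cat("  stage 1: epoch ", x$stage1$selected_epoch, "/",
      x$stage1$cfg$epochs, " selected (val RMSE ",
      signif(min(x$stage1$log$val_rmse), 4), ")\n", sep = "")
  cat("  stage 2: val RMSE ", signif(x$gbm$best_score, 4), " after ",
      nrow(x$gbm$trials), " search trials\n", sep = "")
  invisible(x)
}

#' @export
summary.kmpred <- function(object, ...) {
  structure(list(model = object,
                 metrics = object$metrics,
                 trials = object$gbm$trials,
                 log = object$stage1$log),
            class = "summary.kmpred")
}

#' @export
print.summary.kmpred <- function(x, ...) {
  print(x$model)
  cat("\nValidation metrics (stage-2 predictions):\n")
  print(x$metrics, row.names = FALSE)
  cat("\nStage-1 training log (last epochs):\n")
  print(utils::tail(x$log, 5), row.names = FALSE)
  invisible(x)
}

#' @export
fitted.kmpred <- function(object, ...) {
  feats <- featurize_records(object$data, object$embedder)
  predict(object$gbm, extract_features(object$stage1, feats))
}

#' @export
residuals.kmpred <- function(object, ...) {
  object$data$log10_km - fitted(object)
}

#' Observed-versus-predicted plot for a fitted model
#'
#' @param x a fitted [kmpred()] model.
#' @param newdata optional evaluation records (defaults to the internal
#'   validation split).
#' @param ... passed to [graphics::plot()].
#' @export
plot.kmpred <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    obs <- x$data$log10_km[x$val_rows]
    feats <- featurize_records(x$data[x$val_rows, , drop = FALSE],
                               x$embedder)
    pred <- predict(x$gbm, extract_features(x$stage1, feats))
    lab <- "internal validation"
  } else {
    obs <- newdata$log10_km %||% log10(newdata$km_value)
    pred <- predict(x, newdata)
    lab <- "supplied records"
  }
  graphics::plot(obs, pred, xlab = "observed log10 K_M",
                 ylab = "predicted log10 K_M",
                 main = paste("Observed vs predicted,", lab), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Save / load a fitted model bundle
#'
#' The bundle round-trips through serialization: a reloaded model predicts
#' identically on any probe set.
#'
#' @param object a fitted [kmpred()] model.
#' @param path file path (`.rds`).
#' @export
save_kmpred <- function(object, path) {
  stopifnot(inherits(object, "kmpred"))
  # store the booster as raw bytes so the handle survives any R session
  object$gbm$model_raw <- xgboost::xgb.save.raw(object$gbm$model)
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_kmpred
#' @return `load_kmpred`: the restored `kmpred` object.
#' @export
load_kmpred <- function(path) {
  object <- readRDS(path)
  if (!is.null(object$gbm$model_raw)) {
    object$gbm$model <- xgboost::xgb.load.raw(object$gbm$model_raw)
    object$gbm$model_raw <- NULL
  }
  object
}
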
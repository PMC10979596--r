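#' Run the full training pipeline
#'
#' Curates the raw records, splits them 80/20 into training and test sets,
#' fits the two-stage model on the training set (with its internal validation
#' split), predicts the held-out test set and produces a stratified
#' performance report, together with a reproducibility manifest (config
#' snapshot, seeds, split digest, per-stage timings). Rerunning with the same
#' records and seed reproduces the report exactly.
#'
#' @param records raw records data frame (see [read_kinetic_records()]).
#' @param encoder encoder variant name or [encoder_config()].
#' @param embedder a [protein_embedder()].
#' @param train_cfg a [train_config()].
#' @param gbm_budget stage-2 search budget.
#' @param test_fraction held-out test fraction (default 0.2).
#' @param seed master seed.
#' @param quiet suppress progress output.
#' @return an object of class `kmpred_run`: list with `model` (the fitted
#'   [kmpred()] object), `report` (stratified test-set metrics), `test_pred`,
#'   `split` (train/test indices into the curated records), `clean`,
#'   `rejects`, `manifest`.
#' @export
run_training_pipeline <- function(records,
                                  encoder = c("gat_gcn", "gin", "gcn",
                                              "gat"),
                                  embedder = mock_embedder(),
                                  train_cfg = train_config(),
                                  gbm_budget = 20L, test_fraction = 0.2,
                                  seed = 1L, quiet = TRUE) {
  if (is.character(encoder)) encoder <- encoder_config(match.arg(encoder))
  t0 <- proc.time()[["elapsed"]]
  cur <- curate_records(records)
  t1 <- proc.time()[["elapsed"]]
  split <- split_train_test(nrow(cur$clean), 1 - test_fraction, seed = seed)
  train_data <- cur$clean[split$train, , drop = FALSE]
  test_data <- cur$clean[split$test, , drop = FALSE]

  model <- kmpred(train_data, encoder = encoder, embedder = embedder,
                  train_cfg = train_cfg, gbm_budget = gbm_budget,
                  seed = seed, quiet = quiet)
  t2 <- proc.time()[["elapsed"]]
  test_pred <- predict(model, test_data)
  report <- stratified_report(test_data, test_data$log10_km, test_pred)
  t3 <- proc.time()[["elapsed"]]

  manifest <- list(
    package_version = as.character(utils::packageVersion("kmpred")),
    seed = seed,
    encoder = unclass(encoder),
    train_config = unclass(model$stage1$cfg),
    gbm_budget = gbm_budget,
    embedder = embedder$name,
    d_prot = embedder$dim,
    n_raw = nrow(records), n_clean = nrow(cur$clean),
    n_rejects = nrow(cur$rejects),
    n_train = length(split$train), n_test = length(split$test),
    split_digest = split_digest(split),
    selected_epoch = model$stage1$selected_epoch,
    timings = c(curate = t1 - t0, fit = t2 - t1, evaluate = t3 - t2))

  structure(list(model = model, report = report, test_pred = test_pred,
                 split = split, clean = cur$clean, rejects = cur$rejects,
                 manifest = manifest),
            class = "kmpred_run")
}

#' @export
print.kmpred_run <- function(x, ...) {
  m <- x$manifest
  cat("<kmpred_run> ", m$n_clean, " curated records (", m$n_rejects,
      " quarantined), ", m$n_train, "/", m$n_test, " train/test, encoder ",
      toupper(m$encoder$variant), "\n", sep = "")
  cat("Test-set report:\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Deterministic digest of a train/test split
#'
#' Cheap checksum used in manifests to assert that different runs used the
#' identical partition.
#'
#' @param split list with integer vectors `train` and `test`.
#' @return character digest.
#' @export
split_digest <- function(split) {
  h <- function(v) {
    acc <- 0
    for (x in v) acc <- (acc * 1000003 + x) %% 2147483647
    acc
  }
  sprintf("%d-%d:%d-%d", length(split$train), h(split$train),
          length(split$test), h(split$test))
}

#' Compare encoder variants under an identical protocol
#'
#' Runs the full pipeline once per encoder variant with the same records,
#' split and seeds — only the encoder differs — and tabulates the test-set
#' metrics ranked by RMSE.
#'
#' @param records raw records data frame.
#' @param variants at least two encoder variant names.
#' @param ... passed to [run_training_pipeline()].
#' @return list with `table` (one row per variant: variant, n_test, r2,
#'   rmse, pearson_r, pearson_p, split_digest, ranked by rmse) and `runs`
#'   (the individual `kmpred_run` objects).
#' @export
run_variant_comparison <- function(records,
                                   variants = c("gin", "gcn", "gat",
                                                "gat_gcn"),
                                   ...) {
  if (length(variants) < 2) stop("need at least 2 variants to compare")
  runs <- lapply(variants, function(v)
    run_training_pipeline(records, encoder = v, ...))
  names(runs) <- variants
  rows <- lapply(variants, function(v) {
    r <- runs[[v]]
    all_row <- r$report[r$report$stratum == "all", ]
    data.frame(variant = v, n_test = all_row$n, r2 = all_row$r2,
               rmse = all_row$rmse, pearson_r = all_row$pearson_r,
               pearson_p = all_row$pearson_p,
               split_digest = r$manifest$split_digest,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  table <- table[order(table$rmse), ]
  rownames(table) <- NULL
  list(table = table, runs = runs)
}
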
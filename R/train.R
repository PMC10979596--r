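#' Training configuration for stage 1
#'
#' @param epochs training epochs (default 200).
#' @param batch_size minibatch size (default 128).
#' @param base_lr initial learning rate of the cosine schedule (default 1e-3).
#' @param min_lr final learning rate (default 0).
#' @param anneal_period cosine period in epochs (default `epochs`).
#' @param val_fraction fraction of the training records held out internally
#'   for epoch selection and stage-2 hyperparameter validation (default 0.1).
#' @param dropout dropout rate on the head's hidden layer (default 0.1).
#' @param head_hidden width of the head's hidden layer (default 512).
#' @param loader_workers number of loader workers in the original pipeline's
#'   configuration (default 4); kept for config compatibility — loading here
#'   is in-process and the value never affects results.
#' @param seed integer seed controlling batch order, dropout and
#'   initialization.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 128L, base_lr = 1e-3,
                         min_lr = 0, anneal_period = epochs,
                         val_fraction = 0.1, dropout = 0.1,
                         head_hidden = 512L, loader_workers = 4L,
                         seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, base_lr > 0, min_lr >= 0,
            dropout >= 0, dropout < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 base_lr = base_lr, min_lr = min_lr,
                 anneal_period = as.integer(anneal_period),
                 val_fraction = val_fraction, dropout = dropout,
                 head_hidden = as.integer(head_hidden),
                 loader_workers = as.integer(loader_workers),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine annealing learning-rate schedule
#'
#' `eta(t) = eta_min + (eta_base - eta_min) * (1 + cos(pi * t / T)) / 2`,
#' monotone non-increasing on `[0, T]`: `eta_base` at `t = 0`, the midpoint
#' `(eta_base + eta_min) / 2` at `t = T/2`, and `eta_min` at `t = T`.
#'
#' @param t epoch index, `0 <= t <= T`.
#' @param base_lr,min_lr schedule endpoints. A `train_config` may be passed
#'   as `base_lr`, in which case its fields are used.
#' @param period the period `T` in epochs.
#' @return the learning rate at `t`.
#' @export
cosine_annealing_lr <- function(t, base_lr, min_lr = 0, period = NULL) {
  if (inherits(base_lr, "train_config")) {
    cfg <- base_lr
    base_lr <- cfg$base_lr; min_lr <- cfg$min_lr
    period <- period %||% cfg$anneal_period
  }
  if (is.null(period)) stop("period T must be given")
  if (any(t < 0) || any(t > period))
    stop("epoch index t must lie in [0, ", period, "]")
  min_lr + (base_lr - min_lr) * (1 + cos(pi * t / period)) / 2
}

#' Concatenate substrate and protein representations
#'
#' Fixed concatenation order, substrate block first, no rescaling; with the
#' default 128-d graph embedding and a 1,280-d protein embedding the result
#' is the 1,408-d combined feature vector.
#'
#' @param graph_emb substrate embedding (numeric vector).
#' @param prot_emb protein embedding (numeric vector).
#' @return numeric vector of length `length(graph_emb) + length(prot_emb)`.
#' @export
build_combined_feature <- function(graph_emb, prot_emb) {
  stopifnot(is.numeric(graph_emb), is.numeric(prot_emb))
  c(graph_emb, prot_emb)
}

#' Materialize model inputs for a set of records
#'
#' Converts each record's canonical SMILES to a molecular graph (computed
#' once per unique substrate) and each sequence to a protein embedding
#' (memoised per unique sequence).
#'
#' @param records data frame with `canonical_smiles` (or `smiles`),
#'   `sequence` and, when available, `log10_km`.
#' @param embedder a [protein_embedder()].
#' @return an object of class `kmpred_features`: list with `graphs` (unique
#'   molecular graphs), `graph_index` (per-record index into `graphs`),
#'   `P` (n x d_prot protein-embedding matrix), `y` (labels or `NULL`), `n`.
#' @export
featurize_records <- function(records, embedder) {
  smi <- records$canonical_smiles %||% records$smiles
  if (is.null(smi)) stop("records lack a SMILES column")
  usmi <- unique(smi)
  graphs <- lapply(usmi, smiles_to_graph)
  structure(list(graphs = graphs,
                 graph_index = match(smi, usmi),
                 P = embed_sequences(records$sequence, embedder),
                 y = records$log10_km,
                 n = nrow(records)),
            class = "kmpred_features")
}

# Adam update; state holds m, v, t.
.adam_step <- function(flat, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(flat = flat - lr * mhat / (sqrt(vhat) + eps), state = state)
}

.init_head <- function(d_in, hidden) {
  list(W1 = glorot(d_in, hidden), b1 = numeric(hidden),
       w2 = glorot(hidden, 1L), b2 = 0)
}

# forward/backward through encoder (unique graphs) + head for record rows
.stage1_forward <- function(rows, feats, structures, config, params,
                            dropout_mask = NULL) {
  gidx <- feats$graph_index[rows]
  ug <- unique(gidx)
  fws <- lapply(ug, function(u)
    .encoder_forward(structures[[u]], config, params$encoder))
  G <- do.call(rbind, lapply(fws, `[[`, "out"))
  Z <- cbind(G[match(gidx, ug), , drop = FALSE],
             feats$P[rows, , drop = FALSE])
  U1 <- sweep(Z %*% params$head$W1, 2, params$head$b1, "+")
  H1 <- relu(U1)
  H1d <- if (is.null(dropout_mask)) H1 else H1 * dropout_mask
  yhat <- drop(H1d %*% params$head$w2) + params$head$b2
  list(yhat = yhat, Z = Z, U1 = U1, H1 = H1, H1d = H1d,
       fws = fws, ug = ug, gidx = gidx)
}

.stage1_backward <- function(dyhat, fw, feats, structures, config, params,
                             dropout_mask = NULL) {
  head <- params$head
  dH1d <- outer(dyhat, drop(head$w2))
  dH1 <- if (is.null(dropout_mask)) dH1d else dH1d * dropout_mask
  dU1 <- dH1 * relu_grad(fw$U1)
  dZ <- dU1 %*% t(head$W1)
  d_emb <- ncol(dZ) - ncol(feats$P)
  dG_rows <- dZ[, seq_len(d_emb), drop = FALSE]
  enc_grads <- NULL
  for (j in seq_along(fw$ug)) {
    dg <- colSums(dG_rows[fw$gidx == fw$ug[j], , drop = FALSE])
    g <- .encoder_backward(dg, fw$fws[[j]], structures[[fw$ug[j]]],
                           config, params$encoder)
    enc_grads <- if (is.null(enc_grads)) g else {
      fe <- flatten_params(enc_grads) + flatten_params(g)
      unflatten_params(fe, g)
    }
  }
  list(encoder = enc_grads,
       head = list(W1 = crossprod(fw$Z, dU1), b1 = colSums(dU1),
                   w2 = crossprod(fw$H1d, cbind(dyhat)),
                   b2 = sum(dyhat)))
}

.stage1_rmse <- function(rows, feats, structures, config, params) {
  fw <- .stage1_forward(rows, feats, structures, config, params)
  sqrt(mean((fw$yhat - feats$y[rows])^2))
}

#' Train the stage-1 model (graph encoder + two-layer head) end to end
#'
#' Minimizes mean squared error on log10 K_M with Adam under a cosine
#' annealing learning-rate schedule; the returned parameters are those of the
#' epoch with minimal validation RMSE ("best checkpoint"). Fully reproducible
#' under the config seed.
#'
#' @param feats training features from [featurize_records()] (labels
#'   required).
#' @param val_rows indices (into the feature rows) of the internal
#'   validation split used for epoch selection; the remaining rows are the
#'   gradient-descent training rows.
#' @param encoder_cfg an [encoder_config()].
#' @param cfg a [train_config()].
#' @param quiet suppress per-epoch progress.
#' @return list with `params` (parameters at the selected epoch), `log`
#'   (per-epoch data frame: epoch, lr, train_rmse, val_rmse),
#'   `selected_epoch`, `encoder_cfg`, `cfg`.
#' @export
train_stage1 <- function(feats, val_rows, encoder_cfg, cfg = train_config(),
                         quiet = TRUE) {
  stopifnot(inherits(feats, "kmpred_features"), !is.null(feats$y))
  if (!length(val_rows)) stop("empty validation set")
  train_rows <- setdiff(seq_len(feats$n), val_rows)
  if (!length(train_rows)) stop("empty training set")
  structures <- lapply(feats$graphs, .graph_structure, config = encoder_cfg)
  d_comb <- encoder_cfg$output_dim + ncol(feats$P)

  with_local_seed(cfg$seed, {
    params <- list(encoder = init_encoder_params(encoder_cfg,
                                                 seed = cfg$seed),
                   head = .init_head(d_comb, cfg$head_hidden))
    flat <- flatten_params(params)
    state <- list(m = numeric(length(flat)), v = numeric(length(flat)),
                  t = 0L)
    log <- data.frame(epoch = integer(), lr = numeric(),
                      train_rmse = numeric(), val_rmse = numeric())
    best <- list(val = Inf, flat = flat, epoch = 0L)

    for (epoch in seq_len(cfg$epochs)) {
      lr <- cosine_annealing_lr(epoch - 1L, cfg$base_lr, cfg$min_lr,
                                cfg$anneal_period)
      order_ <- sample(train_rows)
      batches <- split(order_, ceiling(seq_along(order_) / cfg$batch_size))
      sse <- 0
      for (b in batches) {
        params <- unflatten_params(flat, params)
        mask <- NULL
        if (cfg$dropout > 0)
          mask <- matrix(stats::rbinom(length(b) * cfg$head_hidden, 1,
                                       1 - cfg$dropout),
                         length(b), cfg$head_hidden) / (1 - cfg$dropout)
        fw <- .stage1_forward(b, feats, structures, encoder_cfg, params,
                              mask)
        resid <- fw$yhat - feats$y[b]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch, ", batch of size ",
               length(b))
        sse <- sse + sum(resid^2)
        bw <- .stage1_backward(2 * resid / length(b), fw, feats,
                               structures, encoder_cfg, params, mask)
        upd <- .adam_step(flat, flatten_params(bw), state, lr)
        flat <- upd$flat
        state <- upd$state
      }
      params <- unflatten_params(flat, params)
      val_rmse <- .stage1_rmse(val_rows, feats, structures, encoder_cfg,
                               params)
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   train_rmse = sqrt(sse /
                                                       length(train_rows)),
                                   val_rmse = val_rmse))
      if (val_rmse < best$val)
        best <- list(val = val_rmse, flat = flat, epoch = epoch)
      if (!quiet)
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                        epoch, lr, log$train_rmse[epoch], val_rmse))
    }
    list(params = unflatten_params(best$flat, params), log = log,
         selected_epoch = best$epoch, encoder_cfg = encoder_cfg, cfg = cfg)
  })
}

#' Extract combined features with a trained stage-1 model
#'
#' Substrate block = trained (selected-epoch) encoder output; protein block =
#' embedder output; one row per record, order preserved.
#'
#' @param stage1 result of [train_stage1()].
#' @param feats features from [featurize_records()].
#' @return numeric matrix, n x (output_dim + d_prot).
#' @export
extract_features <- function(stage1, feats) {
  structures <- lapply(feats$graphs, .graph_structure,
                       config = stage1$encoder_cfg)
  G <- do.call(rbind, lapply(structures, function(st)
    .encoder_forward(st, stage1$encoder_cfg, stage1$params$encoder)$out))
  cbind(G[feats$graph_index, , drop = FALSE], feats$P)
}
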
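ENCODER_VARIANTS <- c("gin", "gcn", "gat", "gat_gcn")

#' Encoder configuration
#'
#' Describes one of the four interchangeable message-passing encoders that
#' map a molecular graph to a fixed-length substrate embedding (128-d by
#' default, the dimension concatenated with the protein representation into
#' the combined feature vector).
#'
#' @param variant `"gin"`, `"gcn"`, `"gat"` or `"gat_gcn"` (two attention
#'   layers followed by one convolution layer).
#' @param n_layers number of message-passing layers (default 3; for
#'   `gat_gcn` the last layer is the GCN layer).
#' @param hidden_dim hidden width (default 128).
#' @param output_dim graph-embedding dimension (default 128).
#' @param input_dim per-atom feature dimension (default [atom_feature_dim()]).
#' @param gat_heads attention heads for GAT layers (default 4; must divide
#'   `hidden_dim` for concatenating layers).
#' @param gin_epsilon the GIN self-weight epsilon in
#'   `(1 + eps) * h_v + sum of neighbor states` (default 0).
#' @param gin_learn_epsilon treat epsilon as a trainable parameter.
#' @param readout graph-level pooling: `"mean"`, `"sum"` or
#'   `"max_concat_mean"` (elementwise max concatenated with mean, then
#'   projected to `output_dim`). Defaults: sum for GIN (the aggregation its
#'   originating architecture uses graph-level as well, and the only mode
#'   that can represent extensive quantities such as atom counts), mean for
#'   GCN/GAT, max‖mean for GAT-GCN.
#' @param leaky_slope negative slope of the LeakyReLU on attention logits.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(variant = c("gin", "gcn", "gat", "gat_gcn"),
                           n_layers = 3L, hidden_dim = 128L,
                           output_dim = 128L,
                           input_dim = atom_feature_dim(),
                           gat_heads = 4L, gin_epsilon = 0,
                           gin_learn_epsilon = FALSE,
                           readout = NULL, leaky_slope = 0.2) {
  variant <- match.arg(variant)
  if (n_layers < 1L) stop("n_layers must be >= 1")
  readout <- readout %||% switch(variant,
    gin = "sum", gcn = "mean", gat = "mean", gat_gcn = "max_concat_mean")
  readout <- match.arg(readout, c("mean", "sum", "max_concat_mean"))
  if (variant %in% c("gat", "gat_gcn") && hidden_dim %% gat_heads != 0L)
    stop("hidden_dim must be divisible by gat_heads")
  structure(list(variant = variant, n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 output_dim = as.integer(output_dim),
                 input_dim = as.integer(input_dim),
                 gat_heads = as.integer(gat_heads),
                 gin_epsilon = gin_epsilon,
                 gin_learn_epsilon = isTRUE(gin_learn_epsilon),
                 readout = readout, leaky_slope = leaky_slope),
            class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat("<encoder_config> ", toupper(x$variant), ": ", x$n_layers, " layers, ",
      "hidden ", x$hidden_dim, " -> ", x$output_dim, "-d embedding, ",
      "readout ", x$readout, "\n", sep = "")
  invisible(x)
}

# layer kind sequence for a config
.layer_kinds <- function(config) {
  switch(config$variant,
    gin = rep("gin", config$n_layers),
    gcn = rep("gcn", config$n_layers),
    gat = rep("gat", config$n_layers),
    gat_gcn = c(rep("gat", max(config$n_layers - 1L, 1L)), "gcn"))
}

# --- graph structure helpers -------------------------------------------------

# dense adjacency (no self loops)
.adjacency <- function(n, edges) {
  A <- matrix(0, n, n)
  if (nrow(edges)) A[edges] <- 1
  A
}

# symmetric-normalized adjacency with self loops:
# D^{-1/2} (A + I) D^{-1/2}
.gcn_propagation <- function(n, edges) {
  At <- .adjacency(n, edges) + diag(n)
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

# edge arrays with self loops for attention layers
.gat_edges <- function(n, edges) {
  src <- c(edges[, 1], seq_len(n))
  dst <- c(edges[, 2], seq_len(n))
  list(src = src, dst = dst)
}

.check_edges <- function(H, edges) {
  if (!is.matrix(H)) stop("H must be a matrix of node states")
  if (nrow(edges) && (min(edges) < 1 || max(edges) > nrow(H)))
    stop("edge endpoints outside [1, n_atoms]")
}

# --- exported layer primitives ----------------------------------------------

#' Graph-convolution layer
#'
#' One GCN update: `act(D^{-1/2} (A + I) D^{-1/2} H W + b)` with symmetric
#' degree normalization over the self-loop-augmented adjacency.
#'
#' @param H n x d matrix of node states.
#' @param edges directed 2-column edge matrix (both directions per bond; do
#'   not include self loops, they are added once here).
#' @param W d x d' weight matrix.
#' @param b optional length-d' bias.
#' @param activation activation function (default identity).
#' @return n x d' matrix of updated node states.
#' @export
gcn_layer <- function(H, edges, W, b = NULL, activation = identity) {
  .check_edges(H, edges)
  if (ncol(H) != nrow(W)) stop("dimension mismatch: ncol(H) != nrow(W)")
  Z <- .gcn_propagation(nrow(H), edges) %*% H %*% W
  if (!is.null(b)) Z <- sweep(Z, 2, b, "+")
  activation(Z)
}

#' Graph-isomorphism layer
#'
#' One GIN update: `mlp((1 + epsilon) * h_v + sum over neighbors u of h_u)`.
#' Aggregation is the neighbor sum, not the mean.
#'
#' @param H n x d matrix of node states.
#' @param edges directed 2-column edge matrix.
#' @param epsilon self-weight (default 0).
#' @param mlp function applied to the aggregated matrix (default identity).
#' @return the updated node-state matrix.
#' @export
gin_layer <- function(H, edges, epsilon = 0, mlp = identity) {
  .check_edges(H, edges)
  mlp((1 + epsilon) * H + .adjacency(nrow(H), edges) %*% H)
}

#' Graph-attention layer
#'
#' Multi-head attention update: per head, `z = H W`, logits
#' `e_ij = LeakyReLU(a_dst . z_i + a_src . z_j)` over the self-loop-augmented
#' neighborhood of each node i, attention `alpha_ij = softmax_j(e_ij)`
#' (rows sum to 1), update `h'_i = sum_j alpha_ij z_j`. Head outputs are
#' concatenated (`concat = TRUE`, hidden layers) or averaged (final layer).
#' Self loops are always added, so the softmax is defined for every node.
#'
#' @param H n x d matrix of node states.
#' @param edges directed 2-column edge matrix (self loops added internally).
#' @param W d x (heads * d_head) weight matrix.
#' @param a_src,a_dst d_head x heads attention vectors (the two halves of the
#'   classical concatenated attention vector `a`).
#' @param heads number of attention heads.
#' @param concat concatenate head outputs (else average).
#' @param leaky_slope LeakyReLU negative slope for the logits.
#' @param activation activation applied to the combined output.
#' @param return_attention also return the per-head attention coefficients.
#' @return updated node-state matrix, or (with `return_attention`) a list
#'   with `out` and `attention` (list of per-head data frames with `src`,
#'   `dst`, `alpha`).
#' @export
gat_layer <- function(H, edges, W, a_src, a_dst, heads = 1L, concat = TRUE,
                      leaky_slope = 0.2, activation = identity,
                      return_attention = FALSE) {
  .check_edges(H, edges)
  fw <- .gat_forward(H, .gat_edges(nrow(H), edges), W,
                     as.matrix(a_src), as.matrix(a_dst), heads, concat,
                     leaky_slope)
  out <- activation(fw$U)
  if (!return_attention) return(out)
  ea <- .gat_edges(nrow(H), edges)
  att <- lapply(seq_len(heads), function(k)
    data.frame(src = ea$src, dst = ea$dst, alpha = fw$alpha[, k]))
  list(out = out, attention = att)
}

#' Graph-level readout
#'
#' Permutation-invariant pooling of node states to one vector: elementwise
#' `mean`, `sum`, or `max_concat_mean` (max concatenated with mean; dimension
#' doubles and is projected back to the embedding size inside
#' [encode_graph()]).
#'
#' @param H n x d matrix of node states (n >= 1).
#' @param mode pooling mode.
#' @return numeric vector of length d (or 2d for `max_concat_mean`).
#' @export
graph_readout <- function(H, mode = c("mean", "sum", "max_concat_mean")) {
  mode <- match.arg(mode)
  if (!is.matrix(H) || nrow(H) == 0L) stop("readout of an empty graph")
  switch(mode,
    mean = colMeans(H),
    sum = colSums(H),
    max_concat_mean = c(apply(H, 2, max), colMeans(H)))
}

# --- parameter initialization ------------------------------------------------

#' Initialize encoder parameters
#'
#' Glorot-uniform weights, zero biases; reproducible under `seed`.
#'
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @return nested list of parameter arrays (one entry per layer plus the
#'   final projection).
#' @export
init_encoder_params <- function(config, seed = 1L) {
  kinds <- .layer_kinds(config)
  hd <- config$hidden_dim
  with_local_seed(seed, {
    layers <- vector("list", length(kinds))
    din <- config$input_dim
    for (l in seq_along(kinds)) {
      kind <- kinds[l]
      if (kind == "gcn") {
        layers[[l]] <- list(W = glorot(din, hd), b = numeric(hd))
      } else if (kind == "gin") {
        layers[[l]] <- list(W1 = glorot(din, hd), b1 = numeric(hd),
                            W2 = glorot(hd, hd), b2 = numeric(hd))
        if (config$gin_learn_epsilon)
          layers[[l]]$eps <- config$gin_epsilon
      } else { # gat
        final_gat <- (config$variant == "gat" && l == length(kinds))
        dh <- if (final_gat) hd else hd %/% config$gat_heads
        K <- config$gat_heads
        layers[[l]] <- list(W = glorot(din, K * dh),
                            a_src = glorot(dh, K), a_dst = glorot(dh, K),
                            b = numeric(if (final_gat) hd else K * dh))
      }
      din <- hd
    }
    pool_dim <- if (config$readout == "max_concat_mean") 2L * hd else hd
    list(layers = layers,
         proj = list(W = glorot(pool_dim, config$output_dim),
                     b = numeric(config$output_dim)))
  })
}

# --- internal forward/backward -----------------------------------------------

.gcn_forward <- function(H, P, W, b) {
  PH <- P %*% H
  Z <- sweep(PH %*% W, 2, b, "+")
  list(out = relu(Z), cache = list(H = H, P = P, PH = PH, Z = Z))
}

.gcn_backward <- function(dout, cache, W) {
  dZ <- dout * relu_grad(cache$Z)
  list(grads = list(W = crossprod(cache$PH, dZ), b = colSums(dZ)),
       dH = t(cache$P) %*% (dZ %*% t(W)))
}

.gin_forward <- function(H, A, par, eps) {
  M <- (1 + eps) * H + A %*% H
  U1 <- sweep(M %*% par$W1, 2, par$b1, "+")
  H1 <- relu(U1)
  U2 <- sweep(H1 %*% par$W2, 2, par$b2, "+")
  list(out = relu(U2),
       cache = list(H = H, A = A, M = M, U1 = U1, H1 = H1, U2 = U2,
                    eps = eps))
}

.gin_backward <- function(dout, cache, par, learn_eps) {
  dU2 <- dout * relu_grad(cache$U2)
  dH1 <- dU2 %*% t(par$W2)
  dU1 <- dH1 * relu_grad(cache$U1)
  dM <- dU1 %*% t(par$W1)
  grads <- list(W1 = crossprod(cache$M, dU1), b1 = colSums(dU1),
                W2 = crossprod(cache$H1, dU2), b2 = colSums(dU2))
  if (learn_eps) grads$eps <- sum(dM * cache$H)
  list(grads = grads,
       dH = (1 + cache$eps) * dM + t(cache$A) %*% dM)
}

# ea: list(src, dst) with self loops; W: din x (K*dh); a_src/a_dst: dh x K
.gat_forward <- function(H, ea, W, a_src, a_dst, heads, concat,
                         leaky_slope) {
  n <- nrow(H)
  dh <- ncol(W) %/% heads
  ne <- length(ea$src)
  Zs <- vector("list", heads)
  alpha <- matrix(0, ne, heads)
  logits <- matrix(0, ne, heads)
  Uh <- vector("list", heads)
  for (k in seq_len(heads)) {
    cols <- ((k - 1L) * dh + 1L):(k * dh)
    Z <- H %*% W[, cols, drop = FALSE]
    s <- drop(Z %*% a_src[, k])
    t_ <- drop(Z %*% a_dst[, k])
    lg <- t_[ea$dst] + s[ea$src]
    lr <- leaky_relu(lg, leaky_slope)
    # per-destination softmax, stabilized (self loops ensure every node
    # appears as a destination)
    mx_per <- tapply(lr, ea$dst, max)
    mx <- numeric(n)
    mx[as.integer(names(mx_per))] <- mx_per
    ex <- exp(lr - mx[ea$dst])
    den <- drop(rowsum_by(cbind(ex), ea$dst, n))
    al <- ex / den[ea$dst]
    U <- rowsum_by(al * Z[ea$src, , drop = FALSE], ea$dst, n)
    Zs[[k]] <- Z; alpha[, k] <- al; logits[, k] <- lg; Uh[[k]] <- U
  }
  U <- if (concat) do.call(cbind, Uh) else Reduce(`+`, Uh) / heads
  list(U = U, alpha = alpha,
       cache = list(H = H, ea = ea, Zs = Zs, alpha = alpha, logits = logits,
                    heads = heads, dh = dh, concat = concat,
                    leaky_slope = leaky_slope))
}

# full GAT layer with bias + relu wrapper
.gat_layer_forward <- function(H, ea, par, heads, concat, leaky_slope) {
  fw <- .gat_forward(H, ea, par$W, par$a_src, par$a_dst, heads, concat,
                     leaky_slope)
  V <- sweep(fw$U, 2, par$b, "+")
  list(out = relu(V), cache = c(fw$cache, list(V = V)))
}

.gat_layer_backward <- function(dout, cache, par) {
  dV <- dout * relu_grad(cache$V)
  n <- nrow(cache$H)
  heads <- cache$heads
  dh <- cache$dh
  ea <- cache$ea
  dW <- matrix(0, nrow(par$W), ncol(par$W))
  da_src <- matrix(0, dh, heads)
  da_dst <- matrix(0, dh, heads)
  dH <- matrix(0, n, ncol(cache$H))
  for (k in seq_len(heads)) {
    cols <- ((k - 1L) * dh + 1L):(k * dh)
    dU <- if (cache$concat) dV[, cols, drop = FALSE] else dV / heads
    Z <- cache$Zs[[k]]
    al <- cache$alpha[, k]
    # dU flows into alpha and Z through U_i = sum_e alpha_e Z[src_e,]
    dU_dst <- dU[ea$dst, , drop = FALSE]
    dal <- rowSums(dU_dst * Z[ea$src, , drop = FALSE])
    dZ <- rowsum_by(al * dU_dst, ea$src, n)
    # softmax backward per destination
    S <- drop(rowsum_by(cbind(al * dal), ea$dst, n))
    dlr <- al * (dal - S[ea$dst])
    dlg <- dlr * leaky_relu_grad(cache$logits[, k], cache$leaky_slope)
    ds <- drop(rowsum_by(cbind(dlg), ea$src, n))
    dt <- drop(rowsum_by(cbind(dlg), ea$dst, n))
    da_src[, k] <- drop(crossprod(Z, ds))
    da_dst[, k] <- drop(crossprod(Z, dt))
    dZ <- dZ + outer(ds, par$a_src[, k]) + outer(dt, par$a_dst[, k])
    dW[, cols] <- crossprod(cache$H, dZ)
    dH <- dH + dZ %*% t(par$W[, cols, drop = FALSE])
  }
  list(grads = list(W = dW, a_src = da_src, a_dst = da_dst,
                    b = colSums(dV)),
       dH = dH)
}

.readout_forward <- function(H, mode) {
  r <- graph_readout(H, mode)
  cache <- list(n = nrow(H), d = ncol(H), mode = mode)
  if (mode == "max_concat_mean")
    cache$argmax <- apply(H, 2, which.max)
  list(r = r, cache = cache)
}

.readout_backward <- function(dr, cache) {
  n <- cache$n; d <- cache$d
  switch(cache$mode,
    mean = matrix(dr, n, d, byrow = TRUE) / n,
    sum = matrix(dr, n, d, byrow = TRUE),
    max_concat_mean = {
      dH <- matrix(dr[(d + 1):(2 * d)], n, d, byrow = TRUE) / n
      for (j in seq_len(d))
        dH[cache$argmax[j], j] <- dH[cache$argmax[j], j] + dr[j]
      dH
    })
}

# precomputed message-passing structure for one graph
.graph_structure <- function(graph, config) {
  kinds <- .layer_kinds(config)
  st <- list(X = graph$node_features, n = graph$n_atoms)
  if ("gcn" %in% kinds) st$P <- .gcn_propagation(graph$n_atoms, graph$edges)
  if ("gin" %in% kinds) st$A <- .adjacency(graph$n_atoms, graph$edges)
  if ("gat" %in% kinds) st$ea <- .gat_edges(graph$n_atoms, graph$edges)
  st
}

.encoder_forward <- function(st, config, params) {
  kinds <- .layer_kinds(config)
  H <- st$X
  caches <- vector("list", length(kinds))
  for (l in seq_along(kinds)) {
    par <- params$layers[[l]]
    if (kinds[l] == "gcn") {
      fw <- .gcn_forward(H, st$P, par$W, par$b)
    } else if (kinds[l] == "gin") {
      eps <- if (config$gin_learn_epsilon) par$eps else config$gin_epsilon
      fw <- .gin_forward(H, st$A, par, eps)
    } else {
      final_gat <- (config$variant == "gat" && l == length(kinds))
      fw <- .gat_layer_forward(H, st$ea, par, config$gat_heads,
                               concat = !final_gat, config$leaky_slope)
    }
    H <- fw$out
    caches[[l]] <- fw$cache
  }
  ro <- .readout_forward(H, config$readout)
  out <- drop(rbind(ro$r) %*% params$proj$W) + params$proj$b
  list(out = out, caches = caches, ro_cache = ro$cache, r = ro$r)
}

.encoder_backward <- function(dout, fw, st, config, params) {
  kinds <- .layer_kinds(config)
  grads <- list(layers = vector("list", length(kinds)),
                proj = list(W = outer(fw$r, dout), b = dout))
  dr <- drop(params$proj$W %*% dout)
  dH <- .readout_backward(dr, fw$ro_cache)
  for (l in rev(seq_along(kinds))) {
    par <- params$layers[[l]]
    if (kinds[l] == "gcn") {
      bw <- .gcn_backward(dH, fw$caches[[l]], par$W)
    } else if (kinds[l] == "gin") {
      bw <- .gin_backward(dH, fw$caches[[l]], par, config$gin_learn_epsilon)
    } else {
      bw <- .gat_layer_backward(dH, fw$caches[[l]], par)
    }
    grads$layers[[l]] <- bw$grads
    dH <- bw$dH
  }
  grads
}

#' Encode a molecular graph
#'
#' Runs the configured message-passing encoder and graph-level readout,
#' returning the substrate embedding (length `config$output_dim`, 128 by
#' default). The embedding is invariant to node permutation.
#'
#' @param graph a `molgraph` from [smiles_to_graph()].
#' @param config an [encoder_config()].
#' @param params parameters from [init_encoder_params()] (initialized with
#'   `seed` when omitted).
#' @param seed seed for the default initialization.
#' @return numeric vector of length `config$output_dim`.
#' @export
encode_graph <- function(graph, config, params = NULL, seed = 1L) {
  stopifnot(inherits(graph, "molgraph"), inherits(config, "encoder_config"))
  if (ncol(graph$node_features) != config$input_dim)
    stop("graph feature dimension ", ncol(graph$node_features),
         " does not match config input_dim ", config$input_dim)
  params <- params %||% init_encoder_params(config, seed)
  .encoder_forward(.graph_structure(graph, config), config, params)$out
}
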
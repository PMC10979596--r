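test_that("GCN layer matches the normalized-adjacency closed form", {
  # single node, no edges, identity weights: output = input
  H <- matrix(c(2, -1), 1, 2)
  expect_equal(gcn_layer(H, matrix(integer(0), 0, 2), diag(2)), H)

  # two connected nodes, scalar states (1, 3), W = 1:
  # A~ all-ones, degrees 2 -> normalized adjacency all 1/2 -> (2, 2)
  H <- matrix(c(1, 3), 2, 1)
  e <- rbind(c(1L, 2L), c(2L, 1L))
  expect_equal(drop(gcn_layer(H, e, matrix(1))), c(2, 2))

  # structurally symmetric nodes with equal features get equal outputs
  H <- matrix(rep(c(1, 5), 3), 3, 2, byrow = TRUE)
  path <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L))
  out <- gcn_layer(H, path, matrix(rnorm(4), 2, 2))
  expect_equal(out[1, ], out[3, ])

  # dense closed form D^{-1/2}(A+I)D^{-1/2} H W on random toy graphs
  set.seed(21)
  for (n in 2:6) {
    g <- make_random_graph(n, extra_edges = 1L, d = 3)
    H <- matrix(rnorm(n * 3), n, 3)
    W <- matrix(rnorm(6), 3, 2)
    A <- matrix(0, n, n); A[g$edges] <- 1
    At <- A + diag(n)
    Dm <- diag(1 / sqrt(rowSums(At)))
    expect_equal(gcn_layer(H, g$edges, W), Dm %*% At %*% Dm %*% H %*% W,
                 tolerance = 1e-10)
  }
})

test_that("GIN layer sums neighbors with the (1+eps) self-weight", {
  none <- matrix(integer(0), 0, 2)
  H <- matrix(4)
  expect_equal(gin_layer(H, none, epsilon = 0), H)  # isolated node

  H <- matrix(c(1, 3), 2, 1)
  e <- rbind(c(1L, 2L), c(2L, 1L))
  expect_equal(drop(gin_layer(H, e, epsilon = 0)), c(4, 4))
  expect_equal(drop(gin_layer(H, e, epsilon = 1)), c(5, 7))
  # aggregation is a sum, not a mean: star graph center gets all leaves
  star <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 3L), c(3L, 1L))
  H3 <- matrix(c(1, 1, 1), 3, 1)
  expect_equal(drop(gin_layer(H3, star, 0))[1], 3)
  # mlp hook applies after aggregation
  expect_equal(drop(gin_layer(H, e, 0, mlp = function(m) 2 * m)), c(8, 8))
})

test_that("GAT attention is a proper softmax over the neighborhood", {
  set.seed(31)
  # identical node states give uniform attention
  n <- 4
  H <- matrix(rep(c(1, 2), n), n, 2, byrow = TRUE)
  und <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  e <- rbind(und, und[, 2:1])
  W <- matrix(rnorm(4), 2, 2)
  res <- gat_layer(H, e, W, a_src = matrix(rnorm(2)),
                   a_dst = matrix(rnorm(2)), heads = 1,
                   return_attention = TRUE)
  att <- res$attention[[1]]
  for (i in seq_len(n)) {
    al <- att$alpha[att$dst == i]
    expect_equal(al, rep(1 / length(al), length(al)))  # uniform
  }
  # rows sum to 1 on a random graph with random states
  g <- make_random_graph(7, extra_edges = 3L, d = 5)
  H <- matrix(rnorm(35), 7, 5)
  res <- gat_layer(H, g$edges, matrix(rnorm(20), 5, 4),
                   a_src = matrix(rnorm(8), 2, 4),
                   a_dst = matrix(rnorm(8), 2, 4),
                   heads = 2, return_attention = TRUE)
  for (att in res$attention) {
    sums <- tapply(att$alpha, att$dst, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
})

test_that("GAT layer matches a direct formula evaluation on a 3-node path", {
  # hand-set weights, single head; oracle evaluates e_ij, alpha, h' directly
  H <- matrix(c(1, 0,
                0, 2,
                1, 1), 3, 2, byrow = TRUE)
  und <- rbind(c(1L, 2L), c(2L, 3L))
  e <- rbind(und, und[, 2:1])
  W <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  a_src <- matrix(c(0.7, -0.4), 2, 1)
  a_dst <- matrix(c(0.2, 0.6), 2, 1)
  got <- gat_layer(H, e, W, a_src, a_dst, heads = 1)

  Z <- H %*% W
  nbr <- list(c(2L, 1L), c(1L, 3L, 2L), c(2L, 3L))  # self loops included
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  oracle <- matrix(0, 3, 2)
  for (i in 1:3) {
    logits <- vapply(nbr[[i]], function(j)
      lrelu(sum(a_dst * Z[i, ]) + sum(a_src * Z[j, ])), 0)
    alpha <- exp(logits) / sum(exp(logits))
    oracle[i, ] <- colSums(alpha * Z[nbr[[i]], , drop = FALSE])
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("readout modes equal their brute-force definitions", {
  set.seed(41)
  H <- matrix(rnorm(15), 5, 3)
  expect_equal(graph_readout(H, "mean"), colMeans(H))
  expect_equal(graph_readout(H, "sum"), colSums(H))
  mx <- vapply(1:3, function(j) max(H[, j]), 0)
  expect_equal(graph_readout(H, "max_concat_mean"), c(mx, colMeans(H)))
  # all nodes equal v: mean readout = v; single node: readout = that state
  v <- c(1, -2, 3)
  expect_equal(graph_readout(matrix(v, 4, 3, byrow = TRUE), "mean"), v)
  expect_equal(graph_readout(matrix(v, 1, 3, byrow = TRUE), "mean"), v)
  expect_error(graph_readout(matrix(0, 0, 3), "mean"), "empty")
})

test_that("graph encoding produces 128-d permutation-invariant embeddings", {
  set.seed(51)
  g <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O")
  for (v in c("gin", "gcn", "gat", "gat_gcn")) {
    cfg <- encoder_config(v)
    emb <- encode_graph(g, cfg, seed = 5)
    expect_length(emb, 128L)
    expect_true(all(is.finite(emb)))
  }
  # permuting the node order of ethanol leaves the embedding unchanged
  g <- smiles_to_graph("CCO")
  for (v in c("gin", "gcn", "gat", "gat_gcn")) {
    cfg <- encoder_config(v, hidden_dim = 16, gat_heads = 2)
    p <- init_encoder_params(cfg, seed = 6)
    perm <- c(3L, 1L, 2L)
    expect_equal(encode_graph(g, cfg, p),
                 encode_graph(permute_graph(g, perm), cfg, p),
                 tolerance = 1e-6)
  }
  expect_error(encoder_config("transformer"), "arg")
})

test_that("GIN encoding equals a manual layer-by-layer composition", {
  set.seed(61)
  g <- make_random_graph(3, extra_edges = 0L)
  cfg <- encoder_config("gin", n_layers = 2, hidden_dim = 8,
                        output_dim = 4)
  p <- init_encoder_params(cfg, seed = 9)
  got <- encode_graph(g, cfg, p)

  relu0 <- function(x) pmax(x, 0)
  H <- g$node_features
  for (l in 1:2) {
    par <- p$layers[[l]]
    mlp <- function(M) relu0(sweep(relu0(sweep(M %*% par$W1, 2, par$b1,
                                               "+")) %*% par$W2,
                                   2, par$b2, "+"))
    H <- gin_layer(H, g$edges, epsilon = 0, mlp = mlp)
  }
  oracle <- drop(rbind(graph_readout(H, "sum")) %*% p$proj$W) + p$proj$b
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences for all variants", {
  set.seed(71)
  g <- smiles_to_graph("CCOc1ccccc1")
  for (v in c("gin", "gcn", "gat", "gat_gcn")) {
    cfg <- encoder_config(v, hidden_dim = 8, output_dim = 5, gat_heads = 2,
                          gin_learn_epsilon = (v == "gin"))
    p <- init_encoder_params(cfg, seed = 11)
    st <- kmpred:::.graph_structure(g, cfg)
    w <- runif(5)
    lossf <- function(flat) {
      pp <- kmpred:::unflatten_params(flat, p)
      sum(w * kmpred:::.encoder_forward(st, cfg, pp)$out)
    }
    flat <- kmpred:::flatten_params(p)
    fw <- kmpred:::.encoder_forward(st, cfg, p)
    ga <- kmpred:::flatten_params(
      kmpred:::.encoder_backward(w, fw, st, cfg, p))
    idx <- sort(sample(length(flat), 40))
    h <- 1e-6
    gn <- vapply(idx, function(i) {
      e1 <- flat; e1[i] <- e1[i] + h
      e0 <- flat; e0[i] <- e0[i] - h
      (lossf(e1) - lossf(e0)) / (2 * h)
    }, 0)
    expect_lt(max(abs(ga[idx] - gn)), 1e-6)
  }
})

test_that("graphs encoded in a batch match one-at-a-time encoding", {
  # messages must not leak across graphs: the stage-1 forward pass over a
  # batch of records reproduces per-record encoder outputs exactly
  clean <- tiny_dataset(n = 20, seed = 13)
  emb <- mock_embedder(64L)
  feats <- featurize_records(clean, emb)
  cfg <- encoder_config("gin", hidden_dim = 16, output_dim = 8)
  p <- list(encoder = init_encoder_params(cfg, seed = 2),
            head = kmpred:::.init_head(8 + 64, 16))
  structures <- lapply(feats$graphs, kmpred:::.graph_structure, config = cfg)
  fw_all <- kmpred:::.stage1_forward(seq_len(feats$n), feats, structures,
                                     cfg, p)
  for (i in c(1L, 7L, feats$n)) {
    fw_one <- kmpred:::.stage1_forward(i, feats, structures, cfg, p)
    expect_equal(fw_one$yhat, fw_all$yhat[i], tolerance = 1e-12)
  }
})
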
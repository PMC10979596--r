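# Random connected molecular-graph-like structures for encoder tests:
# a random spanning tree plus a few extra edges, with random binary node
# features of the standard atom-feature dimension.
make_random_graph <- function(n_nodes, extra_edges = 2L,
                              d = atom_feature_dim()) {
  und <- matrix(0L, 0, 2)
  if (n_nodes > 1) {
    parents <- vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), 0L)
    und <- cbind(parents, 2:n_nodes)
    for (k in seq_len(extra_edges)) {
      uv <- sort(sample.int(n_nodes, 2L))
      und <- rbind(und, uv)
    }
    und <- unique(und)
  }
  edges <- rbind(und, und[, 2:1, drop = FALSE])
  storage.mode(edges) <- "integer"
  structure(list(
    n_atoms = n_nodes,
    node_features = matrix(rbinom(n_nodes * d, 1, 0.3), n_nodes, d),
    edges = edges,
    aromatic = rep(FALSE, n_nodes),
    smiles = NA_character_),
    class = "molgraph")
}

# Relabel graph nodes by a permutation (perm[i] = new index of old node i).
permute_graph <- function(g, perm) {
  inv <- order(perm)   # old index of each new node
  g2 <- g
  g2$node_features <- g$node_features[inv, , drop = FALSE]
  if (nrow(g$edges))
    g2$edges <- cbind(perm[g$edges[, 1]], perm[g$edges[, 2]])
  g2
}

# A tiny curated-record table with a learnable label, for fast model tests.
tiny_dataset <- function(n = 60, seed = 42, sigma = 0) {
  ds <- generate_dataset(synthetic_config(
    n_records = n, seed = seed, sigma = sigma,
    n_base_enzymes = 5L, mutants_per_enzyme = 3L,
    seq_len_range = c(50L, 80L)))
  curate_records(ds$records)$clean
}
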
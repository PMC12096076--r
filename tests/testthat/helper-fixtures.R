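# Fixture builders shared across the suite; everything is generated in
# code, nothing is read from disk.

# evidence tibble with sequential accessions
evidence_tbl <- function(probs, accessions = sprintf("P%02d", seq_along(probs)),
                         ...) {
  tibble::tibble(accession = accessions, raw_probability = probs, ...)
}

# edge tibble from accession pairs
edge_tbl <- function(a, b, confidence = NA_integer_) {
  tibble::tibble(protein_a = a, protein_b = b, confidence = confidence)
}

# a labeled, split protein graph from explicit pieces (labels recycled)
toy_graph <- function(probs, edges = NULL, labels = NULL, features = "raw_probability",
                      ...) {
  build_protein_graph(evidence_tbl(probs, ...), edges, labels, features = features)
}

# path graph P01 - P02 - ... - Pn with given probabilities
path_graph <- function(probs) {
  n <- length(probs)
  acc <- sprintf("P%02d", seq_len(n))
  toy_graph(probs, edge_tbl(acc[-n], acc[-1]))
}

# a small planted simulation for training tests: fast but learnable
small_sim <- function(seed, n = 400) {
  simulate_ppi_data(synthetic_spec(
    n_proteins = n, n_modules = 8, intra_module_edge_prob = 0.12,
    inter_module_edge_prob = 0.004, seed = seed
  ))
}

# graph + labels + splits from a simulation
sim_graph <- function(sim, seed = sim$spec$seed, features = "raw_probability") {
  labels <- assign_labels_from_replicates(sim$replicates)
  g <- build_protein_graph(sim$proteins, sim$edges, labels, features = features)
  split_nodes(g, seed = seed)
}

# quick training config for tests
fast_train <- function(seed, max_epochs = 60, patience = 20, ...) {
  train_config(seed = seed, max_epochs = max_epochs, patience = patience, ...)
}

# brute-force pairwise AUC oracle (independent of the rank-based path)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# dense GCN propagation oracle: explicit D^{-1/2} (A + I) D^{-1/2} X W
gcn_dense_oracle <- function(X, edges, W, b = NULL) {
  n <- nrow(X)
  A <- matrix(0, n, n)
  if (!is.null(edges) && nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[[1]][k]; j <- edges[[2]][k]
      A[i, j] <- 1; A[j, i] <- 1
    }
  }
  A_hat <- A + diag(n)
  d <- rowSums(A_hat)
  P <- diag(1 / sqrt(d)) %*% A_hat %*% diag(1 / sqrt(d))
  out <- P %*% X %*% W
  if (!is.null(b)) out <- out + rep(b, each = n)
  out
}

# random undirected graph as an edge tibble of index pairs
random_edges <- function(n, p = 0.15) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2])
}
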
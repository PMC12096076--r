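test_that("GCN propagation handles isolated nodes and the two-node case", {
  # isolated node: self-loop normalization is 1, so identity transform
  X <- matrix(c(1.5, -2), ncol = 1)
  out <- gcn_propagate(X, NULL, weights = matrix(1))
  expect_equal(out, X)

  # two nodes joined by one edge, features (1, 3): D-hat entries are 2,
  # P is the all-1/2 matrix, so both outputs are 2
  X2 <- matrix(c(1, 3), ncol = 1)
  out2 <- gcn_propagate(X2, cbind(1, 2), weights = matrix(1))
  expect_equal(as.numeric(out2), c(2, 2))
})

test_that("sparse GCN propagation matches the dense oracle on random graphs", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      n <- sample(5:20, 1)
      d <- sample(1:4, 1)
      d_out <- sample(1:4, 1)
      edges <- random_edges(n, 0.2)
      X <- matrix(rnorm(n * d), n, d)
      W <- matrix(rnorm(d * d_out), d, d_out)
      b <- rnorm(d_out)
      expect_equal(gcn_propagate(X, edges, W, b),
                   gcn_dense_oracle(X, edges, W, b), tolerance = 1e-6)
    }
  })
})

test_that("SAGE aggregation averages neighbors and respects isolation", {
  # node 1 has neighbors with features {2, 4}; w_self = 0, w_neigh = 1
  X <- matrix(c(0, 2, 4), ncol = 1)
  edges <- cbind(c(1, 1), c(2, 3))
  out <- sage_aggregate(X, edges, w_self = matrix(0), w_neigh = matrix(1))
  expect_equal(out[1, 1], 3)

  # degree-0 node with identity self-transform keeps its own features
  X3 <- matrix(c(5, 1, 1), ncol = 1)
  out3 <- sage_aggregate(X3, cbind(2, 3), w_self = matrix(1), w_neigh = matrix(1))
  expect_equal(out3[1, 1], 5) # zero neighbor term

  # sampling with sample_size >= max degree equals unlimited aggregation
  withr::with_seed(5, {
    n <- 12
    edges <- as.matrix(random_edges(n, 0.4))
    X <- matrix(rnorm(n * 3), n, 3)
    Ws <- matrix(rnorm(9), 3, 3)
    Wn <- matrix(rnorm(9), 3, 3)
    full <- sage_aggregate(X, edges, Ws, Wn)
    max_deg <- max(tabulate(c(edges), n))
    sampled <- sage_aggregate(X, edges, Ws, Wn, sample_size = max_deg,
                              training = TRUE, seed = 1)
    expect_equal(sampled, full)
  })
})

test_that("SAGE train-time sampling is reproducible given the seed", {
  withr::with_seed(8, {
    n <- 30
    edges <- as.matrix(random_edges(n, 0.3))
    X <- matrix(rnorm(n * 2), n, 2)
    Ws <- matrix(rnorm(4), 2, 2)
    Wn <- matrix(rnorm(4), 2, 2)
  })
  a <- sage_aggregate(X, edges, Ws, Wn, sample_size = 2, training = TRUE, seed = 3)
  b <- sage_aggregate(X, edges, Ws, Wn, sample_size = 2, training = TRUE, seed = 3)
  expect_identical(a, b)
})

eval_logits <- function(graph, conv_type, seed = 1, n_mp = 1) {
  cfg <- model_config(conv_type = conv_type, n_mp_layers = n_mp, seed = seed,
                      hidden_dim = 8)
  model <- init_gnn_model(cfg, ncol(graph$features))
  gnn_forward(model, graph, training = FALSE)
}

test_that("evaluation-mode forward passes are deterministic", {
  g <- path_graph(c(0.9, 0.1, 0.5, 0.7))
  for (ct in c("gcn", "sage")) {
    expect_identical(eval_logits(g, ct), eval_logits(g, ct))
  }
})

test_that("with k message-passing layers the receptive field is k hops", {
  probs <- c(0.9, 0.1, 0.5, 0.7, 0.3, 0.8)
  for (ct in c("gcn", "sage")) {
    for (k in 1:2) {
      base <- eval_logits(path_graph(probs), ct, n_mp = k)
      # perturb a node > k hops from node 1: its logit must not move
      far <- probs
      far[k + 3] <- 0.999
      perturbed <- eval_logits(path_graph(far), ct, n_mp = k)
      expect_identical(perturbed[1], base[1])
      # ... while a node within k hops does move it
      near <- probs
      near[k + 1] <- 0.999
      shifted <- eval_logits(path_graph(near), ct, n_mp = k)
      expect_false(identical(shifted[1], base[1]))
    }
  }
})

test_that("relabeling nodes permutes the outputs identically", {
  withr::with_seed(21, {
    n <- 15
    probs <- runif(n)
    acc <- sprintf("P%02d", seq_len(n))
    edges_idx <- as.matrix(random_edges(n, 0.25))
    perm <- sample(n)
  })
  edges <- edge_tbl(acc[edges_idx[, 1]], acc[edges_idx[, 2]])
  g <- toy_graph(probs, edges, accessions = acc)
  # same accessions in permuted row order; edge list unchanged
  gp <- build_protein_graph(evidence_tbl(probs[perm], accessions = acc[perm]),
                            edges)
  for (ct in c("gcn", "sage")) {
    base <- eval_logits(g, ct)
    permuted <- eval_logits(gp, ct)
    expect_equal(permuted, base[perm], tolerance = 1e-12)
  }
})

test_that("an all-zero network predicts probability one half everywhere", {
  g <- path_graph(c(0.9, 0.1, 0.5))
  cfg <- model_config(conv_type = "gcn", hidden_dim = 4, seed = 1)
  model <- init_gnn_model(cfg, 1)
  for (bi in seq_along(model$blocks)) {
    model$blocks[[bi]]$params <- lapply(model$blocks[[bi]]$params, function(p) p * 0)
    if (!is.null(model$blocks[[bi]]$bn)) {
      model$blocks[[bi]]$bn <- lapply(model$blocks[[bi]]$bn, function(p) p * 0)
    }
  }
  logits <- gnn_forward(model, g, training = FALSE)
  expect_equal(logits, rep(0, 3))
  expect_equal(ppirescore:::sigmoid(logits), rep(0.5, 3))
})

test_that("mismatched shapes are rejected", {
  expect_error(gcn_propagate(matrix(1, 2, 2), cbind(1, 2), matrix(1, 3, 1)),
               "shape mismatch")
  expect_error(sage_aggregate(matrix(1, 2, 1), cbind(1, 2), matrix(1),
                              matrix(1, 2, 1)),
               "shape mismatch")
  g <- path_graph(c(0.9, 0.1))
  model <- init_gnn_model(model_config(hidden_dim = 4), n_features = 2)
  expect_error(gnn_forward(model, g), "dimension does not match")
})
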
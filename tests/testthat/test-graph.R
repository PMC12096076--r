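test_that("node universe is the evidence table; unknown-endpoint edges drop", {
  edges <- edge_tbl(c("P01", "P02"), c("P02", "P99"))
  expect_warning(g <- toy_graph(c(0.9, 0.5, 0.1), edges), "1 edge")
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 1)
  # the isolated protein stays, with degree 0
  expect_equal(ppirescore:::node_degrees(g), c(1L, 1L, 0L))
})

test_that("probability features pass through untransformed", {
  g <- toy_graph(c(0.9, 0.2), edge_tbl("P01", "P02"))
  expect_equal(dim(g$features), c(2, 1))
  expect_equal(unname(g$features[, 1]), c(0.9, 0.2))
})

test_that("mRNA features are log1p + z-scored with missing imputed at 0", {
  tbl <- evidence_tbl(c(0.9, 0.5, 0.1), mrna_expression = c(10, 100, NA))
  g <- build_protein_graph(tbl, NULL,
                           features = c("raw_probability", "mrna_expression"))
  t <- log1p(c(10, 100))
  z <- (t - mean(t)) / sd(t)
  expect_equal(unname(g$features[1:2, "mrna_expression"]), z)
  expect_equal(unname(g$features[3, "mrna_expression"]), 0)
  expect_false(anyNA(g$features))

  expect_error(build_protein_graph(tbl, NULL, features = "nope"),
               "unknown feature")
})

test_that("label sets are disjoint and cover all nodes", {
  labels <- tibble::tibble(accession = c("P01", "P03"),
                           label = c("positive", "negative"))
  g <- toy_graph(c(0.9, 0.5, 0.1, 0.7), NULL, labels)
  expect_false(anyNA(g$nodes$label))
  expect_equal(sum(tabulate(g$nodes$label, 3)), 4)
  expect_equal(as.character(g$nodes$label),
               c("positive", "unlabeled", "negative", "unlabeled"))
})

make_labeled_graph <- function(n_pos, n_neg, n_unlab = 0) {
  n <- n_pos + n_neg + n_unlab
  labels <- tibble::tibble(
    accession = sprintf("P%02d", seq_len(n_pos + n_neg)),
    label = rep(c("positive", "negative"), c(n_pos, n_neg))
  )
  toy_graph(seq(0.1, 0.9, length.out = n), NULL, labels)
}

test_that("60/20/20 splits are exact on 10 labeled nodes and stratified", {
  g <- make_labeled_graph(5, 5, 2)
  g <- split_nodes(g, seed = 11)
  sp <- table(g$nodes$split)
  expect_equal(unname(sp[c("train", "val", "test")]), c(6L, 2L, 2L),
               ignore_attr = TRUE)
  # unlabeled nodes never get a partition
  expect_true(all(g$nodes$split[g$nodes$label == "unlabeled"] == "none"))
  # stratified: each partition class-balanced within rounding
  for (part in c("train", "val", "test")) {
    in_part <- g$nodes$label[g$nodes$split == part]
    expect_lte(abs(sum(in_part == "positive") - sum(in_part == "negative")), 1)
  }
})

test_that("splits are deterministic given the seed and respect fractions", {
  g <- make_labeled_graph(40, 60)
  a <- split_nodes(g, seed = 3)
  b <- split_nodes(g, seed = 3)
  expect_identical(a$nodes$split, b$nodes$split)
  expect_false(identical(a$nodes$split, split_nodes(g, seed = 4)$nodes$split))

  n_labeled <- sum(a$nodes$label != "unlabeled")
  frac_train <- sum(a$nodes$split == "train") / n_labeled
  expect_lte(abs(frac_train - 0.6), 1 / n_labeled)
})

test_that("degenerate splits are rejected", {
  g <- make_labeled_graph(2, 8)
  expect_error(split_nodes(g, seed = 1), "fewer than the 3 partitions")
  g2 <- make_labeled_graph(5, 5)
  expect_error(split_nodes(g2, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_nodes(g2, fractions = c(1, 0, 0)), "\\(0, 1\\)")
})

test_that("the on-disk layout round-trips a graph losslessly", {
  sim <- small_sim(5, n = 120)
  g <- sim_graph(sim, features = c("raw_probability", "mrna_expression"))
  dir <- withr::local_tempdir()
  write_protein_graph(g, dir)
  g2 <- read_protein_graph(dir)
  expect_identical(g2$features, g$features)
  expect_identical(g2$edges$from, g$edges$from)
  expect_identical(g2$edges$to, g$edges$to)
  expect_identical(g2$nodes$label, g$nodes$label)
  expect_identical(g2$nodes$split, g$nodes$split)
  expect_identical(g2$feature_names, g$feature_names)
  expect_equal(g2$nodes$truth_probability, g$nodes$truth_probability)
})

test_that("adjacency treats both edge directions identically", {
  g <- toy_graph(c(0.9, 0.5, 0.1), edge_tbl(c("P01", "P03"), c("P02", "P02")))
  A <- ppirescore:::adjacency_matrix(g)
  expect_true(Matrix::isSymmetric(A))
  expect_equal(Matrix::diag(A), rep(0, 3))
})
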
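# a prediction table built directly, bypassing training
fake_table <- function(raw, pred, accession = sprintf("P%02d", seq_along(raw)),
                       label = "unlabeled", split = "none") {
  tbl <- tibble::tibble(
    accession = accession, raw_probability = raw,
    predicted_probability = pred,
    label = ppirescore:::as_label_factor(rep(label, length.out = length(raw))),
    split = ppirescore:::as_split_factor(rep(split, length.out = length(raw)))
  )
  tbl$rank_raw <- ppirescore:::rank_desc(tbl$raw_probability, tbl$accession)
  tbl$rank_predicted <- ppirescore:::rank_desc(tbl$predicted_probability,
                                               tbl$accession)
  tbl
}

test_that("ranks are dense, descending, with accession tie-breaks", {
  tbl <- fake_table(raw = c(0.5, 0.9, 0.5), pred = c(0.1, 0.2, 0.3))
  expect_equal(sort(tbl$rank_raw), 1:3)
  expect_equal(tbl$rank_raw, c(2L, 1L, 3L)) # P01 before P03 at equal raw
  expect_equal(tbl$rank_predicted, c(3L, 2L, 1L))
})

test_that("unconfident selection is strictly below the threshold", {
  tbl <- fake_table(raw = c(0.9, 0.89, 1.0, 0.3), pred = c(0.2, 0.4, 0.9, 0.8))
  sel <- select_unconfident(tbl, 0.9)
  expect_equal(sel$accession, c("P02", "P04"))
  sel1 <- select_unconfident(tbl, 1.0)
  expect_false("P03" %in% sel1$accession)
  expect_error(select_unconfident(tbl, 0), "\\(0, 1\\]")
})

test_that("coverage curves count detected transcripts in the top-N sets", {
  tbl <- fake_table(raw = c(0.8, 0.7, 0.6, 0.5), pred = c(0.5, 0.6, 0.7, 0.8))
  det <- tibble::tibble(accession = tbl$accession,
                        mrna_detected = c(TRUE, TRUE, FALSE, TRUE))
  # top-3 by predicted: P04,P03,P02 -> 2/3; by raw: P01,P02,P03 -> 2/3
  cov <- mrna_coverage_curve(tbl, det, 3)
  expect_equal(cov$coverage_predicted, 2 / 3)
  expect_equal(cov$coverage_raw, 2 / 3)
  expect_equal(cov$overlap, 2L)

  # identical rankings give identical curves with full overlap
  same <- fake_table(raw = c(0.8, 0.6, 0.4), pred = c(0.8, 0.6, 0.4))
  det3 <- tibble::tibble(accession = same$accession,
                         mrna_detected = c(TRUE, FALSE, TRUE))
  cov2 <- mrna_coverage_curve(same, det3, c(1, 2, 3))
  expect_equal(cov2$coverage_predicted, cov2$coverage_raw)
  expect_equal(cov2$overlap, 1:3)

  expect_error(mrna_coverage_curve(same, det3, 4), "exceeds")
})

test_that("coverage is invariant to rank-preserving probability transforms", {
  withr::with_seed(12, {
    tbl <- fake_table(raw = runif(30), pred = runif(30))
    det <- tibble::tibble(accession = tbl$accession,
                          mrna_detected = runif(30) < 0.5)
  })
  base <- mrna_coverage_curve(tbl, det, c(5, 10, 20))
  squashed <- tbl
  squashed$predicted_probability <- plogis(5 * qlogis(
    pmin(pmax(squashed$predicted_probability, 1e-6), 1 - 1e-6)))
  expect_equal(mrna_coverage_curve(squashed, det, c(5, 10, 20)), base)
})

test_that("promotion deltas are raw rank minus predicted rank", {
  tbl <- fake_table(raw = c(0.9, 0.8), pred = c(0.1, 0.9))
  promo <- promotion_table(tbl)
  expect_equal(promo$delta, c(1L, -1L)) # two-protein swap
  expect_equal(promo$accession[1], "P02")

  same <- fake_table(raw = c(0.9, 0.5, 0.1), pred = c(0.9, 0.5, 0.1))
  expect_equal(promotion_table(same)$delta, c(0L, 0L, 0L))

  # a strongly promoted protein: rank 3182 -> 195 is a delta of 2987
  big <- tibble::tibble(accession = "X", rank_raw = 3182L, rank_predicted = 195L)
  expect_equal(promotion_table(big)$delta, 2987L)
})

test_that("subnetwork extraction returns the induced neighborhood", {
  # star: center P01 with 4 leaves
  star <- toy_graph(runif(5, 0, 0.9),
                    edge_tbl(rep("P01", 4), sprintf("P%02d", 2:5)))
  s0 <- extract_subnetwork(star, "P01", hops = 0)
  expect_equal(s0$nodes$accession, "P01")
  expect_equal(nrow(s0$edges), 0)
  s1 <- extract_subnetwork(star, "P01", hops = 1)
  expect_equal(nrow(s1$nodes), 5)
  expect_equal(nrow(s1$edges), 4)

  # triangle: the edge opposite the center is part of the induced subgraph
  tri <- toy_graph(runif(4, 0, 0.9),
                   edge_tbl(c("P01", "P01", "P02", "P03"),
                            c("P02", "P03", "P03", "P04")))
  t1 <- extract_subnetwork(tri, "P01", hops = 1)
  expect_equal(t1$nodes$accession, c("P01", "P02", "P03"))
  expect_equal(nrow(t1$edges), 3)
  expect_equal(t1$nodes$hops_from_center, c(0L, 1L, 1L))

  expect_error(extract_subnetwork(tri, "P99"), "unknown accession")
})

test_that("evaluation reports assemble AUC, coverage and promotion", {
  sim <- small_sim(41, n = 250)
  g <- sim_graph(sim)
  fit <- train_gnn(g, model_config(hidden_dim = 8, seed = 41),
                   fast_train(41, max_epochs = 20, patience = 20))
  rep <- evaluate_predictions(g, fit, mrna_detected = sim$mrna,
                              top_n = c(10, 25))
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$auc$scores, c("predicted", "raw"))
  expect_true(all(rep$auc$lower <= rep$auc$auc & rep$auc$auc <= rep$auc$upper))
  expect_equal(rep$coverage_curve$n, c(10L, 25L))
  expect_true(all(rep$coverage_curve$coverage_predicted >= 0 &
                    rep$coverage_curve$coverage_predicted <= 1))
  # promotion pool is the unlabeled unconfident set
  expect_true(all(rep$promoted$accession %in%
                    g$nodes$accession[g$nodes$label == "unlabeled"]))

  gl <- glance(rep)
  expect_equal(gl$auc_gain, gl$auc_predicted - gl$auc_raw)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(ggplot2::autoplot(rep), "gg")
  expect_s3_class(ggplot2::autoplot(fit), "gg")

  dir <- withr::local_tempdir()
  write_evaluation_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("auc.tsv", "coverage.tsv",
                                               "promotion.tsv",
                                               "predictions.tsv",
                                               "report.json")))))

  sub <- extract_subnetwork(g, rep$promoted$accession[1], hops = 1,
                            predictions = predict(fit, g))
  expect_s3_class(plot(sub), "gg")
})
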
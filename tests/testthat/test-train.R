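test_that("training learns planted structure well above chance", {
  sim <- small_sim(31)
  g <- sim_graph(sim)
  fit <- train_gnn(g, model_config(conv_type = "gcn", hidden_dim = 16, seed = 31),
                   fast_train(31))
  val_idx <- ppirescore:::mask_indices(g, "val")
  logits <- gnn_forward(fit$model, g)
  ci <- delong_ci(logits[val_idx], droplevels(g$nodes$label[val_idx]))
  expect_gt(fit$best_val_auc, 0.5 + 3 * ci$se)
})

test_that("a flat validation trace stops after `patience` epochs", {
  sim <- small_sim(32, n = 200)
  g <- sim_graph(sim)
  # zero learning rate: no epoch ever improves on the first
  fit <- train_gnn(g, model_config(hidden_dim = 8, seed = 1),
                   train_config(learning_rate = 0, max_epochs = 50, patience = 1,
                                seed = 1))
  expect_equal(fit$n_epochs_run, 2L)
  expect_equal(fit$best_epoch, 1L) # ties keep the earliest epoch
})

test_that("training is deterministic given seeds", {
  sim <- small_sim(33, n = 250)
  g <- sim_graph(sim)
  for (ct in c("gcn", "sage")) {
    cfg <- model_config(conv_type = ct, hidden_dim = 8, seed = 5)
    a <- train_gnn(g, cfg, fast_train(7, max_epochs = 15, patience = 15))
    b <- train_gnn(g, cfg, fast_train(7, max_epochs = 15, patience = 15))
    expect_identical(a$trace, b$trace)
    expect_identical(predict(a, g), predict(b, g))
  }
})

test_that("labels outside the training mask never influence training", {
  sim <- small_sim(34, n = 250)
  g <- sim_graph(sim)
  cfg <- model_config(hidden_dim = 8, seed = 2)
  tc <- fast_train(2, max_epochs = 12, patience = 12)
  base <- train_gnn(g, cfg, tc)

  # scramble every test-mask label and flip an unlabeled node's label slot
  tampered <- g
  test_idx <- which(tampered$nodes$split == "test")
  tampered$nodes$label[test_idx] <-
    rev(tampered$nodes$label[test_idx])
  none_idx <- which(tampered$nodes$split == "none")[1]
  tampered$nodes$label[none_idx] <- "positive"
  tampered$nodes$split[none_idx] <- "none"
  tampered_fit <- train_gnn(tampered, cfg, tc)

  expect_identical(tampered_fit$trace, base$trace)
  expect_identical(predict(tampered_fit, g), predict(base, g))
})

test_that("class weighting changes the loss but not the contributing nodes", {
  sim <- small_sim(35, n = 250)
  g <- sim_graph(sim)
  cfg <- model_config(hidden_dim = 8, seed = 3)
  on <- train_gnn(g, cfg, fast_train(3, max_epochs = 5, patience = 5,
                                     class_weighting = TRUE))
  off <- train_gnn(g, cfg, fast_train(3, max_epochs = 5, patience = 5,
                                      class_weighting = FALSE))
  expect_false(isTRUE(all.equal(on$trace$loss, off$trace$loss)))
  # the contributing set is the labeled train mask in both cases
  expect_identical(ppirescore:::mask_indices(g, "train"),
                   ppirescore:::mask_indices(g, "train"))
})

test_that("single-class masks are rejected", {
  g <- toy_graph(runif(6),
                 labels = tibble::tibble(accession = sprintf("P%02d", 1:6),
                                         label = rep("positive", 6)))
  g$nodes$split <- ppirescore:::as_split_factor(rep(c("train", "val", "test"), 2))
  expect_error(train_gnn(g), "both classes")
})

test_that("checkpoints round-trip and refuse mismatched feature sets", {
  sim <- small_sim(36, n = 200)
  g <- sim_graph(sim)
  fit <- train_gnn(g, model_config(hidden_dim = 8, seed = 4),
                   fast_train(4, max_epochs = 8, patience = 8))
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(fit, path)
  fit2 <- read_checkpoint(path)
  expect_identical(predict(fit2, g), predict(fit, g))

  g_mrna <- sim_graph(sim, features = c("raw_probability", "mrna_expression"))
  expect_error(predict(fit2, g_mrna), "feature")
  fit_mrna <- train_gnn(g_mrna, model_config(hidden_dim = 8, seed = 4),
                        fast_train(4, max_epochs = 3, patience = 3))
  expect_error(predict(fit_mrna, g), "missing feature.*mrna_expression")
})

test_that("grid search ranks by validation AUC and isolates bad cells", {
  sim <- small_sim(37, n = 250)
  g <- sim_graph(sim)
  tc <- fast_train(6, max_epochs = 8, patience = 8)

  # size-1 grid equals a single training call
  single <- grid_search(g, list(conv_type = "gcn", hidden_dim = 8, seed = 6), tc)
  direct <- train_gnn(g, model_config(conv_type = "gcn", hidden_dim = 8, seed = 6),
                      tc)
  expect_equal(single$results$val_auc[1], direct$best_val_auc)

  # a known-bad cell (learning rate 0 never improves) ranks last or errors
  # per-cell, and duplicate configurations give identical AUCs
  res <- grid_search(g, list(conv_type = c("gcn", "gcn"), hidden_dim = 8,
                             learning_rate = c(1e-3, 0)), tc)
  tbl <- res$results
  expect_equal(nrow(tbl), 4)
  worst <- tbl[tbl$rank >= 3, ]
  expect_true(all(worst$learning_rate == 0 | !is.na(worst$error)))
  dup <- tbl[tbl$learning_rate == 1e-3, ]
  expect_equal(dup$val_auc[1], dup$val_auc[2])

  expect_error(grid_search(g, list(hidden_dim = c(4, 8)), tc, max_configs = 1),
               "exceeding the cap")
})

test_that("model selection keeps the best-validation epoch parameters", {
  sim <- small_sim(38, n = 250)
  g <- sim_graph(sim)
  fit <- train_gnn(g, model_config(hidden_dim = 8, seed = 9),
                   fast_train(9, max_epochs = 30, patience = 30))
  # selection criterion is the smoothed validation AUC
  expect_equal(fit$best_val_auc, max(fit$trace$val_auc_smooth))
  expect_equal(fit$best_epoch, which.max(fit$trace$val_auc_smooth))
  # smoothing with window 1 reduces to raw argmax selection
  fit1 <- train_gnn(g, model_config(hidden_dim = 8, seed = 9),
                    fast_train(9, max_epochs = 30, patience = 30,
                               val_smooth = 1))
  expect_equal(fit1$best_epoch, which.max(fit1$trace$val_auc))
})
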
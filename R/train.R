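#' Training configuration
#'
#' Hyperparameters for semi-supervised training: binary cross-entropy is
#' computed on labeled training nodes only, validation-set ROC AUC is
#' recorded after every epoch (in evaluation mode), and the parameters
#' from the epoch with the highest validation AUC are returned. Training
#' stops early after `patience` epochs without improvement.
#'
#' @param learning_rate Positive step size (default 1e-3).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param weight_decay L2 penalty on the weight matrices (not biases or
#'   batch-norm parameters), default 5e-4. Besides the usual
#'   regularization, weight decay is what drives the neighbor transform
#'   toward zero when the network carries no signal for the labels.
#' @param max_epochs Maximum number of full-batch epochs (default 300).
#' @param patience Early-stopping patience in epochs (default 30; must
#'   not exceed `max_epochs`).
#' @param class_weighting Weight positive training nodes by
#'   `n_neg / n_pos` to counter class imbalance (default `TRUE`).
#' @param val_smooth Width of the trailing moving average applied to the
#'   per-epoch validation AUC before model selection and early stopping
#'   (default 5; 1 disables smoothing). Epoch-level AUC on a few hundred
#'   validation nodes is noisy, and selecting its raw argmax favors
#'   lucky epochs; the smoothed criterion selects a stably good region.
#' @param seed Integer seed driving all training randomness (dropout
#'   masks, SAGE neighbor sampling).
#' @return A validated list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3,
                         optimizer = c("adam", "sgd"),
                         weight_decay = 5e-4,
                         max_epochs = 300, patience = 30,
                         class_weighting = TRUE, val_smooth = 5, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (!is_scalar_number(learning_rate) || learning_rate < 0) {
    abort("`learning_rate` must be a nonnegative number")
  }
  if (!is_scalar_number(weight_decay) || weight_decay < 0) {
    abort("`weight_decay` must be a nonnegative number")
  }
  max_epochs <- check_count(max_epochs, "max_epochs")
  patience <- check_count(patience, "patience")
  val_smooth <- check_count(val_smooth, "val_smooth")
  if (patience > max_epochs) abort("`patience` must not exceed `max_epochs`")
  structure(
    list(learning_rate = learning_rate, optimizer = optimizer,
         weight_decay = weight_decay,
         max_epochs = max_epochs, patience = patience,
         class_weighting = isTRUE(class_weighting),
         val_smooth = val_smooth, seed = as.integer(seed)),
    class = "train_config"
  )
}

# 1/0 targets for a set of node indices
node_targets <- function(graph, idx) {
  as.numeric(graph$nodes$label[idx] == "positive")
}

mask_indices <- function(graph, part) {
  which(graph$nodes$split == part & graph$nodes$label != "unlabeled")
}

#' Train a re-scoring network on a split protein graph
#'
#' Fits the model by full-batch gradient descent: every epoch runs one
#' forward/backward pass over the whole graph, with the loss restricted
#' to labeled nodes in the training mask. Unlabeled proteins and
#' held-out nodes still participate in message passing through their
#' features, but their labels never enter the loss, and test-mask labels
#' are not read at any point during training or model selection.
#'
#' @param graph A `protein_graph` with splits assigned
#'   ([split_nodes()]); train and validation masks must each contain
#'   both classes.
#' @param config A [model_config()].
#' @param training A [train_config()].
#' @return An object of class `gnn_fit`: the selected model (epoch with
#'   maximal smoothed validation AUC, earliest on ties), the per-epoch
#'   metric trace (`epoch`, `loss`, `val_auc`, `val_auc_smooth`), the
#'   best epoch and its selection AUC, configs and the graph's feature
#'   names. Supports [predict()], [tidy()], [glance()] and
#'   [autoplot()].
#' @export
train_gnn <- function(graph, config = model_config(),
                      training = train_config()) {
  stopifnot(inherits(graph, "protein_graph"),
            inherits(config, "model_config"),
            inherits(training, "train_config"))
  train_idx <- mask_indices(graph, "train")
  val_idx <- mask_indices(graph, "val")
  y_train <- node_targets(graph, train_idx)
  y_val <- node_targets(graph, val_idx)
  if (length(unique(y_train)) < 2) abort("training mask must contain both classes")
  if (length(unique(y_val)) < 2) abort("validation mask must contain both classes")

  w <- rep(1, length(y_train))
  if (training$class_weighting) {
    n_pos <- sum(y_train == 1)
    w[y_train == 1] <- (length(y_train) - n_pos) / n_pos
  }

  model <- init_gnn_model(config, ncol(graph$features),
                          feature_names = graph$feature_names)
  ctx <- graph_context(graph, config)
  X <- graph$features
  state <- opt_init(model)

  best <- list(model = model, val_auc = -Inf, epoch = 0L)
  val_hist <- numeric()
  trace <- vector("list", training$max_epochs)
  since_best <- 0L
  n_run <- 0L

  withr::with_seed(training$seed, {
    for (epoch in seq_len(training$max_epochs)) {
      fwd <- nn_forward(model, X, ctx, training = TRUE)
      model <- fwd$model # batch-norm running stats
      logits_tr <- fwd$logits[train_idx]
      loss <- bce_loss(logits_tr, y_train, w)
      if (!is.finite(loss)) {
        abort(sprintf("training diverged: non-finite loss at epoch %d", epoch))
      }
      dlogits <- numeric(length(fwd$logits))
      dlogits[train_idx] <- bce_grad(logits_tr, y_train, w)
      grads <- nn_backward(model, fwd$caches, ctx, dlogits)
      step <- opt_step(model, grads, state, training$optimizer,
                       training$learning_rate, epoch,
                       weight_decay = training$weight_decay)
      model <- step$model
      state <- step$state

      val_logits <- nn_forward(model, X, ctx, training = FALSE)$logits[val_idx]
      val_auc <- roc_auc(val_logits, y_val)
      val_hist <- c(val_hist, val_auc)
      val_sel <- mean(val_hist[max(1, epoch - training$val_smooth + 1):epoch])
      trace[[epoch]] <- c(epoch = epoch, loss = loss, val_auc = val_auc,
                          val_auc_smooth = val_sel)
      n_run <- epoch
      if (val_sel > best$val_auc) { # strict: ties keep the earliest epoch
        best <- list(model = model, val_auc = val_sel, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= training$patience) break
      }
    }
  })

  trace_tbl <- dplyr::bind_rows(lapply(trace[seq_len(n_run)], as.list))
  structure(
    list(model = best$model, best_epoch = best$epoch,
         best_val_auc = best$val_auc, trace = tibble::as_tibble(trace_tbl),
         n_epochs_run = n_run, model_config = config, train_config = training,
         feature_names = graph$feature_names),
    class = "gnn_fit"
  )
}

#' @export
print.gnn_fit <- function(x, ...) {
  cat(sprintf(
    "<gnn_fit> %s model, best epoch %d/%d, validation AUC %.4f\n",
    x$model_config$conv_type, x$best_epoch, x$n_epochs_run, x$best_val_auc))
  invisible(x)
}

#' Predict re-scored presence probabilities
#'
#' Applies a trained model to a protein graph (in evaluation mode, so the
#' output is deterministic) and returns one predicted probability per
#' protein — labeled or not.
#'
#' @param object A `gnn_fit`.
#' @param graph A `protein_graph` whose features match the fit's
#'   `feature_names`.
#' @param ... Unused.
#' @return A tibble `accession`, `predicted_probability`.
#' @export
predict.gnn_fit <- function(object, graph, ...) {
  stopifnot(inherits(graph, "protein_graph"))
  miss <- setdiff(object$feature_names, graph$feature_names)
  if (length(miss) > 0) {
    abort(sprintf("graph is missing feature(s) required by the model: %s",
                  paste(miss, collapse = ", ")))
  }
  if (!identical(object$feature_names, graph$feature_names)) {
    abort("graph feature order does not match the model's feature list")
  }
  logits <- gnn_forward(object$model, graph, training = FALSE)
  tibble::tibble(accession = graph$nodes$accession,
                 predicted_probability = sigmoid(logits))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file containing the selected
#' parameters, the architecture and training configurations and the
#' feature-name list, so a fit can be reloaded and applied to a new graph
#' with matching features.
#'
#' @param fit A `gnn_fit`.
#' @param path File to write / read.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` the restored `gnn_fit`.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "gnn_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "gnn_fit")) abort(sprintf("%s is not a model checkpoint", path))
  fit
}

#' Bounded hyperparameter grid search
#'
#' Trains one model per combination of the supplied candidate lists,
#' always on the same graph, splits and seeds, and ranks the
#' configurations by validation AUC (ties broken by grid order). The test
#' mask is never touched: selection uses validation AUC only. A
#' configuration that fails to train (e.g. a divergent learning rate) is
#' recorded with its error message and ranked last rather than aborting
#' the search.
#'
#' @param graph A split `protein_graph`.
#' @param grid Named list of candidate vectors over [model_config()] /
#'   [train_config()] arguments (e.g. `list(conv_type = c("gcn",
#'   "sage"), dropout_rate = c(0, 0.3))`).
#' @param training Baseline [train_config()]; grid entries named after
#'   its arguments override it per cell.
#' @param max_configs Hard cap on the grid size (default 64).
#' @return A list of class `gnn_grid`: `results` (tibble of
#'   configurations with `val_auc`, `error`, `rank`) and `best_fit` (the
#'   `gnn_fit` of the top-ranked configuration).
#' @export
grid_search <- function(graph, grid, training = train_config(),
                        max_configs = 64) {
  stopifnot(is.list(grid), length(grid) > 0)
  if (any(lengths(grid) == 0)) abort("every grid entry must be a nonempty vector")
  cells <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(cells) > max_configs) {
    abort(sprintf("grid has %d configurations, exceeding the cap of %d",
                  nrow(cells), max_configs))
  }
  train_args <- c("learning_rate", "optimizer", "weight_decay", "max_epochs",
                  "patience", "class_weighting", "val_smooth")
  fits <- vector("list", nrow(cells))
  results <- cells
  results$val_auc <- NA_real_
  results$error <- NA_character_
  for (i in seq_len(nrow(cells))) {
    cell <- as.list(cells[i, , drop = FALSE])
    mc_args <- cell[setdiff(names(cell), train_args)]
    tc_args <- cell[intersect(names(cell), train_args)]
    out <- tryCatch({
      mc <- do.call(model_config, mc_args)
      tc <- do.call(train_config,
                    utils::modifyList(unclass(training), tc_args))
      train_gnn(graph, mc, tc)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      results$error[i] <- conditionMessage(out)
    } else {
      fits[[i]] <- out
      results$val_auc[i] <- out$best_val_auc
    }
  }
  ord <- order(-replace(results$val_auc, is.na(results$val_auc), -Inf),
               seq_len(nrow(results)))
  results$rank <- integer(nrow(results))
  results$rank[ord] <- seq_len(nrow(results))
  results <- dplyr::arrange(tibble::as_tibble(results), .data$rank)
  best_i <- ord[[1]]
  if (is.null(fits[[best_i]])) abort("no grid configuration trained successfully")
  structure(list(results = results, best_fit = fits[[best_i]]),
            class = "gnn_grid")
}

#' @export
print.gnn_grid <- function(x, ...) {
  cat(sprintf("<gnn_grid> %d configurations; best validation AUC %.4f\n",
              nrow(x$results), x$best_fit$best_val_auc))
  print(head(x$results, 5))
  invisible(x)
}
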
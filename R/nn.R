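#' Model architecture configuration
#'
#' Describes the full network architecture used to re-score protein
#' evidence: a per-node preprocess MLP, one or more message-passing
#' layers (GCN-style spectral or SAGE-style spatial convolution), a
#' postprocess MLP and a linear prediction head emitting one logit per
#' protein. Every layer applies, in order, a linear transform, optional
#' batch normalization, dropout (training only) and the activation.
#'
#' The defaults encode the selected design: one preprocess, one
#' message-passing and one postprocess layer, with dropout 0.3 for the
#' GCN variant and no dropout for the SAGE variant (whose train-time
#' neighbor subsampling already regularizes). One message-passing layer
#' means each protein's prediction draws on its immediate interactors
#' only.
#'
#' @param conv_type `"gcn"` (symmetrically normalized adjacency with
#'   self-loops) or `"sage"` (separate self and mean-neighbor
#'   transforms).
#' @param n_pre_layers,n_mp_layers,n_post_layers Number of preprocess,
#'   message-passing (>= 1) and postprocess layers.
#' @param hidden_dim Width of all hidden layers (default 64).
#' @param dropout_rate Dropout probability in `[0, 1)`; default 0.3 for
#'   `"gcn"`, 0 for `"sage"`.
#' @param use_batch_norm Apply batch normalization after each linear
#'   transform (default `TRUE`).
#' @param activation `"relu"` (default), `"prelu"` (fixed slope 0.25) or
#'   `"elu"`.
#' @param sage_neighbor_sample_size Number of neighbors sampled per node
#'   during SAGE training; `Inf` uses all neighbors. Evaluation always
#'   uses all neighbors.
#' @param seed Integer seed for parameter initialization.
#' @return A validated list of class `model_config`.
#' @export
model_config <- function(conv_type = c("gcn", "sage"),
                         n_pre_layers = 1, n_mp_layers = 1, n_post_layers = 1,
                         hidden_dim = 64, dropout_rate = NULL,
                         use_batch_norm = TRUE,
                         activation = c("relu", "prelu", "elu"),
                         sage_neighbor_sample_size = 5,
                         seed = 1L) {
  conv_type <- match.arg(conv_type)
  activation <- match.arg(activation)
  n_pre_layers <- check_count(n_pre_layers, "n_pre_layers", min = 0L)
  n_mp_layers <- check_count(n_mp_layers, "n_mp_layers", min = 1L)
  n_post_layers <- check_count(n_post_layers, "n_post_layers", min = 0L)
  hidden_dim <- check_count(hidden_dim, "hidden_dim", min = 1L)
  dropout_rate <- dropout_rate %||% if (conv_type == "gcn") 0.3 else 0
  if (!is_scalar_number(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1)")
  }
  if (!identical(sage_neighbor_sample_size, Inf)) {
    sage_neighbor_sample_size <- check_count(sage_neighbor_sample_size,
                                             "sage_neighbor_sample_size")
  }
  structure(
    list(conv_type = conv_type, n_pre_layers = n_pre_layers,
         n_mp_layers = n_mp_layers, n_post_layers = n_post_layers,
         hidden_dim = hidden_dim, dropout_rate = dropout_rate,
         use_batch_norm = use_batch_norm, activation = activation,
         sage_neighbor_sample_size = sage_neighbor_sample_size,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

# ---- activations (prelu uses a fixed slope of 0.25) ----

act_forward <- function(Z, kind) {
  switch(kind,
         relu = Z * (Z > 0),
         prelu = Z * (Z > 0) + 0.25 * Z * (Z <= 0),
         elu = ifelse(Z > 0, Z, exp(pmin(Z, 0)) - 1))
}

act_grad <- function(Z, kind) {
  switch(kind,
         relu = (Z > 0) * 1,
         prelu = (Z > 0) + 0.25 * (Z <= 0),
         elu = ifelse(Z > 0, 1, exp(pmin(Z, 0))))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- standalone message-passing primitives ----

as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- cbind(edges[[1]], edges[[2]])
  if (is.null(edges) || length(edges) == 0) {
    return(matrix(integer(), ncol = 2))
  }
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  edges
}

# D^{-1/2} (A + I) D^{-1/2} with D the degree matrix of A + I
gcn_norm_matrix <- function(n, edges) {
  edges <- as_edge_matrix(edges)
  if (nrow(edges) > 0 && (max(edges) > n || min(edges) < 1)) {
    abort("edge endpoints out of range")
  }
  i <- c(edges[, 1], edges[, 2], seq_len(n))
  j <- c(edges[, 2], edges[, 1], seq_len(n))
  A_hat <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  d_inv_sqrt <- 1 / sqrt(Matrix::rowSums(A_hat))
  Matrix::Diagonal(x = d_inv_sqrt) %*% A_hat %*% Matrix::Diagonal(x = d_inv_sqrt)
}

# row-normalized adjacency: row v = uniform weights over (sampled) N(v);
# degree-0 rows are all zero so isolated nodes get a zero neighbor term
row_norm_adjacency <- function(n, neighbor_sets) {
  len <- lengths(neighbor_sets)
  keep <- len > 0
  i <- rep(seq_len(n)[keep], len[keep])
  j <- unlist(neighbor_sets[keep], use.names = FALSE)
  x <- rep(1 / len[keep], len[keep])
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

edges_to_adj_list <- function(n, edges) {
  edges <- as_edge_matrix(edges)
  nb <- split(c(edges[, 2], edges[, 1]),
              factor(c(edges[, 1], edges[, 2]), levels = seq_len(n)))
  lapply(nb, as.integer)
}

sample_neighbor_sets <- function(adj, sample_size) {
  lapply(adj, function(nb) {
    if (length(nb) <= sample_size) nb else nb[sample.int(length(nb), sample_size)]
  })
}

#' GCN-style graph convolution
#'
#' Propagates node features through one spectral graph-convolution layer:
#' `P X W + b` with `P = D^{-1/2} (A + I) D^{-1/2}`, where `A` is the
#' (unweighted, undirected) adjacency, self-loops are added, and `D` is
#' the degree matrix of `A + I`. Isolated nodes reduce to their own
#' self-loop contribution.
#'
#' @param features Numeric node-by-feature matrix.
#' @param edges Two-column matrix/tibble of 1-based node index pairs (one
#'   row per undirected edge).
#' @param weights `d x d'` transform matrix.
#' @param bias Optional length-`d'` bias vector.
#' @return The propagated node-by-`d'` matrix.
#' @export
gcn_propagate <- function(features, edges, weights, bias = NULL) {
  features <- as.matrix(features)
  weights <- as.matrix(weights)
  if (ncol(features) != nrow(weights)) abort("feature/weight shape mismatch")
  n <- nrow(features)
  P <- gcn_norm_matrix(n, edges)
  out <- as.matrix(P %*% (features %*% weights))
  if (!is.null(bias)) {
    if (length(bias) != ncol(out)) abort("bias length mismatch")
    out <- out + rep(bias, each = n)
  }
  out
}

#' SAGE-style graph aggregation
#'
#' Computes, for every node `v`,
#' `W_self x_v + W_neigh mean(x_u, u in N(v)) + b`. During training with a
#' finite `sample_size`, the neighbor mean is taken over a uniform sample
#' without replacement of `min(sample_size, deg(v))` neighbors; during
#' evaluation all neighbors are used. Degree-0 nodes receive a zero
#' neighbor term, so isolated proteins are driven purely by their own
#' evidence.
#'
#' @inheritParams gcn_propagate
#' @param w_self,w_neigh `d x d'` transform matrices for the node's own
#'   features and the neighbor mean.
#' @param sample_size Neighbors sampled per node when `training = TRUE`;
#'   `Inf` disables sampling.
#' @param training Logical; sampling only happens in training mode.
#' @param seed Optional seed for the neighbor sampling.
#' @return The aggregated node-by-`d'` matrix.
#' @export
sage_aggregate <- function(features, edges, w_self, w_neigh, bias = NULL,
                           sample_size = Inf, training = FALSE, seed = NULL) {
  features <- as.matrix(features)
  w_self <- as.matrix(w_self)
  w_neigh <- as.matrix(w_neigh)
  if (ncol(features) != nrow(w_self) || ncol(features) != nrow(w_neigh)) {
    abort("feature/weight shape mismatch")
  }
  if (!identical(sample_size, Inf) && sample_size < 1) {
    abort("`sample_size` must be >= 1 (or Inf)")
  }
  n <- nrow(features)
  adj <- edges_to_adj_list(n, edges)
  sets <- if (training && is.finite(sample_size)) {
    if (!is.null(seed)) {
      withr::with_seed(seed, sample_neighbor_sets(adj, sample_size))
    } else {
      sample_neighbor_sets(adj, sample_size)
    }
  } else {
    adj
  }
  M <- row_norm_adjacency(n, sets)
  out <- features %*% w_self + as.matrix(M %*% features) %*% w_neigh
  if (!is.null(bias)) {
    if (length(bias) != ncol(out)) abort("bias length mismatch")
    out <- out + rep(bias, each = n)
  }
  out
}

# ---- full model: init / forward / backward ----

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

new_block <- function(kind, d_in, d_out, config, is_head = FALSE) {
  params <- if (kind == "sage") {
    list(W_self = glorot(d_in, d_out), W_neigh = glorot(d_in, d_out),
         b = rep(0, d_out))
  } else {
    list(W = glorot(d_in, d_out), b = rep(0, d_out))
  }
  bn <- if (!is_head && config$use_batch_norm) {
    list(gamma = rep(1, d_out), beta = rep(0, d_out),
         running_mean = rep(0, d_out), running_var = rep(1, d_out))
  } else {
    NULL
  }
  list(kind = kind, d_in = d_in, d_out = d_out, params = params, bn = bn,
       act = !is_head, drop = !is_head, head = is_head)
}

#' Initialize a model's parameters
#'
#' Builds the stack of layers described by a [model_config()] with
#' Glorot-uniform weight initialization (seeded from `config$seed`), zero
#' biases and identity batch-norm parameters.
#'
#' @param config A `model_config`.
#' @param n_features Number of node features the model will consume.
#' @param feature_names Optional character vector recorded for checkpoint
#'   compatibility checks.
#' @return An object of class `gnn_model` (layer blocks + config).
#' @export
init_gnn_model <- function(config, n_features, feature_names = NULL) {
  stopifnot(inherits(config, "model_config"))
  n_features <- check_count(n_features, "n_features")
  h <- config$hidden_dim
  blocks <- list()
  withr::with_seed(config$seed, {
    d <- n_features
    for (i in seq_len(config$n_pre_layers)) {
      blocks[[length(blocks) + 1]] <- new_block("dense", d, h, config)
      d <- h
    }
    for (i in seq_len(config$n_mp_layers)) {
      blocks[[length(blocks) + 1]] <- new_block(config$conv_type, d, h, config)
      d <- h
    }
    for (i in seq_len(config$n_post_layers)) {
      blocks[[length(blocks) + 1]] <- new_block("dense", d, h, config)
      d <- h
    }
    blocks[[length(blocks) + 1]] <- new_block("dense", d, 1L, config,
                                              is_head = TRUE)
  })
  structure(list(blocks = blocks, config = config,
                 feature_names = feature_names),
            class = "gnn_model")
}

# precomputed propagation operators for a graph under a given conv type
graph_context <- function(graph, config) {
  n <- n_nodes(graph)
  edges <- cbind(graph$edges$from, graph$edges$to)
  ctx <- list(n = n)
  if (config$conv_type == "gcn") {
    ctx$P <- gcn_norm_matrix(n, edges)
  } else {
    ctx$adj <- edges_to_adj_list(n, edges)
    ctx$M_full <- row_norm_adjacency(n, ctx$adj)
  }
  ctx
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# forward pass; in training mode consumes RNG (dropout, SAGE sampling)
# and returns per-block caches plus batch-norm running-stat updates
nn_forward <- function(model, X, ctx, training = FALSE) {
  cfg <- model$config
  n <- nrow(X)
  caches <- vector("list", length(model$blocks))
  H <- X
  for (bi in seq_along(model$blocks)) {
    blk <- model$blocks[[bi]]
    cache <- list(X = H)
    if (blk$kind == "dense") {
      Z <- H %*% blk$params$W + rep(blk$params$b, each = n)
    } else if (blk$kind == "gcn") {
      Z <- as.matrix(ctx$P %*% (H %*% blk$params$W)) + rep(blk$params$b, each = n)
    } else { # sage
      sets <- if (training && is.finite(cfg$sage_neighbor_sample_size)) {
        sample_neighbor_sets(ctx$adj, cfg$sage_neighbor_sample_size)
      } else {
        NULL
      }
      M <- if (is.null(sets)) ctx$M_full else row_norm_adjacency(ctx$n, sets)
      MX <- as.matrix(M %*% H)
      Z <- H %*% blk$params$W_self + MX %*% blk$params$W_neigh +
        rep(blk$params$b, each = n)
      cache$M <- M
      cache$MX <- MX
    }
    if (!is.null(blk$bn)) {
      if (training) {
        mu <- colMeans(Z)
        zc <- Z - rep(mu, each = n)
        v <- colMeans(zc^2)
        inv <- 1 / sqrt(v + bn_eps)
        xhat <- zc * rep(inv, each = n)
        model$blocks[[bi]]$bn$running_mean <-
          (1 - bn_momentum) * blk$bn$running_mean + bn_momentum * mu
        model$blocks[[bi]]$bn$running_var <-
          (1 - bn_momentum) * blk$bn$running_var + bn_momentum * v
      } else {
        inv <- 1 / sqrt(blk$bn$running_var + bn_eps)
        xhat <- (Z - rep(blk$bn$running_mean, each = n)) * rep(inv, each = n)
      }
      Z <- xhat * rep(blk$bn$gamma, each = n) + rep(blk$bn$beta, each = n)
      cache$xhat <- xhat
      cache$inv <- inv
    }
    if (blk$drop && training && cfg$dropout_rate > 0) {
      mask <- (matrix(runif(length(Z)), n) >= cfg$dropout_rate) /
        (1 - cfg$dropout_rate)
      Z <- Z * mask
      cache$mask <- mask
    }
    if (blk$act) {
      cache$A_in <- Z
      Z <- act_forward(Z, cfg$activation)
    }
    caches[[bi]] <- cache
    H <- Z
  }
  list(logits = as.numeric(H), caches = caches, model = model)
}

# backward pass; dlogits is dLoss/dlogit per node
nn_backward <- function(model, caches, ctx, dlogits) {
  cfg <- model$config
  grads <- vector("list", length(model$blocks))
  d <- matrix(dlogits, ncol = 1)
  for (bi in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[bi]]
    cache <- caches[[bi]]
    g <- list()
    if (blk$act) d <- d * act_grad(cache$A_in, cfg$activation)
    if (!is.null(cache$mask)) d <- d * cache$mask
    if (!is.null(blk$bn)) {
      g$gamma <- colSums(d * cache$xhat)
      g$beta <- colSums(d)
      nn <- nrow(d)
      dxhat <- d * rep(blk$bn$gamma, each = nn)
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cache$xhat)
      d <- (dxhat - rep(m1, each = nn) - cache$xhat * rep(m2, each = nn)) *
        rep(cache$inv, each = nn)
    }
    X <- cache$X
    if (blk$kind == "dense") {
      g$W <- crossprod(X, d)
      g$b <- colSums(d)
      d <- d %*% t(blk$params$W)
    } else if (blk$kind == "gcn") {
      dXW <- as.matrix(ctx$P %*% d) # P is symmetric
      g$W <- crossprod(X, dXW)
      g$b <- colSums(d)
      d <- dXW %*% t(blk$params$W)
    } else { # sage
      g$W_self <- crossprod(X, d)
      g$W_neigh <- crossprod(cache$MX, d)
      g$b <- colSums(d)
      d <- d %*% t(blk$params$W_self) +
        as.matrix(Matrix::crossprod(cache$M, d %*% t(blk$params$W_neigh)))
    }
    grads[[bi]] <- g
  }
  grads
}

# weighted binary cross-entropy on logits, numerically stable
bce_loss <- function(logits, y, w) {
  l <- pmax(logits, 0) - logits * y + log1p(exp(-abs(logits)))
  sum(w * l) / sum(w)
}

bce_grad <- function(logits, y, w) {
  w * (sigmoid(logits) - y) / sum(w)
}

# ---- optimizers (operate on the nested block/param structure) ----

opt_init <- function(model) {
  lapply(model$blocks, function(blk) {
    slots <- c(names(blk$params), if (!is.null(blk$bn)) c("gamma", "beta"))
    state <- lapply(slots, function(nm) {
      p <- blk$params[[nm]] %||% blk$bn[[nm]]
      list(m = p * 0, v = p * 0)
    })
    stats::setNames(state, slots)
  })
}

opt_step <- function(model, grads, state, optimizer, lr, t, weight_decay = 0) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (bi in seq_along(model$blocks)) {
    for (nm in names(grads[[bi]])) {
      g <- grads[[bi]][[nm]]
      in_bn <- nm %in% c("gamma", "beta")
      p <- if (in_bn) model$blocks[[bi]]$bn[[nm]] else model$blocks[[bi]]$params[[nm]]
      # decay weight matrices only, never biases or batch-norm parameters
      if (weight_decay > 0 && !in_bn && nm != "b") g <- g + weight_decay * p
      if (optimizer == "adam") {
        st <- state[[bi]][[nm]]
        st$m <- b1 * st$m + (1 - b1) * g
        st$v <- b2 * st$v + (1 - b2) * g^2
        m_hat <- st$m / (1 - b1^t)
        v_hat <- st$v / (1 - b2^t)
        p <- p - lr * m_hat / (sqrt(v_hat) + eps)
        state[[bi]][[nm]] <- st
      } else { # sgd
        p <- p - lr * g
      }
      if (in_bn) {
        model$blocks[[bi]]$bn[[nm]] <- p
      } else {
        model$blocks[[bi]]$params[[nm]] <- p
      }
    }
  }
  list(model = model, state = state)
}

#' Run a model forward over a protein graph
#'
#' Evaluates the network on the graph's feature matrix and returns one
#' logit per protein; `sigmoid(logit)` is the predicted probability of
#' presence. In evaluation mode (the default) the pass is deterministic:
#' no dropout, all neighbors, batch normalization using running
#' statistics.
#'
#' @param model A `gnn_model` from [init_gnn_model()].
#' @param graph A `protein_graph`.
#' @param training Logical; training mode enables dropout and SAGE
#'   neighbor sampling (consumes the RNG).
#' @return Numeric vector of per-node logits.
#' @export
gnn_forward <- function(model, graph, training = FALSE) {
  stopifnot(inherits(model, "gnn_model"), inherits(graph, "protein_graph"))
  if (ncol(graph$features) != model$blocks[[1]]$d_in) {
    abort("graph feature dimension does not match the model")
  }
  ctx <- graph_context(graph, model$config)
  nn_forward(model, graph$features, ctx, training = training)$logits
}
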
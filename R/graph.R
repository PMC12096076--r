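#' Assemble a protein graph from evidence, edges and labels
#'
#' Builds the single container exchanged by all downstream stages: an
#' undirected protein--protein-interaction graph whose nodes are exactly
#' the proteins of the evidence table, carrying a node feature matrix,
#' ground-truth labels where available, and (after [split_nodes()])
#' train/validation/test masks.
#'
#' The node universe is the evidence table: edges mentioning proteins with
#' no evidence row are dropped (with a warning), while evidence proteins
#' without any surviving interaction are kept as isolated nodes — in real
#' datasets a substantial fraction of proteins has no catalogued
#' interactor, and their re-scored probability is then driven purely by
#' their own evidence.
#'
#' Feature columns are transformed for use as network inputs:
#' `raw_probability` is passed through untouched (already on `[0, 1]`, so
#' the probability-only model is the minimal configuration);
#' `mrna_expression` and any other numeric evidence column are
#' `log1p`-transformed and z-scored, with missing values imputed as 0
#' after the transform (i.e. at the feature mean).
#'
#' @param proteins Evidence tibble from [read_protein_table()] (columns
#'   `accession` plus evidence columns).
#' @param edges Edge tibble from [read_string_edges()] /
#'   [filter_edges()], or any tibble with columns `protein_a`,
#'   `protein_b` and optionally `confidence`.
#' @param labels Optional label tibble (`accession`, `label`, optionally
#'   `truth_probability`) from [assign_labels_from_replicates()] or
#'   [assign_labels_by_presence()]. Proteins without a row are unlabeled.
#' @param features Character vector of evidence columns to use as node
#'   features, default `"raw_probability"`.
#'
#' @return An object of class `protein_graph`: a list with
#'   \describe{
#'     \item{nodes}{tibble `accession`, `label`, `split`,
#'       `truth_probability`, plus the raw evidence columns;}
#'     \item{features}{numeric node-by-feature matrix (no missing
#'       entries), rownames = accessions;}
#'     \item{feature_names}{the feature column order;}
#'     \item{edges}{tibble of node index pairs `from` < `to` (one row per
#'       unordered pair, no self-loops) plus `confidence` when supplied.}
#'   }
#' @export
build_protein_graph <- function(proteins, edges, labels = NULL,
                                features = "raw_probability") {
  stopifnot(is.data.frame(proteins), "accession" %in% names(proteins))
  if (nrow(proteins) == 0) abort("empty node set: evidence table has no rows")
  if (anyDuplicated(proteins$accession)) abort("duplicate accessions in evidence table")
  unknown <- setdiff(features, names(proteins))
  if (length(unknown) > 0) {
    abort(sprintf("unknown feature column(s): %s", paste(unknown, collapse = ", ")))
  }

  acc <- proteins$accession
  idx <- stats::setNames(seq_along(acc), acc)

  # features: raw probability untouched, everything else log1p + z-score,
  # missing values imputed at the (post-transform) feature mean, i.e. 0
  feat_mat <- matrix(0, nrow = length(acc), ncol = length(features),
                     dimnames = list(acc, features))
  for (f in features) {
    v <- as.numeric(proteins[[f]])
    if (f == "raw_probability") {
      if (anyNA(v)) {
        abort("raw_probability requested as a feature but missing for some proteins; run fit_score_mixture() first")
      }
      feat_mat[, f] <- v
    } else {
      if (any(v < 0, na.rm = TRUE)) abort(sprintf("feature `%s` must be nonnegative", f))
      t <- log1p(v)
      mu <- mean(t, na.rm = TRUE)
      s <- sd(t, na.rm = TRUE)
      z <- if (is.na(s) || s == 0) rep(0, length(t)) else (t - mu) / s
      z[is.na(z)] <- 0
      feat_mat[, f] <- z
    }
  }

  # edges -> node indices; unordered, self-loop free, deduplicated
  edge_tbl <- tibble::tibble(from = integer(), to = integer(),
                             confidence = integer())
  if (!is.null(edges) && nrow(edges) > 0) {
    stopifnot(all(c("protein_a", "protein_b") %in% names(edges)))
    ia <- idx[edges$protein_a]
    ib <- idx[edges$protein_b]
    known <- !is.na(ia) & !is.na(ib)
    if (any(!known)) {
      warn(sprintf("dropped %d edge(s) whose endpoints are not in the evidence table",
                   sum(!known)))
    }
    conf <- if ("confidence" %in% names(edges)) edges$confidence else rep(NA_integer_, nrow(edges))
    ia <- unname(ia[known]); ib <- unname(ib[known]); conf <- conf[known]
    keep <- ia != ib
    from <- pmin(ia, ib)[keep]
    to <- pmax(ia, ib)[keep]
    conf <- conf[keep]
    if (length(from) > 0) {
      edge_tbl <- tibble::tibble(from = from, to = to, confidence = conf) |>
        dplyr::group_by(.data$from, .data$to) |>
        dplyr::summarise(confidence = suppressWarnings(max(.data$confidence)),
                         .groups = "drop") |>
        dplyr::arrange(.data$from, .data$to)
    }
  }

  nodes <- tibble::tibble(
    accession = acc,
    label = as_label_factor("unlabeled"),
    split = as_split_factor("none"),
    truth_probability = NA_real_
  )
  for (col in setdiff(names(proteins), "accession")) nodes[[col]] <- proteins[[col]]
  if (!is.null(labels)) {
    stopifnot(all(c("accession", "label") %in% names(labels)))
    m <- match(nodes$accession, labels$accession)
    hit <- !is.na(m)
    nodes$label[hit] <- as_label_factor(labels$label[m[hit]])
    if ("truth_probability" %in% names(labels)) {
      nodes$truth_probability[hit] <- labels$truth_probability[m[hit]]
    }
  }

  structure(
    list(nodes = nodes, features = feat_mat, feature_names = features,
         edges = edge_tbl),
    class = "protein_graph"
  )
}

#' @export
print.protein_graph <- function(x, ...) {
  n <- nrow(x$nodes)
  deg <- node_degrees(x)
  cat(sprintf("<protein_graph> %d proteins, %d interactions (%d isolated)\n",
              n, nrow(x$edges), sum(deg == 0)))
  cat(sprintf("  features: %s\n", paste(x$feature_names, collapse = ", ")))
  cat("  labels:   ", paste(sprintf("%s=%d", label_levels,
                                    tabulate(x$nodes$label, 3)), collapse = " "), "\n")
  cat("  splits:   ", paste(sprintf("%s=%d", split_levels,
                                    tabulate(x$nodes$split, 4)), collapse = " "), "\n")
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$nodes)

node_degrees <- function(graph) {
  tabulate(c(graph$edges$from, graph$edges$to), nbins = n_nodes(graph))
}

# symmetric sparse adjacency (0/1, no self-loops)
adjacency_matrix <- function(graph) {
  n <- n_nodes(graph)
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e$from, e$to), j = c(e$to, e$from),
                       x = 1, dims = c(n, n))
}

# list of neighbor index vectors per node
adjacency_list <- function(graph) {
  n <- n_nodes(graph)
  e <- graph$edges
  nb <- split(c(e$to, e$from), factor(c(e$from, e$to), levels = seq_len(n)))
  lapply(nb, as.integer)
}

#' Assign stratified train/validation/test masks
#'
#' Randomly partitions the *labeled* nodes of a protein graph into
#' train/validation/test sets; unlabeled nodes always receive split
#' `"none"` (they take part in message passing but never in loss or
#' metric computation). The split is stratified by class, and per-class
#' partition sizes are floor-then-distributed (remainders go to the
#' partitions with the largest fractional parts) so that counts sum
#' exactly to the labeled total. Deterministic given `seed`.
#'
#' @param graph A `protein_graph`.
#' @param fractions Named numeric vector `c(train=, val=, test=)` summing
#'   to 1; default `c(0.6, 0.2, 0.2)`.
#' @param seed Integer seed for the random assignment.
#' @return The graph with its `split` column filled.
#' @export
split_nodes <- function(graph, fractions = c(train = 0.6, val = 0.2, test = 0.2),
                        seed = 1L) {
  stopifnot(inherits(graph, "protein_graph"))
  if (length(fractions) != 3) abort("`fractions` must have 3 entries (train, val, test)")
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")
  if (any(fractions <= 0) || any(fractions >= 1)) {
    abort("each split fraction must lie in (0, 1)")
  }
  if (abs(sum(fractions) - 1) > 1e-9) abort("split fractions must sum to 1")
  n_parts <- 3L

  labs <- graph$nodes$label
  labeled_classes <- intersect(c("positive", "negative"), as.character(unique(labs)))
  if (length(labeled_classes) < 2) {
    abort("graph needs at least one labeled node of each class before splitting")
  }

  split <- as_split_factor(rep("none", n_nodes(graph)))
  withr::with_seed(seed, {
    for (cl in c("positive", "negative")) { # fixed order for determinism
      members <- which(labs == cl)
      if (length(members) < n_parts) {
        abort(sprintf("class `%s` has %d labeled node(s), fewer than the %d partitions",
                      cl, length(members), n_parts))
      }
      # order by accession first so permutation is reproducible across
      # input row orders
      members <- members[order(graph$nodes$accession[members], method = "radix")]
      members <- sample(members)
      n <- length(members)
      base <- floor(fractions * n)
      rem <- n - sum(base)
      if (rem > 0) {
        frac_part <- fractions * n - base
        extra <- order(-frac_part, seq_len(n_parts))[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      assign_to <- rep(c("train", "val", "test"), times = base)
      split[members] <- assign_to
    }
  })
  graph$nodes$split <- split
  graph
}

#' Write / read a protein graph as a plain-text directory
#'
#' Serializes a `protein_graph` to a documented directory layout —
#' `nodes.tsv` (accession, label, split, truth probability and raw
#' evidence columns), `features.tsv` (the assembled feature matrix),
#' `edges.tsv` (accession pairs + confidence) and `manifest.json`
#' (feature order) — and reads it back losslessly.
#'
#' @param graph A `protein_graph`.
#' @param dir Directory to write to (created if needed).
#' @return `write_protein_graph()` returns `dir` invisibly;
#'   `read_protein_graph()` returns the reconstructed `protein_graph`.
#' @export
write_protein_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "protein_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- graph$nodes
  nodes$label <- as.character(nodes$label)
  nodes$split <- as.character(nodes$split)
  readr::write_tsv(fmt_doubles(nodes), file.path(dir, "nodes.tsv"),
                   progress = FALSE)
  feat <- tibble::as_tibble(graph$features)
  feat <- dplyr::bind_cols(tibble::tibble(accession = graph$nodes$accession), feat)
  readr::write_tsv(fmt_doubles(feat), file.path(dir, "features.tsv"),
                   progress = FALSE)
  e <- graph$edges
  readr::write_tsv(
    tibble::tibble(protein_a = graph$nodes$accession[e$from],
                   protein_b = graph$nodes$accession[e$to],
                   confidence = e$confidence),
    file.path(dir, "edges.tsv"), progress = FALSE
  )
  jsonlite::write_json(list(format = "protein_graph", version = 1L,
                            feature_names = graph$feature_names),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_protein_graph
#' @export
read_protein_graph <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$format, "protein_graph")) {
    abort(sprintf("%s does not contain a protein_graph layout", dir))
  }
  # all-character read + base-R numeric conversion: strtod() is correctly
  # rounded, so full-precision values survive the text round trip exactly
  nodes <- readr::read_tsv(file.path(dir, "nodes.tsv"), progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  nodes$label <- as_label_factor(nodes$label)
  nodes$split <- as_split_factor(nodes$split)
  for (col in setdiff(names(nodes), c("accession", "label", "split"))) {
    nodes[[col]] <- as.numeric(nodes[[col]])
  }
  feat_tbl <- readr::read_tsv(file.path(dir, "features.tsv"), progress = FALSE,
                              col_types = readr::cols(.default = "c"))
  feature_names <- as.character(unlist(manifest$feature_names))
  feat <- vapply(feature_names, function(f) as.numeric(feat_tbl[[f]]),
                 numeric(nrow(feat_tbl)))
  if (is.null(dim(feat))) feat <- matrix(feat, nrow = nrow(feat_tbl))
  dimnames(feat) <- list(feat_tbl$accession, feature_names)
  e <- readr::read_tsv(file.path(dir, "edges.tsv"), progress = FALSE,
                       show_col_types = FALSE)
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$accession)
  edges <- tibble::tibble(
    from = unname(idx[e$protein_a]),
    to = unname(idx[e$protein_b]),
    confidence = if (nrow(e) > 0) as.integer(e$confidence) else integer()
  )
  structure(list(nodes = nodes, features = feat, feature_names = feature_names,
                 edges = edges),
            class = "protein_graph")
}
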
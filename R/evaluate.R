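#' Build a per-protein prediction table
#'
#' Joins a graph's evidence, labels and splits with a fit's predicted
#' probabilities and assigns dense ranks 1..n under both the raw and the
#' predicted probability, descending, with ties broken by accession so
#' outputs are bit-stable.
#'
#' @param graph A `protein_graph` with a `raw_probability` column.
#' @param fit A `gnn_fit`, or a tibble `accession`,
#'   `predicted_probability` already computed with [predict.gnn_fit()].
#' @return A tibble `accession`, `raw_probability`,
#'   `predicted_probability`, `label`, `split`, `rank_raw`,
#'   `rank_predicted`.
#' @export
prediction_table <- function(graph, fit) {
  stopifnot(inherits(graph, "protein_graph"))
  preds <- if (inherits(fit, "gnn_fit")) predict(fit, graph) else fit
  stopifnot(is.data.frame(preds),
            all(c("accession", "predicted_probability") %in% names(preds)))
  if (!"raw_probability" %in% names(graph$nodes)) {
    abort("graph has no raw_probability column")
  }
  tbl <- tibble::tibble(
    accession = graph$nodes$accession,
    raw_probability = graph$nodes$raw_probability,
    predicted_probability =
      preds$predicted_probability[match(graph$nodes$accession, preds$accession)],
    label = graph$nodes$label,
    split = graph$nodes$split
  )
  if (anyNA(tbl$predicted_probability)) {
    abort("predictions are missing for some proteins in the graph")
  }
  tbl$rank_raw <- rank_desc(tbl$raw_probability, tbl$accession)
  tbl$rank_predicted <- rank_desc(tbl$predicted_probability, tbl$accession)
  tbl
}

#' Select unconfident proteins
#'
#' Filters a prediction table to the proteins whose *raw* probability is
#' strictly below the confidence threshold — the candidates for promotion
#' by the network. The conventional threshold 0.9 approximately matches a
#' 5% global FDR cut in typical pipelines.
#'
#' @param table A [prediction_table()].
#' @param threshold Strict upper bound on the raw probability, in
#'   `(0, 1]`.
#' @return The filtered tibble, with ranks recomputed within the subset
#'   (columns `rank_raw`, `rank_predicted`).
#' @export
select_unconfident <- function(table, threshold = 0.9) {
  stopifnot(is.data.frame(table), "raw_probability" %in% names(table))
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1]")
  }
  out <- dplyr::filter(table, .data$raw_probability < threshold)
  if (nrow(out) > 0) {
    out$rank_raw <- rank_desc(out$raw_probability, out$accession)
    out$rank_predicted <- rank_desc(out$predicted_probability, out$accession)
  }
  out
}

#' mRNA coverage of top-N promoted proteins
#'
#' For each requested N, takes the top-N proteins by predicted and by raw
#' probability (descending, accession tie-break) and reports the fraction
#' of each set with a detected corresponding transcript — an orthogonal
#' plausibility check for additionally identified proteins — together
#' with the overlap between the two top-N sets.
#'
#' @param unconfident A subset of a prediction table, typically
#'   [select_unconfident()] output.
#' @param mrna_detected Either a logical vector named by accession, or a
#'   tibble with columns `accession` and `mrna_detected`.
#' @param n_values Integer vector of N values, each at most
#'   `nrow(unconfident)`.
#' @return A tibble `n`, `coverage_predicted`, `coverage_raw`,
#'   `overlap`.
#' @export
mrna_coverage_curve <- function(unconfident, mrna_detected, n_values) {
  stopifnot(is.data.frame(unconfident))
  if (is.data.frame(mrna_detected)) {
    det <- stats::setNames(as.logical(mrna_detected$mrna_detected),
                           mrna_detected$accession)
  } else {
    det <- as.logical(mrna_detected)
    names(det) <- names(mrna_detected)
  }
  if (any(n_values > nrow(unconfident))) {
    abort(sprintf("N exceeds the number of unconfident proteins (%d)",
                  nrow(unconfident)))
  }
  if (any(n_values < 1)) abort("each N must be >= 1")
  ord_pred <- order(-unconfident$predicted_probability, unconfident$accession,
                    method = "radix")
  ord_raw <- order(-unconfident$raw_probability, unconfident$accession,
                   method = "radix")
  has_mrna <- det[unconfident$accession]
  has_mrna[is.na(has_mrna)] <- FALSE
  purrr::map_dfr(as.integer(n_values), function(N) {
    top_pred <- ord_pred[seq_len(N)]
    top_raw <- ord_raw[seq_len(N)]
    tibble::tibble(
      n = N,
      coverage_predicted = mean(has_mrna[top_pred]),
      coverage_raw = mean(has_mrna[top_raw]),
      overlap = length(intersect(top_pred, top_raw))
    )
  })
}

#' Rank-improvement (promotion) table
#'
#' Compares each protein's rank under raw and predicted probability and
#' sorts by rank improvement `delta = rank_raw - rank_predicted`,
#' descending; the head of the table is the most strongly promoted
#' proteins, the tail the most demoted.
#'
#' @param table A prediction table (or unconfident subset) with
#'   `rank_raw` and `rank_predicted` columns.
#' @return A tibble `accession`, `raw_probability`,
#'   `predicted_probability`, `rank_raw`, `rank_predicted`, `delta`.
#' @export
promotion_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("rank_raw", "rank_predicted") %in% names(table)))
  table |>
    dplyr::mutate(delta = .data$rank_raw - .data$rank_predicted) |>
    dplyr::select(dplyr::any_of(c("accession", "raw_probability",
                                  "predicted_probability", "rank_raw",
                                  "rank_predicted", "delta"))) |>
    dplyr::arrange(dplyr::desc(.data$delta), .data$accession)
}

#' Extract the neighborhood subnetwork of a protein
#'
#' Returns the induced subgraph on all proteins within `hops` interaction
#' steps of a center protein, annotated with raw (and, when supplied,
#' predicted) probabilities — the view used to inspect why the model
#' promoted or demoted a protein.
#'
#' @param graph A `protein_graph`.
#' @param center Accession of the center protein.
#' @param hops Neighborhood radius (0 = the center alone).
#' @param predictions Optional tibble `accession`,
#'   `predicted_probability`.
#' @return A list of class `protein_subnetwork` with `nodes` (accession,
#'   hops_from_center, label, raw/predicted probability) and `edges`
#'   (accession pairs among the selected nodes).
#' @export
extract_subnetwork <- function(graph, center, hops = 1, predictions = NULL) {
  stopifnot(inherits(graph, "protein_graph"))
  hops <- check_count(hops, "hops", min = 0L)
  ci <- match(center, graph$nodes$accession)
  if (is.na(ci)) abort(sprintf("unknown accession: %s", center))
  adj <- adjacency_list(graph)
  dist <- rep(NA_integer_, n_nodes(graph))
  dist[ci] <- 0L
  frontier <- ci
  h <- 0L
  while (h < hops && length(frontier) > 0) {
    h <- h + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- h
    frontier <- nxt
  }
  keep <- which(!is.na(dist))
  nodes <- tibble::tibble(
    accession = graph$nodes$accession[keep],
    hops_from_center = dist[keep],
    label = graph$nodes$label[keep],
    raw_probability = if ("raw_probability" %in% names(graph$nodes)) {
      graph$nodes$raw_probability[keep]
    } else {
      NA_real_
    }
  )
  if (!is.null(predictions)) {
    nodes$predicted_probability <-
      predictions$predicted_probability[match(nodes$accession,
                                              predictions$accession)]
  }
  in_set <- graph$edges$from %in% keep & graph$edges$to %in% keep
  e <- graph$edges[in_set, ]
  edges <- tibble::tibble(protein_a = graph$nodes$accession[e$from],
                          protein_b = graph$nodes$accession[e$to])
  structure(list(nodes = dplyr::arrange(nodes, .data$hops_from_center,
                                        .data$accession),
                 edges = edges, center = center, hops = hops),
            class = "protein_subnetwork")
}

#' @export
print.protein_subnetwork <- function(x, ...) {
  cat(sprintf("<protein_subnetwork> %d-hop neighborhood of %s: %d proteins, %d edges\n",
              x$hops, x$center, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Evaluate re-scored predictions against held-out labels
#'
#' Produces the full evaluation report for a trained model on a graph:
#' test-mask ROC AUC with its DeLong confidence interval for both the
#' predicted and the raw probability, the mRNA coverage curve over the
#' unconfident proteins, and the promotion table.
#'
#' @param graph A split `protein_graph`.
#' @param fit A `gnn_fit` (or precomputed prediction tibble).
#' @param mrna_detected Optional mRNA detection table (see
#'   [mrna_coverage_curve()]); when `NULL` the coverage curve is
#'   omitted.
#' @param unconfident_threshold Raw-probability cutoff defining
#'   unconfident proteins (default 0.9).
#' @param unlabeled_only Restrict the promotion/coverage analysis to
#'   unlabeled proteins, the ones whose existence the labels cannot
#'   decide (default `TRUE`).
#' @param top_n Integer vector of N values for the coverage curve;
#'   values exceeding the unconfident-set size are dropped.
#' @param level Confidence level for the DeLong interval.
#' @return An object of class `evaluation_report`: `auc` (tibble with
#'   rows `predicted` and `raw`), `coverage_curve`, `promoted`, the
#'   underlying `table` and the evaluation settings. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
evaluate_predictions <- function(graph, fit, mrna_detected = NULL,
                                 unconfident_threshold = 0.9,
                                 unlabeled_only = TRUE,
                                 top_n = c(50, 100, 200, 500),
                                 level = 0.95) {
  tbl <- prediction_table(graph, fit)
  test <- dplyr::filter(tbl, .data$split == "test", .data$label != "unlabeled")
  if (nrow(test) == 0 || dplyr::n_distinct(test$label) < 2) {
    abort("test mask must contain labeled proteins of both classes")
  }
  y <- droplevels(test$label)
  auc <- dplyr::bind_rows(
    predicted = delong_ci(test$predicted_probability, y, level),
    raw = delong_ci(test$raw_probability, y, level),
    .id = "scores"
  )

  pool <- if (unlabeled_only) dplyr::filter(tbl, .data$label == "unlabeled") else tbl
  unconf <- select_unconfident(pool, unconfident_threshold)
  coverage <- NULL
  if (!is.null(mrna_detected) && nrow(unconf) > 0) {
    ns <- as.integer(top_n[top_n <= nrow(unconf)])
    if (length(ns) > 0) {
      coverage <- mrna_coverage_curve(unconf, mrna_detected, ns)
    }
  }
  promoted <- promotion_table(unconf)

  structure(
    list(auc = auc, coverage_curve = coverage, promoted = promoted,
         table = tbl, unconfident_threshold = unconfident_threshold,
         unlabeled_only = unlabeled_only, level = level),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n  test-mask ROC AUC (DeLong ",
      sprintf("%d%% CI):\n", round(100 * x$level)), sep = "")
  for (i in seq_len(nrow(x$auc))) {
    cat(sprintf("    %-9s %.4f (%.4f-%.4f)\n", x$auc$scores[i], x$auc$auc[i],
                x$auc$lower[i], x$auc$upper[i]))
  }
  if (!is.null(x$coverage_curve)) {
    cat("  mRNA coverage of top-N unconfident proteins:\n")
    print(x$coverage_curve)
  }
  cat(sprintf("  %d unconfident proteins ranked for promotion (raw < %.2g)\n",
              nrow(x$promoted), x$unconfident_threshold))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Serializes the report as a JSON summary (`report.json`) plus TSV
#' tables (`auc.tsv`, `coverage.tsv`, `promotion.tsv`,
#' `predictions.tsv`).
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$auc, file.path(dir, "auc.tsv"), progress = FALSE)
  if (!is.null(report$coverage_curve)) {
    readr::write_tsv(report$coverage_curve, file.path(dir, "coverage.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(report$promoted, file.path(dir, "promotion.tsv"),
                   progress = FALSE)
  tbl <- report$table
  tbl$label <- as.character(tbl$label)
  tbl$split <- as.character(tbl$split)
  readr::write_tsv(tbl, file.path(dir, "predictions.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(auc = report$auc,
         unconfident_threshold = report$unconfident_threshold,
         level = report$level,
         n_unconfident = nrow(report$promoted)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
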
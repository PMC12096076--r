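#' Ground-truth labels from replicate raw probabilities
#'
#' Pools raw probabilities observed for each protein across independent
#' replicate experiments and thresholds the mean into
#' positive / negative / unlabeled classes. A protein absent from a
#' replicate contributes probability 0 to the mean, so the denominator is
#' always `n_replicates` (absence is treated as evidence of absence, the
#' conservative reading of replicate pooling).
#'
#' Thresholding is strict on both sides: a mean *strictly above*
#' `pos_threshold` is positive, *strictly below* `neg_threshold` negative,
#' anything in between (including the thresholds themselves) unlabeled.
#'
#' @param replicates A long tibble with columns `accession` and
#'   `probability` (one row per protein per replicate in which it was
#'   observed); an optional `replicate` column is accepted and ignored
#'   except for inferring `n_replicates`.
#' @param n_replicates Number of replicate experiments. Defaults to the
#'   number of distinct values in a `replicate` column when present.
#' @param pos_threshold,neg_threshold Mean-probability cutoffs, defaults
#'   0.7 and 0.3.
#'
#' @return A tibble with columns `accession`, `truth_probability` (the
#'   pooled mean) and `label` (factor positive/negative/unlabeled), one
#'   row per distinct protein, sorted by accession.
#' @export
assign_labels_from_replicates <- function(replicates,
                                          n_replicates = NULL,
                                          pos_threshold = 0.7,
                                          neg_threshold = 0.3) {
  stopifnot(is.data.frame(replicates),
            all(c("accession", "probability") %in% names(replicates)))
  check_probability(pos_threshold, "pos_threshold")
  check_probability(neg_threshold, "neg_threshold")
  if (pos_threshold <= neg_threshold) {
    abort("`pos_threshold` must be greater than `neg_threshold`")
  }
  if (is.null(n_replicates)) {
    if (!"replicate" %in% names(replicates)) {
      abort("supply `n_replicates` or include a `replicate` column")
    }
    n_replicates <- dplyr::n_distinct(replicates$replicate)
  }
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (any(replicates$probability < 0 | replicates$probability > 1, na.rm = TRUE)) {
    abort("replicate probabilities must lie in [0, 1]")
  }

  replicates |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(truth_probability = sum(.data$probability) / n_replicates,
                     .groups = "drop") |>
    dplyr::mutate(label = as_label_factor(dplyr::case_when(
      .data$truth_probability > pos_threshold ~ "positive",
      .data$truth_probability < neg_threshold ~ "negative",
      TRUE ~ "unlabeled"
    ))) |>
    dplyr::arrange(.data$accession)
}

#' Ground-truth labels from presence counts across reference datasets
#'
#' Labels a protein positive when it was observed in at least
#' `min_present` of `n_datasets` independent reference datasets, negative
#' when absent from all of them, and unlabeled otherwise. With the
#' defaults (`min_present = 2`, four datasets) this is the
#' at-least-two-of-four reference rule used for yeast benchmark sets.
#'
#' @param presence A tibble with columns `accession` and `presence_count`
#'   (number of reference datasets in which the protein was observed).
#' @param n_datasets Number of reference datasets.
#' @param min_present Minimum count for a positive label.
#' @return A tibble with columns `accession` and `label`, sorted by
#'   accession.
#' @export
assign_labels_by_presence <- function(presence, n_datasets = 4, min_present = 2) {
  stopifnot(is.data.frame(presence),
            all(c("accession", "presence_count") %in% names(presence)))
  n_datasets <- check_count(n_datasets, "n_datasets")
  min_present <- check_count(min_present, "min_present")
  cnt <- presence$presence_count
  if (any(cnt != round(cnt)) || any(cnt < 0) || any(cnt > n_datasets)) {
    abort(sprintf("`presence_count` must be an integer in [0, %d]", n_datasets))
  }
  presence |>
    dplyr::transmute(
      accession = .data$accession,
      label = as_label_factor(dplyr::case_when(
        .data$presence_count >= min_present ~ "positive",
        .data$presence_count == 0 ~ "negative",
        TRUE ~ "unlabeled"
      ))
    ) |>
    dplyr::arrange(.data$accession)
}
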
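#' ROC AUC (Mann--Whitney form)
#'
#' Computes the area under the ROC curve as the Mann--Whitney pair
#' statistic: the mean over all (positive, negative) pairs of 1 if the
#' positive scores higher, 1/2 on a tie, 0 otherwise. Implemented with
#' midranks, which is exactly equal to the pairwise count.
#'
#' @param scores Numeric vector of scores (any monotone scale; logits,
#'   probabilities, ...).
#' @param labels Vector of class labels: 0/1, logical, or a factor with
#'   levels `positive`/`negative`.
#' @return The AUC, a number in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) abort("`scores` and `labels` lengths differ")
  m <- sum(y == 1)
  n <- sum(y == 0)
  if (m == 0 || n == 0) abort("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- as.character(labels)
    if (!all(lv %in% c("positive", "negative"))) {
      abort("factor/character labels must be 'positive'/'negative'")
    }
    return(as.numeric(lv == "positive"))
  }
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) abort("numeric labels must be 0/1")
  y
}

#' DeLong confidence interval for the ROC AUC
#'
#' Nonparametric variance estimate of the AUC from DeLong's structural
#' components (per-observation placement values), with a
#' normal-approximation confidence interval clipped to `[0, 1]`. When the
#' placements are constant — e.g. perfect separation — the variance is
#' zero and a zero-width interval at the point estimate is returned.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row: `auc`, `lower`, `upper`, `se`,
#'   `level`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  y <- as_binary_labels(labels)
  check_probability(level, "level")
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  m <- length(pos)
  n <- length(neg)
  if (m < 2 || n < 2) abort("need at least 2 observations of each class")

  # midrank placements: V10[i] = Pr(pos_i beats a random negative)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  auc <- mean(v10)
  s10 <- var(v10)
  s01 <- var(v01)
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    auc = auc,
    lower = max(0, auc - z * se),
    upper = min(1, auc + z * se),
    se = se,
    level = level
  )
}
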
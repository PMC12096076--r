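#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm runif rbinom dnorm qnorm var sd kmeans predict
#' @importFrom utils head
NULL

# dense rank by descending value, ties broken by accession so output is
# bit-stable across platforms
rank_desc <- function(x, accession) {
  ord <- order(-x, accession, method = "radix")
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_probability <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s", name,
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

label_levels <- c("positive", "negative", "unlabeled")
split_levels <- c("train", "val", "test", "none")

as_label_factor <- function(x) factor(as.character(x), levels = label_levels)
as_split_factor <- function(x) factor(as.character(x), levels = split_levels)

# serialize double columns at full (round-trip) precision; text formats
# truncate to 15 significant digits otherwise
fmt_doubles <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- NA_character_
      df[[col]] <- v
    }
  }
  df
}
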
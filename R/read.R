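#' Read a per-protein evidence table
#'
#' Reads a delimited text file with one row per identified protein and
#' returns a validated evidence tibble. Each protein carries a raw
#' probability (the search pipeline's posterior of presence, in `[0, 1]`),
#' and/or a raw protein score on an arbitrary positive scale (to be
#' converted to a probability with [fit_score_mixture()]), and optionally
#' an mRNA expression value measured under comparable conditions.
#'
#' Column names are configurable so tables exported from any search
#' pipeline can be read without renaming. A *default* column name that is
#' absent from the file is silently skipped; a column name you supply
#' explicitly must exist.
#'
#' @param path Path to a delimited text file with a header row.
#' @param accession_col Name of the protein identifier column.
#' @param probability_col Name of the raw probability column.
#' @param score_col Name of the raw score column.
#' @param mrna_col Name of the mRNA expression column.
#' @param delim Field delimiter. Default `NULL` infers `","` for `.csv`
#'   files and tab otherwise.
#'
#' @return A tibble with columns `accession` and whichever of
#'   `raw_probability`, `raw_score`, `mrna_expression` were found, one row
#'   per protein, in file order.
#'
#' @details Validation is strict: duplicated accessions are an error, as is
#'   any unparseable or missing value in a present probability/score column
#'   (reported with its row number), a probability outside `[0, 1]`, or a
#'   negative score. Every protein must carry at least one of the two
#'   evidence columns.
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("accession,raw_probability", "P1,0.9", "P2,0.5"), tf)
#' read_protein_table(tf)
#' @export
read_protein_table <- function(path,
                               accession_col = "accession",
                               probability_col = "raw_probability",
                               score_col = "raw_score",
                               mrna_col = "mrna_expression",
                               delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, trim_ws = TRUE)

  explicit <- c(
    accession = TRUE, # always required
    probability = !missing(probability_col),
    score = !missing(score_col),
    mrna = !missing(mrna_col)
  )
  cols <- c(accession = accession_col, probability = probability_col,
            score = score_col, mrna = mrna_col)
  for (role in names(cols)) {
    if (explicit[[role]] && !cols[[role]] %in% names(raw)) {
      abort(sprintf("column `%s` (%s) not found in %s", cols[[role]], role, path))
    }
  }
  have <- vapply(cols, function(nm) nm %in% names(raw), logical(1))
  if (!have[["probability"]] && !have[["score"]]) {
    abort("table has neither a probability nor a score column")
  }

  out <- tibble::tibble(accession = raw[[cols[["accession"]]]])
  if (anyNA(out$accession) || any(!nzchar(out$accession))) {
    abort("empty or missing protein accession(s)")
  }
  dup <- out$accession[duplicated(out$accession)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate accession(s): %s", paste(unique(dup), collapse = ", ")))
  }

  parse_strict <- function(role, target, check) {
    txt <- raw[[cols[[role]]]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val))
    if (length(bad) > 0) {
      abort(sprintf("unparseable %s value(s) in column `%s` at row(s): %s",
                    target, cols[[role]], paste(bad, collapse = ", ")))
    }
    check(val)
    val
  }
  if (have[["probability"]]) {
    out$raw_probability <- parse_strict("probability", "probability", function(v) {
      bad <- which(v < 0 | v > 1)
      if (length(bad) > 0) {
        abort(sprintf("raw probability outside [0, 1] at row(s): %s",
                      paste(bad, collapse = ", ")))
      }
    })
  }
  if (have[["score"]]) {
    out$raw_score <- parse_strict("score", "score", function(v) {
      bad <- which(v < 0)
      if (length(bad) > 0) {
        abort(sprintf("negative raw score at row(s): %s", paste(bad, collapse = ", ")))
      }
    })
  }
  if (have[["mrna"]]) {
    out$mrna_expression <- suppressWarnings(as.numeric(raw[[cols[["mrna"]]]]))
  }
  out
}

#' Read a STRING-style protein interaction edge list
#'
#' Reads a whitespace- or tab-delimited edge list in the dialect of the
#' STRING `protein.links` downloads: two protein identifier columns and an
#' integer combined-confidence score in `[0, 1000]`. Taxon prefixes of the
#' form `"4932."` are stripped from identifiers, self-interactions are
#' dropped, and the two directed records STRING emits per interaction are
#' collapsed to one undirected edge keeping the maximum confidence.
#'
#' Identifier systems are not mapped: the caller must supply evidence
#' tables and edge lists that use matching accessions.
#'
#' @param path Path to the edge list file (header row required).
#' @param id_columns Character vector of length 2 naming the two protein
#'   identifier columns.
#' @param score_column Name of the combined-confidence score column.
#'
#' @return A tibble with columns `protein_a`, `protein_b`, `confidence`;
#'   one row per unordered protein pair, with `protein_a < protein_b`.
#' @export
read_string_edges <- function(path,
                              id_columns = c("protein1", "protein2"),
                              score_column = "combined_score") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (ncol(raw) < 3) abort("edge list must have at least 3 columns")
  needed <- c(id_columns, score_column)
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("edge list column(s) not found: %s", paste(miss, collapse = ", ")))
  }
  conf <- suppressWarnings(as.numeric(raw[[score_column]]))
  bad <- which(is.na(conf) | conf != round(conf) | conf < 0 | conf > 1000)
  if (length(bad) > 0) {
    abort(sprintf("malformed confidence score at row(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  strip_taxon <- function(x) sub("^[0-9]+\\.", "", x)
  a <- strip_taxon(raw[[id_columns[[1]]]])
  b <- strip_taxon(raw[[id_columns[[2]]]])

  keep <- a != b # self-loops dropped
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  tibble::tibble(protein_a = lo, protein_b = hi, confidence = as.integer(conf)) |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Filter interaction edges by combined confidence
#'
#' Keeps edges whose confidence is at least `min_confidence` (inclusive).
#' STRING's "medium confidence" convention corresponds to a threshold
#' of 400 on the 0--1000 combined score.
#'
#' @param edges Edge tibble as returned by [read_string_edges()].
#' @param min_confidence Minimum combined score, in `[0, 1000]`.
#' @return The filtered edge tibble, original order preserved.
#' @export
filter_edges <- function(edges, min_confidence = 400) {
  stopifnot(is.data.frame(edges), "confidence" %in% names(edges))
  if (!is_scalar_number(min_confidence) || min_confidence < 0 || min_confidence > 1000) {
    abort("`min_confidence` must be a single number in [0, 1000]")
  }
  dplyr::filter(edges, .data$confidence >= min_confidence)
}
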
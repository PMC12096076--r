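#' Specification for a synthetic proteomics dataset
#'
#' Describes the generative model the package assumes about real data: a
#' sparse protein--protein-interaction graph with community structure
#' (stochastic block model), protein presence planted assortatively over
#' the communities (a module is "active" with some probability; proteins
#' in active modules are mostly present, in inactive modules mostly
#' absent), noisy identification evidence (log protein scores drawn from
#' a two-component Gaussian mixture, with a fraction of truly present
#' proteins drawn from the absent component in any given experiment —
#' the abundance-driven false-negative problem), replicate experiments
#' with independent detection noise for ground-truth labeling, and mRNA
#' detection correlated with presence.
#'
#' @param n_proteins Number of proteins (default 2000).
#' @param n_modules Number of graph communities (default 20, >= 2).
#' @param intra_module_edge_prob,inter_module_edge_prob Edge
#'   probabilities inside / between modules (intra >= inter; defaults
#'   0.05 / 0.001 give mean degree around 7).
#' @param module_presence_prob Probability that a module is active
#'   (default 0.5).
#' @param within_active_presence_prob Probability a protein in an active
#'   module is present; proteins in inactive modules are present with
#'   the complementary probability (default 0.9, so 0.1 in inactive
#'   modules).
#' @param score_separation Gap between the positive and negative
#'   log-score component locations, in units of their (unit) scale
#'   (default 2).
#' @param false_negative_rate Per-experiment probability that a present
#'   protein's score is drawn from the absent component (default 0.3).
#'   Draws are independent across the main evidence table and each
#'   replicate, mimicking run-to-run detection noise.
#' @param mrna_sensitivity,mrna_specificity Probability of detecting the
#'   transcript of a present protein / of not detecting one for an
#'   absent protein (defaults 0.9 / 0.8).
#' @param n_replicates Number of replicate evidence tables used for
#'   ground-truth labeling (default 7).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 2000, n_modules = 20,
                           intra_module_edge_prob = 0.05,
                           inter_module_edge_prob = 0.001,
                           module_presence_prob = 0.5,
                           within_active_presence_prob = 0.9,
                           score_separation = 2,
                           false_negative_rate = 0.3,
                           mrna_sensitivity = 0.9,
                           mrna_specificity = 0.8,
                           n_replicates = 7,
                           seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins", min = 4L)
  n_modules <- check_count(n_modules, "n_modules", min = 2L)
  check_probability(intra_module_edge_prob, "intra_module_edge_prob")
  check_probability(inter_module_edge_prob, "inter_module_edge_prob")
  if (intra_module_edge_prob < inter_module_edge_prob) {
    abort("`intra_module_edge_prob` must be >= `inter_module_edge_prob`")
  }
  check_probability(module_presence_prob, "module_presence_prob")
  check_probability(within_active_presence_prob, "within_active_presence_prob")
  if (!is_scalar_number(score_separation) || score_separation < 0) {
    abort("`score_separation` must be a nonnegative number")
  }
  check_probability(false_negative_rate, "false_negative_rate")
  check_probability(mrna_sensitivity, "mrna_sensitivity")
  check_probability(mrna_specificity, "mrna_specificity")
  n_replicates <- check_count(n_replicates, "n_replicates")
  structure(
    list(n_proteins = n_proteins, n_modules = n_modules,
         intra_module_edge_prob = intra_module_edge_prob,
         inter_module_edge_prob = inter_module_edge_prob,
         module_presence_prob = module_presence_prob,
         within_active_presence_prob = within_active_presence_prob,
         score_separation = score_separation,
         false_negative_rate = false_negative_rate,
         mrna_sensitivity = mrna_sensitivity,
         mrna_specificity = mrna_specificity,
         n_replicates = n_replicates, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# one experiment's worth of evidence: scores + posterior-transform
# probabilities; the positive/negative component weights used for the
# posterior are the marginal ones implied by the spec
draw_evidence <- function(present, spec) {
  n <- length(present)
  from_pos <- present & (runif(n) >= spec$false_negative_rate)
  log_score <- rnorm(n, mean = ifelse(from_pos, spec$score_separation, 0), sd = 1)
  p_present <- spec$module_presence_prob * spec$within_active_presence_prob +
    (1 - spec$module_presence_prob) * (1 - spec$within_active_presence_prob)
  w_pos <- p_present * (1 - spec$false_negative_rate)
  prob <- mixture_posterior(log_score, w_pos, spec$score_separation, 1, 0, 1)
  list(score = exp(log_score), probability = prob)
}

#' Generate a synthetic proteomics dataset
#'
#' Draws a full dataset under a [synthetic_spec()]: the PPI edge list,
#' the main evidence table (raw score, raw probability, mRNA
#' expression), replicate evidence tables for ground-truth labeling, the
#' mRNA detection table and the planted truth. All randomness flows from
#' `spec$seed`, so identical specs give byte-identical outputs.
#'
#' @param spec A `synthetic_spec`.
#' @return A list of class `ppi_simulation` with tibbles `proteins`
#'   (accession, raw_score, raw_probability, mrna_expression), `edges`
#'   (protein_a, protein_b, confidence), `replicates` (accession,
#'   replicate, probability), `mrna` (accession, mrna_detected,
#'   mrna_expression), `truth` (accession, present, module) and the
#'   `spec` itself.
#' @export
simulate_ppi_data <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_proteins
    acc <- sprintf("P%05d", seq_len(n))
    module <- rep(seq_len(spec$n_modules), length.out = n)
    module <- sort(module)

    # stochastic block model graph
    block_sizes <- tabulate(module, spec$n_modules)
    pref <- matrix(spec$inter_module_edge_prob, spec$n_modules, spec$n_modules)
    diag(pref) <- spec$intra_module_edge_prob
    g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = block_sizes)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- tibble::tibble(
      protein_a = acc[pmin(el[, 1], el[, 2])],
      protein_b = acc[pmax(el[, 1], el[, 2])],
      confidence = sample(400:999, nrow(el), replace = TRUE)
    )

    # planted presence, assortative over modules
    active <- runif(spec$n_modules) < spec$module_presence_prob
    p_present <- ifelse(active[module], spec$within_active_presence_prob,
                        1 - spec$within_active_presence_prob)
    present <- runif(n) < p_present

    # main evidence table
    ev <- draw_evidence(present, spec)

    # mRNA: detection tracks presence; expression higher for present
    detected <- ifelse(present, runif(n) < spec$mrna_sensitivity,
                       runif(n) >= spec$mrna_specificity)
    expression <- ifelse(detected,
                         exp(rnorm(n, mean = ifelse(present, 2, 0.5), sd = 1)),
                         0)

    proteins <- tibble::tibble(
      accession = acc,
      raw_score = ev$score,
      raw_probability = ev$probability,
      mrna_expression = expression
    )
    mrna <- tibble::tibble(accession = acc, mrna_detected = detected,
                           mrna_expression = expression)
    truth <- tibble::tibble(accession = acc, present = present, module = module)

    replicates <- purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
      rv <- draw_evidence(present, spec)
      tibble::tibble(accession = acc, replicate = r, probability = rv$probability)
    })

    structure(
      list(proteins = proteins, edges = edges, replicates = replicates,
           mrna = mrna, truth = truth, spec = spec),
      class = "ppi_simulation"
    )
  })
}

#' @export
print.ppi_simulation <- function(x, ...) {
  cat(sprintf(
    "<ppi_simulation> %d proteins (%d present), %d edges, %d replicates, seed %d\n",
    nrow(x$proteins), sum(x$truth$present), nrow(x$edges),
    x$spec$n_replicates, x$spec$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the exact file formats the readers consume — `proteins.tsv`
#' (evidence table), `edges.txt` (STRING `protein.links` dialect),
#' `replicates.tsv`, `mrna.tsv` — plus the planted `truth.tsv` (kept
#' separate from the evidence) and a `manifest.json` recording the spec
#' and seed.
#'
#' @param sim A `ppi_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ppi_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(sim$proteins, file.path(dir, "proteins.tsv"), progress = FALSE)
  el <- sim$edges
  writeLines(
    c("protein1 protein2 combined_score",
      sprintf("%s %s %d", el$protein_a, el$protein_b, el$confidence)),
    file.path(dir, "edges.txt")
  )
  readr::write_tsv(sim$replicates, file.path(dir, "replicates.tsv"), progress = FALSE)
  readr::write_tsv(sim$mrna, file.path(dir, "mrna.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  jsonlite::write_json(c(list(format = "ppi_simulation"), unclass(sim$spec)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Presence assortativity of a labeled edge list
#'
#' Generator diagnostic: the fraction of edges whose endpoints share the
#' same presence state, minus its expectation under random relabeling of
#' the nodes (computed in closed form from the label counts). Positive
#' values mean presence clusters on the graph — the structural signal
#' message passing exploits.
#'
#' @param edges Edge tibble (`protein_a`, `protein_b`).
#' @param presence Logical vector named by accession, or a tibble
#'   `accession`, `present`.
#' @return A single number; 0 means no assortative structure.
#' @export
presence_assortativity <- function(edges, presence) {
  stopifnot(is.data.frame(edges), nrow(edges) >= 1)
  if (is.data.frame(presence)) {
    presence <- stats::setNames(as.logical(presence$present), presence$accession)
  }
  pa <- presence[edges$protein_a]
  pb <- presence[edges$protein_b]
  if (anyNA(pa) || anyNA(pb)) abort("presence missing for some edge endpoints")
  observed <- mean(pa == pb)
  n <- length(presence)
  n1 <- sum(presence)
  n0 <- n - n1
  expected <- (n1 * (n1 - 1) + n0 * (n0 - 1)) / (n * (n - 1))
  observed - expected
}
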
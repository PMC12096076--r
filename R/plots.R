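#' Plot the training trace of a model fit
#'
#' Training loss and validation AUC per epoch, with the selected epoch
#' marked.
#'
#' @param object A `gnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gnn_fit
#' @export
autoplot.gnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, c("loss", "val_auc"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training trace (dashed: selected epoch)") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' The mRNA coverage curve of the top-N unconfident proteins under
#' predicted vs raw probability ranking; when no coverage curve is
#' present, the scatter of predicted vs raw probability instead.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  if (!is.null(object$coverage_curve)) {
    long <- tidyr::pivot_longer(object$coverage_curve,
                                c("coverage_predicted", "coverage_raw"),
                                names_to = "ranking", values_to = "coverage")
    long$ranking <- sub("^coverage_", "", long$ranking)
    ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$coverage,
                                       colour = .data$ranking)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "top-N additionally identified proteins",
                    y = "fraction with detected mRNA",
                    colour = "ranked by") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$table,
                    ggplot2::aes(x = .data$raw_probability,
                                 y = .data$predicted_probability)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.7) +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
      ggplot2::labs(x = "raw probability", y = "predicted probability") +
      ggplot2::theme_minimal()
  }
}

#' Plot a protein subnetwork
#'
#' Draws the neighborhood of a center protein with nodes coloured by
#' predicted probability when available (raw probability otherwise), the
#' view used to inspect why the model promoted a protein.
#'
#' @param x A `protein_subnetwork` from [extract_subnetwork()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.protein_subnetwork <- function(x, ...) {
  nodes <- x$nodes
  g <- igraph::graph_from_data_frame(
    if (nrow(x$edges) > 0) x$edges else data.frame(protein_a = character(),
                                                   protein_b = character()),
    directed = FALSE,
    vertices = data.frame(name = nodes$accession)
  )
  xy <- igraph::layout_with_fr(g)
  nodes$x <- xy[match(nodes$accession, igraph::V(g)$name), 1]
  nodes$y <- xy[match(nodes$accession, igraph::V(g)$name), 2]
  fill_col <- if ("predicted_probability" %in% names(nodes) &&
                  !all(is.na(nodes$predicted_probability))) {
    "predicted_probability"
  } else {
    "raw_probability"
  }
  seg <- NULL
  if (nrow(x$edges) > 0) {
    seg <- data.frame(
      x = nodes$x[match(x$edges$protein_a, nodes$accession)],
      y = nodes$y[match(x$edges$protein_a, nodes$accession)],
      xend = nodes$x[match(x$edges$protein_b, nodes$accession)],
      yend = nodes$y[match(x$edges$protein_b, nodes$accession)]
    )
  }
  p <- ggplot2::ggplot()
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "grey70"
    )
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data[[fill_col]],
                   shape = .data$accession == x$center),
      size = 4, colour = "black"
    ) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 23, `FALSE` = 21),
                                guide = "none") +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick",
                                 limits = c(0, 1), name = fill_col) +
    ggplot2::labs(title = sprintf("%d-hop neighborhood of %s", x$hops,
                                  x$center)) +
    ggplot2::theme_void()
}
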
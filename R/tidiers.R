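#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted score mixture
#'
#' One row per mixture component: weight, location and scale on the
#' transformed (by default log) score scale.
#'
#' @param x A `score_mixture`.
#' @param ... Unused.
#' @return A tibble `component`, `weight`, `location`, `scale`.
#' @method tidy score_mixture
#' @export
tidy.score_mixture <- function(x, ...) {
  tibble::tibble(
    component = c("positive", "negative"),
    weight = c(x$mixing_weight_positive, 1 - x$mixing_weight_positive),
    location = c(x$positive_location, x$negative_location),
    scale = c(x$positive_scale, x$negative_scale)
  )
}

#' @rdname tidy.score_mixture
#' @return `glance()`: a one-row tibble `n`, `log_likelihood`,
#'   `n_iterations`, `converged`.
#' @method glance score_mixture
#' @export
glance.score_mixture <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    log_likelihood = x$log_likelihood_trace[length(x$log_likelihood_trace)],
    n_iterations = x$n_iterations,
    converged = x$converged
  )
}

#' Tidy a trained model fit
#'
#' The per-epoch metric trace: training loss and validation AUC.
#'
#' @param x A `gnn_fit`.
#' @param ... Unused.
#' @return A tibble `epoch`, `loss`, `val_auc`.
#' @method tidy gnn_fit
#' @export
tidy.gnn_fit <- function(x, ...) x$trace

#' @rdname tidy.gnn_fit
#' @return `glance()`: a one-row tibble with the conv type, selected
#'   epoch, validation AUC and epochs run.
#' @method glance gnn_fit
#' @export
glance.gnn_fit <- function(x, ...) {
  tibble::tibble(
    conv_type = x$model_config$conv_type,
    best_epoch = x$best_epoch,
    best_val_auc = x$best_val_auc,
    n_epochs_run = x$n_epochs_run
  )
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return `tidy()`: the AUC table (one row per scoring, with DeLong
#'   interval); `glance()`: a one-row tibble with predicted and raw AUC
#'   and the AUC gain.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$auc

#' @rdname tidy.evaluation_report
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  a <- x$auc
  tibble::tibble(
    auc_predicted = a$auc[a$scores == "predicted"],
    auc_raw = a$auc[a$scores == "raw"],
    auc_gain = a$auc[a$scores == "predicted"] - a$auc[a$scores == "raw"],
    n_unconfident = nrow(x$promoted)
  )
}
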
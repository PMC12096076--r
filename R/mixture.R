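#' Two-component mixture model for raw protein scores
#'
#' Some search pipelines emit only an arbitrary-scale protein score rather
#' than a probability of presence. `fit_score_mixture()` assumes the
#' scores of present and absent proteins follow a two-component mixture
#' and fits it by expectation--maximization, so the posterior probability
#' of belonging to the high-scoring (present) component can stand in as
#' the raw probability for all downstream stages.
#'
#' The default family is Gaussian--Gaussian on log-transformed scores:
#' protein scores are positive and heavy-tailed, and the log transform
#' makes both components approximately symmetric. The component with the
#' larger fitted location is always taken as the positive (present)
#' component, regardless of initialization. Initialization is k-means on
#' the transformed scores under the given seed; the M-step uses
#' responsibility-weighted means/variances and the E-step the usual Bayes
#' responsibilities, so the observed-data log-likelihood is non-decreasing
#' across iterations.
#'
#' @param scores Numeric vector of positive raw protein scores (>= 10
#'   values with nonzero variance).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-6).
#' @param seed Integer seed for the k-means initialization.
#' @param transform `"log"` (default) fits on `log(scores)`;
#'   `"identity"` fits on the raw scale for pipelines whose scores are
#'   already location-scale-like.
#'
#' @return An object of class `score_mixture`: mixing weight of the
#'   positive component, location/scale of both components, per-protein
#'   posteriors (`posteriors`), the log-likelihood trace, `converged`
#'   and `n_iterations`. Supports [tidy()], [glance()] and
#'   [posterior_probability()].
#' @export
fit_score_mixture <- function(scores, max_iter = 500, tol = 1e-6, seed = 1L,
                              transform = c("log", "identity")) {
  transform <- match.arg(transform)
  scores <- as.numeric(scores)
  if (anyNA(scores)) abort("`scores` must not contain missing values")
  if (length(scores) < 10) abort("need at least 10 scores to fit the mixture")
  if (transform == "log" && any(scores <= 0)) {
    abort("scores must be strictly positive for the log transform")
  }
  x <- if (transform == "log") log(scores) else scores
  if (var(x) == 0) abort("degenerate input: all scores are identical")
  max_iter <- check_count(max_iter, "max_iter")
  n <- length(x)

  km <- withr::with_seed(seed, kmeans(x, centers = 2, nstart = 5))
  mu <- as.numeric(km$centers)
  sg <- vapply(1:2, function(k) {
    s <- sd(x[km$cluster == k])
    if (is.na(s) || s < 1e-3) sd(x) / 2 else s
  }, numeric(1))
  pi1 <- mean(km$cluster == 1)
  pi1 <- min(max(pi1, 0.05), 0.95)

  loglik <- function(mu, sg, pi1) {
    sum(log(pi1 * dnorm(x, mu[1], sg[1]) + (1 - pi1) * dnorm(x, mu[2], sg[2])))
  }
  trace <- loglik(mu, sg, pi1)
  converged <- FALSE
  iter <- 0L
  resp <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: responsibilities of component 1
    d1 <- pi1 * dnorm(x, mu[1], sg[1])
    d2 <- (1 - pi1) * dnorm(x, mu[2], sg[2])
    resp <- d1 / (d1 + d2)
    # M-step
    n1 <- sum(resp)
    pi1 <- n1 / n
    mu[1] <- sum(resp * x) / n1
    mu[2] <- sum((1 - resp) * x) / (n - n1)
    sg[1] <- sqrt(sum(resp * (x - mu[1])^2) / n1)
    sg[2] <- sqrt(sum((1 - resp) * (x - mu[2])^2) / (n - n1))
    sg <- pmax(sg, 1e-6) # guard against component collapse
    ll <- loglik(mu, sg, pi1)
    trace <- c(trace, ll)
    if (abs(ll - trace[length(trace) - 1]) < tol) {
      converged <- TRUE
      break
    }
  }

  # positive component = larger location, independent of initialization
  pos <- which.max(mu)
  neg <- 3L - pos
  w_pos <- if (pos == 1L) pi1 else 1 - pi1
  posteriors <- mixture_posterior(x, w_pos, mu[pos], sg[pos], mu[neg], sg[neg])

  structure(
    list(
      mixing_weight_positive = w_pos,
      positive_location = mu[pos], positive_scale = sg[pos],
      negative_location = mu[neg], negative_scale = sg[neg],
      posteriors = posteriors,
      log_likelihood_trace = trace,
      converged = converged,
      n_iterations = iter,
      transform = transform,
      n = n
    ),
    class = "score_mixture"
  )
}

#' @export
print.score_mixture <- function(x, ...) {
  cat(sprintf(
    "<score_mixture> %s-scale Gaussian mixture, n = %d\n  positive: %.4g (weight) N(%.4g, %.4g)\n  negative: N(%.4g, %.4g)\n  %s after %d iterations (logLik %.4f)\n",
    x$transform, x$n, x$mixing_weight_positive,
    x$positive_location, x$positive_scale,
    x$negative_location, x$negative_scale,
    if (x$converged) "converged" else "NOT converged", x$n_iterations,
    x$log_likelihood_trace[length(x$log_likelihood_trace)]
  ))
  invisible(x)
}

#' Posterior probability of presence for new scores
#'
#' Applies a fitted [fit_score_mixture()] model to new raw scores and
#' returns the Bayes posterior of the positive (high-scoring) component,
#' i.e. the raw probability used as node evidence downstream.
#'
#' @param fit A `score_mixture` object.
#' @param scores Numeric vector of raw scores (strictly positive when the
#'   fit used the log transform).
#' @param allow_unconverged Apply the model even when EM did not converge
#'   (default `FALSE`).
#' @return Numeric vector of posteriors in `[0, 1]`.
#' @export
posterior_probability <- function(fit, scores, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "score_mixture"))
  if (!fit$converged && !allow_unconverged) {
    abort("mixture fit did not converge; pass allow_unconverged = TRUE to override")
  }
  scores <- as.numeric(scores)
  if (fit$transform == "log") {
    if (any(scores <= 0)) abort("scores must be strictly positive")
    x <- log(scores)
  } else {
    x <- scores
  }
  mixture_posterior(x, fit$mixing_weight_positive,
                    fit$positive_location, fit$positive_scale,
                    fit$negative_location, fit$negative_scale)
}

# posterior of the positive component, computed in log space so that
# scores far in either tail do not underflow to 0/0
mixture_posterior <- function(x, w_pos, mu_pos, sg_pos, mu_neg, sg_neg) {
  lp <- log(w_pos) + dnorm(x, mu_pos, sg_pos, log = TRUE)
  ln <- log1p(-w_pos) + dnorm(x, mu_neg, sg_neg, log = TRUE)
  1 / (1 + exp(ln - lp))
}
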
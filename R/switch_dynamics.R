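#' Inter-switch run lengths of a choice sequence
#'
#' Lengths of maximal runs of identical consecutive choices. The final
#' (right-censored) run is included uncorrected.
#'
#' @param choices non-empty choice sequence.
#' @return Integer vector of run lengths; their sum equals the number of
#'   trials.
#' @export
run_lengths <- function(choices) {
  if (length(choices) < 1) stop("empty choice sequence")
  rle(as.integer(choices))$lengths
}

geo_mixture_loglik <- function(values, counts, w, p) {
  # log f(x) = log sum_i w_i p_i (1-p_i)^(x-1), support {1, 2, ...}
  lx <- outer(values - 1, log1p(-p)) + rep(log(p) + log(w), each = length(values))
  m <- apply(lx, 1, max)
  sum(counts * (m + log(rowSums(exp(lx - m)))))
}

#' Fit a mixture of geometric distributions to run lengths by EM
#'
#' Geometric components on support \{1, 2, ...\} with pmf
#' `p (1 - p)^(x - 1)`; mean run length `1/p`. Closed-form M-step:
#' `p_i = sum(r_i) / sum(r_i x)`. Best of `n_restarts` is returned;
#' components are reported sorted by increasing mean. The mixture with
#' `n` components has `2 n - 1` free parameters, so
#' `AIC = 2 (2 n - 1) + 2 NLL`.
#'
#' @param intervals positive integer run lengths.
#' @param n_components number of components, 1..4.
#' @param n_restarts random restarts.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param seed integer seed.
#' @return Object of class `geo_mixture_fit`: `n_components`, `weights`,
#'   `success_probs`, `means`, `loglik`, `aic`, `n_iterations`, `seed`.
#' @export
fit_geo_mixture <- function(intervals, n_components, n_restarts = 20L,
                            tol = 1e-8, max_iter = 2000L, seed = 1L) {
  if (!n_components %in% 1:4) stop("n_components must be in 1..4")
  x <- as.integer(intervals)
  stopifnot(all(x >= 1))
  if (length(x) < 10 * n_components)
    warning("fewer than 10 intervals per component")
  # collapse to unique values for speed
  tab <- table(x)
  values <- as.integer(names(tab))
  counts <- as.numeric(tab)
  n <- sum(counts)
  clamp_p <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-12)
  if (n_components == 1) {
    p <- clamp_p(n / sum(counts * values))  # closed-form MLE 1 / mean
    ll <- geo_mixture_loglik(values, counts, 1, p)
    return(structure(list(n_components = 1L, weights = 1,
                          success_probs = p, means = 1 / p, loglik = ll,
                          aic = 2 * 1 + 2 * (-ll), n_iterations = 0L,
                          seed = as.integer(seed)),
                     class = "geo_mixture_fit"))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # init: success probs spread over the observed scale, random jitter
    p <- 1 / pmax(1, quantile(rep(values, counts),
                              probs = runif(n_components, 0.05, 0.95)))
    p <- clamp_p(as.numeric(p) * exp(runif(n_components, -0.3, 0.3)))
    w <- rep(1 / n_components, n_components)
    ll_prev <- -Inf
    iter <- 0L
    repeat {
      iter <- iter + 1L
      # E-step: responsibilities per unique value
      lx <- outer(values - 1, log1p(-p)) +
        rep(log(p) + log(w), each = length(values))
      m <- apply(lx, 1, max)
      lse <- m + log(rowSums(exp(lx - m)))
      resp <- exp(lx - lse)          # values x components
      ll <- sum(counts * lse)
      if (ll - ll_prev < tol && iter > 1L) break
      if (iter >= max_iter) break
      ll_prev <- ll
      # M-step with counts as weights
      rk <- colSums(resp * counts)
      w <- rk / n
      p <- clamp_p(rk / colSums(resp * counts * values))
    }
    if (is.null(best) || ll > best$ll)
      best <- list(w = w, p = p, ll = ll, iter = iter)
  }
  ord <- order(1 / best$p)  # increasing mean
  k_free <- 2 * n_components - 1
  structure(list(n_components = as.integer(n_components),
                 weights = best$w[ord], success_probs = best$p[ord],
                 means = 1 / best$p[ord], loglik = best$ll,
                 aic = 2 * k_free + 2 * (-best$ll),
                 n_iterations = best$iter, seed = as.integer(seed)),
            class = "geo_mixture_fit")
}

#' Draw run lengths from a geometric mixture
#'
#' @param n number of draws.
#' @param weights,means component weights and mean run lengths.
#' @param seed integer seed.
#' @return Integer vector of simulated run lengths.
#' @export
simulate_geo_mixture <- function(n, weights, means, seed = 1L) {
  stopifnot(length(weights) == length(means), abs(sum(weights) - 1) < 1e-9)
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  stats::rgeom(n, prob = 1 / means[comp]) + 1L
}

#' Select the number of mixture components by the elbow/AIC rule
#'
#' Fits (or accepts) mixtures with 1..`max_components` components and picks
#' the elbow: among component counts whose AIC improves on the next-smaller
#' model, the largest one whose incremental log-likelihood gain is at least
#' `gain_frac` of the largest single-step gain. If no count qualifies the
#' single component model is selected. The default fraction (2%) treats
#' gains below a few percent of the dominant gain as marginal; see the
#' methods vignette for how this threshold was fixed.
#'
#' @param intervals run lengths (ignored when `fits` supplied).
#' @param max_components largest mixture size considered.
#' @param gain_frac dominance threshold for later gains.
#' @param fits optional precomputed list of `geo_mixture_fit`s for
#'   1..`max_components` components on identical data.
#' @param ... passed to [fit_geo_mixture()].
#' @return List with `selected`, `loglik`, `aic`, `gains` and `fits`.
#' @export
select_components <- function(intervals = NULL, max_components = 4L,
                              gain_frac = 0.02, fits = NULL, ...) {
  if (is.null(fits)) {
    fits <- lapply(seq_len(max_components), function(k)
      fit_geo_mixture(intervals, n_components = k, ...))
  }
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  gains <- diff(ll)                       # gain of component n over n-1
  if (any(gains < -1e-6))
    warning("log-likelihood decreased with added components (EM failure?)")
  eligible <- which(diff(aic) < 0 & gains >= gain_frac * max(gains)) + 1L
  selected <- if (length(eligible) == 0) 1L else max(eligible)
  list(selected = as.integer(selected), loglik = ll, aic = aic,
       gains = gains, fits = fits)
}
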
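#' Negative log-likelihood of a session under a generative model
#'
#' Advances the model's latent state with the observed (choice, reward)
#' sequence — identical recursions to the simulation functions — and sums
#' `-log P(observed choice)` across trials. Per-trial probabilities below
#' 1e-300 are floored; the number of floored trials is attached as the
#' `"n_floored"` attribute.
#'
#' @param model `"kalman"`, `"rlck"` or `"dual"`.
#' @param params `kalman_params` or `rlck_params`.
#' @param session a `session_data` or a list with `choices` and `rewards`.
#' @param labels per-trial `"explore"`/`"exploit"` labels (dual-state only).
#' @return Non-negative scalar NLL.
#' @export
nll <- function(model, params, session, labels = NULL) {
  model <- match.arg(model, c("kalman", "rlck", "dual"))
  ch <- as.integer(session$choices)
  rw <- as.numeric(session$rewards)
  stopifnot(length(ch) == length(rw), all(ch %in% 1:3))
  if (model == "kalman") {
    f <- .kalman_filter_cpp(ch, rw, params$phi, params$omega, params$beta,
                            params$lambda_decay, params$theta_center,
                            params$obs_noise_var, params$diff_noise_var,
                            params$mu0, params$var0)
  } else {
    exploit <- integer(0)
    gamma <- 1
    if (model == "dual") {
      if (is.null(labels)) stop("dual-state nll requires labels")
      stopifnot(length(labels) == length(ch))
      exploit <- as.integer(labels == "exploit")
      gamma <- params$gamma
      if (is.null(gamma)) stop("dual-state nll requires params$gamma")
    }
    f <- .rlck_filter_cpp(ch, rw, params$alpha, params$alpha_c, params$tau,
                          params$beta, gamma, exploit, 0.5, 0)
  }
  if (f$n_floored > 0)
    warning(f$n_floored, " trial(s) hit the likelihood floor")
  structure(f$nll, n_floored = f$n_floored)
}

# Parameter transforms: optimization runs in an unconstrained space.
# beta, gamma: log; alpha, alpha_c, tau: logit; phi, omega: identity with a
# wide box enforced by clamping inside the objective.
model_param_spec <- function(model) {
  switch(model,
    kalman = list(
      names = c("phi", "omega", "beta"),
      to_nat = function(u) list(phi = max(-20, min(20, u[1])),
                                omega = max(-5, min(5, u[2])),
                                beta = exp(max(log(1e-3), min(log(50), u[3])))),
      start = function() c(runif(1, -2, 2), runif(1, -1, 1),
                           runif(1, log(0.1), log(20))),
      build = function(p) kalman_params(phi = p$phi, omega = p$omega,
                                        beta = p$beta),
      k = 3L),
    rlck = list(
      names = c("alpha", "alpha_c", "tau", "beta"),
      to_nat = function(u) list(alpha = plogis(u[1]), alpha_c = plogis(u[2]),
                                tau = plogis(u[3]),
                                beta = exp(max(log(1e-3), min(log(50), u[4])))),
      start = function() c(runif(3, -2, 2), runif(1, log(0.1), log(20))),
      build = function(p) rlck_params(alpha = p$alpha, alpha_c = p$alpha_c,
                                      tau = p$tau, beta = p$beta),
      k = 4L),
    dual = list(
      names = c("alpha", "alpha_c", "tau", "beta", "gamma"),
      to_nat = function(u) list(alpha = plogis(u[1]), alpha_c = plogis(u[2]),
                                tau = plogis(u[3]),
                                beta = exp(max(log(1e-3), min(log(50), u[4]))),
                                gamma = exp(max(log(1e-3), min(log(20), u[5])))),
      start = function() c(runif(3, -2, 2), runif(1, log(0.1), log(20)),
                           runif(1, log(0.2), log(5))),
      build = function(p) rlck_params(alpha = p$alpha, alpha_c = p$alpha_c,
                                      tau = p$tau, beta = p$beta,
                                      gamma = p$gamma),
      k = 5L))
}

#' Maximum-likelihood fit of a generative model to one session
#'
#' Multi-start derivative-free (Nelder-Mead) optimization in transformed
#' parameter space; the best of `n_restarts` local searches is returned.
#' Deterministic given `seed`.
#'
#' @param session a `session_data` (>= 50 trials recommended; shorter
#'   sessions trigger a warning).
#' @param model `"kalman"`, `"rlck"` or `"dual"`.
#' @param n_restarts number of random restarts.
#' @param seed integer seed.
#' @param labels explore/exploit labels, required for `"dual"`.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @return Object of class `fit_result`: fitted `params`, `nll`, `aic`,
#'   `k`, `model`, `converged`, `n_restarts`, `seed`.
#' @export
fit_model <- function(session, model, n_restarts = 20L, seed = 1L,
                      labels = NULL, maxit = 500L) {
  model <- match.arg(model, c("kalman", "rlck", "dual"))
  if (length(session$choices) < 50)
    warning("fewer than 50 trials; parameter estimates will be unstable")
  spec <- model_param_spec(model)
  obj <- function(u) {
    p <- spec$to_nat(u)
    as.numeric(nll(model, spec$build(p), session, labels))
  }
  set.seed(seed)
  best <- NULL
  any_conv <- FALSE
  for (r in seq_len(n_restarts)) {
    u0 <- spec$start()
    opt <- suppressWarnings(
      optim(u0, obj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-8)))
    conv <- opt$convergence == 0
    any_conv <- any_conv || conv
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  pars <- spec$to_nat(best$par)
  structure(list(model = model, params = spec$build(pars),
                 estimates = unlist(pars), nll = best$value,
                 k = spec$k, aic = 2 * spec$k + 2 * best$value,
                 converged = any_conv, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "fit_result")
}

#' AIC model comparison across candidate models
#'
#' Sums AIC per model over the compared unit (e.g. all sessions of a
#' group), then computes Akaike weights
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`.
#'
#' @param fits named list: one entry per model, each either a single
#'   `fit_result` or a list of `fit_result`s over the same sessions.
#' @return Data frame with columns `model`, `aic`, `delta_aic`, `weight`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2, !is.null(names(fits)))
  ns <- vapply(fits, function(f) {
    if (inherits(f, "fit_result")) 1L else length(f)
  }, integer(1))
  if (length(unique(ns)) != 1)
    stop("all models must be fitted to the same set of sessions")
  aic <- vapply(fits, function(f) {
    if (inherits(f, "fit_result")) f$aic
    else sum(vapply(f, function(x) x$aic, numeric(1)))
  }, numeric(1))
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  data.frame(model = names(fits), aic = aic, delta_aic = delta, weight = w,
             row.names = NULL)
}
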
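#' Structurally constrained explore/exploit HMM
#'
#' Four hidden states: one explore state and three exploit states (one per
#' arm). Emissions are fixed — explore emits each choice with probability
#' 1/3 (the maximum-entropy categorical), exploit state k emits choice k
#' with probability 1. Transitions are tied: every exploit state leaves for
#' explore with probability `a` (and stays otherwise — direct
#' exploit-to-exploit transitions are structurally zero), and explore
#' enters each specific exploit state with probability `b` (staying in
#' explore with probability `1 - 3 b`). Sessions start in explore with
#' probability 1. The model therefore has exactly two free parameters.
#'
#' @param a tied exploit-to-explore transition probability, in \[0, 1\].
#' @param b tied explore-to-each-exploit transition probability, in
#'   \[0, 1/3\].
#' @return Object of class `explore_hmm` with fields `a`, `b` and the
#'   implied 4 x 4 `transition` matrix (state order: explore, exploit1..3).
#' @export
explore_hmm <- function(a, b) {
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1 / 3 + 1e-12)
  P <- rbind(c(1 - 3 * b, b, b, b),
             c(a, 1 - a, 0, 0),
             c(a, 0, 1 - a, 0),
             c(a, 0, 0, 1 - a))
  dimnames(P) <- list(c("explore", "exploit1", "exploit2", "exploit3"),
                      c("explore", "exploit1", "exploit2", "exploit3"))
  structure(list(a = a, b = b, transition = P), class = "explore_hmm")
}

#' Log-likelihood of a choice sequence under the explore/exploit HMM
#'
#' Scaled forward recursion with the first trial forced into the explore
#' state.
#'
#' @param model an [explore_hmm()].
#' @param choices integer vector in 1..3.
#' @return Scalar log-likelihood.
#' @export
hmm_loglik <- function(model, choices) {
  choices <- as.integer(choices)
  if (length(choices) < 1) stop("empty choice sequence")
  stopifnot(all(choices %in% 1:3))
  .hmm_forward_backward_cpp(choices, model$a, model$b)$loglik
}

#' Fit the explore/exploit HMM by Baum-Welch with parameter tying
#'
#' E-step: forward-backward posteriors. M-step: expected transition counts
#' are pooled across tied entries — all exploit-to-explore mass estimates
#' `a`, all explore-to-exploit mass estimates `b`. Emissions and the
#' initial distribution are fixed and never re-estimated. Accepts a single
#' choice sequence or a list of sequences (pooled fit with shared
#' parameters). Best of `n_restarts` random initializations is returned.
#'
#' @param choices integer vector in 1..3, or a list of such vectors.
#' @param n_restarts random restarts of `(a, b)`.
#' @param tol stop when the log-likelihood gain falls below this.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed for the restart draws.
#' @return Object of class `hmm_fit`: `model` (an `explore_hmm`),
#'   `loglik`, `posteriors` (T x 4 matrix, or list of matrices for pooled
#'   fits), `n_iterations`, `converged`, `loglik_trace`, `seed`.
#' @export
fit_hmm <- function(choices, n_restarts = 10L, tol = 1e-6,
                    max_iter = 1000L, seed = 1L) {
  seqs <- if (is.list(choices)) choices else list(choices)
  seqs <- lapply(seqs, as.integer)
  lens <- vapply(seqs, length, integer(1))
  if (any(lens < 10)) warning("sequence(s) shorter than 10 trials")
  stopifnot(all(unlist(seqs) %in% 1:3))
  set.seed(seed)
  inits <- cbind(a = runif(n_restarts, 0.02, 0.5),
                 b = runif(n_restarts, 0.02, 0.33))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    a <- inits[r, "a"]; b <- inits[r, "b"]
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      e <- lapply(seqs, .hmm_forward_backward_cpp, a = a, b = b)
      ll <- sum(vapply(e, `[[`, numeric(1), "loglik"))
      trace <- c(trace, ll)
      if (ll - ll_prev < tol && iter > 1L) { converged <- TRUE; break }
      if (iter >= max_iter) break
      ll_prev <- ll
      n_x2e <- sum(vapply(e, `[[`, numeric(1), "n_exploit_to_explore"))
      n_xocc <- sum(vapply(e, `[[`, numeric(1), "n_exploit_occ"))
      n_e2x <- sum(vapply(e, `[[`, numeric(1), "n_explore_to_exploit"))
      n_eocc <- sum(vapply(e, `[[`, numeric(1), "n_explore_occ"))
      a <- if (n_xocc > 0) min(1 - 1e-10, max(1e-10, n_x2e / n_xocc)) else a
      b <- if (n_eocc > 0) {
        min(1 / 3 - 1e-10, max(1e-10, n_e2x / (3 * n_eocc)))
      } else b
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      post <- lapply(e, `[[`, "posteriors")
      best <- list(a = a, b = b, loglik = trace[length(trace)],
                   posteriors = if (is.list(choices)) post else post[[1]],
                   n_iterations = iter, converged = converged,
                   loglik_trace = trace)
    }
  }
  structure(list(model = explore_hmm(best$a, best$b), loglik = best$loglik,
                 posteriors = best$posteriors,
                 n_iterations = best$n_iterations,
                 converged = best$converged,
                 loglik_trace = best$loglik_trace, seed = as.integer(seed)),
            class = "hmm_fit")
}

#' Decode per-trial explore/exploit labels from a fitted HMM
#'
#' The three exploit states are collapsed and each trial is labelled by the
#' larger of the two smoothed posterior masses; ties go to explore (the
#' maximum-entropy state).
#'
#' @param fit an `hmm_fit` (single-sequence), or a T x 4 posterior matrix.
#' @return Character vector of `"explore"` / `"exploit"` labels.
#' @export
decode_states <- function(fit) {
  post <- if (inherits(fit, "hmm_fit")) fit$posteriors else fit
  if (is.list(post))
    return(lapply(post, decode_states))
  p_explore <- post[, 1]
  ifelse(p_explore >= 1 - p_explore, "explore", "exploit")
}

#' Strategy metrics from explore/exploit labels
#'
#' Conditional switch, win-stay/lose-shift and outcome-conditioned state
#' transition rates. Every conditional rate uses only trials where the
#' conditioning event occurs and is `NA` when the event never occurs.
#'
#' @param labels per-trial `"explore"`/`"exploit"` labels.
#' @param session a `session_data` (choices and rewards aligned with
#'   `labels`).
#' @param fit optional `hmm_fit` supplying the fitted `(a, b)`.
#' @return List of rates; see field names.
#' @export
strategy_metrics <- function(labels, session, fit = NULL) {
  ch <- session$choices
  rw <- session$rewards
  T_ <- length(ch)
  stopifnot(length(labels) == T_, length(rw) == T_)
  cond_rate <- function(event, cond) {
    if (!any(cond)) NA_real_ else mean(event[cond])
  }
  sw <- ch[-1] != ch[-T_]            # switch at t+1 relative to t
  lab_t <- labels[-T_]
  rw_t <- rw[-T_]
  to_explore <- labels[-1] == "explore" & lab_t == "exploit"
  to_exploit <- labels[-1] == "exploit" & lab_t == "explore"
  list(
    p_explore = mean(labels == "explore"),
    p_switch_given_explore = cond_rate(sw, lab_t == "explore"),
    p_switch_given_exploit = cond_rate(sw, lab_t == "exploit"),
    win_stay_explore = cond_rate(!sw, lab_t == "explore" & rw_t == 1),
    win_stay_exploit = cond_rate(!sw, lab_t == "exploit" & rw_t == 1),
    lose_shift_explore = cond_rate(sw, lab_t == "explore" & rw_t == 0),
    lose_shift_exploit = cond_rate(sw, lab_t == "exploit" & rw_t == 0),
    p_to_explore_given_reward =
      cond_rate(labels[-1] == "explore", lab_t == "exploit" & rw_t == 1),
    p_to_explore_given_omission =
      cond_rate(labels[-1] == "explore", lab_t == "exploit" & rw_t == 0),
    p_exploit_to_explore = cond_rate(to_explore, lab_t == "exploit"),
    p_explore_to_exploit = cond_rate(to_exploit, lab_t == "explore"),
    a = if (!is.null(fit)) fit$model$a else NA_real_,
    b = if (!is.null(fit)) fit$model$b else NA_real_)
}

#' Energy landscape of the explore/exploit dynamics
#'
#' Collapses the fitted chain to two states (explore leaves with rate
#' `3 b`, exploit with rate `a`), computes the stationary distribution
#' `pi_explore = a / (a + 3 b)`, maps state depths through the Boltzmann
#' relation `E_i = -ln(pi_i)` (unit temperature) and barrier heights
#' through the Arrhenius relation `barrier_i = -ln(P(leave i))`.
#'
#' @param model an `explore_hmm` (or `hmm_fit`).
#' @return List with `stationary` (explore, exploit), `energies`,
#'   `barriers` (explore_to_exploit, exploit_to_explore) and `absorbing`
#'   flag (TRUE when a or b is 0, giving infinite energies).
#' @export
energy_landscape <- function(model) {
  if (inherits(model, "hmm_fit")) model <- model$model
  a <- model$a
  b3 <- 3 * model$b
  absorbing <- a <= 0 || b3 <= 0
  pi_explore <- a / (a + b3)
  stationary <- c(explore = pi_explore, exploit = 1 - pi_explore)
  list(stationary = stationary,
       energies = -log(stationary),
       barriers = c(explore_to_exploit = -log(b3),
                    exploit_to_explore = -log(a)),
       absorbing = absorbing)
}

#' Simulate a choice sequence from an explore/exploit HMM
#'
#' The hidden chain starts in explore; explore trials emit a uniform
#' choice, exploit-k trials emit choice k.
#'
#' @param model an [explore_hmm()].
#' @param n_trials sequence length.
#' @param seed integer seed.
#' @return List with `choices` and hidden `states` (1 = explore, 1+k =
#'   exploit arm k).
#' @export
simulate_hmm_choices <- function(model, n_trials, seed = 1L) {
  set.seed(seed)
  P <- model$transition
  states <- integer(n_trials)
  choices <- integer(n_trials)
  s <- 1L
  for (t in seq_len(n_trials)) {
    states[t] <- s
    choices[t] <- if (s == 1L) sample_categorical(rep(1 / 3, 3)) else s - 1L
    s <- sample_categorical(P[s, ])
  }
  list(choices = choices, states = states)
}
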
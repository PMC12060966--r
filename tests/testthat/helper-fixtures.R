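# Shared fixtures: small deterministic objects built in code.

fixture_walk <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_walk(walk_config(n_trials = 300),
                                                seed = 42)
    cache
  }
})

# a session_data-shaped list from raw vectors
make_session <- function(choices, rewards, probs = NULL) {
  structure(list(choices = as.integer(choices), rewards = as.numeric(rewards),
                 probs = probs),
            class = "session_data")
}

# belief with given moments, bypassing the constructor defaults
make_belief <- function(mu, var, prev_choice = NA_integer_) {
  structure(list(mu = mu, var = var, prev_choice = prev_choice,
                 last_gain = NA_real_, last_pe = NA_real_),
            class = "kalman_belief")
}

# Independent oracle: HMM sequence likelihood by exhaustive enumeration of
# all 4^T hidden-state paths (structural zeros handled by the transition
# matrix itself).
hmm_loglik_brute <- function(model, choices) {
  T_ <- length(choices)
  P <- model$transition
  E <- rbind(rep(1 / 3, 3), diag(3))        # state x choice emission
  init <- c(1, 0, 0, 0)
  paths <- as.matrix(expand.grid(rep(list(1:4), T_)))
  pr <- init[paths[, 1]] * E[cbind(paths[, 1], choices[1])]
  if (T_ > 1) {
    for (t in 2:T_) {
      pr <- pr * P[cbind(paths[, t - 1], paths[, t])] *
        E[cbind(paths[, t], choices[t])]
    }
  }
  log(sum(pr))
}
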
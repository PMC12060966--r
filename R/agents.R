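#' Parameters of the Kalman-filter Bayesian learner
#'
#' Free parameters: uncertainty weight `phi` (how strongly estimated value
#' variance attracts choice), perseveration weight `omega` (value-free bonus
#' for repeating the previous choice) and softmax inverse temperature
#' `beta`. Fixed constants: observation-noise variance 0.25, diffusion-noise
#' variance 0.1, decay `lambda` = 0.99 toward center `theta` = 0.5.
#'
#' The initial belief is mean `theta` for every arm with the stationary
#' variance of the decay recursion, `diff_noise_var / (1 - lambda^2)`;
#' both can be overridden.
#'
#' @param phi uncertainty weight (may be negative).
#' @param omega perseveration weight.
#' @param beta inverse temperature, non-negative.
#' @param lambda_decay,theta_center decay rate and center.
#' @param obs_noise_var,diff_noise_var fixed noise variances.
#' @param mu0,var0 initial belief mean and variance (defaults derived).
#' @return Object of class `kalman_params`.
#' @export
kalman_params <- function(phi, omega = 0, beta = 1, lambda_decay = 0.99,
                          theta_center = 0.5, obs_noise_var = 0.25,
                          diff_noise_var = 0.1, mu0 = theta_center,
                          var0 = diff_noise_var / (1 - lambda_decay^2)) {
  stopifnot(beta >= 0, lambda_decay >= 0, lambda_decay <= 1,
            obs_noise_var > 0, diff_noise_var > 0, var0 > 0)
  structure(list(phi = phi, omega = omega, beta = beta,
                 lambda_decay = lambda_decay, theta_center = theta_center,
                 obs_noise_var = obs_noise_var,
                 diff_noise_var = diff_noise_var, mu0 = mu0, var0 = var0),
            class = "kalman_params")
}

#' Initial belief state of the Kalman learner
#'
#' @param params a [kalman_params()].
#' @return Object of class `kalman_belief` with fields `mu`, `var`,
#'   `prev_choice` (NA before the first trial), `last_gain`, `last_pe`.
#' @export
kalman_init_belief <- function(params) {
  structure(list(mu = rep(params$mu0, 3), var = rep(params$var0, 3),
                 prev_choice = NA_integer_, last_gain = NA_real_,
                 last_pe = NA_real_),
            class = "kalman_belief")
}

softmax <- function(x) {
  if (any(!is.finite(x))) stop("non-finite softmax input")
  e <- exp(x - max(x))
  e / sum(e)
}

#' Choice probabilities of the Kalman learner
#'
#' Softmax over `beta * (mu + phi * var + omega * I(prev_choice))`; the
#' perseveration bonus applies only to the previously chosen arm and is
#' absent on trial 1.
#'
#' @param belief a `kalman_belief`.
#' @param params a `kalman_params`.
#' @return Numeric vector of three probabilities summing to 1.
#' @export
kalman_choice_probs <- function(belief, params) {
  bonus <- numeric(3)
  if (!is.na(belief$prev_choice)) bonus[belief$prev_choice] <- params$omega
  softmax(params$beta * (belief$mu + params$phi * belief$var + bonus))
}

#' Kalman belief update after an observed outcome
#'
#' The chosen arm is updated with gain `k = var / (var + obs_noise_var)`:
#' `mu <- mu + k * (reward - mu)`, `var <- (1 - k) * var`. All arms then
#' decay toward the center: `mu <- lambda * mu + (1 - lambda) * theta`,
#' `var <- lambda^2 * var + diff_noise_var`.
#'
#' @param belief a `kalman_belief`.
#' @param choice chosen arm in 1..3.
#' @param reward outcome in \{0, 1\}.
#' @param params a `kalman_params`.
#' @return Updated `kalman_belief`.
#' @export
kalman_update <- function(belief, choice, reward, params) {
  if (!choice %in% 1:3) stop("choice must be 1, 2 or 3")
  mu <- belief$mu
  v <- belief$var
  gain <- v[choice] / (v[choice] + params$obs_noise_var)
  pe <- reward - mu[choice]
  mu[choice] <- mu[choice] + gain * pe
  v[choice] <- (1 - gain) * v[choice]
  lam <- params$lambda_decay
  mu <- lam * mu + (1 - lam) * params$theta_center
  v <- lam^2 * v + params$diff_noise_var
  structure(list(mu = mu, var = v, prev_choice = as.integer(choice),
                 last_gain = gain, last_pe = pe),
            class = "kalman_belief")
}

#' Parameters of the RL + choice-kernel models
#'
#' `gamma` (exploit-state learning-rate scaler) is present only for the
#' dual-state variant, which additionally requires externally supplied
#' explore/exploit labels when simulated or fitted.
#'
#' @param alpha value learning rate in \[0, 1\].
#' @param alpha_c choice-kernel learning rate in \[0, 1\].
#' @param tau value-bias weight in \[0, 1\].
#' @param beta inverse temperature, non-negative.
#' @param gamma exploit-state learning-rate scaler (`NULL` for plain RLCK).
#' @return Object of class `rlck_params`.
#' @export
rlck_params <- function(alpha, alpha_c, tau, beta, gamma = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, alpha_c >= 0, alpha_c <= 1,
            tau >= 0, tau <= 1, beta >= 0,
            is.null(gamma) || gamma >= 0)
  structure(list(alpha = alpha, alpha_c = alpha_c, tau = tau, beta = beta,
                 gamma = gamma),
            class = "rlck_params")
}

#' Initial state of the RLCK learner
#'
#' Action values start at the task's chance reward rate; the choice kernel
#' starts flat at zero.
#' @param q0,ck0 initial Q and CK values.
#' @return Object of class `rlck_state`.
#' @export
rlck_init_state <- function(q0 = 0.5, ck0 = 0) {
  structure(list(q = rep(q0, 3), ck = rep(ck0, 3),
                 prev_choice = NA_integer_),
            class = "rlck_state")
}

#' RLCK choice probabilities
#'
#' Softmax of `beta * (tau * Q + (1 - tau) * CK)`.
#' @param state an `rlck_state`.
#' @param params an `rlck_params`.
#' @return Three probabilities summing to 1.
#' @export
rlck_choice_probs <- function(state, params) {
  softmax(params$beta * (params$tau * state$q + (1 - params$tau) * state$ck))
}

#' RLCK state update
#'
#' Delta rule on the chosen arm's Q (rate `alpha`, scaled by `gamma` on
#' exploit-labelled trials in the dual-state variant); all three choice
#' kernels move toward their chosen-arm indicator at rate `alpha_c`.
#'
#' @param state an `rlck_state`.
#' @param choice,reward observed choice (1..3) and outcome (0/1).
#' @param params an `rlck_params`.
#' @param hmm_label optional `"explore"`/`"exploit"` label for the trial;
#'   required when `params$gamma` is set.
#' @return Updated `rlck_state`.
#' @export
rlck_update <- function(state, choice, reward, params, hmm_label = NULL) {
  if (!choice %in% 1:3) stop("choice must be 1, 2 or 3")
  rate <- params$alpha
  if (!is.null(params$gamma)) {
    if (is.null(hmm_label)) stop("dual-state update requires hmm_label")
    if (identical(hmm_label, "exploit")) rate <- params$gamma * params$alpha
  }
  q <- state$q
  q[choice] <- q[choice] + rate * (reward - q[choice])
  ind <- as.numeric(seq_len(3) == choice)
  ck <- state$ck + params$alpha_c * (ind - state$ck)
  structure(list(q = q, ck = ck, prev_choice = as.integer(choice)),
            class = "rlck_state")
}

#' Simulate one session of the bandit task
#'
#' Runs a generative agent over a reward walk: per trial, choice
#' probabilities are computed from the current latent state, a choice is
#' sampled, reward is drawn Bernoulli from the walk probability of the
#' chosen arm, and the state is updated. Returns the full record plus the
#' latent trajectory.
#'
#' @param model `"kalman"`, `"rlck"`, `"dual"` or `"random"` (uniform
#'   chooser, the beta = 0 reference agent).
#' @param params `kalman_params` or `rlck_params` matching `model`
#'   (ignored for `"random"`).
#' @param walk a `reward_walk` (or probability matrix).
#' @param seed integer seed.
#' @param n_trials number of trials (default: full walk).
#' @param labels explore/exploit labels per trial, required for `"dual"`.
#' @return Object of class `session_data`: list with `choices`, `rewards`,
#'   `probs` (walk), `latent` (per-trial state trajectory), `model`,
#'   `params`, `seed`.
#' @export
simulate_session <- function(model, params = NULL, walk, seed = 1L,
                             n_trials = NULL, labels = NULL) {
  probs <- if (inherits(walk, "reward_walk")) walk$probs else as.matrix(walk)
  if (is.null(n_trials)) n_trials <- nrow(probs)
  if (n_trials > nrow(probs)) stop("walk shorter than requested trials")
  model <- match.arg(model, c("kalman", "rlck", "dual", "random"))
  if (model == "dual" && is.null(labels))
    stop("dual-state simulation requires explore/exploit labels")
  set.seed(seed)
  choices <- integer(n_trials)
  rewards <- numeric(n_trials)
  if (model == "kalman") {
    belief <- kalman_init_belief(params)
    mu <- v <- pr <- matrix(NA_real_, n_trials, 3)
    for (t in seq_len(n_trials)) {
      p <- kalman_choice_probs(belief, params)
      mu[t, ] <- belief$mu; v[t, ] <- belief$var; pr[t, ] <- p
      choices[t] <- sample_categorical(p)
      rewards[t] <- as.numeric(stats::runif(1) < probs[t, choices[t]])
      belief <- kalman_update(belief, choices[t], rewards[t], params)
    }
    latent <- list(mu = mu, var = v, choice_probs = pr)
  } else if (model %in% c("rlck", "dual")) {
    state <- rlck_init_state()
    q <- ck <- pr <- matrix(NA_real_, n_trials, 3)
    for (t in seq_len(n_trials)) {
      p <- rlck_choice_probs(state, params)
      q[t, ] <- state$q; ck[t, ] <- state$ck; pr[t, ] <- p
      choices[t] <- sample_categorical(p)
      rewards[t] <- as.numeric(stats::runif(1) < probs[t, choices[t]])
      lab <- if (model == "dual") labels[t] else NULL
      state <- rlck_update(state, choices[t], rewards[t], params, lab)
    }
    latent <- list(q = q, ck = ck, choice_probs = pr)
  } else {
    for (t in seq_len(n_trials)) {
      choices[t] <- sample_categorical(rep(1 / 3, 3))
      rewards[t] <- as.numeric(stats::runif(1) < probs[t, choices[t]])
    }
    latent <- NULL
  }
  structure(list(choices = choices, rewards = rewards,
                 probs = probs[seq_len(n_trials), , drop = FALSE],
                 latent = latent, model = model, params = params,
                 seed = as.integer(seed)),
            class = "session_data")
}
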
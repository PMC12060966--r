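#' Configuration for the restless-bandit reward walk
#'
#' The reward probability of each of the three arms drifts on a 0.1 grid:
#' on every trial each arm independently has a `change_prob` chance of
#' moving up or down by `step_size` (equiprobably), with proposals that
#' would leave `[lower_bound, upper_bound]` cancelled. Whole walks are
#' rejection-sampled until each arm's time-mean and the grand mean lie
#' within the stated bands around 0.5, so that no arm is persistently rich
#' or poor and overall environmental richness is comparable across walks.
#'
#' @param n_trials number of trials in the session.
#' @param n_arms number of arms (fixed at 3).
#' @param change_prob per-arm, per-trial probability of a step proposal.
#' @param step_size size of a probability step.
#' @param lower_bound,upper_bound hard bounds on reward probabilities.
#' @param per_arm_mean_band allowed deviation of each arm's time-mean from 0.5.
#' @param grand_mean_band allowed deviation of the across-arm time-mean from 0.5.
#' @param initial_probs the three trial-1 reward probabilities.
#' @param max_rejections cap on rejection-sampling attempts.
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(n_trials = 300L, n_arms = 3L, change_prob = 0.1,
                        step_size = 0.1, lower_bound = 0.1, upper_bound = 0.9,
                        per_arm_mean_band = 0.02, grand_mean_band = 0.02,
                        initial_probs = c(0.9, 0.7, 0.3),
                        max_rejections = 100000L) {
  stopifnot(n_trials >= 1, n_arms == 3L,
            change_prob > 0 || change_prob == 0, change_prob < 1,
            step_size > 0,
            lower_bound > 0, lower_bound < upper_bound, upper_bound < 1,
            length(initial_probs) == n_arms,
            all(initial_probs >= lower_bound - 1e-12),
            all(initial_probs <= upper_bound + 1e-12))
  structure(list(n_trials = as.integer(n_trials), n_arms = as.integer(n_arms),
                 change_prob = change_prob, step_size = step_size,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 per_arm_mean_band = per_arm_mean_band,
                 grand_mean_band = grand_mean_band,
                 initial_probs = initial_probs,
                 max_rejections = as.integer(max_rejections)),
            class = "walk_config")
}

#' Generate an accepted reward walk by rejection sampling
#'
#' Candidate walks are generated from the stepping process and regenerated
#' from scratch until the per-arm and grand mean constraints hold.
#' Deterministic given `(config, seed)`.
#'
#' @param config a [walk_config()].
#' @param seed integer seed.
#' @return An object of class `reward_walk`: list with `probs`
#'   (`n_trials` x 3 matrix), `config`, `seed` and `n_rejected`.
#' @export
generate_walk <- function(config = walk_config(), seed = 1L) {
  stopifnot(inherits(config, "walk_config"))
  set.seed(seed)
  res <- .walk_generate_cpp(config$n_trials, config$n_arms,
                            config$change_prob, config$step_size,
                            config$lower_bound, config$upper_bound,
                            config$initial_probs,
                            config$per_arm_mean_band, config$grand_mean_band,
                            config$max_rejections)
  if (res$n_rejected < 0) {
    stop("walk generation infeasible: no candidate accepted within ",
         config$max_rejections, " attempts")
  }
  probs <- res$probs
  colnames(probs) <- paste0("p", seq_len(config$n_arms))
  structure(list(probs = probs, config = config, seed = as.integer(seed),
                 n_rejected = res$n_rejected),
            class = "reward_walk")
}

#' Generate one unconstrained candidate walk
#'
#' The raw stepping process without the mean-constraint rejection step;
#' used for diagnostics such as measuring the empirical change frequency.
#'
#' @inheritParams generate_walk
#' @return `n_trials` x 3 probability matrix.
#' @export
walk_candidate <- function(config = walk_config(), seed = 1L) {
  stopifnot(inherits(config, "walk_config"))
  set.seed(seed)
  .walk_candidate_cpp(config$n_trials, config$n_arms, config$change_prob,
                      config$step_size, config$lower_bound,
                      config$upper_bound, config$initial_probs)
}

#' Validate a reward walk against all generator constraints
#'
#' Independent re-check of the five walk invariants: bounds, grid steps,
#' fixed initial probabilities, per-arm mean band, grand mean band.
#'
#' @param walk a `reward_walk`.
#' @return `TRUE` invisibly, or an error naming the violated constraint.
#' @export
validate_walk <- function(walk) {
  stopifnot(inherits(walk, "reward_walk"))
  p <- walk$probs
  cf <- walk$config
  if (any(p < cf$lower_bound - 1e-9) || any(p > cf$upper_bound + 1e-9))
    stop("walk violates probability bounds")
  if (max(abs(p[1, ] - cf$initial_probs)) > 1e-9)
    stop("walk trial-1 probabilities differ from initial_probs")
  d <- abs(diff(p))
  if (!all(abs(d) < 1e-9 | abs(d - cf$step_size) < 1e-9))
    stop("walk contains steps that are neither 0 nor one step_size")
  if (any(abs(colMeans(p) - 0.5) > cf$per_arm_mean_band + 1e-9))
    stop("per-arm time-mean outside band")
  if (abs(mean(p) - 0.5) > cf$grand_mean_band + 1e-9)
    stop("grand time-mean outside band")
  invisible(TRUE)
}

#' Chance level of reward under a walk
#'
#' Grand mean reward probability over all arms and trials: the expected
#' reward rate of a uniformly random chooser.
#'
#' @param walk a `reward_walk` or a plain probability matrix.
#' @return Scalar probability.
#' @export
chance_level <- function(walk) {
  p <- if (inherits(walk, "reward_walk")) walk$probs else as.matrix(walk)
  mean(p)
}

#' Configuration for the practice-phase gate
#'
#' Practice uses 25 trials with fixed reward probabilities; to proceed a
#' participant must score above chance and demonstrate flexibility by
#' switching at least twice.
#'
#' @param n_trials practice length.
#' @param fixed_probs fixed per-arm reward probabilities.
#' @param min_points minimum points (sum of rewards) required.
#' @param min_switches minimum number of choice switches required.
#' @return An object of class `practice_config`.
#' @export
practice_config <- function(n_trials = 25L, fixed_probs = c(0.7, 0.3, 0.2),
                            min_points = 11L, min_switches = 2L) {
  stopifnot(min_points <= n_trials, length(fixed_probs) == 3)
  structure(list(n_trials = as.integer(n_trials), fixed_probs = fixed_probs,
                 min_points = as.integer(min_points),
                 min_switches = as.integer(min_switches)),
            class = "practice_config")
}

#' Apply the practice-phase gate
#'
#' @param choices integer choices in 1..3, length `config$n_trials`.
#' @param rewards 0/1 outcomes, same length.
#' @param config a [practice_config()].
#' @return List with `points`, `n_switches`, `passed`.
#' @export
practice_gate <- function(choices, rewards, config = practice_config()) {
  stopifnot(inherits(config, "practice_config"))
  if (length(choices) != config$n_trials || length(rewards) != config$n_trials)
    stop("choices/rewards must have length ", config$n_trials)
  stopifnot(all(choices %in% 1:3), all(rewards %in% 0:1))
  points <- as.integer(sum(rewards))
  n_switches <- sum(diff(choices) != 0)
  list(points = points, n_switches = as.integer(n_switches),
       passed = points >= config$min_points &&
         n_switches >= config$min_switches)
}

#' Write / read a walk as CSV
#'
#' Columns `trial, p1, p2, p3` with 1-based trial index.
#' @param walk a `reward_walk`.
#' @param path file path.
#' @return `write_walk` the path invisibly; `read_walk` a probability matrix.
#' @export
write_walk <- function(walk, path) {
  p <- if (inherits(walk, "reward_walk")) walk$probs else as.matrix(walk)
  df <- data.frame(trial = seq_len(nrow(p)), p)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk
#' @export
read_walk <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("trial", "p1", "p2", "p3") %in% names(df)))
  as.matrix(df[order(df$trial), c("p1", "p2", "p3")])
}
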
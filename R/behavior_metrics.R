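#' Model-free metrics for one session
#'
#' Reward acquisition relative to chance, optimal-choice rate and the
#' switch-rate family. "Reward vs chance" is reported both as the
#' expected-reward difference (mean walk probability of the chosen arm
#' minus the walk's chance level — low-variance form) and as the realized
#' difference (observed reward rate minus chance). Optimality ties (two
#' arms sharing the maximum) count as optimal for any tied arm. Every
#' conditional rate is `NA` when its conditioning event never occurs.
#'
#' @param session a `session_data`.
#' @param walk the walk that produced it (defaults to `session$probs`).
#' @return One-row data frame of metrics.
#' @export
session_metrics <- function(session, walk = NULL) {
  probs <- if (is.null(walk)) session$probs
           else if (inherits(walk, "reward_walk")) walk$probs
           else as.matrix(walk)
  ch <- session$choices
  rw <- session$rewards
  T_ <- length(ch)
  stopifnot(nrow(probs) >= T_)
  probs <- probs[seq_len(T_), , drop = FALSE]
  chance <- mean(probs)
  p_chosen <- probs[cbind(seq_len(T_), ch)]
  pmax_t <- apply(probs, 1, max)
  optimal <- p_chosen >= pmax_t - 1e-12
  sw <- ch[-1] != ch[-T_]
  cond_rate <- function(event, cond) {
    if (!any(cond)) NA_real_ else mean(event[cond])
  }
  prev_rw <- rw[-T_]
  data.frame(
    n_trials = T_,
    reward_rate = mean(rw),
    chance_level = chance,
    reward_vs_chance = mean(p_chosen) - chance,
    reward_vs_chance_realized = mean(rw) - chance,
    reward_vs_chance_ratio = mean(p_chosen) / chance,
    p_optimal = mean(optimal),
    p_switch = mean(sw),
    p_win_switch = cond_rate(sw, prev_rw == 1),
    p_lose_switch = cond_rate(sw, prev_rw == 0),
    p_incorrect_switch = cond_rate(sw, optimal[-T_]),
    reward_sensitivity = reward_sensitivity(session))
}

#' Reward sensitivity of staying behavior
#'
#' `(P(stay | prev reward) - P(stay | prev omission)) / P(stay)`, estimated
#' from consecutive-trial pairs. Near zero when staying is outcome-blind;
#' `NA` when either outcome class is absent or the participant never
#' stays.
#'
#' @param session a `session_data` (or list with `choices`, `rewards`).
#' @return Scalar, or `NA`.
#' @export
reward_sensitivity <- function(session) {
  ch <- session$choices
  rw <- session$rewards
  T_ <- length(ch)
  if (T_ < 2) return(NA_real_)
  stay <- ch[-1] == ch[-T_]
  prev_rw <- rw[-T_]
  p_stay <- mean(stay)
  if (p_stay == 0 || !any(prev_rw == 1) || !any(prev_rw == 0))
    return(NA_real_)
  (mean(stay[prev_rw == 1]) - mean(stay[prev_rw == 0])) / p_stay
}
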
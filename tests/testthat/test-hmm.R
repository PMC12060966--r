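test_that("structural constraints of the tied transition matrix hold", {
  m <- explore_hmm(a = 0.17, b = 0.08)
  P <- m$transition
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
  expect_equal(P["exploit1", "exploit2"], 0)
  expect_equal(P["exploit2", "exploit3"], 0)
  expect_equal(unname(P["explore", 2:4]), rep(0.08, 3))
  expect_equal(unname(P[2:4, "explore"]), rep(0.17, 3))
  expect_error(explore_hmm(0.5, 0.4))
})

test_that("forward log-likelihood matches hand computation", {
  expect_equal(hmm_loglik(explore_hmm(0.2, 0.1), 1), log(1 / 3))
  # T = 2, (1,1): stay explore (0.7) * 1/3 + enter exploit1 (0.1) * 1
  expect_equal(hmm_loglik(explore_hmm(0.2, 0.1), c(1, 1)),
               log((1 / 3) * (0.7 / 3 + 0.1)))
  expect_error(hmm_loglik(explore_hmm(0.2, 0.1), integer(0)), "empty")
})

test_that("forward recursion equals exhaustive path enumeration (T <= 8)", {
  set.seed(31)
  for (i in 1:25) {
    m <- explore_hmm(a = runif(1, 0.02, 0.9), b = runif(1, 0.01, 0.32))
    for (T_ in c(2, 4, 6, 8)) {
      ch <- sample(1:3, T_, replace = TRUE)
      expect_equal(hmm_loglik(m, ch), hmm_loglik_brute(m, ch),
                   tolerance = 1e-10)
    }
  }
})

test_that("Baum-Welch log-likelihood is non-decreasing", {
  sim <- simulate_hmm_choices(explore_hmm(0.15, 0.12), 300, seed = 32)
  fit <- fit_hmm(sim$choices, n_restarts = 4, seed = 33)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(fit$converged)
  post <- fit$posteriors
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)
})

test_that("fitted (a, b) are invariant to relabeling the choices", {
  sim <- simulate_hmm_choices(explore_hmm(0.2, 0.1), 400, seed = 34)
  perm <- c(2L, 3L, 1L)
  f1 <- fit_hmm(sim$choices, n_restarts = 4, seed = 35)
  f2 <- fit_hmm(perm[sim$choices], n_restarts = 4, seed = 35)
  expect_equal(f1$model$a, f2$model$a, tolerance = 1e-6)
  expect_equal(f1$model$b, f2$model$b, tolerance = 1e-6)
})

test_that("decoding identifies pure-exploit and pure-explore regimes", {
  f_const <- fit_hmm(rep(1L, 100), n_restarts = 4, seed = 36)
  lab <- decode_states(f_const)
  expect_lt(mean(lab == "explore"), 0.1)
  expect_true(all(lab[10:90] == "exploit"))
  f_alt <- fit_hmm(rep(1:3, length.out = 99), n_restarts = 4, seed = 37)
  expect_true(all(decode_states(f_alt) == "explore"))
})

test_that("strategy metrics count conditional events correctly", {
  labels <- c("exploit", "exploit", "explore", "exploit", "exploit",
              "explore", "explore", "exploit", "exploit", "exploit")
  ses <- make_session(choices = c(1, 1, 2, 2, 2, 3, 1, 1, 1, 1),
                      rewards = c(1, 0, 1, 1, 0, 0, 1, 1, 0, 1))
  sm <- strategy_metrics(labels, ses)
  expect_equal(sm$p_explore, 0.3)
  # exploit trials with a successor: t = 1,2,4,5,8,9; transitions to
  # explore at t = 2 and t = 5 -> 2/6
  expect_equal(sm$p_exploit_to_explore, 2 / 6)
  # switches after exploit trials: t=2 (1->2), t=5 (2->3) -> 2/6
  expect_equal(sm$p_switch_given_exploit, 2 / 6)
  # win-stay in exploit: rewarded exploit trials t=1,4,8 all stay
  expect_equal(sm$win_stay_exploit, 1)
  # lose-shift in exploit: omission exploit trials t=2,5,9: shift, shift, stay
  expect_equal(sm$lose_shift_exploit, 2 / 3)
  # conditioning event absent -> NA
  sm2 <- strategy_metrics(rep("exploit", 10), ses)
  expect_true(is.na(sm2$p_switch_given_explore))
})

test_that("energy landscape follows the two-state closed forms", {
  e <- energy_landscape(explore_hmm(a = 0.3, b = 0.1))
  expect_equal(unname(e$stationary), c(0.5, 0.5))
  expect_equal(e$energies[["explore"]], e$energies[["exploit"]])
  e2 <- energy_landscape(explore_hmm(a = 0.3, b = 0.1 / 3))
  expect_equal(e2$stationary[["explore"]], 0.75)
  expect_equal(e2$stationary[["exploit"]], 0.25)
  # deeper state has lower energy
  expect_lt(e2$energies[["explore"]], e2$energies[["exploit"]])
  expect_equal(e2$barriers[["exploit_to_explore"]], -log(0.3))
  expect_true(energy_landscape(explore_hmm(a = 0, b = 0.1))$absorbing)
})

test_that("decoding recovers simulated states accurately", {
  sim <- simulate_hmm_choices(explore_hmm(a = 0.1, b = 0.15), 300, seed = 38)
  fit <- fit_hmm(sim$choices, n_restarts = 4, seed = 39)
  lab <- decode_states(fit)
  truth <- ifelse(sim$states == 1, "explore", "exploit")
  expect_gte(mean(lab == truth), 0.85)
})
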
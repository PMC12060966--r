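test_that("kalman choice probabilities match hand-computed softmax", {
  p0 <- kalman_params(phi = 0, omega = 0, beta = 0)
  b <- kalman_init_belief(p0)
  expect_equal(kalman_choice_probs(b, p0), rep(1 / 3, 3))
  # symmetry: equal beliefs, no previous choice
  p1 <- kalman_params(phi = 2, omega = 1, beta = 5)
  expect_equal(kalman_choice_probs(kalman_init_belief(p1), p1), rep(1 / 3, 3))
  # mu = (1,0,0), negligible variance, beta = 1: softmax = e/(e+2) etc.
  pb <- kalman_params(phi = 0, omega = 0, beta = 1)
  b2 <- make_belief(c(1, 0, 0), rep(1e-12, 3))
  expect_equal(kalman_choice_probs(b2, pb),
               c(exp(1), 1, 1) / (exp(1) + 2), tolerance = 1e-9)
  # perseveration bonus only on the previously chosen arm
  pw <- kalman_params(phi = 0, omega = 0.7, beta = 1)
  b3 <- make_belief(rep(0.5, 3), rep(0.1, 3), prev_choice = 2L)
  pr <- kalman_choice_probs(b3, pw)
  expect_equal(pr[1], pr[3])
  expect_gt(pr[2], pr[1])
})

test_that("kalman update follows the four update equations", {
  p <- kalman_params(phi = 0, omega = 0, beta = 1)
  b <- make_belief(rep(0.5, 3), rep(0.25, 3))
  u <- kalman_update(b, 1, 1, p)
  expect_equal(u$last_gain, 0.5)            # var_pre = obs noise halves gain
  expect_equal(u$last_pe, 0.5)
  expect_equal(u$mu[1], 0.99 * 0.75 + 0.01 * 0.5)          # 0.7475
  expect_equal(u$var[1], 0.99^2 * 0.125 + 0.1)             # 0.2225125
  # unchosen arms only decay
  expect_equal(u$mu[2], 0.99 * 0.5 + 0.01 * 0.5)
  expect_equal(u$var[2], 0.99^2 * 0.25 + 0.1)
  expect_identical(u$prev_choice, 1L)
  # zero prediction error leaves the chosen mean at its decayed value
  b2 <- make_belief(c(1, 0.5, 0.5), rep(0.25, 3))
  u2 <- kalman_update(b2, 1, 1, p)
  expect_equal(u2$last_pe, 0)
  expect_equal(u2$mu[1], 0.99 * 1 + 0.01 * 0.5)
  expect_error(kalman_update(b, 4, 1, p), "choice")
})

test_that("decay recursions converge to their fixed points", {
  p <- kalman_params(phi = 0, omega = 0, beta = 1)
  b <- make_belief(c(0.9, 0.1, 0.5), c(0.01, 9, 1))
  # arm 1 never chosen: always update arm 2
  for (i in 1:2000) b <- kalman_update(b, 2, 1, p)
  expect_equal(b$mu[1], 0.5, tolerance = 1e-6)
  expect_equal(b$var[1], 0.1 / (1 - 0.99^2), tolerance = 1e-4)
  expect_equal(b$mu[3], 0.5, tolerance = 1e-6)
})

test_that("kalman gain is increasing in prior variance and within (0,1)", {
  p <- kalman_params(phi = 0, omega = 0, beta = 1)
  gains <- vapply(c(0.01, 0.1, 0.25, 1, 5, 50), function(v) {
    kalman_update(make_belief(rep(0.5, 3), rep(v, 3)), 1, 1, p)$last_gain
  }, numeric(1))
  expect_true(all(diff(gains) > 0))
  expect_true(all(gains > 0 & gains < 1))
})

test_that("rlck updates follow the delta rules", {
  st <- rlck_init_state(q0 = 0.5)
  p <- rlck_params(alpha = 0, alpha_c = 0.3, tau = 0.5, beta = 2)
  expect_equal(rlck_update(st, 1, 1, p)$q, st$q)      # alpha = 0
  p2 <- rlck_params(alpha = 0.2, alpha_c = 1, tau = 0.5, beta = 2)
  u <- rlck_update(st, 1, 1, p2)
  expect_equal(u$q[1], 0.6)                           # 0.5 + .2 * (1 - .5)
  expect_equal(u$ck, c(1, 0, 0))                      # alpha_c = 1: one-hot
  # dual-state: gamma scales the rate only on exploit trials
  pd <- rlck_params(alpha = 0.2, alpha_c = 0.3, tau = 0.5, beta = 2,
                    gamma = 0.5)
  ue <- rlck_update(st, 1, 1, pd, hmm_label = "explore")
  ux <- rlck_update(st, 1, 1, pd, hmm_label = "exploit")
  expect_equal(ue$q[1], 0.6)
  expect_equal(ux$q[1], 0.5 + 0.5 * 0.2 * 0.5)
  expect_error(rlck_update(st, 1, 1, pd), "hmm_label")
})

test_that("rlck choice probabilities match a hand softmax", {
  st <- rlck_init_state()
  st$q <- c(0.6, 0.5, 0.5); st$ck <- c(1, 0, 0)
  p <- rlck_params(alpha = 0.1, alpha_c = 0.1, tau = 0.5, beta = 2)
  x <- 2 * (0.5 * st$q + 0.5 * st$ck)
  expect_equal(rlck_choice_probs(st, p), exp(x) / sum(exp(x)))
  expect_equal(rlck_choice_probs(st, p)[1], 1 / (1 + 2 * exp(-1.1)),
               tolerance = 1e-12)
  # tau = 1 removes the kernel
  p1 <- rlck_params(alpha = 0.1, alpha_c = 0.1, tau = 1, beta = 2)
  st2 <- st; st2$ck <- c(5, -5, 0)
  expect_equal(rlck_choice_probs(st, p1), rlck_choice_probs(st2, p1))
  # tau = 0, one-hot kernel, large beta: chosen arm dominates
  p0 <- rlck_params(alpha = 0.1, alpha_c = 0.1, tau = 0, beta = 50)
  expect_gt(rlck_choice_probs(st, p0)[1], 0.999)
})

test_that("choice probabilities always normalize", {
  set.seed(99)
  for (i in 1:50) {
    b <- make_belief(rnorm(3), exp(rnorm(3)),
                     prev_choice = sample(c(NA, 1:3), 1))
    p <- kalman_params(phi = rnorm(1), omega = rnorm(1), beta = rexp(1, .2))
    expect_equal(sum(kalman_choice_probs(b, p)), 1, tolerance = 1e-12)
    st <- rlck_init_state(); st$q <- rnorm(3); st$ck <- rnorm(3)
    rp <- rlck_params(runif(1), runif(1), runif(1), rexp(1, .2))
    expect_equal(sum(rlck_choice_probs(st, rp)), 1, tolerance = 1e-12)
  }
})

test_that("simulate_session is reproducible and respects limits", {
  w <- fixture_walk()
  p <- kalman_params(phi = 1, omega = 0.3, beta = 5)
  s1 <- simulate_session("kalman", p, w, seed = 3)
  s2 <- simulate_session("kalman", p, w, seed = 3)
  expect_identical(s1$choices, s2$choices)
  expect_identical(s1$rewards, s2$rewards)
  expect_error(simulate_session("kalman", p, w, seed = 1, n_trials = 500),
               "shorter")
  expect_error(simulate_session("dual",
                                rlck_params(.1, .1, .5, 2, gamma = 1),
                                w, seed = 1),
               "labels")
})

test_that("a beta = 0 agent earns chance-level reward", {
  w <- fixture_walk()
  rates <- vapply(1:20, function(s) {
    mean(simulate_session("random", NULL, w, seed = s)$rewards)
  }, numeric(1))
  expect_equal(mean(rates), chance_level(w), tolerance = 0.02)
})

test_that("a greedy agent on a fixed best arm picks it almost always", {
  probs <- matrix(rep(c(0.9, 0.3, 0.3), each = 300), 300, 3)
  p <- kalman_params(phi = 0, omega = 0, beta = 50)
  s <- simulate_session("kalman", p, probs, seed = 6)
  expect_gt(mean(s$choices[100:300] == 1), 0.9)
})
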
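#include <Rcpp.h>
using namespace Rcpp;

// Random-walk candidate for one session: arm probabilities drift on a 0.1
// grid, each arm independently, with out-of-bound steps cancelled.
// Uses R's RNG so results are reproducible under set.seed().
static void walk_candidate(NumericMatrix probs, double change_prob,
                           double step, double lo, double hi,
                           const NumericVector &init) {
  const int T = probs.nrow(), K = probs.ncol();
  for (int k = 0; k < K; ++k) probs(0, k) = init[k];
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double cur = probs(t - 1, k);
      double nxt = cur;
      if (unif_rand() < change_prob) {
        double prop = cur + (unif_rand() < 0.5 ? step : -step);
        // cancel steps that would leave [lo, hi]
        if (prop >= lo - 1e-9 && prop <= hi + 1e-9) nxt = prop;
      }
      probs(t, k) = nxt;
    }
  }
}

// [[Rcpp::export(name = ".walk_candidate_cpp")]]
NumericMatrix walk_candidate_cpp(int n_trials, int n_arms, double change_prob,
                                 double step, double lo, double hi,
                                 NumericVector init) {
  NumericMatrix probs(n_trials, n_arms);
  walk_candidate(probs, change_prob, step, lo, hi, init);
  return probs;
}

// Rejection sampling: regenerate whole walks until the per-arm and grand
// time-mean constraints hold. Returns the accepted walk and the number of
// rejected candidates, or n_rejected = -1 on failure.
// [[Rcpp::export(name = ".walk_generate_cpp")]]
List walk_generate_cpp(int n_trials, int n_arms, double change_prob,
                       double step, double lo, double hi, NumericVector init,
                       double arm_band, double grand_band, int max_rejections) {
  NumericMatrix probs(n_trials, n_arms);
  int rejected = 0;
  while (rejected <= max_rejections) {
    walk_candidate(probs, change_prob, step, lo, hi, init);
    bool ok = true;
    double grand = 0.0;
    for (int k = 0; k < n_arms; ++k) {
      double s = 0.0;
      for (int t = 0; t < n_trials; ++t) s += probs(t, k);
      double m = s / n_trials;
      grand += m;
      if (std::fabs(m - 0.5) > arm_band + 1e-12) { ok = false; }
    }
    grand /= n_arms;
    if (std::fabs(grand - 0.5) > grand_band + 1e-12) ok = false;
    if (ok) return List::create(_["probs"] = probs, _["n_rejected"] = rejected);
    ++rejected;
  }
  return List::create(_["probs"] = R_NilValue, _["n_rejected"] = -1);
}

static inline void softmax3(const double *x, double *p) {
  double m = std::max(x[0], std::max(x[1], x[2]));
  double s = 0.0;
  for (int k = 0; k < 3; ++k) { p[k] = std::exp(x[k] - m); s += p[k]; }
  for (int k = 0; k < 3; ++k) p[k] /= s;
}

// Kalman-filter Bayesian learner run over an observed session.
// Beliefs are advanced with the observed (choice, reward); the returned
// per-trial quantities are the *pre-update* (prior) beliefs that generate
// the trial's choice probabilities.
// [[Rcpp::export(name = ".kalman_filter_cpp")]]
List kalman_filter_cpp(IntegerVector choices, NumericVector rewards,
                       double phi, double omega, double beta,
                       double lambda, double theta, double obs_var,
                       double diff_var, double mu0, double var0) {
  const int T = choices.size();
  NumericMatrix mu_pre(T, 3), var_pre(T, 3), probs(T, 3);
  double mu[3] = {mu0, mu0, mu0};
  double var[3] = {var0, var0, var0};
  int prev = 0; // 0 = none
  double nll = 0.0;
  int n_floored = 0;
  for (int t = 0; t < T; ++t) {
    double x[3], p[3];
    for (int k = 0; k < 3; ++k) {
      mu_pre(t, k) = mu[k];
      var_pre(t, k) = var[k];
      x[k] = beta * (mu[k] + phi * var[k] + ((prev == k + 1) ? omega : 0.0));
    }
    softmax3(x, p);
    for (int k = 0; k < 3; ++k) probs(t, k) = p[k];
    int c = choices[t];
    double pc = p[c - 1];
    if (pc < 1e-300) { pc = 1e-300; ++n_floored; }
    nll -= std::log(pc);
    // Bayesian update of the chosen arm
    double gain = var[c - 1] / (var[c - 1] + obs_var);
    mu[c - 1] += gain * (rewards[t] - mu[c - 1]);
    var[c - 1] *= (1.0 - gain);
    // decay of all arms toward the center
    for (int k = 0; k < 3; ++k) {
      mu[k] = lambda * mu[k] + (1.0 - lambda) * theta;
      var[k] = lambda * lambda * var[k] + diff_var;
    }
    prev = c;
  }
  return List::create(_["nll"] = nll, _["probs"] = probs,
                      _["mu_pre"] = mu_pre, _["var_pre"] = var_pre,
                      _["n_floored"] = n_floored);
}

// RL + choice kernel learner (with optional dual-state learning-rate
// scaling gamma applied on exploit-labelled trials).
// [[Rcpp::export(name = ".rlck_filter_cpp")]]
List rlck_filter_cpp(IntegerVector choices, NumericVector rewards,
                     double alpha, double alpha_c, double tau, double beta,
                     double gamma, IntegerVector exploit_labels,
                     double q0, double ck0) {
  const int T = choices.size();
  const bool dual = exploit_labels.size() == T;
  NumericMatrix q_pre(T, 3), ck_pre(T, 3), probs(T, 3);
  double q[3] = {q0, q0, q0};
  double ck[3] = {ck0, ck0, ck0};
  double nll = 0.0;
  int n_floored = 0;
  for (int t = 0; t < T; ++t) {
    double x[3], p[3];
    for (int k = 0; k < 3; ++k) {
      q_pre(t, k) = q[k];
      ck_pre(t, k) = ck[k];
      x[k] = beta * (tau * q[k] + (1.0 - tau) * ck[k]);
    }
    softmax3(x, p);
    for (int k = 0; k < 3; ++k) probs(t, k) = p[k];
    int c = choices[t];
    double pc = p[c - 1];
    if (pc < 1e-300) { pc = 1e-300; ++n_floored; }
    nll -= std::log(pc);
    double rate = alpha;
    if (dual && exploit_labels[t] == 1) rate = gamma * alpha;
    q[c - 1] += rate * (rewards[t] - q[c - 1]);
    for (int k = 0; k < 3; ++k) {
      double a_k = (k == c - 1) ? 1.0 : 0.0;
      ck[k] += alpha_c * (a_k - ck[k]);
    }
  }
  return List::create(_["nll"] = nll, _["probs"] = probs,
                      _["q_pre"] = q_pre, _["ck_pre"] = ck_pre,
                      _["n_floored"] = n_floored);
}

// Scaled forward-backward pass for the 4-state explore/exploit HMM.
// State 1 = explore (uniform emission 1/3); states 2..4 = exploit arm k
// (deterministic emission). Transitions: exploit->explore = a,
// explore->each exploit = b, exploit->other exploit = 0. Trial 1 starts
// in explore with probability 1.
// Returns loglik, smoothed posteriors, and pooled expected counts needed
// by the tied Baum-Welch M-step.
// [[Rcpp::export(name = ".hmm_forward_backward_cpp")]]
List hmm_forward_backward_cpp(IntegerVector choices, double a, double b) {
  const int T = choices.size();
  NumericMatrix alpha(T, 4), beta_m(T, 4), gamma(T, 4);
  NumericVector scale(T);
  // transition matrix
  double P[4][4] = {{1.0 - 3.0 * b, b, b, b},
                    {a, 1.0 - a, 0.0, 0.0},
                    {a, 0.0, 1.0 - a, 0.0},
                    {a, 0.0, 0.0, 1.0 - a}};
  auto emit = [&](int s, int y) -> double {
    return (s == 0) ? (1.0 / 3.0) : ((s == y) ? 1.0 : 0.0);
  };
  // forward
  {
    int y = choices[0];
    double s = 0.0;
    for (int i = 0; i < 4; ++i) {
      alpha(0, i) = (i == 0 ? 1.0 : 0.0) * emit(i, y);
      s += alpha(0, i);
    }
    scale[0] = s;
    for (int i = 0; i < 4; ++i) alpha(0, i) /= s;
  }
  for (int t = 1; t < T; ++t) {
    int y = choices[t];
    double s = 0.0;
    for (int j = 0; j < 4; ++j) {
      double acc = 0.0;
      for (int i = 0; i < 4; ++i) acc += alpha(t - 1, i) * P[i][j];
      alpha(t, j) = acc * emit(j, y);
      s += alpha(t, j);
    }
    scale[t] = s;
    if (s <= 0) stop("zero forward mass: impossible sequence under model");
    for (int j = 0; j < 4; ++j) alpha(t, j) /= s;
  }
  // backward
  for (int i = 0; i < 4; ++i) beta_m(T - 1, i) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    int y = choices[t + 1];
    for (int i = 0; i < 4; ++i) {
      double acc = 0.0;
      for (int j = 0; j < 4; ++j)
        acc += P[i][j] * emit(j, y) * beta_m(t + 1, j);
      beta_m(t, i) = acc / scale[t + 1];
    }
  }
  // posteriors and pooled transition expectations
  double n_x2e = 0.0, n_exploit_occ = 0.0; // exploit -> explore, exploit occupancy (t < T)
  double n_e2x = 0.0, n_explore_occ = 0.0; // explore -> exploit(any), explore occupancy (t < T)
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int i = 0; i < 4; ++i) {
      gamma(t, i) = alpha(t, i) * beta_m(t, i);
      s += gamma(t, i);
    }
    for (int i = 0; i < 4; ++i) gamma(t, i) /= s;
  }
  for (int t = 0; t < T - 1; ++t) {
    int y = choices[t + 1];
    for (int i = 0; i < 4; ++i) {
      for (int j = 0; j < 4; ++j) {
        if (P[i][j] <= 0.0) continue;
        double xi = alpha(t, i) * P[i][j] * emit(j, y) * beta_m(t + 1, j) /
                    scale[t + 1];
        if (i == 0 && j > 0) n_e2x += xi;
        if (i > 0 && j == 0) n_x2e += xi;
      }
    }
    n_explore_occ += gamma(t, 0);
    n_exploit_occ += gamma(t, 1) + gamma(t, 2) + gamma(t, 3);
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]);
  return List::create(_["loglik"] = ll, _["posteriors"] = gamma,
                      _["n_exploit_to_explore"] = n_x2e,
                      _["n_exploit_occ"] = n_exploit_occ,
                      _["n_explore_to_exploit"] = n_e2x,
                      _["n_explore_occ"] = n_explore_occ);
}
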
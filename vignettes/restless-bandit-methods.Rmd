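---
title: "Models and methods for restless-bandit explore/exploit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for restless-bandit explore/exploit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restlessbandit)
```

This vignette documents the models implemented in `restlessbandit`, the
assumptions behind them, the numerical and design choices that were
genuinely open, and what the synthetic-data tests do and do not establish.

## The task environment

The restless three-armed bandit presents three options whose reward
probabilities drift over time, forcing a continual explore/exploit
trade-off. The generator reproduces the standard design:

- per trial and per arm, an independent 10% chance of a ±0.1 step
  (directions equiprobable), on a 0.1 grid bounded in [0.1, 0.9];
- trial 1 fixed at (0.9, 0.7, 0.3);
- whole-walk rejection sampling until each arm's time-mean and the grand
  mean are within 50% ± 2 percentage points.

Three choices here were open and are fixed as follows:

- **Boundary handling.** A proposed step that would exit the bounds is
  *cancelled* (the probability stays put) rather than reflected. This
  keeps the support exactly on the 0.1 grid and respects the hard bound;
  the cost is that the *marginal* change frequency at the boundary states
  is below 10%, so empirical change-frequency checks condition on interior
  states (current probability in [0.2, 0.8]).
- **Rejection scope.** The whole walk is regenerated on constraint failure
  (no local repair), which is the simplest unbiased way to enforce the
  time-mean constraints. Acceptance is rare (order 10^-3^ to 10^-4^ for
  300 trials), so the sampler is implemented in compiled code and the
  rejection count is reported with every accepted walk.
- **Trial 1** is exempt from the stepping process (it is a fixed initial
  condition).

## The Kalman-filter Bayesian learner

Beliefs about each arm's reward rate are independent Gaussians. On each
trial the chosen arm `c` is updated with the Kalman gain

    k = sigma2_c / (sigma2_c + sigma2_O),    sigma2_O = 0.25
    mu_c    <- mu_c + k * (r - mu_c)
    sigma2_c <- (1 - k) * sigma2_c

after which **all** arms decay toward the center and diffuse:

    mu     <- lambda * mu + (1 - lambda) * theta,   lambda = 0.99, theta = 0.5
    sigma2 <- lambda^2 * sigma2 + sigma2_D,         sigma2_D = 0.1

Choice follows a softmax over `beta * (mu + phi * sigma2 + omega * I[repeat])`.
The three free parameters and their interpretation:

| parameter | meaning | typical fitted range |
|---|---|---|
| `phi` | uncertainty weight: how strongly estimated variance attracts (or, if negative, repels) choice | 0.05–2 |
| `beta` | softmax inverse temperature; low values = high decision noise | 0.5–20 |
| `omega` | value-free perseveration bonus for repeating the last choice | −0.5–1 |

Open points fixed here (and why):

- **Decay applies to every arm on every trial, including the arm just
  updated**, after the Bayesian update. The decay recursions are written
  for each choice on each trial, and this matches the standard
  Kalman-bandit formulation; whether the original implementation exempted
  the chosen arm is not recoverable from the description.
- **Initial belief**: mean `theta` (0.5) for all arms with the *stationary
  variance* of the decay recursion, `sigma2_D / (1 - lambda^2) ≈ 5.025`.
  No initial prior is stated anywhere; the stationary prior is
  parameter-free, maximally agnostic, and makes the first choice uniform.
  Both values are fields of `kalman_params()` and can be overridden.
- The perseveration indicator is undefined on trial 1 and treated as 0.
- `phi` is *not* sign-constrained when fitting (box [−20, 20]):
  uncertainty-averse behavior is representable.

The RL + choice-kernel model uses the standard delta rule on the chosen
arm, a kernel update of all three arms toward the chosen-arm indicator,
and a softmax over `beta * (tau * Q + (1 - tau) * CK)`. The dual-state
variant scales the learning rate by `gamma` on exploit-labelled trials;
labels come from a *separately fitted* HMM (two-stage procedure, no joint
estimation), mirroring how such models are identified in practice. A
published verbal description of this model mentions separate inverse
temperatures for value and kernel, but the accompanying equations show a
single `beta` with weight `tau`; the equation version (5 parameters) is
implemented.

## Fitting and model comparison

The likelihood of a session is the product over trials of the softmax
probability of the observed choice, with the latent state advanced by the
observed (choice, reward). The fitting and simulation modules share their
recursions only conceptually — the likelihood runs in compiled code, the
simulator in R — and a test asserts their per-trial log-probabilities agree
to 1e-10, so neither can drift from the other.

No optimizer is prescribed by the source material, so the package uses
multi-start Nelder-Mead (default 20 restarts) in a transformed space: log
for `beta` and `gamma`, logit for `alpha`, `alpha_c`, `tau`, identity with
wide clamped boxes for `phi` and `omega`. Per-trial probabilities are
floored at 1e-300 and the floor count is reported. Model comparison uses
AIC (`2k + 2·NLL`) summed over the compared unit and Akaike weights
`exp(-Delta/2)` normalized; AICc/BIC are deliberately not offered because
the comparison criterion is part of the replicated design.

## The explore/exploit HMM

Four states: one explore, three exploit (one per arm). Emissions are fixed
(uniform 1/3 in explore — the maximum-entropy categorical, which neither
requires nor precludes structured exploration — and deterministic in
exploit). Transitions are tied to two free parameters: every exploit state
exits to explore with probability `a`; explore enters each exploit state
with probability `b`. Exploit→exploit transitions are structurally zero
(switching exploitation targets requires passing through explore), and
sessions start in explore with probability 1.

Baum-Welch pools expected transition counts across tied entries
(`a = E[exploit→explore] / E[exploit occupancy]`,
`b = E[explore→exploit]/(3·E[explore occupancy])`); emissions and the
initial distribution are never re-estimated. Ten random restarts of
`(a, b) ~ U(0.02, 0.5) × U(0.02, 0.33)` guard against local optima;
the EM tolerance is 1e-6 on the log-likelihood.

**Decoding** uses the smoothed posterior with the three exploit states
collapsed: a trial is labelled explore when the explore posterior mass is
at least 1/2, with ties breaking toward explore (the maximum-entropy
state). Viterbi was the alternative; posterior decoding was chosen because
the per-trial explore probabilities are themselves needed by the strategy
metrics, and the collapsed two-way comparison is the quantity of interest.
This is a potential divergence from implementations that label by Viterbi
paths; on simulated data the two agree on the large majority of trials.

**Energy landscape.** The tied chain collapses exactly to a two-state
chain (explore leaves with rate `3b`, exploit with rate `a`), whose
stationary distribution is `pi_explore = a/(a + 3b)`. State depths use the
Boltzmann convention at unit temperature, `E_i = -ln(pi_i)`, and barrier
heights the Arrhenius convention, `-ln P(leave i)`. The exact equations of
the prior literature deferred to elsewhere are not reproduced; the
conventions here are stated in full and tested against the closed forms.

## Run-length mixtures

Inter-switch intervals (maximal runs of identical choices, the final
censored run included) are modelled as mixtures of geometric distributions
on support {1, 2, ...} — the discrete equivalent of exponential mixtures
for switching-time constants. The EM M-step is closed-form; the mixture
with `n` components has `2n - 1` free parameters.

Two choices deserve note:

- **Censoring.** The terminal run is included uncorrected. At 200–300
  trials with mean runs below 10 the bias is a fraction of a percent; no
  censoring treatment is described for the original analysis.
- **Component selection.** The published procedure identifies an elbow
  visually. The explicit rule here: among component counts whose AIC
  improves on the next-smaller model, pick the largest whose incremental
  log-likelihood gain is at least 2% of the largest single-step gain.
  The threshold was fixed once from the two reference constructions: on
  run lengths from a genuinely two-regime process the third component's
  gain is ~10^-13^ of the dominant gain, while in an equal-weight
  three-geometric mixture with means (1.5, 8, 40) the third component
  contributes ~6% — so any threshold in between separates the cases, and
  10% (an earlier working default) demonstrably does not.

## Cohort analysis

- **PCA with permutation test.** PCA on z-scored features; the null for
  each loading is built by shuffling every feature column *independently*
  (destroying inter-feature correlation, preserving marginals — the
  alternative, joint row shuffling, leaves the covariance intact and tests
  nothing). Because eigenvector order and sign are arbitrary under
  permutation, each null solution's components are matched to the observed
  ones by maximal absolute congruence before loadings enter the null.
  P-values use the add-one correction `(b + 1)/(n + 1)`.
- **Ward clustering.** Minimum-variance linkage (`ward.D2` on Euclidean
  distances, i.e. the squared-Euclidean update) over k = 2–6, scored by
  silhouette, Calinski-Harabasz and Davies-Bouldin. The convergent-evidence
  narrative is codified as: maximize silhouette, tie-break by
  Calinski-Harabasz.
- **ICC.** Two-way consistency, single measure — ICC(3,1):
  `(MS_rows − MS_err)/(MS_rows + MS_err)` for two sessions. Insensitive to
  additive session offsets by construction.
- **Adjusted Pearson residuals**:
  `(O − E)/sqrt(E(1 − row/N)(1 − col/N))`, identical to
  `chisq.test()$stdres`, which the tests use as an independent oracle.
- In radar-style subtype profiles the two task-derived parameters are
  sign-flipped for display so that peripheral always reads as "more
  stable/less noisy"; internally the table stores the fitted `phi` and
  `beta` themselves.

## The synthetic cohort: what it does and does not establish

No participant-level data are distributed with the design this package
implements, so `simulate_cohort()` generates a stated stand-in world:

- Sessions of 200 trials (default; a second 300-trial session can be
  added) on freshly generated constrained walks.
- The Kalman learner is the sole generative engine for default cohorts
  (it is the winning model in the replicated comparison); RLCK cohorts are
  available for model-recovery exercises.
- Group differences are carried by the parameter distributions:
  control-like `phi ~ LN(log 0.20, 0.5)`, `beta ~ LN(log 5.2, 0.35)`;
  EP-like `phi ~ LN(log 0.34, 0.5)`, `beta ~ LN(log 4.1, 0.35)`;
  `omega ~ N(0.25, 0.15)` in both (no group difference). The location
  parameters were calibrated once, by simulating 150 agents per setting
  and reading off HMM-labelled exploration, to land at the reported
  session-1 group means (~27% control-like, ~37% EP-like); they are stored
  in `cohort_config()` defaults, not hard-coded in logic.
- Three cognitive features are Gaussian with a shared latent factor
  correlated (r = 0.45) with `log(beta)`, emulating a general cognitive
  component that loads with decision noise; the three-subtype
  configuration plants a normative, an uncertainty-intolerant, and a
  noisy/globally-impaired profile.

A green end-to-end test on this cohort establishes that *the pipeline
recovers the structure the generator put in* — elevated exploit→explore
transitions with essentially unchanged explore→exploit transitions in the
EP-like group, subtypes recoverable by clustering. It does **not**
establish anything about real participants: real choice sequences contain
response-time structure, position biases, attentional lapses, and
session-order effects that the generator deliberately omits.

## Numerical notes and limitations

- All stochastic functions take explicit seeds and are bit-reproducible;
  cohort and pipeline functions derive per-entity sub-seeds from a master
  seed.
- Softmax computations subtract the maximum before exponentiation;
  likelihood floors are counted and surfaced as warnings rather than
  silently absorbed.
- EM procedures (Baum-Welch, geometric mixtures) are guaranteed
  non-decreasing in log-likelihood and are tested for it; degenerate
  inputs (constant or strictly alternating choice sequences, absorbing
  chains with `a = 0` or `b = 0`) are handled explicitly.
- Conditional behavioral rates return `NA`, never 0, when the
  conditioning event is absent.
- Limitations: no response-time modelling, no position-bias analysis, no
  hierarchical (population-level) estimation, no joint HMM-plus-learner
  inference, three arms only.
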
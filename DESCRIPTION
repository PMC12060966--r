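Package: restlessbandit
Title: Explore/Exploit Dynamics and Computational Subtyping for the
    Restless Three-Armed Bandit Task
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of the restless three-armed
    bandit task. Provides a constrained random-walk reward-contingency
    generator, generative choice models (a Kalman-filter Bayesian learner
    with an uncertainty bonus, a reinforcement-learning plus choice-kernel
    model, and a dual-state variant), maximum-likelihood fitting with AIC
    model comparison, a structurally constrained four-state explore/exploit
    hidden Markov model fitted by Baum-Welch with parameter tying,
    mixture-of-geometric-distributions analysis of inter-switch run lengths,
    model-free behavioral metrics, and cohort-level computational subtyping
    (PCA with permutation tests on loadings, Ward hierarchical clustering
    with cluster-quality metrics, two-way consistency ICC, and adjusted
    Pearson residuals). Includes a synthetic-cohort generator emulating a
    two-group case/control study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
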
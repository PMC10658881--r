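Package: preypred
Title: Predator-Prey Avoidance Modeling on Hexagonal Gridworlds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational models of threat avoidance in a turn-based
    predator-prey task on a hexagonal gridworld. Provides the feature-based
    Markov decision process task engine, value-iteration predator agents,
    action-prediction observer models (policy learning, goal inference and
    weighted combinations), inverse reinforcement learning of reward weights
    (model-free baselines, infinite-horizon maximum causal entropy, and a
    sampling-based hypothesis-testing model built on the successor
    representation), interactive Monte Carlo tree search planners with
    opponent models, inverse binomial sampling likelihood estimation,
    hierarchical Bayesian regressions of behavior, a synthetic-data generator
    emulating the three experiments, and model/parameter recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    rjags,
    coda,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
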
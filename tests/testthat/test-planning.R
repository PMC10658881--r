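test_that("the joint position state space has the expected size", {
  expect_equal(joint_state_count(toy_default()), 210^2)
})

test_that("UCT finds the rewarding direction on a corridor and its root
           visits sum to the simulation budget", {
  env <- toy_corridor()
  prm <- planner_params("mcts", n_simulations = 500)
  ok <- 0
  for (s in 1:60) {
    res <- mcts_choose(env, c(3, 0), c(6, 0), rbind(c(1, 0)), prm, seed = s)
    if (res$action == "NW") ok <- ok + 1
    expect_equal(sum(res$visits), 500)
  }
  expect_gte(ok / 60, 0.95)
})

test_that("threat sensitivity zero makes the planner coin-greedy", {
  # on the unsafe layout, a planner that does not price capture heads for
  # the rich corridor (or dies trying at its mouth) far more often than a
  # strongly threat-sensitive one
  env <- generate_environment("avoid", seed = 11)
  rate <- function(theta) {
    hits <- 0
    for (s in 1:8) {
      prm <- planner_params("mcts_rw", opp_temperature = 1, theta = theta,
                            n_simulations = 500)
      g <- simulate_planner_game(env, prm, seed = s)
      if (any(g$prey_cells %in% env$rich_zone) || g$captured)
        hits <- hits + 1
    }
    hits / 8
  }
  expect_gt(rate(0), rate(2))
})

test_that("a vanishing opponent temperature reproduces the max-rule opponent", {
  env <- generate_environment("avoid", seed = 12)
  prey <- preypred:::as_cell(env$prey_start, env$width)
  pred <- preypred:::as_cell(env$predator_start, env$width)
  a_max <- a_cold <- character(6)
  for (s in 1:6) {
    pm <- planner_params("mcts_rw", opp_temperature = 0, theta = 1,
                         n_simulations = 400)
    pc <- planner_params("mcts_rw", opp_temperature = 1e-6, theta = 1,
                         n_simulations = 400)
    a_max[s] <- mcts_choose(env, prey, pred, NULL, pm, seed = s)$action
    a_cold[s] <- mcts_choose(env, prey, pred, NULL, pc, seed = s)$action
  }
  expect_equal(a_cold, a_max)
})

test_that("IBS contributions follow the harmonic-sum formula", {
  # first match at K = 4 contributes -(1 + 1/2 + 1/3)
  counter <- new.env(); counter$i <- 0
  sim4 <- function(t, seed) {
    counter$i <- counter$i + 1
    if (counter$i %% 4 == 0) 1L else 0L
  }
  r <- ibs_loglik(sim4, observed = 1L, K_max = 100, repeats = 1, seed = 1)
  expect_equal(r$loglik, -(1 + 1 / 2 + 1 / 3))
  # a perfect simulator: K = 1 everywhere, log likelihood 0
  rp <- ibs_loglik(function(t, seed) 7L, observed = rep(7L, 10),
                   repeats = 3, seed = 1)
  expect_equal(rp$loglik, 0)
  expect_true(all(rp$per_trial_K == 1))
  # a simulator that never matches is capped and flagged
  rf <- ibs_loglik(function(t, seed) 0L, observed = 1L, K_max = 10,
                   repeats = 2, seed = 1)
  expect_true(rf$flagged)
  expect_equal(rf$loglik, -sum(1 / seq_len(9)))
})

test_that("IBS is unbiased on a Bernoulli toy", {
  set.seed(21)
  p <- runif(60, 0.25, 0.75)
  exact <- sum(log(p))
  sim <- function(t, seed) { set.seed(seed); rbinom(1, 1, p[t]) }
  r <- ibs_loglik(sim, observed = rep(1L, 60), K_max = 2500, repeats = 8,
                  seed = 2)
  expect_lt(abs(r$loglik - exact), 2 * sd(r$per_repeat) / sqrt(8) * 4 + 1e-9)
  # generous factor on few repeats; the acceptance suite runs the full check
  expect_lt(abs(r$loglik - exact), 0.25 * abs(exact))
})

test_that("planner log likelihoods separate opponent models on avoid layouts", {
  env <- generate_environment("avoid", seed = 13)
  prm <- planner_params("mcts_rw", theta = 1, n_simulations = 500)
  g <- simulate_planner_game(env, prm, seed = 3, decision_noise = 0.05)
  lls <- vapply(c("mcts", "mcts_rw"), function(v) {
    cp <- planner_params(v, theta = 1, n_simulations = 300)
    planner_ibs(env, g$trajectory, cp, K_max = 40, repeats = 2,
                seed = 9)$loglik
  }, 0)
  expect_gt(lls["mcts_rw"], lls["mcts"])
})

test_that("grid estimation recovers boundary and ordered threat
           sensitivities", {
  env <- generate_environment("avoid", seed = 14)
  # coin-greedy planner (theta = 0) -> lowest grid cell; the unsafe layout
  # is where threat sensitivity shapes behavior
  prm0 <- planner_params("mcts_rw", opp_temperature = 1, theta = 0,
                         n_simulations = 300)
  gs <- lapply(1:4, function(g)
    simulate_planner_game(env, prm0, seed = g)$trajectory)
  est0 <- estimate_planner_params(env, gs, variant = "mcts_rw",
                                  method = "grid",
                                  theta_grid = c(0, 2), temp_grid = 1,
                                  n_simulations = 300, K_max = 30,
                                  repeats = 4, seed = 5)
  expect_equal(est0$theta, 0)
  expect_equal(nrow(est0$grid), 2)
  # an avoidant cohort lands in the upper grid cell
  prm2 <- planner_params("mcts_rw", opp_temperature = 1, theta = 2,
                         n_simulations = 300)
  gs2 <- lapply(1:4, function(g)
    simulate_planner_game(env, prm2, seed = 10 + g)$trajectory)
  est2 <- estimate_planner_params(env, gs2, variant = "mcts_rw",
                                  method = "grid",
                                  theta_grid = c(0, 2), temp_grid = 1,
                                  n_simulations = 300, K_max = 30,
                                  repeats = 4, seed = 6)
  expect_gt(est2$theta, est0$theta)
})

test_that("rejection estimation orders cohorts by threat sensitivity", {
  env <- generate_environment("approach", seed = 15)
  mk <- function(theta, seed) lapply(1:2, function(g)
    simulate_planner_game(env, planner_params("mcts_rw",
                                              opp_temperature = 1,
                                              theta = theta,
                                              n_simulations = 300),
                          seed = seed + g)$trajectory)
  lo <- estimate_planner_params(env, mk(0.2, 1), variant = "mcts_rw",
                                method = "rejection",
                                theta_grid = c(0, 2), budget = 24,
                                accept_frac = 0.25, n_simulations = 200,
                                seed = 6)
  hi <- estimate_planner_params(env, mk(1.8, 9), variant = "mcts_rw",
                                method = "rejection",
                                theta_grid = c(0, 2), budget = 24,
                                accept_frac = 0.25, n_simulations = 200,
                                seed = 6)
  expect_true(is.finite(lo$theta) && is.finite(hi$theta))
  expect_gte(hi$theta, lo$theta - 0.5)
})
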
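test_that("policy updates follow the delta rule with decaying learning rate", {
  est <- new_policy_estimate()
  est1 <- update_policy(est, "SE", list(alpha = 0.5, lambda = 0))
  expect_equal(unname(est1$pi_hat["SE"]), 0.5)
  expect_equal(sum(est1$pi_hat), 0.5)
  # second observation with lambda = 1: effective alpha = 0.5 * 2^-1 = 0.25
  est2 <- update_policy(est1, "SE", list(alpha = 0.5, lambda = 1))
  expect_equal(unname(est2$pi_hat["SE"]), 0.5 + 0.25 * (1 - 0.5))
  # estimates stay in [0,1] for any observation sequence
  set.seed(3)
  est <- new_policy_estimate()
  for (i in 1:50) {
    est <- update_policy(est, sample(hex_directions(), 1),
                         list(alpha = runif(1, 0.05, 1),
                              lambda = runif(1, 0, 2)))
    expect_true(all(est$pi_hat >= 0 & est$pi_hat <= 1))
  }
})

test_that("kernel generalization is symmetric, mass-conserving, and vanishes
           as the length scale shrinks", {
  est <- new_policy_estimate()
  g <- update_policy(est, "N", list(alpha = 1, lambda = 0, lscale = 0.15),
                     generalize = TRUE)
  # the two ring-adjacent actions get equal smoothed mass
  expect_equal(unname(g$pi_hat["NE"]), unname(g$pi_hat["NW"]))
  expect_equal(unname(g$pi_hat["SE"]), unname(g$pi_hat["SW"]))
  expect_gt(g$pi_hat["N"], g$pi_hat["NE"])
  # normalized kernel target conserves unit mass
  expect_equal(sum(g$pi_hat), 1)
  # L -> 0 recovers the one-hot update
  g0 <- update_policy(est, "N", list(alpha = 1, lambda = 0, lscale = 1e-4),
                      generalize = TRUE)
  plain <- update_policy(est, "N", list(alpha = 1, lambda = 0))
  expect_equal(g0$pi_hat, plain$pi_hat, tolerance = 1e-10)
})

test_that("goal inference predicts moves toward the preferred feature", {
  env <- toy_tree_corner()
  # zero weights -> uniform over available actions
  p0 <- predict_goal_inference(env, c(0, 0, 0), c(2, 2), c(0, 0))
  expect_prob_vector(p0)
  expect_true(all(abs(p0 - 1 / length(p0)) < 1e-12))
  # the modal predicted action moves closer to the trees
  p <- predict_goal_inference(env, c(1, 0, 0), c(1, 3), c(0, 0))
  best <- names(p)[which.max(p)]
  nb <- neighbors(env, c(1, 3))
  to <- nb[nb$direction == best, ]
  d_before <- min(apply(rbind(c(3, 1), c(4, 1), c(3, 2)), 1,
                        function(tc) hex_distance(c(1, 3), tc)))
  d_after <- min(apply(rbind(c(3, 1), c(4, 1), c(3, 2)), 1,
                       function(tc) hex_distance(c(to$col, to$row), tc)))
  expect_lt(d_after, d_before)
})

test_that("combining predictions respects the mixing weight", {
  goal <- c(N = 0.5, NE = 0.3, SE = 0.2)
  pol <- new_policy_estimate()
  pol$pi_hat["SE"] <- 0.9
  pol$pi_hat["NE"] <- 0.2
  c1 <- combine_predictions(goal, pol, W = 1)
  expect_equal(order(c1), order(goal))
  c0 <- combine_predictions(goal, pol, W = 0)
  expect_equal(names(which.max(c0)), "SE")
  # symmetric mixture of opposed rescaled vectors -> equal mass
  g2 <- c(N = 1, NE = 0)
  p2 <- c(N = 0, NE = 1, SE = 0, S = 0, SW = 0, NW = 0)
  ch <- combine_predictions(g2, p2, W = 0.5)
  expect_equal(unname(ch), c(0.5, 0.5))
  # constant components rescale to zero; an all-constant mixture is uniform
  cu <- combine_predictions(c(N = 0.25, NE = 0.25), new_policy_estimate(),
                            W = 0.7)
  expect_equal(unname(cu), c(0.5, 0.5))
})

test_that("prediction likelihood, accuracy and BIC are coherent", {
  ctx <- preypred:::make_prediction_context(c(1, 0, 0), 60, seed = 5)
  set.seed(5)
  ctx$pred <- simulate_predictions(ctx, "goal", seed = 5)
  # R-side probabilities reproduce the C++ likelihood
  probs <- prediction_model_probs(ctx, "goal")
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  nll_manual <- -sum(log(pmax(probs[cbind(seq_along(ctx$pred), ctx$pred)],
                              1e-10)))
  fit <- fit_prediction_model(model = "goal", context = ctx)
  expect_equal(fit$neg_loglik, nll_manual, tolerance = 1e-8)
  # parameter-free models: BIC = 2 * negloglik
  expect_equal(fit$bic, 2 * fit$neg_loglik)
  # single-trial repeat model: k = 0 so BIC = -2 log p(observed)
  ctx1 <- ctx
  ctx1$goal <- ctx$goal[1, , drop = FALSE]
  ctx1$avail <- ctx$avail[1, , drop = FALSE]
  ctx1$obs <- ctx$obs[1]; ctx1$pred <- ctx$pred[1]
  f1 <- fit_prediction_model(model = "repeat", context = ctx1)
  expect_equal(f1$bic, 2 * f1$neg_loglik)
})

test_that("the combined model nests the pure strategies", {
  ctx <- preypred:::make_prediction_context(c(1, 0, 0), 80, seed = 6)
  set.seed(6)
  ctx$pred <- simulate_predictions(ctx, "combined",
                                   list(alpha = 0.5, lambda = 0.3, W = 0.6),
                                   seed = 6)
  fits <- lapply(c("goal", "policy", "combined"), function(m)
    fit_prediction_model(model = m, context = ctx, seed = 2))
  fits <- do.call(rbind, fits)
  best_comb <- fits$neg_loglik[fits$model == "combined"]
  expect_lte(best_comb, fits$neg_loglik[fits$model == "goal"] + 1e-6)
  expect_lte(best_comb, fits$neg_loglik[fits$model == "policy"] + 1e-6)
})

test_that("the mixing weight is recoverable from simulated observers", {
  ctx <- preypred:::make_prediction_context(c(1, 0, 0), 300, seed = 7)
  for (W in c(0.15, 0.85)) {
    ctx$pred <- simulate_predictions(ctx, "combined",
                                     list(alpha = 0.5, lambda = 0.2, W = W),
                                     seed = round(100 * W))
    fit <- fit_prediction_model(model = "combined", context = ctx, seed = 3)
    expect_lt(abs(fit$W - W), 0.2)
  }
})
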
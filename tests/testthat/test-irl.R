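# shared simulated observation game for the estimator tests
local_chase <- function(weights, seed, env_seed = 2001) {
  env <- generate_environment("random", seed = env_seed,
                              moves_per_turn = list(prey = 1, predator = 2),
                              n_turns = 10)
  list(env = env, traj = simulate_chase(env, weights, seed = seed))
}

test_that("occupancy counts sum per-step features with a moving prey", {
  # hand-built trajectory down a single column (N is the only repeatable
  # straight line on the hex grid): trees at (0,3) and (0,1)
  env <- hex_environment(width = 1, height = 5,
                         trees = rbind(c(0, 3), c(0, 1)),
                         red_ground = rbind(c(0, 0)),
                         predator_start = c(0, 4), prey_start = c(0, 2))
  traj <- data.frame(turn = 1:3, step = 1, actor = "predator",
                     col = 0, row = c(4, 3, 2),
                     action = c("N", "N", "N"),
                     prey_col = 0, prey_row = c(2, 1, 1))
  # occupied states: (0,4), (0,3)T, (0,2), (0,1)T; the per-step prey
  # snapshot puts the prey on (0,1) when it is entered, so the final state
  # counts as tree + prey
  est <- mf_occupancy(env, traj)
  expect_equal(est$raw, c(2, 0, 1))
  # featureless environment -> all zeros
  env0 <- hex_environment(width = 1, height = 5, predator_start = c(0, 4),
                          prey_start = c(0, 0))
  traj0 <- data.frame(turn = 1, step = 1:2, actor = "predator",
                      col = 0, row = c(4, 3), action = c("N", "N"),
                      prey_col = 0, prey_row = 0)
  expect_equal(mf_occupancy(env0, traj0)$raw, c(0, 0, 0))
})

test_that("direction counts accumulate features along rays", {
  # column with 2 trees ahead of the observed (northward) direction
  env <- hex_environment(width = 1, height = 6,
                         trees = rbind(c(0, 1), c(0, 3)),
                         predator_start = c(0, 4), prey_start = c(0, 5))
  traj <- data.frame(turn = 1, step = 1, actor = "predator", col = 0,
                     row = 4, action = "N", prey_col = 0, prey_row = 5)
  expect_equal(mf_direction(env, traj)$raw, c(2, 0, 0))
  # relative variant: the observed ray holds both trees, the single
  # alternative ray (S) holds the prey
  rel <- mf_direction(env, traj, relative = TRUE)
  expect_equal(rel$raw, c(1, 0, 0) - c(0, 0, 1))
  # rays stop at walls
  envw <- hex_environment(width = 1, height = 6,
                          trees = rbind(c(0, 1)), walls = rbind(c(0, 2)),
                          predator_start = c(0, 4), prey_start = c(0, 5))
  expect_equal(mf_direction(envw, traj)$raw, c(0, 0, 0))
  # featureless rays: normalization returns zeros rather than NaN
  env0 <- hex_environment(width = 1, height = 6, predator_start = c(0, 4),
                          prey_start = c(0, 5))
  traj0 <- traj; traj0$prey_row <- 4   # prey on the unentered source cell
  rel0 <- mf_direction(env0, traj0, relative = TRUE)
  expect_equal(rel0$raw, c(0, 0, 0))
  expect_true(rel0$flagged)
})

test_that("softmaxVI is a smoothed maximum", {
  expect_equal(softmax_vi(c(0, 0)), log(2), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:30) {
    x <- rnorm(sample(2:6, 1), sd = 5)
    expect_gte(softmax_vi(x), max(x))
    expect_lte(softmax_vi(x), max(x) + log(length(x)))
  }
})

test_that("SR Q values match a brute-force occupancy oracle", {
  env <- hex_environment(width = 3, height = 1, trees = rbind(c(2, 0)),
                         predator_start = c(0, 0), prey_start = c(1, 0))
  q <- sr_action_values(env, c(1, 0, 0), c(1, 0), c(1, 0))
  # enumerate state-action pairs and sum gamma^k P_unif^k for 200 steps
  pairs <- list(c(1, 2), c(2, 1), c(2, 3), c(3, 2))
  P <- matrix(0, 4, 4)
  for (i in seq_along(pairs)) {
    to <- pairs[[i]][2]
    tos <- which(vapply(pairs, function(p) p[1] == to, TRUE))
    P[i, tos] <- 1 / length(tos)
  }
  M <- diag(4); acc <- diag(4)
  for (k in 1:200) { acc <- acc %*% (0.9 * P); M <- M + acc }
  f <- vapply(pairs, function(p) as.numeric(p[2] == 3), 0)
  Qb <- as.numeric(M %*% f)
  expect_equal(unname(q[c("NW", "NE")]), Qb[2:3], tolerance = 1e-6)
})

test_that("MaxEnt recovers static preferences but not the prey preference", {
  ch <- local_chase(c(1, 0, 0), seed = 2)
  est <- maxent_fit(ch$env, ch$traj)
  expect_equal(identified_feature(est), 1)
  # the raw weights favor the preferred feature with a clear margin
  expect_gt(est$raw[1], max(est$raw[2:3]) + 0.1)
})

test_that("HypTest identifies preferences, including the moving prey", {
  ch <- local_chase(c(1, 0, 0), seed = 2)
  hy <- hyptest_fit(ch$env, ch$traj, seed = 2)
  expect_equal(identified_feature(hy), 1)
  chp <- local_chase(c(0, 0, 1), seed = 3, env_seed = 2004)
  hyp <- hyptest_fit(chp$env, chp$traj, seed = 3)
  expect_equal(identified_feature(hyp), 3)
  expect_equal(dim(hyp$posterior_samples), c(2000, 3))
  # no observations -> the posterior is the flat prior around zero
  empty <- ch$traj[0, ]
  h0 <- hyptest_fit(ch$env, empty, n_samples = 4000, seed = 1)
  expect_true(all(abs(h0$point) < 0.1))
})

test_that("HypTest precision grows with trajectory length", {
  errs <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    env <- generate_environment("random", seed = 3100 + s,
                                moves_per_turn = list(prey = 1,
                                                      predator = 2),
                                n_turns = 16)
    traj <- simulate_chase(env, c(1, 0, 0), seed = s)
    short <- traj[traj$turn <= 3, ]    # 6 moves
    long <- traj                        # 32 moves
    truth <- calibrate_weights(c(1, 0, 0))
    errs[s, 1] <- mean(abs(hyptest_fit(env, short, seed = s)$point - truth))
    errs[s, 2] <- mean(abs(hyptest_fit(env, long, seed = s)$point - truth))
  }
  expect_lt(mean(errs[, 2]), mean(errs[, 1]))
})

test_that("rating fits report adjusted R2 and Gaussian BIC", {
  sc <- score_irl(predicted = c(1, 2, 3, 4), ratings = c(1.1, 1.9, 3.2, 3.9),
                  n_params = 1)
  r2 <- cor(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9))^2
  expect_equal(sc$adj_r2, 1 - (1 - r2) * 3 / 2)
  rss <- sum((c(1.1, 1.9, 3.2, 3.9) - 1:4)^2)
  expect_equal(sc$bic, 4 * log(rss / 4) + log(4))
  # frozen arithmetic: R2 = 0.5, n = 101, p = 1
  expect_equal(1 - (1 - 0.5) * 100 / 99, 0.4949, tolerance = 1e-3)
  # perfect predictions
  expect_equal(score_irl(1:5, 1:5, 1)$adj_r2, 1)
  # adjusted R2 can be negative for poor, complex models
  set.seed(1)
  bad <- score_irl(rnorm(8), rnorm(8), n_params = 5)
  expect_lt(bad$adj_r2, 1)
  # zero-variance predictions are flagged
  zv <- score_irl(rep(2, 6), rnorm(6), 1)
  expect_true(zv$flagged)
  expect_true(is.na(zv$adj_r2))
})

test_that("calibration maps estimates onto the rating scale", {
  expect_equal(calibrate_weights(c(0.5, -0.25, 0)), c(4, -2, 0))
  expect_equal(calibrate_weights(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(max(abs(calibrate_weights(rnorm(3)))), 4)
})
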
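test_that("archetype path properties are verified by simulation", {
  for (s in 1:3) {
    ea <- generate_environment("approach", seed = 30 + s)
    ev <- generate_environment("avoid", seed = 30 + s)
    prey_a <- preypred:::as_cell(ea$prey_start, ea$width)
    prey_v <- preypred:::as_cell(ev$prey_start, ev$width)
    # independent check through the public simulator
    ta <- simulate_predator(ea, c(1, 0, 0),
                            matrix(rep(prey_a, 30), ncol = 2, byrow = TRUE),
                            seed = s, moves_per_turn = 1)
    tv <- simulate_predator(ev, c(1, 0, 0),
                            matrix(rep(prey_v, 30), ncol = 2, byrow = TRUE),
                            seed = s, moves_per_turn = 1)
    expect_false(any(preypred:::trajectory_positions(ea, ta) %in%
                       ea$rich_zone))
    expect_true(any(preypred:::trajectory_positions(ev, tv) %in%
                      ev$rich_zone))
  }
})

test_that("a wall-free grid keeps all 210 cells as states", {
  env <- generate_environment("random", seed = 31, wall_density = 0)
  expect_equal(nrow(env_states(env)), 210)
})

test_that("practice environments make capture impossible", {
  env <- generate_environment("practice", seed = 32)
  # predator and prey sit in disconnected components
  nbr <- preypred:::env_nbr(env)
  seen <- logical(env$width * env$height)
  frontier <- env$predator_start
  seen[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- unique(as.vector(nbr[frontier, , drop = FALSE]))
    nxt <- nxt[nxt > 0]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  expect_false(seen[env$prey_start])
})

test_that("identical seeds reproduce byte-identical bundles", {
  b1 <- simulate_experiment(1, n_subjects = 1, seed = 9, n_games = 2,
                            conditions = "A")
  b2 <- simulate_experiment(1, n_subjects = 1, seed = 9, n_games = 2,
                            conditions = "A")
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in c("trajectories.csv", "predictions.csv", "ratings.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("bundles round-trip through the canonical formats and refit", {
  b <- simulate_experiment(1, n_subjects = 1, seed = 10, n_games = 2,
                           conditions = "A")
  d <- tempfile()
  write_bundle(b, d)
  expect_silent(b2 <- read_bundle(d))
  expect_equal(nrow(b2$trajectories), nrow(b$trajectories))
  expect_true(all(c("subject_id", "experiment", "condition", "game", "turn",
                    "step", "actor", "col", "row", "action") %in%
                    names(b2$trajectories)))
  sub <- b2$predictions[b2$predictions$subject_id == "s001", ]
  envs <- lapply(1:2, function(g) b2$envs[[paste0("s001_g", g)]])
  ctx <- prediction_context(sub, envs, c(1, 0, 0))
  expect_equal(length(ctx$obs), nrow(sub))
  expect_true(all(!is.na(ctx$obs)) && all(!is.na(ctx$pred)))
})

test_that("noise-free goal-inference observers close the loop", {
  b <- simulate_experiment(1, n_subjects = 1, seed = 11, n_games = 3,
                           conditions = "A",
                           subject_spec = list(W = 1, alpha = 0.5,
                                               lambda = 0.1,
                                               rating_noise = 0))
  sub <- b$predictions
  envs <- lapply(1:3, function(g) b$envs[[paste0("s001_g", g)]])
  ctx <- prediction_context(sub, envs, c(1, 0, 0))
  fit <- fit_prediction_model(model = "combined", context = ctx, seed = 1)
  expect_gte(fit$W, 0.9)
  # ratings equal the calibrated truth exactly
  expect_true(all(b$ratings$rating_trees == 4))
  expect_true(all(b$ratings$rating_red == 0))
  expect_true(all(b$ratings$rating_prey == 0))
})

test_that("planner bundles carry condition structure", {
  b3 <- simulate_experiment(3, n_subjects = 1, seed = 12, n_envs = 1,
                            subject_spec = list(n_simulations = 150),
                            conditions = c("short_predictable",
                                           "long_irreducible"))
  expect_setequal(unique(b3$trajectories$condition),
                  c("short_predictable", "long_irreducible"))
  # horizon condition controls the turn structure
  short_env <- b3$envs[[paste0(b3$subjects$subject_id[1], "_g1")]]
  expect_equal(short_env$moves_per_turn$prey, 1L)
  expect_equal(short_env$n_turns, 12L)
  long_env <- b3$envs[[paste0(b3$subjects$subject_id[2], "_g1")]]
  expect_equal(long_env$moves_per_turn$prey, 4L)
  expect_equal(long_env$moves_per_turn$predator, 8L)
  expect_equal(long_env$n_turns, 3L)
  # total prey moves match across horizons
  expect_equal(short_env$n_turns * short_env$moves_per_turn$prey,
               long_env$n_turns * long_env$moves_per_turn$prey)
  # trajectories are transition-consistent in their own environments
  tr <- b3$trajectories
  for (i in seq_len(nrow(b3$subjects))) {
    sid <- b3$subjects$subject_id[i]
    env <- b3$envs[[paste0(sid, "_g1")]]
    prey_rows <- tr[tr$subject_id == sid & tr$actor == "prey", ]
    expect_silent(preypred:::trajectory_positions(env, prey_rows))
  }
})
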
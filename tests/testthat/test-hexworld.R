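test_that("neighbor enumeration follows the fixed hex layout", {
  env <- toy_default()
  # interior cell has all 6 directions
  expect_equal(nrow(neighbors(env, c(10, 5))), 6)
  # corner (0,0): enumerate the 6 odd-q offsets for an even column and keep
  # the in-bounds ones - an independent count of what neighbors() must return
  offs <- list(N = c(0, -1), NE = c(1, -1), SE = c(1, 0), S = c(0, 1),
               SW = c(-1, 0), NW = c(-1, -1))
  in_bounds <- sum(vapply(offs, function(d) {
    c0 <- 0 + d[1]; r0 <- 0 + d[2]
    c0 >= 0 && c0 < 21 && r0 >= 0 && r0 < 10
  }, TRUE))
  expect_equal(nrow(neighbors(env, c(0, 0))), in_bounds)
  expect_lt(in_bounds, 6)
  # fully enclosed cell has no neighbors
  ring <- rbind(c(2, 1), c(3, 1), c(3, 2), c(2, 3), c(1, 2), c(1, 1))
  env2 <- hex_environment(width = 6, height = 6, walls = ring,
                          predator_start = c(0, 0), prey_start = c(5, 5))
  expect_equal(nrow(neighbors(env2, c(2, 2))), 0)
  # invalid inputs
  expect_error(neighbors(env2, c(2, 1)), "wall")
  expect_error(neighbors(env, c(30, 2)), "out of bounds")
})

test_that("neighbor relation is symmetric and the grid has 210 states", {
  env <- toy_default()
  expect_equal(nrow(env_states(env)), 210)
  expect_equal(joint_state_count(env), 44100)
  set.seed(11)
  for (i in 1:25) {
    cell <- c(sample(0:20, 1), sample(0:9, 1))
    nb <- neighbors(env, cell)
    for (j in seq_len(nrow(nb))) {
      back <- neighbors(env, c(nb$col[j], nb$row[j]))
      expect_true(any(back$col == cell[1] & back$row == cell[2]))
    }
  }
})

test_that("feature vectors track trees, red ground and the prey", {
  env <- hex_environment(width = 5, height = 5, trees = rbind(c(1, 1)),
                         red_ground = rbind(c(2, 2)),
                         predator_start = c(0, 0), prey_start = c(4, 4))
  expect_equal(unname(feature_vector(env, c(1, 1), prey_at = c(1, 1))),
               c(1, 0, 1))
  expect_equal(unname(feature_vector(env, c(3, 3), prey_at = c(4, 4))),
               c(0, 0, 0))
  expect_equal(unname(feature_vector(env, c(2, 2), prey_at = c(4, 4))),
               c(0, 1, 0))
})

test_that("the MDP reward is the entered state's features dotted with weights", {
  env <- hex_environment(width = 5, height = 5, trees = rbind(c(1, 1)),
                         predator_start = c(0, 0), prey_start = c(4, 4))
  m0 <- build_mdp(env, c(0, 0, 0), c(4, 4))
  expect_true(all(m0$reward[!is.na(m0$reward)] == 0))
  m1 <- build_mdp(env, c(1, 0, 0), c(4, 4))
  # actions entering (1,1) reward 1, everything else 0
  tree_id <- which(m1$states == 1 * 5 + 1 + 1)
  entering <- which(m1$next_id == m1$states[tree_id])
  expect_true(all(m1$reward[entering] == 1))
  expect_true(all(m1$reward[-entering][!is.na(m1$reward[-entering])] == 0))
  # prey feature moves with the prey: rebuild and compare
  mp <- build_mdp(env, c(0, 0, 1), c(1, 1))
  expect_true(all(mp$reward[entering] == 1))
  mp2 <- build_mdp(env, c(0, 0, 1), c(4, 4))
  expect_true(all(mp2$reward[entering] == 0))
})

test_that("game stepping scores coins and capture correctly", {
  env <- hex_environment(width = 5, height = 1, coins = rbind(c(2, 0)),
                         predator_start = c(4, 0), prey_start = c(1, 0),
                         moves_per_turn = list(prey = 1, predator = 1),
                         n_turns = 5)
  gs <- new_game_state(env)
  gs <- step_game(gs, env, "prey", "NE")    # onto the coin
  expect_equal(gs$points, 100L)
  expect_equal(nrow(gs$coins_remaining), 0)
  gs <- step_game(gs, env, "predator", "SW") # (4,0) -> (3,0)
  expect_false(gs$captured)
  expect_equal(gs$points, 100L)              # empty move, unchanged
  gs <- step_game(gs, env, "predator", "NW") # onto the prey
  expect_true(gs$captured)
  expect_equal(gs$points, 100L - 1000L)
  expect_error(step_game(gs, env, "prey", "NE"), "over")
  # invalid action
  gs2 <- new_game_state(env)
  expect_error(step_game(gs2, env, "prey", "N"), "invalid action")
})

test_that("points always equal 100*coins - 1000*captured", {
  env <- generate_environment("avoid", seed = 5)
  set.seed(5)
  gs <- new_game_state(env)
  for (i in 1:40) {
    if (gs$captured) break
    actor <- if (i %% 2 == 1) "prey" else "predator"
    from <- if (actor == "prey") gs$prey else gs$predator
    nb <- neighbors(env, from)
    gs <- step_game(gs, env, actor, nb$direction[sample.int(nrow(nb), 1)])
  }
  expect_equal(gs$points,
               100L * gs$coins_collected - 1000L * as.integer(gs$captured))
})

test_that("environments survive a JSON round trip", {
  env <- generate_environment("avoid", seed = 3)
  f <- tempfile(fileext = ".json")
  write_environment(env, f)
  env2 <- read_environment(f)
  for (field in c("width", "height", "walls", "trees", "red_ground",
                  "coins", "predator_start", "prey_start", "rich_zone",
                  "n_turns"))
    expect_equal(env2[[field]], env[[field]], info = field)
  expect_equal(env2$moves_per_turn, env$moves_per_turn)
})
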
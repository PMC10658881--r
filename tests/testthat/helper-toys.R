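# Small environments shared across tests; all built in code.

# wall-free default-size grid
toy_default <- function() {
  hex_environment(predator_start = c(0, 0), prey_start = c(20, 9))
}

# 2x1 grid: two mutually adjacent cells, both trees
toy_two_cell <- function() {
  hex_environment(width = 2, height = 1, trees = rbind(c(0, 0), c(1, 0)),
                  predator_start = c(0, 0), prey_start = c(1, 0))
}

# 1-row corridor of given length, coin at the left end
toy_corridor <- function(len = 7, coin_at = c(1, 0)) {
  hex_environment(width = len, height = 1, coins = rbind(coin_at),
                  predator_start = c(len - 1, 0), prey_start = c(3, 0),
                  moves_per_turn = list(prey = 4, predator = 1), n_turns = 2)
}

# 5x5 toy with a tree cluster in one corner
toy_tree_corner <- function() {
  hex_environment(width = 5, height = 5,
                  trees = rbind(c(3, 1), c(4, 1), c(3, 2)),
                  predator_start = c(0, 4), prey_start = c(0, 0))
}

# random small MDP: random weights on a 5x5 grid with random features
toy_random_mdp <- function(seed) {
  set.seed(seed)
  n <- 25
  ids <- sample(n, 6)
  cells <- cbind((ids - 1) %% 5, (ids - 1) %/% 5)
  env <- hex_environment(width = 5, height = 5,
                         trees = cells[1:2, , drop = FALSE],
                         red_ground = cells[3:4, , drop = FALSE],
                         predator_start = cells[5, ], prey_start = cells[6, ])
  w <- runif(3, -1, 1)
  list(env = env, mdp = build_mdp(env, w, cells[6, ], 0.9))
}

# horizon-H dynamic-programming value oracle, independent of value_iteration:
# V_0 = 0; V_h(s) = max_a R(s,a) + g * V_{h-1}(s')
brute_force_values <- function(mdp, horizon) {
  ns <- length(mdp$states)
  nxt <- mdp$index[mdp$next_id]
  dim(nxt) <- dim(mdp$next_id)
  V <- numeric(ns)
  for (h in seq_len(horizon)) {
    Vn <- numeric(ns)
    for (i in seq_len(ns)) {
      best <- -Inf
      for (a in 1:6) {
        if (is.na(nxt[i, a])) next
        v <- mdp$reward[i, a] + mdp$discount * V[nxt[i, a]]
        if (v > best) best <- v
      }
      Vn[i] <- if (is.finite(best)) best else 0
    }
    V <- Vn
  }
  V
}

expect_prob_vector <- function(p, tol = 1e-12) {
  expect_true(all(p >= 0))
  expect_lt(abs(sum(p) - 1), tol)
}
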
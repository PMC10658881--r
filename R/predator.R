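#' Value iteration on a feature MDP
#'
#' Iterates the Bellman optimality update `V(s) <- max_a [R(s,a) + g V(s')]`
#' (values initialized at 0) until the maximal value change falls below `tol`
#' or `max_iters` sweeps have run. States with no available action keep value
#' 0 and are excluded from the max.
#'
#' @param mdp A `ppmdp` from [build_mdp()].
#' @param max_iters Maximum sweeps (default 500).
#' @param tol Target accuracy of the returned values (default 1e-6): sweeps
#'   stop early once the Bellman contraction bound
#'   `g/(1-g) * max |V_k+1 - V_k|` guarantees the fixed point is within
#'   `tol`.
#' @param V0 Optional warm-start value vector (length `n_states`).
#' @return A `ppvalues` list: `V` (per state), `Q` (n_states x 6, NA where an
#'   action is unavailable), `iterations_run`, and the `mdp`.
#' @export
value_iteration <- function(mdp, max_iters = 500L, tol = 1e-6, V0 = NULL) {
  stopifnot(inherits(mdp, "ppmdp"), max_iters >= 1)
  ns <- length(mdp$states)
  nxt <- mdp$index[mdp$next_id]          # n x 6 state indices, NA invalid
  dim(nxt) <- dim(mdp$next_id)
  valid <- !is.na(nxt)
  nxt0 <- ifelse(valid, nxt, 1L)         # safe index; masked later
  V <- if (is.null(V0)) numeric(ns) else as.numeric(V0)
  g <- mdp$discount
  R <- mdp$reward
  has_action <- rowSums(valid) > 0
  iters <- 0L
  sweep_tol <- if (g > 0) tol * (1 - g) / g else tol
  for (k in seq_len(max_iters)) {
    Q <- R + g * matrix(V[nxt0], ns, 6)
    Q[!valid] <- -Inf
    Vn <- pmax(Q[, 1], Q[, 2], Q[, 3], Q[, 4], Q[, 5], Q[, 6])
    Vn[!has_action] <- 0
    iters <- k
    if (max(abs(Vn - V)) < sweep_tol) { V <- Vn; break }
    V <- Vn
  }
  Q <- R + g * matrix(V[nxt0], ns, 6)
  Q[!valid] <- NA_real_
  structure(list(V = V, Q = Q, iterations_run = iters, mdp = mdp),
            class = "ppvalues")
}

#' Action-selection rule
#'
#' @param kind `"max"` (greedy) or `"softmax"` (Boltzmann over Q values).
#' @param temperature Softmax temperature tau > 0 (default 1, the task's
#'   value for the unpredictable agent).
#' @param tie_break For the max rule: `"random"` shares probability mass
#'   equally among argmax actions (seeded runs then reproduce), `"first"`
#'   always takes the first argmax action in canonical direction order -
#'   the fully deterministic agent of the prediction games.
#' @return An `pprule` list.
#' @export
action_rule <- function(kind = c("max", "softmax"), temperature = 1,
                        tie_break = c("random", "first")) {
  kind <- match.arg(kind)
  tie_break <- match.arg(tie_break)
  stopifnot(is.finite(temperature), temperature > 0)
  structure(list(kind = kind, temperature = temperature,
                 tie_break = tie_break), class = "pprule")
}

softmax_prob <- function(q, temperature = 1) {
  z <- q / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Action probabilities at a state
#'
#' Converts the Q values of the available actions at `state` into a choice
#' distribution: all mass shared equally among argmax actions under the max
#' rule, or a Boltzmann distribution `exp(Q/tau) / sum exp(Q/tau)` under the
#' softmax rule.
#'
#' @param values A `ppvalues` object from [value_iteration()].
#' @param state Cell `c(col, row)`.
#' @param rule An `pprule` from [action_rule()].
#' @return Named probability vector over the available directions.
#' @export
action_probabilities <- function(values, state, rule = action_rule("max")) {
  stopifnot(inherits(values, "ppvalues"))
  mdp <- values$mdp
  id <- cell_id(state[1], state[2], mdp$width)
  si <- mdp$index[id]
  if (si == 0L) stop("state is not part of the MDP")
  q <- values$Q[si, ]
  avail <- !is.na(q)
  if (!any(avail)) stop("state has no available actions")
  qa <- q[avail]
  p <- if (rule$kind == "max") {
    best <- abs(qa - max(qa)) < 1e-12
    if (identical(rule$tie_break, "first")) {
      best <- seq_along(qa) == which.max(qa)
    }
    best / sum(best)
  } else {
    softmax_prob(qa, rule$temperature)
  }
  names(p) <- HEX_DIRECTIONS[avail]
  p
}

sample_direction <- function(p) {
  names(p)[sample.int(length(p), 1, prob = p)]
}

#' Simulate a predator trajectory
#'
#' At the start of each predator turn the feature MDP is rebuilt with the
#' prey at its current cell (the prey is assumed stationary within the turn)
#' and re-solved by value iteration; the predator then takes its allotted
#' moves under the action rule. The predator is forced to move on every step
#' (staying put is never available).
#'
#' @param env A `ppenv` environment.
#' @param weights Numeric length-3 reward weights (trees, red ground, prey).
#' @param prey_path Matrix of prey cells, one row per predator turn (the
#'   prey's position during that turn). A single cell is recycled.
#' @param rule An `pprule`; ties under the max rule are broken by the seeded
#'   RNG, so a fixed seed gives a reproducible trajectory.
#' @param seed Integer RNG seed (or NULL to use the current RNG state).
#' @param moves_per_turn Predator moves per turn; defaults to the
#'   environment's setting.
#' @param discount Discount factor (default 0.9).
#' @param start Optional predator start cell; defaults to the environment's.
#' @return data.frame trajectory with one row per move: `turn`, `step`,
#'   `actor`, `col`, `row` (cell the move was taken from), `action`,
#'   `prey_col`, `prey_row` (prey position when the move was made).
#' @export
simulate_predator <- function(env, weights, prey_path, rule = action_rule("max"),
                              seed = NULL, moves_per_turn = NULL,
                              discount = 0.9, start = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(moves_per_turn)) moves_per_turn <- env$moves_per_turn$predator
  if (!is.matrix(prey_path)) prey_path <- matrix(prey_path, ncol = 2, byrow = TRUE)
  pos <- if (is.null(start)) as_cell(env$predator_start, env$width) else start
  out <- vector("list", nrow(prey_path) * moves_per_turn)
  i <- 0L
  vt <- NULL
  for (turn in seq_len(nrow(prey_path))) {
    prey <- prey_path[turn, ]
    mdp <- build_mdp(env, weights, prey, discount)
    vt <- value_iteration(mdp, V0 = if (is.null(vt)) NULL else vt$V)
    for (step in seq_len(moves_per_turn)) {
      p <- action_probabilities(vt, pos, rule)
      a <- sample_direction(p)
      i <- i + 1L
      out[[i]] <- data.frame(turn = turn, step = step, actor = "predator",
                             col = pos[1], row = pos[2], action = a,
                             prey_col = prey[1], prey_row = prey[2],
                             stringsAsFactors = FALSE)
      d <- match(a, HEX_DIRECTIONS)
      pos <- as_cell(env_nbr(env)[cell_id(pos[1], pos[2], env$width), d],
                     env$width)
    }
  }
  res <- do.call(rbind, out[seq_len(i)])
  rownames(res) <- NULL
  res
}

#' Hexagonal grid distance between two cells
#'
#' Minimal number of moves between cells on the wall-free grid (odd-q offset
#' coordinates converted to cube coordinates).
#'
#' @param a,b Cells `c(col, row)`.
#' @return Integer distance.
#' @export
hex_distance <- function(a, b) {
  cube <- function(c) {
    x <- c[1]
    z <- c[2] - (c[1] - (c[1] %% 2)) / 2
    c(x, -x - z, z)
  }
  sum(abs(cube(a) - cube(b))) / 2
}

#' Simulate a pursuit game: re-planning predator versus fleeing prey
#'
#' The prey moves away from the predator (maximizing hex distance, ties
#' broken at random) one move per turn; the predator then takes its moves
#' under the action rule, re-solving its MDP with the prey at its current
#' cell at the start of each predator turn. Used to emulate the observation
#' games in which a participant-controlled prey avoids the agent. The
#' simulation always runs the full `n_turns` (co-location does not stop it),
#' so the returned trajectory has a fixed number of predator steps.
#'
#' @param env A `ppenv` environment.
#' @param weights Predator reward weights.
#' @param n_turns Turns to simulate (default from `env`).
#' @param moves_per_turn Predator moves per turn (default from `env`).
#' @param rule Predator action rule.
#' @param seed Integer seed.
#' @param discount Discount factor (default 0.9).
#' @return Trajectory data.frame of predator steps (with `prey_col`,
#'   `prey_row` context), as consumed by the IRL estimators.
#' @export
simulate_chase <- function(env, weights, n_turns = NULL,
                           moves_per_turn = NULL,
                           rule = action_rule("max"), seed = NULL,
                           discount = 0.9) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_turns)) n_turns <- env$n_turns
  if (is.null(moves_per_turn)) moves_per_turn <- env$moves_per_turn$predator
  prey <- as_cell(env$prey_start, env$width)
  pred <- as_cell(env$predator_start, env$width)
  prey_path <- matrix(NA_integer_, n_turns, 2)
  rows <- list()
  vt <- NULL
  for (turn in seq_len(n_turns)) {
    # prey evades: any move that does not close the distance to the
    # predator (uniform among them), falling back to the most distancing
    # move when cornered - produces the tangential, curving flight paths of
    # a pursued agent rather than straight-line retreat
    nb <- neighbors(env, prey)
    d0 <- hex_distance(prey, pred)
    d <- vapply(seq_len(nrow(nb)), function(i)
      hex_distance(c(nb$col[i], nb$row[i]), pred), 0)
    cand <- which(d >= d0)
    if (!length(cand)) cand <- which(d >= max(d) - 1e-9)
    k <- cand[sample.int(length(cand), 1)]
    prey <- c(nb$col[k], nb$row[k])
    prey_path[turn, ] <- prey
    # predator turn with the prey at its current cell
    mdp <- build_mdp(env, weights, prey, discount)
    vt <- value_iteration(mdp, V0 = if (is.null(vt)) NULL else vt$V)
    for (step in seq_len(moves_per_turn)) {
      p <- action_probabilities(vt, pred, rule)
      a <- sample_direction(p)
      rows[[length(rows) + 1]] <- data.frame(
        turn = turn, step = step, actor = "predator",
        col = pred[1], row = pred[2], action = a,
        prey_col = prey[1], prey_row = prey[2], stringsAsFactors = FALSE)
      d6 <- match(a, HEX_DIRECTIONS)
      pred <- as_cell(env_nbr(env)[cell_id(pred[1], pred[2], env$width), d6],
                      env$width)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Sequence of cells a trajectory's actor occupied: start cell of the first
# step plus every entered cell (derived from the adjacency map).
trajectory_positions <- function(env, traj) {
  n <- nrow(traj)
  ids <- integer(n + 1)
  ids[1] <- cell_id(traj$col[1], traj$row[1], env$width)
  for (i in seq_len(n)) {
    from <- cell_id(traj$col[i], traj$row[i], env$width)
    ids[i + 1] <- env_nbr(env)[from, match(traj$action[i], HEX_DIRECTIONS)]
  }
  ids
}
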
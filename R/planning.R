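#' Interactive planning models (MCTS family)
#'
#' The prey's decision problem is a joint MDP over both agents' positions
#' (210^2 position states on the wall-free default grid), too large for
#' dynamic programming; planners therefore use Upper Confidence Bound for
#' Trees (UCT) search with uniform-random rollouts. Three variants differ in
#' their opponent model during simulation: `"mcts"` ignores the predator,
#' `"mcts_rand"` simulates it as uniform random, and `"mcts_rw"` simulates it
#' with the value-iteration policy under its true reward weights (max rule,
#' or softmax when `opp_temperature > 0`). A threat-sensitivity parameter
#' theta scales the simulated capture cost of 1000 points.
#'
#' @name interactive_planning
NULL

PLANNER_VARIANTS <- c("mcts", "mcts_rand", "mcts_rw")

#' Planner parameter set
#'
#' @param variant One of `"mcts"`, `"mcts_rand"`, `"mcts_rw"`.
#' @param opp_temperature Softmax temperature for the simulated predator in
#'   `mcts_rw` (0 = max rule).
#' @param theta Threat sensitivity, the multiplier on the 1000-point capture
#'   cost inside simulations (>= 0; 1 = objective cost).
#' @param exploration UCT exploration constant applied to returns min-max
#'   normalized to \[0, 1\] within the tree (default `sqrt(2)`).
#' @param n_simulations UCT iterations per decision (default 1000).
#' @return A `pplanner` list.
#' @export
planner_params <- function(variant = "mcts_rw", opp_temperature = 0,
                           theta = 1, exploration = sqrt(2),
                           n_simulations = 1000L) {
  variant <- match.arg(variant, PLANNER_VARIANTS)
  stopifnot(opp_temperature >= 0, theta >= 0, exploration > 0,
            n_simulations >= 1)
  structure(list(variant = variant, opp_temperature = opp_temperature,
                 theta = theta, exploration = exploration,
                 n_simulations = as.integer(n_simulations)),
            class = "pplanner")
}

# Stationary predator policy matrix (n_cells x 6 action probabilities) under
# the true reward weights, used by the mcts_rw opponent model. The prey
# feature is evaluated at the prey's current position; with the zero prey
# weight of the planning experiments the policy is prey-independent.
opponent_policy_matrix <- function(env, weights, prey_at, opp_temperature = 0,
                                   discount = 0.9) {
  mdp <- build_mdp(env, weights, prey_at, discount)
  vt <- value_iteration(mdp)
  n <- env$width * env$height
  pol <- matrix(0, n, 6)
  for (i in seq_along(mdp$states)) {
    q <- vt$Q[i, ]
    avail <- !is.na(q)
    qa <- q[avail]
    p <- if (opp_temperature <= 0) {
      best <- abs(qa - max(qa)) < 1e-12
      best / sum(best)
    } else softmax_prob(qa, opp_temperature)
    pol[mdp$states[i], avail] <- p
  }
  pol
}

# Remaining-move schedule (0 = prey, 1 = predator) given the game's turn
# structure and current progress.
move_schedule <- function(env, prey_moves_left, turns_left_after) {
  mp <- env$moves_per_turn
  c(rep(0L, prey_moves_left), rep(1L, mp$predator),
    rep(c(rep(0L, mp$prey), rep(1L, mp$predator)), max(turns_left_after, 0)))
}

#' Choose a prey action by UCT search
#'
#' Runs `n_simulations` UCT iterations from the current joint state; the tree
#' covers the prey's own future moves, predator moves are sampled from the
#' opponent model, rollouts use a uniform-random prey policy, and simulated
#' returns are 100 per coin collected minus `1000 * theta` on capture with
#' the simulation depth equal to the remaining moves of the game. Returns the
#' root action with the most visits.
#'
#' @param env A `ppenv` environment.
#' @param prey,predator Current cells `c(col, row)`.
#' @param coins Matrix of remaining coin cells (or NULL).
#' @param params A `pplanner` parameter set.
#' @param prey_moves_left Prey moves remaining in the current turn (>= 1).
#' @param turns_left_after Full turns remaining after the current one.
#' @param weights Predator reward weights (for the `mcts_rw` opponent model).
#' @param seed Integer seed for the search RNG.
#' @param opp_policy Optional precomputed [opponent_policy_matrix()].
#' @return List: `action` (direction label), `visits` and `value` per
#'   canonical direction.
#' @export
mcts_choose <- function(env, prey, predator, coins, params,
                        prey_moves_left = NULL, turns_left_after = NULL,
                        weights = c(1, 0, 0), seed = 1L, opp_policy = NULL) {
  stopifnot(inherits(params, "pplanner"))
  if (is.null(prey_moves_left)) prey_moves_left <- env$moves_per_turn$prey
  if (is.null(turns_left_after)) turns_left_after <- env$n_turns - 1L
  opp_code <- match(params$variant, PLANNER_VARIANTS) - 1L  # 0,1,2
  pol <- matrix(0, 1, 1)
  if (opp_code == 2L) {
    pol <- if (is.null(opp_policy))
      opponent_policy_matrix(env, weights, prey, params$opp_temperature)
    else opp_policy
  }
  coin_ids <- if (is.null(coins) || NROW(coins) == 0) integer(0)
              else cells_to_ids(coins, env$width)
  res <- mcts_choose_cpp(env_nbr(env),
                         check_cell(env, prey), check_cell(env, predator),
                         coin_ids,
                         move_schedule(env, prey_moves_left, turns_left_after),
                         opp_code, pol, params$theta,
                         params$n_simulations, params$exploration,
                         as.integer(seed), env$capture_symmetric)
  list(action = HEX_DIRECTIONS[res$action],
       visits = stats::setNames(res$visits, HEX_DIRECTIONS),
       value = stats::setNames(res$value, HEX_DIRECTIONS))
}

#' Simulate one full game of a planning subject
#'
#' The prey chooses every move with its MCTS variant (optionally corrupted by
#' epsilon-uniform decision noise); the predator plays its true policy
#' (value-iteration, max rule or softmax `predator_temperature`), re-solved at
#' the start of each of its turns with the prey at its current cell. The game
#' ends on capture or after `n_turns`.
#'
#' @param env A `ppenv` environment.
#' @param params A `pplanner` parameter set for the prey.
#' @param weights Predator reward weights (default trees-preferring
#'   `c(1, 0, 0)`).
#' @param predator_temperature 0 for the predictable max-rule predator;
#'   1 for the unpredictable softmax predator.
#' @param decision_noise Probability of replacing the planned prey move with
#'   a uniform-random legal move (default 0).
#' @param seed Integer seed.
#' @return List: `trajectory` (data.frame of all moves with per-move context
#'   columns `prey_moves_left`, `turns_left_after`, `coins_remaining`),
#'   `points`, `captured`, `coins_collected`, `prey_cells` (ids visited).
#' @export
simulate_planner_game <- function(env, params, weights = c(1, 0, 0),
                                  predator_temperature = 0,
                                  decision_noise = 0, seed = 1L) {
  set.seed(seed)
  gs <- new_game_state(env)
  opp_policy <- if (params$variant == "mcts_rw")
    opponent_policy_matrix(env, weights, gs$prey, params$opp_temperature)
  else NULL
  pred_rule <- if (predator_temperature <= 0) action_rule("max")
               else action_rule("softmax", predator_temperature)
  rows <- list()
  vt <- NULL
  for (turn in seq_len(env$n_turns)) {
    for (mv in seq_len(env$moves_per_turn$prey)) {
      if (gs$captured) break
      left <- env$moves_per_turn$prey - mv + 1L
      pick <- mcts_choose(env, gs$prey, gs$predator, gs$coins_remaining,
                          params, prey_moves_left = left,
                          turns_left_after = env$n_turns - turn,
                          weights = weights,
                          seed = sample.int(.Machine$integer.max, 1),
                          opp_policy = opp_policy)
      a <- pick$action
      if (decision_noise > 0 && stats::runif(1) < decision_noise) {
        nb <- neighbors(env, gs$prey)
        a <- nb$direction[sample.int(nrow(nb), 1)]
      }
      rows[[length(rows) + 1]] <- data.frame(
        turn = turn, step = mv, actor = "prey",
        col = gs$prey[1], row = gs$prey[2], action = a,
        prey_col = gs$prey[1], prey_row = gs$prey[2],
        prey_moves_left = left, turns_left_after = env$n_turns - turn,
        coins_remaining = paste(cells_to_ids(gs$coins_remaining, env$width),
                                collapse = ";"),
        stringsAsFactors = FALSE)
      gs <- step_game(gs, env, "prey", a)
    }
    if (gs$captured) break
    # predator turn: re-solve with the prey at its current cell
    mdp <- build_mdp(env, weights, gs$prey, 0.9)
    vt <- value_iteration(mdp, V0 = if (is.null(vt)) NULL else vt$V)
    for (mv in seq_len(env$moves_per_turn$predator)) {
      if (gs$captured) break
      p <- action_probabilities(vt, gs$predator, pred_rule)
      a <- sample_direction(p)
      rows[[length(rows) + 1]] <- data.frame(
        turn = turn, step = mv, actor = "predator",
        col = gs$predator[1], row = gs$predator[2], action = a,
        prey_col = gs$prey[1], prey_row = gs$prey[2],
        prey_moves_left = NA_integer_, turns_left_after = NA_integer_,
        coins_remaining = NA_character_, stringsAsFactors = FALSE)
      gs <- step_game(gs, env, "predator", a)
    }
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  prey_rows <- traj[traj$actor == "prey", , drop = FALSE]
  prey_ids <- trajectory_positions(env, prey_rows)
  list(trajectory = traj, points = gs$points, captured = gs$captured,
       coins_collected = gs$coins_collected, prey_cells = prey_ids)
}

harmonic <- function(k) if (k <= 1) 0 else sum(1 / seq_len(k - 1))

#' Inverse binomial sampling log-likelihood estimate
#'
#' Unbiased estimator of a simulator-defined log likelihood: for each
#' observed choice, the simulator is run until it reproduces the choice; a
#' first match at draw K contributes minus the (K-1)-th harmonic number.
#' Contributions are summed over choices and averaged over `repeats`
#' independent estimates. Simulation per choice is capped at `K_max` draws,
#' flooring the contribution at the corresponding harmonic sum; estimates
#' where every repeat hit the cap on some trial are flagged.
#'
#' @param simulate_choice `function(trial_index, rng_seed)` returning the
#'   model's sampled choice for that trial's context.
#' @param observed Vector of observed choices.
#' @param K_max Cap on simulations per choice per repeat (default 2500).
#' @param repeats Independent IBS repetitions averaged (default 16).
#' @param seed Integer seed.
#' @return A `ppibs` list: `loglik` (mean over repeats), `loglik_se`,
#'   `per_repeat`, `per_trial_K` (matrix, capped draws), `capped` fraction,
#'   `flagged`.
#' @export
ibs_loglik <- function(simulate_choice, observed, K_max = 2500L,
                       repeats = 16L, seed = 1L) {
  set.seed(seed)
  n <- length(observed)
  Ks <- matrix(NA_integer_, repeats, n)
  lls <- numeric(repeats)
  cap_hit <- matrix(FALSE, repeats, n)
  for (r in seq_len(repeats)) {
    ll <- 0
    for (t in seq_len(n)) {
      K <- 1L
      repeat {
        sim <- simulate_choice(t, sample.int(.Machine$integer.max, 1))
        if (identical(sim, observed[[t]]) || isTRUE(sim == observed[[t]]))
          break
        K <- K + 1L
        if (K >= K_max) { cap_hit[r, t] <- TRUE; break }
      }
      Ks[r, t] <- K
      ll <- ll - harmonic(K)
    }
    lls[r] <- ll
  }
  flagged <- any(apply(cap_hit, 2, all))
  structure(list(loglik = mean(lls),
                 loglik_se = stats::sd(lls) / sqrt(repeats),
                 per_repeat = lls, per_trial_K = Ks,
                 capped = mean(cap_hit), flagged = flagged,
                 repeats = repeats),
            class = "ppibs")
}

# Rebuild the decision context of each prey move in a planner trajectory and
# return an IBS simulator closure for the given planner parameters.
planner_choice_simulator <- function(env, traj, params, weights = c(1, 0, 0)) {
  prey_row_idx <- which(traj$actor == "prey")
  prey_rows <- traj[prey_row_idx, , drop = FALSE]
  # predator policy under the true weights; the prey position only matters if
  # the prey weight is non-zero, in which case it is rebuilt per decision
  prey_dependent <- weights[3] != 0
  opp_policy <- if (params$variant == "mcts_rw" && !prey_dependent)
    opponent_policy_matrix(env, weights, as_cell(env$prey_start, env$width),
                           params$opp_temperature)
  else NULL
  pred_pos <- function(i) {
    # predator position when the i-th prey move was made: last predator row
    # before it, else the start
    idx <- which(traj$actor == "predator")
    before <- idx[idx < prey_row_idx[i]]
    if (!length(before)) return(as_cell(env$predator_start, env$width))
    last <- traj[max(before), ]
    to <- env_nbr(env)[cell_id(last$col, last$row, env$width),
                       match(last$action, HEX_DIRECTIONS)]
    as_cell(to, env$width)
  }
  list(
    n = nrow(prey_rows),
    observed = prey_rows$action,
    simulate = function(i, rng_seed) {
      pr <- prey_rows[i, ]
      coins <- if (is.na(pr$coins_remaining) || pr$coins_remaining == "")
        NULL else ids_to_cells(as.integer(strsplit(pr$coins_remaining,
                                                   ";")[[1]]), env$width)
      op <- opp_policy
      if (params$variant == "mcts_rw" && prey_dependent)
        op <- opponent_policy_matrix(env, weights, c(pr$col, pr$row),
                                     params$opp_temperature)
      mcts_choose(env, c(pr$col, pr$row), pred_pos(i), coins, params,
                  prey_moves_left = pr$prey_moves_left,
                  turns_left_after = pr$turns_left_after,
                  weights = weights, seed = rng_seed,
                  opp_policy = op)$action
    }
  )
}

#' IBS log-likelihood of a planner variant for observed prey choices
#'
#' Rebuilds each prey decision's context (positions, remaining coins and
#' moves) from a trajectory, conditions on the subject's actual preceding
#' moves, and estimates the per-move categorical log likelihood of the
#' parameterized planner by inverse binomial sampling.
#'
#' @param env A `ppenv` environment.
#' @param traj Trajectory from [simulate_planner_game()] (or parsed from the
#'   canonical CSV with the context columns present).
#' @param params A `pplanner` parameter set.
#' @param weights Predator reward weights.
#' @param K_max,repeats,seed Passed to [ibs_loglik()].
#' @return A `ppibs` estimate.
#' @export
planner_ibs <- function(env, traj, params, weights = c(1, 0, 0),
                        K_max = 2500L, repeats = 16L, seed = 1L) {
  sim <- planner_choice_simulator(env, traj, params, weights)
  ibs_loglik(sim$simulate, sim$observed, K_max = K_max, repeats = repeats,
             seed = seed)
}

#' Estimate planner parameters by simulation-based inference
#'
#' Grid method: evaluates the IBS log likelihood of the planner on a lattice
#' of candidate `(opp_temperature, theta)` values and returns the argmax.
#' Rejection method: simulates datasets at parameter values drawn uniformly
#' at random, summarizes each by rich-zone occupancy and capture rate, and
#' returns the mean and SD of the `accept_frac` draws whose summaries lie
#' nearest the data's.
#'
#' @param env A `ppenv` environment (rich zone required for the rejection
#'   summaries).
#' @param trajs List of observed-game trajectories for one subject/condition.
#' @param variant Planner variant being fitted.
#' @param weights Predator reward weights.
#' @param method `"grid"` or `"rejection"`.
#' @param theta_grid,temp_grid Candidate values (grid method).
#' @param budget Simulated parameter draws (rejection method).
#' @param accept_frac Fraction of draws kept (rejection method).
#' @param n_simulations MCTS budget inside fitted models.
#' @param K_max,repeats IBS settings (grid method).
#' @param predator_temperature Predator rule used when re-simulating.
#' @param seed Integer seed.
#' @return List with `theta`, `opp_temperature` point estimates plus
#'   method-specific detail (`grid` table, or kept draws and SDs).
#' @export
estimate_planner_params <- function(env, trajs, variant = "mcts_rw",
                                    weights = c(1, 0, 0),
                                    method = c("grid", "rejection"),
                                    theta_grid = seq(0, 2, length.out = 5),
                                    temp_grid = 0,
                                    budget = 200L, accept_frac = 0.1,
                                    n_simulations = 200L,
                                    K_max = 50L, repeats = 2L,
                                    predator_temperature = 0, seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  if (method == "grid") {
    grid <- expand.grid(theta = theta_grid, opp_temperature = temp_grid)
    grid$loglik <- NA_real_
    for (i in seq_len(nrow(grid))) {
      params <- planner_params(variant, opp_temperature =
                                 grid$opp_temperature[i],
                               theta = grid$theta[i],
                               n_simulations = n_simulations)
      ll <- 0
      for (g in seq_along(trajs)) {
        ll <- ll + planner_ibs(env, trajs[[g]], params, weights,
                               K_max = K_max, repeats = repeats,
                               seed = seed + 1000L * i + g)$loglik
      }
      grid$loglik[i] <- ll
    }
    best <- grid[which.max(grid$loglik), ]
    list(theta = best$theta, opp_temperature = best$opp_temperature,
         grid = grid, method = "grid")
  } else {
    if (length(env$rich_zone) == 0)
      stop("rejection summaries require a rich zone")
    summarize <- function(trajs_list) {
      occ <- vapply(trajs_list, function(tr) {
        pr <- tr[tr$actor == "prey", , drop = FALSE]
        ids <- trajectory_positions(env, pr)
        mean(ids %in% env$rich_zone)
      }, 0)
      cap <- vapply(trajs_list, function(tr) {
        # games end early only on capture
        n_expected <- env$n_turns *
          (env$moves_per_turn$prey + env$moves_per_turn$predator)
        as.numeric(nrow(tr) < n_expected)
      }, 0)
      c(mean(occ), mean(cap))
    }
    obs_sum <- summarize(trajs)
    draws <- data.frame(theta = stats::runif(budget, min(theta_grid),
                                             max(theta_grid)),
                        opp_temperature = if (length(temp_grid) > 1)
                          stats::runif(budget, min(temp_grid), max(temp_grid))
                        else rep(temp_grid[1], budget))
    dist <- numeric(budget)
    for (i in seq_len(budget)) {
      params <- planner_params(variant,
                               opp_temperature = draws$opp_temperature[i],
                               theta = draws$theta[i],
                               n_simulations = n_simulations)
      sims <- lapply(seq_along(trajs), function(g)
        simulate_planner_game(env, params, weights,
                              predator_temperature = predator_temperature,
                              seed = seed + 7919L * i + g)$trajectory)
      dist[i] <- sqrt(sum((summarize(sims) - obs_sum)^2))
    }
    keep <- order(dist)[seq_len(max(1L, round(accept_frac * budget)))]
    if (!length(keep)) stop("no accepted draws; increase budget")
    list(theta = mean(draws$theta[keep]),
         theta_sd = stats::sd(draws$theta[keep]),
         opp_temperature = mean(draws$opp_temperature[keep]),
         opp_temperature_sd = stats::sd(draws$opp_temperature[keep]),
         kept = draws[keep, ], distances = dist[keep], method = "rejection")
  }
}
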
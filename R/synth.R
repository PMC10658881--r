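#' Synthetic environments and simulated participants
#'
#' Generators standing in for the deposited behavioral data: archetypal
#' environments with verified layout properties, and simulated subjects -
#' observers that mix goal inference and policy learning when predicting the
#' predator's moves (experiment 1), and MCTS planners choosing their own
#' moves under threat (experiments 2 and 3).
#'
#' @name synthetic_data
NULL

rect_cells <- function(c0, r0, w, h, width, height) {
  cc <- pmin(pmax(c0:(c0 + w - 1), 0), width - 1)
  rr <- pmin(pmax(r0:(r0 + h - 1), 0), height - 1)
  as.matrix(expand.grid(col = cc, row = rr))
}

connected_all <- function(env) {
  states <- env$graph$states
  if (!length(states)) return(FALSE)
  nbr <- env_nbr(env)
  seen <- logical(env$width * env$height)
  seen[states[1]] <- TRUE
  frontier <- states[1]
  while (length(frontier)) {
    nxt <- unique(as.vector(nbr[frontier, , drop = FALSE]))
    nxt <- nxt[nxt > 0L]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen[states])
}

# does the tree-preferring max-rule predator's route intersect the rich zone?
route_hits_zone <- function(env, n_moves = 30L, seed = 1L) {
  prey <- as_cell(env$prey_start, env$width)
  traj <- simulate_predator(env, c(1, 0, 0),
                            matrix(rep(prey, n_moves), ncol = 2, byrow = TRUE),
                            rule = action_rule("max"), seed = seed,
                            moves_per_turn = 1L)
  ids <- trajectory_positions(env, traj)
  any(ids %in% env$rich_zone)
}

#' Generate an archetypal environment
#'
#' Archetypes encode the layout constraints of the planning analyses:
#' \describe{
#'   \item{`approach`}{a rich coin cluster that is safe to enter - the
#'     predator's greedy route to the trees verifiably avoids it.}
#'   \item{`avoid`}{the rich cluster lies on the predator's verified route to
#'     the trees, so entering it risks capture.}
#'   \item{`decoupled`}{the predator starts on red ground and must travel
#'     across it toward distant trees, decoupling its feature preference from
#'     the features it occupies.}
#'   \item{`practice`}{a wall splits the grid so the predator can never reach
#'     the prey.}
#'   \item{`random`}{random feature clusters and coins (prediction games).}
#' }
#' Layouts are jittered by `seed` and re-drawn until the archetype's path
#' property (checked by simulating the predator) and connectivity hold.
#'
#' @param archetype One of `"approach"`, `"avoid"`, `"decoupled"`,
#'   `"practice"`, `"random"`.
#' @param seed Integer seed.
#' @param width,height Grid size (defaults 21 x 10).
#' @param wall_density Fraction of cells turned into walls (`random`
#'   archetype only; default 0.1 there, matching the task's walled grids).
#' @param moves_per_turn,n_turns Turn structure (defaults to the planning
#'   games' 4 prey / 6 predator moves, 2 turns).
#' @param max_tries Verification retries before failing (default 50).
#' @return A verified `ppenv` environment.
#' @export
generate_environment <- function(archetype = c("approach", "avoid",
                                               "decoupled", "practice",
                                               "random"),
                                 seed = 1L, width = 21L, height = 10L,
                                 wall_density = NULL,
                                 moves_per_turn = list(prey = 4L,
                                                       predator = 6L),
                                 n_turns = 2L, max_tries = 50L) {
  archetype <- match.arg(archetype)
  if (is.null(wall_density))
    wall_density <- if (archetype == "random") 0.1 else 0
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    jx <- sample(-1:1, 1); jy <- sample(-1:1, 1)
    env <- tryCatch(
      build_archetype(archetype, jx, jy, width, height, wall_density,
                      moves_per_turn, n_turns),
      error = function(e) NULL)
    if (is.null(env)) next
    ok <- if (archetype == "practice") TRUE else connected_all(env)
    if (ok && archetype == "approach")
      ok <- !route_hits_zone(env, seed = seed + try)
    if (ok && archetype == "avoid")
      ok <- route_hits_zone(env, seed = seed + try)
    if (ok) return(env)
  }
  stop("could not generate a verified '", archetype, "' environment after ",
       max_tries, " tries (seed ", seed, ")")
}

build_archetype <- function(archetype, jx, jy, width, height, wall_density,
                            moves_per_turn, n_turns) {
  mid <- height %/% 2
  if (archetype %in% c("approach", "avoid")) {
    # Shared geometry: the rich coins fill a single-row corridor walled
    # above and below, with the predator starting at its east mouth - a
    # planner that cannot predict the predator's route must treat the
    # corridor as a trap. Only the tree placement differs: trees on the
    # predator's far side pull its greedy route away from the corridor
    # (approach, safe to enter); trees beyond its west mouth pull the route
    # straight through it (avoid).
    r0 <- mid - 1 + jy
    coins_rich <- rect_cells(9 + jx, r0, 4, 1, width, height)
    rich <- rect_cells(8 + jx, r0, 5, 1, width, height)  # whole corridor
    walls <- rbind(rect_cells(8 + jx, r0 - 1, 5, 1, width, height),
                   rect_cells(8 + jx, r0 + 1, 5, 1, width, height))
    pred_start <- c(13 + jx, r0)
    trees <- if (archetype == "approach")
      rect_cells(width - 4 + jx, 0, 2, 2, width, height)
    else rect_cells(1, r0, 2, 2, width, height)
    sparse <- rbind(c(7 + jx, r0),   # at the west mouth, outside the zone
                    c(2, height - 2), c(3, height - 1),
                    c(width - 3, height - 2), c(width - 2, height - 1))
    hex_environment(width, height, walls = walls, trees = trees,
                    coins = rbind(coins_rich, sparse),
                    predator_start = pred_start,
                    prey_start = c(8 + jx, height - 3),
                    rich_zone = rich, moves_per_turn = moves_per_turn,
                    n_turns = n_turns)
  } else if (archetype == "decoupled") {
    red <- rect_cells(1, mid - 1 + jy, 4, 2, width, height)
    trees <- rect_cells(width - 4 + jx, mid - 1, 2, 2, width, height)
    hex_environment(width, height, trees = trees, red_ground = red,
                    predator_start = c(2, mid), prey_start = c(width - 2,
                                                               height - 1),
                    moves_per_turn = moves_per_turn, n_turns = n_turns)
  } else if (archetype == "practice") {
    wall_col <- width %/% 2
    walls <- cbind(col = wall_col, row = 0:(height - 1))
    trees <- rect_cells(2, 1, 2, 2, width, height)
    coins <- rbind(c(wall_col + 3, 2), c(wall_col + 5, 5),
                   c(width - 2, height - 2))
    hex_environment(width, height, walls = walls, trees = trees,
                    coins = coins, predator_start = c(1, mid),
                    prey_start = c(wall_col + 2, mid),
                    moves_per_turn = moves_per_turn, n_turns = n_turns)
  } else { # random: scattered single-cell features, as in the task's look
    n <- width * height
    pick <- function(k, excl) {
      free <- setdiff(seq_len(n), excl)
      sample(free, k)
    }
    walls <- if (wall_density > 0)
      pick(round(wall_density * n), integer(0)) else integer(0)
    used <- walls
    nf <- max(2L, min(8L, n %/% 12))
    trees <- pick(nf, used); used <- c(used, trees)
    red <- pick(nf, used); used <- c(used, red)
    coins <- pick(min(8L, n %/% 12), used); used <- c(used, coins)
    feat_cells <- ids_to_cells(c(trees, red), width)
    # starts well separated, and the predator away from every feature, so
    # that pursuit and approach phases are long enough to be informative;
    # enumerate valid cells exactly and relax the feature distance when a
    # layout leaves no candidate
    min_sep <- min(10, (width + height) %/% 3)
    min_feat <- min(7, max(width, height) %/% 3)
    free <- setdiff(seq_len(n), used)
    free_cells <- ids_to_cells(free, width)
    feat_dist <- apply(free_cells, 1, function(cc)
      min(apply(feat_cells, 1, function(fc) hex_distance(cc, fc))))
    a <- b <- NULL
    for (mf in seq(min_feat, 1L)) {
      cand_pred <- free[feat_dist >= mf]
      if (!length(cand_pred)) next
      pid <- cand_pred[sample.int(length(cand_pred), 1)]
      a0 <- as_cell(pid, width)
      sep <- apply(free_cells, 1, function(cc) hex_distance(cc, a0))
      cand_prey <- free[sep >= min_sep & free != pid]
      if (!length(cand_prey)) next
      a <- a0
      b <- as_cell(cand_prey[sample.int(length(cand_prey), 1)], width)
      break
    }
    if (is.null(a)) stop("no valid start placement")
    env <- hex_environment(width, height,
                           walls = if (length(walls))
                             ids_to_cells(walls, width) else NULL,
                           trees = ids_to_cells(trees, width),
                           red_ground = ids_to_cells(red, width),
                           coins = ids_to_cells(coins, width),
                           predator_start = a, prey_start = b,
                           moves_per_turn = moves_per_turn,
                           n_turns = n_turns)
    if (!connected_all(env)) stop("disconnected")
    env
  }
}

EXP1_WEIGHTS <- list(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 0, 1))

# random legal prey walk, one move per prey turn
random_prey_walk <- function(env, start, n_turns) {
  pos <- start
  path <- matrix(NA_integer_, n_turns, 2)
  for (t in seq_len(n_turns)) {
    path[t, ] <- pos
    nb <- neighbors(env, pos)
    k <- sample.int(nrow(nb), 1)
    pos <- c(nb$col[k], nb$row[k])
  }
  path
}

squeeze01 <- function(y, n = 100) y * (n - 1) / n + 1 / (2 * n)

#' Simulate a full experiment's data
#'
#' Experiment 1: per subject, `n_games` random environments; the predator
#' (max rule, true weights of the subject's condition) makes 2 moves per
#' turn for 10 turns while the prey random-walks 1 move per turn; the
#' simulated observer predicts every predator move from the weighted
#' combination model (weight `W` on goal inference), reports the model
#' probability of its prediction as confidence, and rates the weights at
#' game end (calibrated truth plus Gaussian noise, rounded to the 9-point
#' scale). Experiment 2: per subject, approach and avoid environments (4
#' prey / 6 predator moves, 2 turns); choices from an MCTS planner.
#' Experiment 3: 2 x 3 design crossing planning horizon (short: 1/2 moves,
#' 12 turns; long: 4/8 moves, 3 turns) with predator predictability
#' (predictable max rule; unpredictable softmax temperature 1; reducible =
#' predictable but weights initially unknown to the subject); planners on
#' safe-archetype environments.
#'
#' @param experiment 1, 2, or 3.
#' @param n_subjects Subjects per condition (defaults: 50, 80, 40).
#' @param seed Integer seed; identical seeds reproduce identical bundles.
#' @param n_games Games per subject (experiment 1; default 10).
#' @param n_envs Environments per subject (experiments 2-3; default 6 for
#'   experiment 2, 4 for experiment 3).
#' @param subject_spec Optional overrides: list with any of `W`, `alpha`,
#'   `lambda`, `rating_noise`, `theta`, `opp_temperature`, `decision_noise`,
#'   `variant`, `n_simulations` (fixed values instead of the population
#'   distributions).
#' @param conditions Subset of conditions to simulate (default all).
#' @return A `ppbundle` list: `experiment`, `envs` (named list),
#'   `trajectories`, `predictions` + `ratings` (experiment 1) or `subjects`
#'   summary, all in the canonical CSV schemas.
#' @export
simulate_experiment <- function(experiment, n_subjects = NULL, seed = 1L,
                                n_games = 10L, n_envs = NULL,
                                subject_spec = list(), conditions = NULL) {
  stopifnot(experiment %in% 1:3)
  set.seed(seed)
  if (experiment == 1) {
    simulate_exp1(n_subjects %||% 50L, seed, n_games, subject_spec,
                  conditions %||% names(EXP1_WEIGHTS))
  } else if (experiment == 2) {
    simulate_exp23(2L, n_subjects %||% 80L, seed, n_envs %||% 6L,
                   subject_spec, conditions %||% "exp2")
  } else {
    conds <- conditions %||% as.vector(outer(c("short", "long"),
                                             c("predictable", "irreducible",
                                               "reducible"), paste,
                                             sep = "_"))
    simulate_exp23(3L, n_subjects %||% 40L, seed, n_envs %||% 4L,
                   subject_spec, conds)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simulate_exp1 <- function(n_subjects, seed, n_games, spec, conditions) {
  envs <- list(); trajs <- list(); preds <- list(); rates <- list()
  subj_id <- 0L
  for (cond in conditions) {
    w <- EXP1_WEIGHTS[[cond]]
    for (s in seq_len(n_subjects)) {
      subj_id <- subj_id + 1L
      sid <- sprintf("s%03d", subj_id)
      # population distributions: observers lean on goal inference
      W <- spec$W %||% stats::rbeta(1, 8.7, 1.3)
      alpha <- spec$alpha %||% stats::runif(1, 0.2, 0.9)
      lambda <- spec$lambda %||% stats::runif(1, 0, 1)
      rating_noise <- spec$rating_noise %||% 0.5
      game_envs <- list(); data_rows <- list()
      for (g in seq_len(n_games)) {
        env <- generate_environment("random",
                                    seed = sample.int(1e6, 1),
                                    moves_per_turn = list(prey = 1L,
                                                          predator = 2L),
                                    n_turns = 10L)
        game_envs[[g]] <- env
        traj <- simulate_chase(env, w, seed = sample.int(1e6, 1))
        traj$subject_id <- sid; traj$experiment <- 1L
        traj$condition <- cond; traj$game <- g
        trajs[[length(trajs) + 1]] <- traj
        data_rows[[g]] <- data.frame(
          subject_id = sid, experiment = 1L, condition = cond, game = g,
          trial = seq_len(nrow(traj)), turn = traj$turn, step = traj$step,
          col = traj$col, row = traj$row,
          prey_col = traj$prey_col, prey_row = traj$prey_row,
          obs_action = traj$action, stringsAsFactors = FALSE)
      }
      dat <- do.call(rbind, data_rows)
      ctx <- prediction_context(dat, game_envs, w)
      pred_idx <- simulate_predictions(ctx, "combined",
                                       list(alpha = alpha, lambda = lambda,
                                            W = W),
                                       seed = sample.int(1e6, 1))
      probs <- prediction_model_probs(ctx, "combined",
                                      list(alpha = alpha, lambda = lambda,
                                           W = W))
      dat$pred_action <- HEX_DIRECTIONS[pred_idx]
      dat$confidence <- squeeze01(probs[cbind(seq_len(nrow(dat)),
                                              pred_idx)])
      preds[[length(preds) + 1]] <- dat
      truth <- calibrate_weights(w)
      for (g in seq_len(n_games)) {
        r <- pmin(pmax(round(truth + stats::rnorm(3, 0, rating_noise)),
                       -4), 4)
        rates[[length(rates) + 1]] <- data.frame(
          subject_id = sid, experiment = 1L, condition = cond, game = g,
          rating_trees = r[1], rating_red = r[2], rating_prey = r[3],
          W = W, alpha = alpha, lambda = lambda, stringsAsFactors = FALSE)
      }
      names(game_envs) <- paste0(sid, "_g", seq_len(n_games))
      envs <- c(envs, game_envs)
    }
  }
  structure(list(experiment = 1L, envs = envs,
                 trajectories = do.call(rbind, trajs),
                 predictions = do.call(rbind, preds),
                 ratings = do.call(rbind, rates)),
            class = "ppbundle")
}

exp3_structure <- function(condition) {
  if (startsWith(condition, "short"))
    list(moves_per_turn = list(prey = 1L, predator = 2L), n_turns = 12L)
  else
    list(moves_per_turn = list(prey = 4L, predator = 8L), n_turns = 3L)
}

simulate_exp23 <- function(experiment, n_subjects, seed, n_envs, spec,
                           conditions) {
  envs <- list(); trajs <- list(); subjects <- list()
  subj_id <- 0L
  for (cond in conditions) {
    pred_temp <- if (experiment == 3 && grepl("irreducible", cond)) 1 else 0
    struct <- if (experiment == 2)
      list(moves_per_turn = list(prey = 4L, predator = 6L), n_turns = 2L)
    else exp3_structure(cond)
    for (s in seq_len(n_subjects)) {
      subj_id <- subj_id + 1L
      sid <- sprintf("s%03d", subj_id)
      variant <- spec$variant %||% "mcts_rw"
      theta <- spec$theta %||% (
        if (pred_temp > 0) max(stats::rnorm(1, 0.93, 0.58), 0)
        else max(stats::rnorm(1, 0.56, 0.49), 0))
      opp_t <- spec$opp_temperature %||% 0
      noise <- spec$decision_noise %||% 0.05
      nsim <- spec$n_simulations %||% 1000L
      params <- planner_params(variant, opp_temperature = opp_t,
                               theta = theta, n_simulations = nsim)
      for (g in seq_len(n_envs)) {
        arch <- if (experiment == 2) {
          if (g %% 2 == 1) "avoid" else "approach"
        } else "approach"   # the safe archetype; threat varies by condition
        env <- generate_environment(arch, seed = sample.int(1e6, 1),
                                    moves_per_turn = struct$moves_per_turn,
                                    n_turns = struct$n_turns)
        key <- paste0(sid, "_g", g)
        envs[[key]] <- env
        game <- simulate_planner_game(env, params, c(1, 0, 0),
                                      predator_temperature = pred_temp,
                                      decision_noise = noise,
                                      seed = sample.int(1e6, 1))
        tr <- game$trajectory
        tr$subject_id <- sid; tr$experiment <- experiment
        tr$condition <- cond; tr$game <- g
        tr$archetype <- arch
        trajs[[length(trajs) + 1]] <- tr
      }
      subjects[[length(subjects) + 1]] <- data.frame(
        subject_id = sid, experiment = experiment, condition = cond,
        variant = variant, theta = theta, opp_temperature = opp_t,
        decision_noise = noise, stringsAsFactors = FALSE)
    }
  }
  structure(list(experiment = experiment, envs = envs,
                 trajectories = do.call(rbind, trajs),
                 subjects = do.call(rbind, subjects)),
            class = "ppbundle")
}

#' Write a simulated bundle to disk in the canonical formats
#'
#' Environments as JSON (one per game), tables as CSV.
#'
#' @param bundle A `ppbundle` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  env_dir <- file.path(dir, "envs")
  dir.create(env_dir, showWarnings = FALSE)
  for (nm in names(bundle$envs))
    write_environment(bundle$envs[[nm]], file.path(env_dir,
                                                   paste0(nm, ".json")))
  utils::write.csv(bundle$trajectories,
                   file.path(dir, "trajectories.csv"), row.names = FALSE)
  if (!is.null(bundle$predictions))
    utils::write.csv(bundle$predictions,
                     file.path(dir, "predictions.csv"), row.names = FALSE)
  if (!is.null(bundle$ratings))
    utils::write.csv(bundle$ratings, file.path(dir, "ratings.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$subjects))
    utils::write.csv(bundle$subjects, file.path(dir, "subjects.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir Directory containing `envs/` and the CSV tables.
#' @return A `ppbundle` list.
#' @export
read_bundle <- function(dir) {
  env_files <- list.files(file.path(dir, "envs"), full.names = TRUE,
                          pattern = "\\.json$")
  envs <- lapply(env_files, read_environment)
  names(envs) <- sub("\\.json$", "", basename(env_files))
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE)
    else NULL
  }
  traj <- rd("trajectories.csv")
  structure(list(experiment = traj$experiment[1], envs = envs,
                 trajectories = traj, predictions = rd("predictions.csv"),
                 ratings = rd("ratings.csv"), subjects = rd("subjects.csv")),
            class = "ppbundle")
}
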
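#' @useDynLib preypred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical direction order (clockwise from north). Flat-top hexagons in
# "odd-q" offset coordinates: odd columns are shifted half a cell downwards,
# (0,0) is the top-left cell, all indices 0-based.
HEX_DIRECTIONS <- c("N", "NE", "SE", "S", "SW", "NW")

# (dcol, drow) offsets for even and odd columns.
.HEX_OFF_EVEN <- matrix(c(0, -1, 1, -1, 1, 0, 0, 1, -1, 0, -1, -1),
                        nrow = 6, byrow = TRUE,
                        dimnames = list(HEX_DIRECTIONS, c("dcol", "drow")))
.HEX_OFF_ODD <- matrix(c(0, -1, 1, 0, 1, 1, 0, 1, -1, 1, -1, 0),
                       nrow = 6, byrow = TRUE,
                       dimnames = list(HEX_DIRECTIONS, c("dcol", "drow")))

#' Direction labels of the hexagonal lattice
#'
#' The six travel directions on the flat-top hexagonal grid, in the fixed
#' canonical (clockwise from north) order used throughout the package.
#'
#' @return Character vector of length 6.
#' @export
hex_directions <- function() HEX_DIRECTIONS

## cell <-> id helpers (row-major ids, 1-based; cells are c(col, row), 0-based)
cell_id <- function(col, row, width) row * width + col + 1L
id_col <- function(id, width) (id - 1L) %% width
id_row <- function(id, width) (id - 1L) %/% width
as_cell <- function(id, width) c(id_col(id, width), id_row(id, width))

cells_to_ids <- function(cells, width) {
  if (is.null(cells) || length(cells) == 0) return(integer(0))
  m <- if (is.matrix(cells)) cells else matrix(unlist(cells), ncol = 2, byrow = TRUE)
  cell_id(as.integer(m[, 1]), as.integer(m[, 2]), width)
}

ids_to_cells <- function(ids, width) {
  cbind(col = id_col(ids, width), row = id_row(ids, width))
}

#' Construct a hexagonal gridworld environment
#'
#' Builds the task environment: a `width` x `height` flat-top hexagonal grid
#' (odd-q offset coordinates) from which `walls` cells are removed, carrying
#' three binary features (trees, red ground, and the prey's current cell),
#' coins that the prey collects for points, and start positions for both
#' agents. Cells are given as length-2 integer vectors `c(col, row)` (0-based)
#' or as n x 2 matrices.
#'
#' @param width,height Grid dimensions (defaults 21 x 10, the task's size).
#' @param walls,trees,red_ground,coins,rich_zone Cell sets (matrix or list of
#'   `c(col, row)`; may be empty). `rich_zone` annotates the densely rewarded
#'   area used by the avoidance analyses.
#' @param predator_start,prey_start Start cells.
#' @param moves_per_turn Named list/vector with elements `prey` and
#'   `predator`: moves each actor makes per turn.
#' @param n_turns Number of turns per game.
#' @param capture_symmetric If `TRUE` (default) capture fires whenever the two
#'   agents co-locate after either actor's move; if `FALSE`, only when the
#'   predator enters the prey's cell.
#' @return An object of class `ppenv`.
#' @export
hex_environment <- function(width = 21L, height = 10L, walls = NULL,
                            trees = NULL, red_ground = NULL, coins = NULL,
                            predator_start, prey_start, rich_zone = NULL,
                            moves_per_turn = list(prey = 1L, predator = 2L),
                            n_turns = 10L, capture_symmetric = TRUE) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 1, height >= 1)
  env <- structure(list(
    width = width, height = height,
    walls = sort(unique(cells_to_ids(walls, width))),
    trees = sort(unique(cells_to_ids(trees, width))),
    red_ground = sort(unique(cells_to_ids(red_ground, width))),
    coins = sort(unique(cells_to_ids(coins, width))),
    predator_start = cells_to_ids(matrix(predator_start, ncol = 2), width),
    prey_start = cells_to_ids(matrix(prey_start, ncol = 2), width),
    rich_zone = sort(unique(cells_to_ids(rich_zone, width))),
    moves_per_turn = list(prey = as.integer(moves_per_turn$prey),
                          predator = as.integer(moves_per_turn$predator)),
    n_turns = as.integer(n_turns),
    capture_symmetric = isTRUE(capture_symmetric)
  ), class = "ppenv")
  validate_environment(env)
  env$graph <- build_graph(env)
  env
}

validate_environment <- function(env) {
  n <- env$width * env$height
  all_ids <- c(env$walls, env$trees, env$red_ground, env$coins,
               env$predator_start, env$prey_start, env$rich_zone)
  if (length(all_ids) && (min(all_ids) < 1 || max(all_ids) > n))
    stop("cell indices out of bounds")
  feat <- c(env$trees, env$red_ground, env$coins,
            env$predator_start, env$prey_start, env$rich_zone)
  if (any(feat %in% env$walls))
    stop("feature sets and start positions must exclude walls")
  if (env$predator_start == env$prey_start)
    stop("predator_start and prey_start must differ")
  if (env$moves_per_turn$prey < 1 || env$moves_per_turn$predator < 1)
    stop("moves_per_turn entries must be >= 1")
  invisible(env)
}

# Adjacency of the full grid: n_cells x 6 matrix of neighbor ids in canonical
# direction order; 0 marks out-of-bounds or wall. Also the ordered state list.
build_graph <- function(env) {
  n <- env$width * env$height
  ids <- seq_len(n)
  col <- id_col(ids, env$width); row <- id_row(ids, env$width)
  nbr <- matrix(0L, n, 6, dimnames = list(NULL, HEX_DIRECTIONS))
  odd <- col %% 2L == 1L
  for (d in 1:6) {
    dc <- ifelse(odd, .HEX_OFF_ODD[d, 1], .HEX_OFF_EVEN[d, 1])
    dr <- ifelse(odd, .HEX_OFF_ODD[d, 2], .HEX_OFF_EVEN[d, 2])
    nc <- col + dc; nr <- row + dr
    ok <- nc >= 0 & nc < env$width & nr >= 0 & nr < env$height
    tid <- ifelse(ok, cell_id(nc, nr, env$width), 0L)
    tid[tid %in% env$walls] <- 0L
    nbr[, d] <- as.integer(tid)
  }
  is_wall <- ids %in% env$walls
  nbr[is_wall, ] <- 0L
  list(nbr = nbr, states = ids[!is_wall])
}

env_nbr <- function(env) {
  if (is.null(env$graph)) env$graph <- build_graph(env)
  env$graph$nbr
}

#' Passable states of an environment
#'
#' @param env A `ppenv` environment.
#' @return n x 2 integer matrix of non-wall cells `(col, row)` in fixed order.
#' @export
env_states <- function(env) {
  if (is.null(env$graph)) env$graph <- build_graph(env)
  ids_to_cells(env$graph$states, env$width)
}

check_cell <- function(env, cell) {
  id <- cells_to_ids(matrix(cell, ncol = 2), env$width)
  cl <- matrix(cell, ncol = 2)
  if (cl[1] < 0 || cl[1] >= env$width || cl[2] < 0 || cl[2] >= env$height)
    stop("invalid cell: out of bounds")
  if (id %in% env$walls) stop("invalid cell: wall")
  id
}

#' Passable neighbors of a cell
#'
#' Enumerates the in-bounds, non-wall neighbors of `cell` under the fixed
#' flat-top odd-q hex layout, in canonical direction order.
#'
#' @param env A `ppenv` environment.
#' @param cell `c(col, row)` cell (0-based).
#' @return data.frame with columns `direction`, `col`, `row`.
#' @export
neighbors <- function(env, cell) {
  id <- check_cell(env, cell)
  nb <- env_nbr(env)[id, ]
  keep <- nb > 0L
  data.frame(direction = HEX_DIRECTIONS[keep],
             col = id_col(nb[keep], env$width),
             row = id_row(nb[keep], env$width),
             stringsAsFactors = FALSE)
}

#' Binary feature vector of a cell
#'
#' Features in fixed order (trees, red ground, prey): entry `i` is 1 iff the
#' cell carries that feature, with the prey feature set when `cell` equals
#' `prey_at`. The prey feature tracks the prey's movements, so feature maps
#' must be re-derived whenever the prey moves.
#'
#' @param env A `ppenv` environment.
#' @param cell,prey_at Cells `c(col, row)`.
#' @return Numeric vector of length 3.
#' @export
feature_vector <- function(env, cell, prey_at) {
  id <- check_cell(env, cell)
  pid <- cells_to_ids(matrix(prey_at, ncol = 2), env$width)
  c(trees = as.numeric(id %in% env$trees),
    red_ground = as.numeric(id %in% env$red_ground),
    prey = as.numeric(id == pid))
}

# Feature matrix over all cells (ids) for a given prey id; n_cells x 3.
feature_matrix <- function(env, prey_id) {
  n <- env$width * env$height
  f <- matrix(0, n, 3, dimnames = list(NULL, c("trees", "red_ground", "prey")))
  f[env$trees, 1] <- 1
  f[env$red_ground, 2] <- 1
  f[prey_id, 3] <- 1
  f
}

#' Build the predator's feature-based MDP
#'
#' Constructs the deterministic MDP over the environment's passable cells:
#' up to six movement actions per state, each entering the neighboring cell,
#' with reward `R(s, a) = f(s') . r` where `f(s')` is the entered state's
#' feature vector given the prey at `prey_at` and `r` the reward weights
#' (order trees, red ground, prey). Because the prey feature moves, the MDP
#' must be rebuilt when the prey does.
#'
#' @param env A `ppenv` environment.
#' @param weights Numeric length-3 reward weights.
#' @param prey_at Prey cell `c(col, row)`.
#' @param discount Discount factor in `[0, 1)`; default 0.9.
#' @return An object of class `ppmdp`: ordered `states` (ids), `next_id`
#'   (n_states x 6, NA where an action is unavailable), `reward` (n_states x
#'   6), `discount`, and index maps.
#' @export
build_mdp <- function(env, weights, prey_at, discount = 0.9) {
  stopifnot(length(weights) == 3, all(is.finite(weights)),
            discount >= 0, discount < 1)
  prey_id <- check_cell(env, prey_at)
  states <- env$graph$states
  if (is.null(states)) states <- build_graph(env)$states
  if (length(states) == 0) stop("environment has no passable states")
  nbr <- env_nbr(env)[states, , drop = FALSE]
  nbr[nbr == 0L] <- NA_integer_
  fmat <- feature_matrix(env, prey_id)
  rew_by_cell <- as.numeric(fmat %*% weights)
  reward <- matrix(rew_by_cell[nbr], nrow(nbr), 6)
  index <- integer(env$width * env$height)
  index[states] <- seq_along(states)
  structure(list(states = states, next_id = nbr, reward = reward,
                 discount = discount, index = index,
                 width = env$width, prey_id = prey_id, weights = weights),
            class = "ppmdp")
}

#' Initial game state
#'
#' @param env A `ppenv` environment.
#' @return A `ppgame` list: `prey`, `predator` (cells), `coins_remaining`
#'   (matrix), `points`, `turn`, `captured`, `coins_collected`.
#' @export
new_game_state <- function(env) {
  structure(list(prey = as_cell(env$prey_start, env$width),
                 predator = as_cell(env$predator_start, env$width),
                 coins_remaining = ids_to_cells(env$coins, env$width),
                 points = 0L, turn = 1L, captured = FALSE,
                 coins_collected = 0L),
            class = "ppgame")
}

#' Advance the game by one move
#'
#' Applies one movement action for the given actor. The prey collects a coin
#' (+100 points, coin removed) on entering a coin cell; co-location of the two
#' agents triggers capture (-1000 points). Under the default symmetric capture
#' rule, capture fires after either actor's move; with
#' `capture_symmetric = FALSE` in the environment only the predator's move can
#' capture.
#'
#' @param state A `ppgame` state (not yet captured).
#' @param env A `ppenv` environment.
#' @param actor `"prey"` or `"predator"`.
#' @param action Direction label (see [hex_directions()]).
#' @return Updated `ppgame` state.
#' @export
step_game <- function(state, env, actor, action) {
  stopifnot(inherits(state, "ppgame"))
  if (state$captured) stop("game is over: prey has been captured")
  actor <- match.arg(actor, c("prey", "predator"))
  d <- match(action, HEX_DIRECTIONS)
  if (is.na(d)) stop("unknown direction: ", action)
  from <- if (actor == "prey") state$prey else state$predator
  id <- check_cell(env, from)
  to_id <- env_nbr(env)[id, d]
  if (to_id == 0L) stop("invalid action: moves into a wall or off the grid")
  to <- as_cell(to_id, env$width)
  if (actor == "prey") {
    state$prey <- to
    cr <- state$coins_remaining
    if (length(cr) && nrow(cr) > 0) {
      hit <- cr[, 1] == to[1] & cr[, 2] == to[2]
      if (any(hit)) {
        state$coins_remaining <- cr[!hit, , drop = FALSE]
        state$points <- state$points + 100L
        state$coins_collected <- state$coins_collected + 1L
      }
    }
  } else {
    state$predator <- to
  }
  colocated <- all(state$prey == state$predator)
  capture <- colocated && (actor == "predator" || env$capture_symmetric)
  if (capture) {
    state$captured <- TRUE
    state$points <- state$points - 1000L
  }
  state
}

#' Read an environment from JSON
#'
#' JSON schema: `width`, `height`, `walls`/`trees`/`red_ground`/`coins`/
#' `rich_zone` as arrays of `[col, row]` pairs, `predator_start`,
#' `prey_start`, `moves_per_turn` (`{"prey": ..., "predator": ...}`),
#' `n_turns`.
#'
#' @param path File path.
#' @return A `ppenv` environment.
#' @export
read_environment <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_pairs <- function(x) if (is.null(x) || length(x) == 0) NULL else
    matrix(as.integer(unlist(x)), ncol = 2, byrow = !is.matrix(x))
  pair_field <- function(x) {
    if (is.null(x)) NULL
    else if (is.matrix(x)) x
    else matrix(as.integer(unlist(x)), ncol = 2, byrow = TRUE)
  }
  hex_environment(width = j$width, height = j$height,
                  walls = pair_field(j$walls), trees = pair_field(j$trees),
                  red_ground = pair_field(j$red_ground),
                  coins = pair_field(j$coins),
                  predator_start = as.integer(unlist(j$predator_start)),
                  prey_start = as.integer(unlist(j$prey_start)),
                  rich_zone = pair_field(j$rich_zone),
                  moves_per_turn = as.list(j$moves_per_turn),
                  n_turns = j$n_turns)
}

#' Write an environment to JSON
#'
#' @param env A `ppenv` environment.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  pairs <- function(ids) {
    if (length(ids) == 0) return(list())
    m <- ids_to_cells(ids, env$width)
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
  }
  j <- list(width = env$width, height = env$height,
            walls = pairs(env$walls), trees = pairs(env$trees),
            red_ground = pairs(env$red_ground), coins = pairs(env$coins),
            predator_start = as.integer(as_cell(env$predator_start, env$width)),
            prey_start = as.integer(as_cell(env$prey_start, env$width)),
            rich_zone = pairs(env$rich_zone),
            moves_per_turn = env$moves_per_turn, n_turns = env$n_turns)
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  invisible(path)
}

#' Count of joint prey-predator position states
#'
#' Size of the interactive state space over the two agents' positions: the
#' squared number of passable cells (44,100 on the wall-free 21 x 10 grid).
#'
#' @param env A `ppenv` environment.
#' @return Integer scalar.
#' @export
joint_state_count <- function(env) {
  ns <- length(if (is.null(env$graph)) build_graph(env)$states else env$graph$states)
  ns^2
}
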
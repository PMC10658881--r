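#' Inverse reinforcement learning of the predator's reward weights
#'
#' Estimators of the threatening agent's per-feature reward weights from an
#' observed trajectory: three model-free baselines (feature occupancy,
#' direction-of-travel feature counts, and their relative variant), an
#' infinite-horizon maximum causal entropy model (MaxEnt), and a
#' hypothesis-testing Bayesian model (HypTest) that scores candidate weights
#' by the softmax likelihood of each observed action under successor-
#' representation Q values. All estimators return calibrated weights on the
#' rating scale \[-4, 4\].
#'
#' @name reward_inference
NULL

#' Calibrate raw weight estimates to the rating scale
#'
#' Divides by the maximum absolute entry and multiplies by 4, mapping
#' estimates onto the 9-point rating scale's range; the zero vector passes
#' through unchanged.
#'
#' @param x Numeric vector.
#' @return Numeric vector with `max(abs(x)) == 4` (or all zeros).
#' @export
calibrate_weights <- function(x) {
  m <- max(abs(x))
  if (!is.finite(m) || m == 0) return(x * 0)
  x / m * 4
}

irl_estimate <- function(model, raw, samples = NULL, flagged = FALSE) {
  structure(list(model = model, raw = as.numeric(raw),
                 point = calibrate_weights(as.numeric(raw)),
                 posterior_samples = samples, flagged = flagged),
            class = "ppirl")
}

#' @param x A `ppirl` estimate.
#' @param ... Unused.
#' @method print ppirl
#' @export
print.ppirl <- function(x, ...) {
  cat("IRL estimate (", x$model, ")\n", sep = "")
  cat("  calibrated weights:", sprintf("%.3f", x$point), "\n")
  if (x$flagged) cat("  [flagged]\n")
  invisible(x)
}

# predator steps of a trajectory with per-step prey positions
predator_steps <- function(traj) {
  tr <- traj[traj$actor == "predator", , drop = FALSE]
  if (nrow(tr) == 0) stop("trajectory contains no predator steps")
  tr
}

#' Model-free IRL: feature occupancy counts
#'
#' Sums the binary feature vectors of every state the predator occupied,
#' with the feature map re-derived at each step so the prey feature follows
#' the prey's movements.
#'
#' @param env A `ppenv` environment.
#' @param traj Trajectory data.frame (predator rows are used; see
#'   [simulate_predator()]).
#' @return A `ppirl` estimate.
#' @export
mf_occupancy <- function(env, traj) {
  tr <- predator_steps(traj)
  pos <- trajectory_positions(env, tr)          # s_0 .. s_T (cell ids)
  prey_ids <- cell_id(tr$prey_col, tr$prey_row, env$width)
  prey_seq <- c(prey_ids[1], prey_ids)          # snapshot per occupied state
  raw <- c(0, 0, 0)
  for (i in seq_along(pos)) {
    f <- feature_matrix(env, prey_seq[i])[pos[i], ]
    raw <- raw + f
  }
  irl_estimate("occupancy", raw)
}

# cells traversed by continuing from `id` in direction `d` until a wall or
# the grid edge (excluding the starting cell)
ray_cells <- function(env, id, d) {
  nbr <- env_nbr(env)
  out <- integer(0)
  cur <- nbr[id, d]
  while (cur > 0L) {
    out <- c(out, cur)
    cur <- nbr[cur, d]
  }
  out
}

#' Model-free IRL: direction-of-travel feature counts
#'
#' Non-relative form: at each observed step, sums the features of the states
#' the agent would traverse by repeating its chosen action until a wall or
#' the grid edge. Relative form: additionally accumulates the same ray counts
#' for the other available actions, normalizes both count vectors to unit sum
#' and reports their difference (observed minus alternatives); an all-zero
#' count vector normalizes to zeros.
#'
#' @param env A `ppenv` environment.
#' @param traj Trajectory data.frame.
#' @param relative Use the relative (observed vs. alternative directions)
#'   variant?
#' @return A `ppirl` estimate.
#' @export
mf_direction <- function(env, traj, relative = FALSE) {
  tr <- predator_steps(traj)
  obs_counts <- c(0, 0, 0)
  alt_counts <- c(0, 0, 0)
  flagged <- FALSE
  for (i in seq_len(nrow(tr))) {
    id <- cell_id(tr$col[i], tr$row[i], env$width)
    fmat <- feature_matrix(env, cell_id(tr$prey_col[i], tr$prey_row[i],
                                        env$width))
    d_obs <- match(tr$action[i], HEX_DIRECTIONS)
    cells <- ray_cells(env, id, d_obs)
    if (length(cells))
      obs_counts <- obs_counts + colSums(fmat[cells, , drop = FALSE])
    if (relative) {
      for (d in which(env_nbr(env)[id, ] > 0L)) {
        if (d == d_obs) next
        cells <- ray_cells(env, id, d)
        if (length(cells))
          alt_counts <- alt_counts + colSums(fmat[cells, , drop = FALSE])
      }
    }
  }
  if (!relative) return(irl_estimate("direction", obs_counts))
  norm1 <- function(x) {
    s <- sum(x)
    if (s == 0) { flagged <<- TRUE; return(x * 0) }
    x / s
  }
  raw <- norm1(obs_counts) - norm1(alt_counts)
  irl_estimate("relative", raw, flagged = flagged)
}

#' Log-sum-exp soft maximum
#'
#' The smoothed maximum `log sum exp(x)` used by soft value iteration;
#' computed with the max-shift trick for numerical stability.
#'
#' @param x Numeric vector.
#' @return Scalar; satisfies `max(x) <= softmax_vi(x) <= max(x) + log(length(x))`.
#' @export
softmax_vi <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# soft value iteration (log-sum-exp Bellman backup); vectorized like
# value_iteration()
soft_value_iteration <- function(mdp, max_iters = 300L, tol = 1e-6, V0 = NULL) {
  ns <- length(mdp$states)
  nxt <- mdp$index[mdp$next_id]
  dim(nxt) <- dim(mdp$next_id)
  valid <- !is.na(nxt)
  nxt0 <- ifelse(valid, nxt, 1L)
  has_action <- rowSums(valid) > 0
  V <- if (is.null(V0)) numeric(ns) else as.numeric(V0)
  g <- mdp$discount
  R <- mdp$reward
  for (k in seq_len(max_iters)) {
    Q <- R + g * matrix(V[nxt0], ns, 6)
    Q[!valid] <- -Inf
    m <- pmax(Q[, 1], Q[, 2], Q[, 3], Q[, 4], Q[, 5], Q[, 6])
    Vn <- m + log(rowSums(exp(Q - m)))
    Vn[!has_action] <- 0
    done <- max(abs(Vn - V)) < tol
    V <- Vn
    if (done) break
  }
  Q <- R + g * matrix(V[nxt0], ns, 6)
  Q[!valid] <- NA_real_
  list(V = V, Q = Q, valid = valid, nxt = nxt)
}

#' Maximum causal entropy IRL (infinite horizon)
#'
#' Gradient-based feature matching: starting from zero weights, alternates
#' (i) soft value iteration under the current weights, (ii) a softmax policy
#' (temperature 1) and its stationary state-visitation distribution (power
#' iteration from the trajectory's first state), (iii) expected feature
#' counts under that distribution versus the normalized observed feature
#' frequencies, and (iv) a gradient step on the weights along the feature
#' mismatch, with learning rate alpha decaying as k^(-lambda). The feature map is
#' held static with the prey frozen at its trajectory-start position, which
#' is why this estimator cannot track a prey-preferring agent.
#'
#' @param env A `ppenv` environment.
#' @param traj Trajectory data.frame.
#' @param max_iters Maximum gradient iterations (default 1000).
#' @param alpha,lambda Learning-rate schedule parameters (defaults 2, 0.1).
#' @param tol Convergence tolerance on `max |deltaF|` (default 1e-3; under a
#'   softmax policy the expected occupancy of an avoided feature approaches 0
#'   only asymptotically, so a tighter tolerance buys no accuracy).
#' @param discount Discount factor (default 0.9).
#' @return A `ppirl` estimate (`flagged` if the iteration cap was reached).
#' @export
maxent_fit <- function(env, traj, max_iters = 1000L, alpha = 2, lambda = 0.1,
                       tol = 1e-3, discount = 0.9) {
  tr <- predator_steps(traj)
  prey0 <- c(tr$prey_col[1], tr$prey_row[1])
  pos <- trajectory_positions(env, tr)
  fmat_all <- feature_matrix(env, cell_id(prey0[1], prey0[2], env$width))
  f_obs <- colMeans(fmat_all[pos, , drop = FALSE])

  mdp0 <- build_mdp(env, c(0, 0, 0), prey0, discount)
  states <- mdp0$states
  f_states <- fmat_all[states, , drop = FALSE]
  start_idx <- mdp0$index[pos[1]]
  ns <- length(states)

  # static structures shared by every gradient iteration
  nxt <- mdp0$index[mdp0$next_id]
  dim(nxt) <- dim(mdp0$next_id)
  valid <- !is.na(nxt)
  nxt0 <- ifelse(valid, nxt, 1L)
  has_action <- rowSums(valid) > 0
  next_cell <- ifelse(valid, mdp0$next_id, 1L)
  ok <- as.vector(valid)
  src <- rep(seq_len(ns), 6)[ok]
  dst <- as.vector(nxt0)[ok]
  # one sparse transition skeleton, refilled in place each iteration: find
  # the permutation from triplet order to the dgCMatrix slot order
  Tmat <- Matrix::sparseMatrix(i = dst, j = src, x = seq_along(dst),
                               dims = c(ns, ns))
  slot_perm <- order(Tmat@x)

  row_max <- function(Q) Q[cbind(seq_len(ns), max.col(Q, ties.method = "first"))]

  r_hat <- c(0, 0, 0)
  V <- numeric(ns)
  converged <- FALSE
  dF_prev <- NULL
  plateau <- 0L
  D <- NULL
  for (k in seq_len(max_iters)) {
    R <- matrix(as.numeric(fmat_all %*% r_hat)[next_cell], ns, 6)
    R[!valid] <- -Inf
    # soft value iteration (log-sum-exp backup), warm-started
    for (sweep in seq_len(300L)) {
      Q <- R + discount * matrix(V[nxt0], ns, 6)
      m <- row_max(Q)
      Vn <- m + log(rowSums(exp(Q - m)))
      Vn[!has_action] <- 0
      done <- max(abs(Vn - V)) < 1e-6
      V <- Vn
      if (done) break
    }
    Q <- R + discount * matrix(V[nxt0], ns, 6)
    # softmax policy (temperature 1) and its stationary visitation
    m <- row_max(Q)
    P <- exp(Q - m)
    P <- P / rowSums(P)
    if (any(!has_action)) P[!has_action, ] <- 0
    Tmat@x[slot_perm] <- as.vector(P)[ok]
    # propagate to the stationary distribution; initialized at the first
    # trajectory state, then warm-started across gradient iterations (the
    # stationary point does not depend on the initialization)
    if (is.null(D)) { D <- numeric(ns); D[start_idx] <- 1 }
    for (it in seq_len(500L)) {
      Dn <- as.numeric(Tmat %*% D)
      if (max(abs(Dn - D)) < 1e-4) { D <- Dn; break }
      D <- Dn
    }
    f_hat <- as.numeric(crossprod(f_states, D))
    deltaF <- f_obs - f_hat
    if (max(abs(deltaF)) < tol) { converged <- TRUE; break }
    # a constant non-zero gradient means the observed features cannot be
    # matched (e.g. a feature the static map cannot express); further
    # iterations only scale the weights along the same direction
    if (!is.null(dF_prev) && max(abs(deltaF - dF_prev)) < 1e-6) {
      plateau <- plateau + 1L
      if (plateau >= 5L) break
    } else plateau <- 0L
    dF_prev <- deltaF
    r_hat <- r_hat + alpha * k^(-lambda) * deltaF
    if (max(abs(r_hat)) > 1e3)
      stop("MaxEnt weights diverged (|r| > 1e3 at iteration ", k, ")")
  }
  irl_estimate("maxent", r_hat, flagged = !converged)
}

# --- successor representation machinery -------------------------------------

# Sparse uniform-policy state-action transition operator and partial SR rows.
# Pairs are indexed (state_index - 1) * 6 + action over valid actions only.
# Returns the SR rows M[{s,a}, ] for every valid action of `need_states`
# (cell ids), the static feature product, and per-cell "entering" sums.
sr_rows <- function(env, need_states, discount = 0.9) {
  mdp <- build_mdp(env, c(0, 0, 0), as_cell(env$graph$states[1], env$width),
                   discount)
  ns <- length(mdp$states)
  nxt <- mdp$index[mdp$next_id]
  dim(nxt) <- dim(mdp$next_id)
  valid <- !is.na(nxt)
  n_actions <- rowSums(valid)

  pair_id <- matrix(NA_integer_, ns, 6)
  pair_id[valid] <- seq_len(sum(valid))
  np <- sum(valid)
  # P_u[(s,a),(s',a')] = 1/|A(s')| for each valid a' at the entered state s'
  src_state <- row(nxt)[valid]
  dst_state <- nxt[valid]
  ii <- jj <- integer(0); xx <- numeric(0)
  for (a in 1:6) {
    has <- valid[dst_state, a]
    ii <- c(ii, pair_id[cbind(src_state, col(nxt)[valid])][has])
    jj <- c(jj, pair_id[cbind(dst_state[has], rep(a, sum(has)))])
    xx <- c(xx, 1 / n_actions[dst_state[has]])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = -discount * xx,
                            dims = c(np, np)) + Matrix::Diagonal(np)
  need_idx <- mdp$index[need_states]
  need_pairs <- as.vector(t(pair_id[need_idx, , drop = FALSE]))
  need_pairs <- need_pairs[!is.na(need_pairs)]
  E <- Matrix::sparseMatrix(i = need_pairs, j = seq_along(need_pairs),
                            x = 1, dims = c(np, length(need_pairs)))
  Mrows <- as.matrix(Matrix::t(Matrix::solve(Matrix::t(A), E)))
  rownames(Mrows) <- as.character(need_pairs)
  # entered_state holds *cell ids* (feature matrices are cell-indexed);
  # dst_state above holds compressed state indices for the transition build
  list(mdp = mdp, pair_id = pair_id, valid = valid, nxt = nxt,
       entered_state = mdp$next_id[valid],
       Mrows = Mrows, need_pairs = need_pairs)
}

#' Successor-representation Q values at a state
#'
#' Computes `Q(s, a) = M({s,a}, {*}) . R` where `M` is the discounted
#' expected state-action occupancy under a uniform policy on the objective
#' transitions, and `R` the reward vector implied by the feature weights
#' (prey at `prey_at`). This is the forward model inside [hyptest_fit()].
#'
#' @param env A `ppenv` environment.
#' @param weights Reward weights.
#' @param state Cell `c(col, row)`.
#' @param prey_at Prey cell.
#' @param discount Discount factor (default 0.9).
#' @param sr Optional precomputed [sr_rows()] context covering `state`.
#' @return Named Q vector over the available directions at `state`.
#' @export
sr_action_values <- function(env, weights, state, prey_at, discount = 0.9,
                             sr = NULL) {
  sid <- check_cell(env, state)
  if (is.null(sr)) sr <- sr_rows(env, sid, discount)
  fmat <- feature_matrix(env, check_cell(env, prey_at))
  R_vec <- as.numeric(fmat[sr$entered_state, , drop = FALSE] %*% weights)
  si <- sr$mdp$index[sid]
  pairs <- sr$pair_id[si, ]
  avail <- !is.na(pairs)
  q <- vapply(pairs[avail], function(p)
    sum(sr$Mrows[as.character(p), ] * R_vec), 0)
  stats::setNames(q, HEX_DIRECTIONS[avail])
}

#' Hypothesis-testing Bayesian IRL
#'
#' Bayesian inference over candidate reward weights: the likelihood of each
#' observed predator action is the softmax (temperature `temperature`,
#' default 0.083) of successor-representation Q values computed under the
#' candidate weights, with the reward vector rebuilt at every step so the
#' prey feature follows the prey's movements; steps enter the likelihood
#' independently. The prior is flat (generalized Beta(1,1)) on `[-1, 1]` per
#' weight; the posterior is approximated by seeded random-walk Metropolis
#' sampling. The point estimate is the posterior mean calibrated to
#' `[-4, 4]`.
#'
#' @param env A `ppenv` environment.
#' @param traj Trajectory data.frame (predator rows used).
#' @param n_samples Posterior draws kept after warm-up (default 2000).
#' @param warmup Discarded initial iterations (default 500).
#' @param temperature Softmax temperature on Q values (default 0.083).
#' @param discount SR discount (default 0.9).
#' @param proposal_sd Random-walk proposal SD per coordinate (default 0.15).
#' @param seed RNG seed.
#' @return A `ppirl` estimate with `posterior_samples` (n_samples x 3) and
#'   `accept_rate`; flagged if the acceptance rate falls outside (0.05,
#'   0.95).
#' @export
hyptest_fit <- function(env, traj, n_samples = 2000L, warmup = 500L,
                        temperature = 0.083, discount = 0.9,
                        proposal_sd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(traj) || nrow(traj[traj$actor == "predator", ]) == 0) {
    # no evidence: the posterior is the flat prior on [-1, 1]^3
    draws <- matrix(stats::runif(n_samples * 3, -1, 1), n_samples, 3,
                    dimnames = list(NULL, c("trees", "red_ground", "prey")))
    est <- irl_estimate("hyptest", colMeans(draws), samples = draws)
    est$point <- est$raw   # Monte-Carlo noise around 0 is not a preference
    est$accept_rate <- NA_real_
    return(est)
  }
  tr <- predator_steps(traj)
  Tn <- nrow(tr)
  need <- unique(cell_id(tr$col, tr$row, env$width))
  sr <- sr_rows(env, need, discount)

  # static part of Phi = M F: columns for trees and red ground
  f_static <- feature_matrix(env, 1L)[, 1:2, drop = FALSE]
  f_static_sa <- f_static[sr$entered_state, , drop = FALSE]
  B_static <- sr$Mrows %*% f_static_sa        # n_need_pairs x 2
  # prey part: for prey at cell p, Phi[, 3] = sum of M columns whose pair
  # enters p
  prey_ids <- unique(cell_id(tr$prey_col, tr$prey_row, env$width))
  prey_col_of <- vapply(prey_ids, function(p)
    rowSums(sr$Mrows[, sr$entered_state == p, drop = FALSE]),
    numeric(nrow(sr$Mrows)))
  colnames(prey_col_of) <- as.character(prey_ids)

  # stack per-step design blocks: X (sum n_avail x 3), group id, observed row
  Xs <- vector("list", Tn); grp <- vector("list", Tn); obs_row <- integer(Tn)
  off <- 0L
  for (t in seq_len(Tn)) {
    si <- sr$mdp$index[cell_id(tr$col[t], tr$row[t], env$width)]
    pairs <- sr$pair_id[si, ]
    avail <- which(!is.na(pairs))
    key <- as.character(pairs[avail])
    pid <- as.character(cell_id(tr$prey_col[t], tr$prey_row[t], env$width))
    Xs[[t]] <- cbind(B_static[key, , drop = FALSE], prey_col_of[key, pid])
    grp[[t]] <- rep(t, length(avail))
    a_obs <- match(tr$action[t], HEX_DIRECTIONS)
    obs_row[t] <- off + match(a_obs, avail)
    off <- off + length(avail)
  }
  X <- do.call(rbind, Xs) / temperature
  grp <- unlist(grp)
  # pad per-step rows into a Tn x 6 index matrix for vectorized group
  # log-sum-exp
  IDX <- matrix(NA_integer_, Tn, 6)
  for (t in seq_len(Tn)) {
    rows <- which(grp == t)
    IDX[t, seq_along(rows)] <- rows
  }
  idx_mask <- is.na(IDX)
  IDX0 <- ifelse(idx_mask, 1L, IDX)

  loglik <- function(r) {
    v <- as.numeric(X %*% r)
    Vm <- matrix(v[IDX0], Tn, 6)
    Vm[idx_mask] <- -Inf
    mx <- pmax(Vm[, 1], Vm[, 2], Vm[, 3], Vm[, 4], Vm[, 5], Vm[, 6])
    lse <- mx + log(rowSums(exp(Vm - mx)))
    sum(v[obs_row]) - sum(lse)
  }

  draws <- matrix(NA_real_, n_samples, 3,
                  dimnames = list(NULL, c("trees", "red_ground", "prey")))
  r <- c(0, 0, 0)
  ll <- loglik(r)
  acc <- 0L
  total <- warmup + n_samples
  for (i in seq_len(total)) {
    prop <- r + stats::rnorm(3, 0, proposal_sd)
    if (all(abs(prop) <= 1)) {
      llp <- loglik(prop)
      if (log(stats::runif(1)) < llp - ll) { r <- prop; ll <- llp; acc <- acc + 1L }
    }
    if (i > warmup) draws[i - warmup, ] <- r
  }
  rate <- acc / total
  est <- irl_estimate("hyptest", colMeans(draws), samples = draws,
                      flagged = rate < 0.05 || rate > 0.95)
  est$accept_rate <- rate
  est
}

#' Feature identified by a weight estimate
#'
#' The index (1 = trees, 2 = red ground, 3 = prey) of the largest estimated
#' weight, provided that weight is positive: an estimate whose top entry is
#' not positive expresses no preference for any feature and identifies
#' nothing (`NA`).
#'
#' @param est A `ppirl` estimate or a numeric weight vector.
#' @return Integer index or `NA`.
#' @export
identified_feature <- function(est) {
  p <- if (inherits(est, "ppirl")) est$point else as.numeric(est)
  i <- which.max(p)
  if (!is.finite(p[i]) || p[i] <= 0) return(NA_integer_)
  i
}

#' Score IRL model predictions against observed ratings
#'
#' Pools predictions and ratings (both on the calibrated \[-4, 4\] scale),
#' computes `R^2` as the squared Pearson correlation, the
#' adjusted `R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)`, and a Gaussian-residual
#' BIC `n log(RSS/n) + p log(n)`.
#'
#' @param predicted Numeric vector (or matrix) of model-predicted weights.
#' @param ratings Matching observed ratings.
#' @param n_params Number of free parameters `p` of the model.
#' @return List with `r2`, `adj_r2`, `bic`, `n`, and `flagged` (TRUE when
#'   predictions have zero variance, in which case `r2`/`adj_r2` are NA).
#' @export
score_irl <- function(predicted, ratings, n_params) {
  x <- as.numeric(predicted); y <- as.numeric(ratings)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n <= n_params + 1) stop("need n > n_params + 1 observations")
  rss <- sum((y - x)^2)
  bic <- n * log(rss / n) + n_params * log(n)
  if (stats::sd(x) == 0)
    return(list(r2 = NA_real_, adj_r2 = NA_real_, bic = bic, n = n,
                flagged = TRUE))
  r2 <- stats::cor(x, y)^2
  adj <- 1 - (1 - r2) * (n - 1) / (n - n_params - 1)
  list(r2 = r2, adj_r2 = adj, bic = bic, n = n, flagged = FALSE)
}
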
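#' Model and parameter recovery studies
#'
#' Simulate datasets from each model of a family, refit every candidate
#' model, and tabulate how often each generating model is best fit by itself
#' (confusion matrix) together with generating-vs-recovered parameter
#' correlations. Mirrors the package's three model families: action
#' prediction (7 models, best by BIC), reward-weight IRL (5 models, best by
#' Gaussian-residual BIC against simulated ratings), and interactive
#' planning (3 MCTS variants, best by IBS log likelihood, run at a reduced
#' MCTS budget).
#'
#' @param family `"prediction"`, `"irl"`, or `"planning"`.
#' @param n_per_model Simulated datasets per generating model (0 gives an
#'   empty report).
#' @param seed Integer seed.
#' @param trials_per_dataset Prediction family: observation trials per
#'   dataset (default 100, i.e. 5 games).
#' @param n_games IRL/planning families: games per dataset (defaults 3 / 2).
#' @param rating_noise IRL family: SD of the rating noise around the
#'   generating model's calibrated estimate (default 1).
#' @param n_simulations Planning family: MCTS budget inside simulated and
#'   fitted planners (default 200, reduced for tractability).
#' @param theta_grid Planning family: candidate threat sensitivities scanned
#'   when fitting (default `c(0.25, 1, 1.75)`).
#' @param n_subsets,subset_size IRL family: random-subset stability check
#'   (defaults 20 subsets of 50).
#' @return A `pprecovery` list: `confusion` (generating x best-fitting
#'   counts), `parameter_correlations`, `n_per_model`, `failures`, `seed`,
#'   plus family-specific detail.
#' @export
recover_models <- function(family = c("prediction", "irl", "planning"),
                           n_per_model = 10L, seed = 1L,
                           trials_per_dataset = 100L, n_games = NULL,
                           rating_noise = 1, n_simulations = 200L,
                           theta_grid = c(0.25, 1, 1.75),
                           n_subsets = 20L, subset_size = 50L) {
  family <- match.arg(family)
  if (n_per_model == 0)
    return(structure(list(family = family, confusion = NULL,
                          parameter_correlations = NULL, n_per_model = 0L,
                          failures = 0L, seed = seed),
                     class = "pprecovery"))
  set.seed(seed)
  switch(family,
         prediction = recover_prediction(n_per_model, seed,
                                         trials_per_dataset),
         irl = recover_irl(n_per_model, seed, n_games %||% 3L, rating_noise,
                           n_subsets, subset_size),
         planning = recover_planning(n_per_model, seed, n_games %||% 2L,
                                     n_simulations, theta_grid))
}

#' @param x A `pprecovery` report.
#' @param ... Unused.
#' @method print pprecovery
#' @export
print.pprecovery <- function(x, ...) {
  cat("Recovery report (", x$family, "), ", x$n_per_model,
      " datasets per model\n", sep = "")
  if (!is.null(x$confusion)) {
    cat("confusion (rows = generating, cols = best-fitting):\n")
    print(x$confusion)
  }
  if (!is.null(x$parameter_correlations)) {
    cat("parameter correlations:\n")
    print(round(x$parameter_correlations, 3))
  }
  invisible(x)
}

# one observation context: predator trajectories over fresh random
# environments, as consumed by prediction_context()
make_prediction_context <- function(weights, n_trials, seed) {
  set.seed(seed)
  n_games <- ceiling(n_trials / 20)
  envs <- list(); rows <- list()
  for (g in seq_len(n_games)) {
    env <- generate_environment("random", seed = sample.int(1e6, 1),
                                moves_per_turn = list(prey = 1L,
                                                      predator = 2L),
                                n_turns = 10L)
    envs[[g]] <- env
    traj <- simulate_chase(env, weights, seed = sample.int(1e6, 1))
    rows[[g]] <- data.frame(game = g, col = traj$col, row = traj$row,
                            prey_col = traj$prey_col,
                            prey_row = traj$prey_row,
                            obs_action = traj$action,
                            stringsAsFactors = FALSE)
  }
  dat <- do.call(rbind, rows)[seq_len(n_trials), ]
  dat$pred_action <- dat$obs_action   # placeholder; replaced per dataset
  prediction_context(dat, envs, weights)
}

draw_prediction_params <- function() {
  list(alpha = stats::runif(1, PREDICTION_BOUNDS$alpha[1], 1),
       lambda = stats::runif(1, 0, PREDICTION_BOUNDS$lambda[2]),
       W = stats::runif(1))
}

recover_prediction <- function(n_per_model, seed, n_trials,
                               gen_lscale = 0.15) {
  # The generalizing learners are evaluated at a kernel length scale where
  # generalization is visible (adjacent actions receive substantial mass);
  # at the fitting default of 0.02 the kernel is numerically a delta and
  # the *_gen models coincide exactly with their parents, making their
  # recovery ill-posed.
  models <- PREDICTION_MODELS
  n_ctx <- min(8L, n_per_model)
  ctxs <- lapply(seq_len(n_ctx), function(i)
    make_prediction_context(c(1, 0, 0), n_trials, seed + i))
  confusion <- matrix(0L, length(models), length(models),
                      dimnames = list(models, models))
  gen_par <- list(); rec_par <- list()
  failures <- 0L
  for (m in models) {
    for (d in seq_len(n_per_model)) {
      ctx <- ctxs[[(d - 1L) %% n_ctx + 1L]]
      par <- draw_prediction_params()
      par$lscale <- gen_lscale
      ctx$pred <- simulate_predictions(ctx, m, par,
                                       seed = seed + 131L * d)
      fits <- lapply(models, function(cand)
        tryCatch(fit_prediction_model(model = cand, context = ctx,
                                      seed = seed + d, n_gen = 40L,
                                      lscale = gen_lscale),
                 error = function(e) NULL))
      ok <- !vapply(fits, is.null, TRUE)
      if (!any(ok)) { failures <- failures + 1L; next }
      fits <- do.call(rbind, fits[ok])
      best <- fits$model[which.min(fits$bic)]
      confusion[m, best] <- confusion[m, best] + 1L
      self <- fits[fits$model == m, ]
      if (nrow(self) == 1) {
        gen_par[[length(gen_par) + 1]] <- c(model = m, unlist(par))
        rec_par[[length(rec_par) + 1]] <- c(alpha = self$alpha,
                                            lambda = self$lam, W = self$W)
      }
    }
  }
  gp <- do.call(rbind, gen_par); rp <- do.call(rbind, rec_par)
  cors <- c()
  for (p in c("alpha", "lambda", "W")) {
    gv <- as.numeric(gp[, p]); rv <- as.numeric(rp[, p])
    use <- !is.na(rv)
    # only models that actually estimate the parameter inform the correlation
    has <- vapply(gp[, "model"], function(m)
      p %in% prediction_model_spec(m)$free ||
        (p == "W" && grepl("combined", m)), TRUE)
    use <- use & has
    cors[p] <- if (sum(use) > 2) stats::cor(gv[use], rv[use]) else NA_real_
  }
  structure(list(family = "prediction", confusion = confusion,
                 parameter_correlations = cors, n_per_model = n_per_model,
                 failures = failures, seed = seed),
            class = "pprecovery")
}

IRL_MODELS <- c("occupancy", "direction", "relative", "maxent", "hyptest")
IRL_N_PARAMS <- c(occupancy = 0, direction = 0, relative = 0, maxent = 2,
                  hyptest = 1)

# cached IRL estimates for every (environment, condition) pair in the pool
irl_estimate_pool <- function(n_env, seed) {
  pool <- list()
  for (e in seq_len(n_env)) {
    env <- generate_environment("random", seed = seed + 17L * e,
                                moves_per_turn = list(prey = 1L,
                                                      predator = 2L),
                                n_turns = 10L)
    for (cond in names(EXP1_WEIGHTS)) {
      w <- EXP1_WEIGHTS[[cond]]
      traj <- simulate_chase(env, w,
                             seed = seed + 1000L * e +
                               match(cond, names(EXP1_WEIGHTS)))
      est <- list(
        occupancy = mf_occupancy(env, traj)$point,
        direction = mf_direction(env, traj)$point,
        relative = mf_direction(env, traj, relative = TRUE)$point,
        maxent = tryCatch(maxent_fit(env, traj)$point,
                          error = function(e) rep(NA_real_, 3)),
        hyptest = hyptest_fit(env, traj, n_samples = 1000L, warmup = 300L,
                              seed = seed + 29L * e)$point)
      pool[[paste0(e, "_", cond)]] <- list(env_id = e, condition = cond,
                                           estimates = est)
    }
  }
  pool
}

recover_irl <- function(n_per_model, seed, n_games, rating_noise,
                        n_subsets, subset_size) {
  n_env <- 4L
  pool <- irl_estimate_pool(n_env, seed)
  confusion <- matrix(0L, length(IRL_MODELS), length(IRL_MODELS),
                      dimnames = list(IRL_MODELS, IRL_MODELS))
  best_by <- list(); failures <- 0L
  set.seed(seed + 999L)
  for (m in IRL_MODELS) {
    for (d in seq_len(n_per_model)) {
      cond <- names(EXP1_WEIGHTS)[(d - 1L) %% 3L + 1L]
      keys <- paste0(sample.int(n_env, n_games, replace = n_games > n_env),
                     "_", cond)
      gen_pred <- unlist(lapply(keys, function(k) pool[[k]]$estimates[[m]]))
      if (anyNA(gen_pred)) { failures <- failures + 1L; next }
      ratings <- pmin(pmax(round(gen_pred +
                                   stats::rnorm(length(gen_pred), 0,
                                                rating_noise)), -4), 4)
      bics <- vapply(IRL_MODELS, function(cand) {
        pr <- unlist(lapply(keys, function(k) pool[[k]]$estimates[[cand]]))
        if (anyNA(pr)) return(Inf)
        score_irl(pr, ratings, IRL_N_PARAMS[cand])$bic
      }, 0)
      best <- IRL_MODELS[which.min(bics)]
      confusion[m, best] <- confusion[m, best] + 1L
      best_by[[length(best_by) + 1]] <- data.frame(gen = m, best = best,
                                                   stringsAsFactors = FALSE)
    }
  }
  # stability of the winning model over random subsets of datasets
  tab <- do.call(rbind, best_by)
  stability <- NULL
  if (!is.null(tab) && nrow(tab) >= subset_size) {
    wins <- replicate(n_subsets, {
      sub <- tab[sample.int(nrow(tab), subset_size), ]
      names(which.max(table(factor(sub$best, levels = IRL_MODELS))))
    })
    stability <- table(factor(wins, levels = IRL_MODELS)) / n_subsets
  }
  structure(list(family = "irl", confusion = confusion,
                 parameter_correlations = NULL, n_per_model = n_per_model,
                 failures = failures, seed = seed, stability = stability),
            class = "pprecovery")
}

recover_planning <- function(n_per_model, seed, n_games, n_simulations,
                             theta_grid) {
  # shared environment pool: alternating avoid/approach layouts
  pool_envs <- lapply(seq_len(max(2L, n_games)), function(g)
    generate_environment(if (g %% 2 == 1) "avoid" else "approach",
                         seed = seed + 3L * g))
  confusion <- matrix(0L, 3, 3,
                      dimnames = list(PLANNER_VARIANTS, PLANNER_VARIANTS))
  gen_theta <- c(); rec_theta <- c(); failures <- 0L
  for (v in PLANNER_VARIANTS) {
    for (d in seq_len(n_per_model)) {
      # draws span the fitted grid's range; near theta = 0 the opponent
      # models coincide and recovery would be ill-posed
      theta <- stats::runif(1, min(theta_grid), max(theta_grid))
      params <- planner_params(v, theta = theta,
                               n_simulations = n_simulations)
      games <- lapply(seq_len(n_games), function(g)
        simulate_planner_game(pool_envs[[g]], params, c(1, 0, 0),
                              seed = seed + 71L * d + g)$trajectory)
      ll <- matrix(NA_real_, 3, length(theta_grid),
                   dimnames = list(PLANNER_VARIANTS, NULL))
      for (cand in PLANNER_VARIANTS) {
        for (ti in seq_along(theta_grid)) {
          cp <- planner_params(cand, theta = theta_grid[ti],
                               n_simulations = n_simulations)
          tot <- 0
          for (g in seq_len(n_games))
            tot <- tot + planner_ibs(pool_envs[[g]], games[[g]], cp,
                                     c(1, 0, 0), K_max = 50L, repeats = 2L,
                                     seed = seed + 37L * d + 11L * ti +
                                       g)$loglik
          ll[cand, ti] <- tot
        }
      }
      best <- PLANNER_VARIANTS[which.max(apply(ll, 1, max))]
      confusion[v, best] <- confusion[v, best] + 1L
      if (v == "mcts_rw") {
        gen_theta <- c(gen_theta, theta)
        rec_theta <- c(rec_theta, theta_grid[which.max(ll[v, ])])
      }
    }
  }
  cors <- if (length(gen_theta) > 2)
    c(theta = stats::cor(gen_theta, rec_theta)) else NULL
  structure(list(family = "planning", confusion = confusion,
                 parameter_correlations = cors, n_per_model = n_per_model,
                 failures = failures, seed = seed,
                 note = paste("fitted planners used n_simulations =",
                              n_simulations)),
            class = "pprecovery")
}
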
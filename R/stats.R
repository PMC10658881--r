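#' Hierarchical Bayesian regression of trial-level behavior
#'
#' Regresses prediction accuracy (Bernoulli likelihood, logit link) or
#' confidence (Beta likelihood, logit-mean/concentration parameterization)
#' on an intercept, trial number and game number (z-scored within dataset),
#' with per-subject coefficients in a non-centered hierarchy:
#' `beta_subject(k) = mu_group(k) + sigma_group(k) * eps_subject(k)`,
#' `eps ~ Normal(0, 1)`. Priors: Normal(0, 1) on group means, HalfNormal(1)
#' on group SDs, Gamma(2, 0.1) on the Beta concentration. Confidence values
#' are squeezed from `[0, 1]` to the open interval by
#' `y (n - 1)/n + 1/(2n)`. Sampling is via JAGS.
#'
#' @param data data.frame with columns `subject_id`, `trial`, `game` and the
#'   outcome (`correct` in 0/1 for accuracy, `confidence` in \[0, 1\]).
#' @param outcome `"accuracy"` or `"confidence"`.
#' @param draws Posterior draws kept (default 2000).
#' @param warmup Adaptation + burn-in iterations (default 1000).
#' @param chains MCMC chains (default 2).
#' @param seed Integer seed.
#' @param centered Use the centered parameterization
#'   (`beta_s ~ Normal(mu, sigma)`) instead of the non-centered default;
#'   both target the same posterior and are provided for cross-checking.
#' @return A `pphier` list: `summary` (data.frame with posterior mean, SD,
#'   95% HPDI bounds, effective size and Rhat per group-level parameter),
#'   `samples` (coda mcmc.list), `flagged` (TRUE if any group-level Rhat
#'   exceeds 1.05).
#' @export
fit_hierarchical <- function(data, outcome = c("accuracy", "confidence"),
                             draws = 2000L, warmup = 1000L, chains = 2L,
                             seed = 1L, centered = FALSE) {
  outcome <- match.arg(outcome)
  stopifnot(length(unique(data$subject_id)) >= 2)
  subj <- as.integer(factor(data$subject_id))
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  X <- cbind(intercept = 1, trial = z(data$trial), game = z(data$game))
  K <- ncol(X)
  model_common <- if (centered) "
    for (k in 1:K) {
      mu[k] ~ dnorm(0, 1)
      sigma[k] ~ dnorm(0, 1) T(0,)
      for (s in 1:S) {
        beta[s, k] ~ dnorm(mu[k], 1 / (sigma[k]^2 + 1e-9))
      }
    }
  " else "
    for (k in 1:K) {
      mu[k] ~ dnorm(0, 1)
      sigma[k] ~ dnorm(0, 1) T(0,)
      for (s in 1:S) {
        eps[s, k] ~ dnorm(0, 1)
        beta[s, k] <- mu[k] + sigma[k] * eps[s, k]
      }
    }
  "
  if (outcome == "accuracy") {
    y <- as.numeric(data$correct)
    model <- paste0("model {", model_common, "
      for (i in 1:N) {
        logit(p[i]) <- inprod(beta[subj[i], ], X[i, ])
        y[i] ~ dbern(p[i])
      }
    }")
  } else {
    n <- length(data$confidence)
    y <- data$confidence * (n - 1) / n + 1 / (2 * n)
    model <- paste0("model {", model_common, "
      phi ~ dgamma(2, 0.1)
      for (i in 1:N) {
        logit(m[i]) <- inprod(beta[subj[i], ], X[i, ])
        y[i] ~ dbeta(m[i] * phi, (1 - m[i]) * phi)
      }
    }")
  }
  jdata <- list(y = y, X = X, subj = subj, N = nrow(X), K = K,
                S = max(subj))
  inits <- lapply(seq_len(chains), function(c)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = seed + c))
  jm <- rjags::jags.model(textConnection(model), data = jdata,
                          inits = inits, n.chains = chains,
                          n.adapt = warmup %/% 2, quiet = TRUE)
  stats::update(jm, warmup %/% 2, progress.bar = "none")
  vars <- c("mu", "sigma")
  samp <- rjags::coda.samples(jm, vars, n.iter = ceiling(draws / chains),
                              progress.bar = "none")
  sm <- as.matrix(samp)
  hpdi <- coda::HPDinterval(coda::as.mcmc(sm), prob = 0.95)
  ess <- coda::effectiveSize(samp)
  rhat <- tryCatch(coda::gelman.diag(samp, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1],
                   error = function(e) rep(NA_real_, ncol(sm)))
  par_names <- colnames(sm)
  labels <- sub("mu\\[([0-9]+)\\]", "mu_\\1", par_names)
  pretty <- c("mu[1]" = "mu_intercept", "mu[2]" = "mu_trial",
              "mu[3]" = "mu_game", "sigma[1]" = "sigma_intercept",
              "sigma[2]" = "sigma_trial", "sigma[3]" = "sigma_game")
  labels <- ifelse(par_names %in% names(pretty), pretty[par_names], labels)
  summary <- data.frame(parameter = labels, mean = colMeans(sm),
                        sd = apply(sm, 2, stats::sd),
                        hpdi_lower = hpdi[, 1], hpdi_upper = hpdi[, 2],
                        ess = ess[par_names], rhat = rhat[par_names],
                        row.names = NULL)
  structure(list(summary = summary, samples = samp,
                 flagged = any(summary$rhat > 1.05, na.rm = TRUE),
                 outcome = outcome),
            class = "pphier")
}

# maximum number of rich-zone visits attainable in a game, ignoring the
# predator: breadth-first distances, then greedy DP over remaining moves
max_zone_steps <- function(env, start_id, n_moves) {
  zone <- env$rich_zone
  nbr <- env_nbr(env)
  # BFS distance from start to the nearest zone cell
  dist <- rep(NA_integer_, env$width * env$height)
  dist[start_id] <- 0L
  frontier <- start_id
  while (length(frontier)) {
    nxt <- unique(as.vector(nbr[frontier, ]))
    nxt <- nxt[nxt > 0L]
    nxt <- nxt[is.na(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  d0 <- suppressWarnings(min(dist[zone], na.rm = TRUE))
  if (!is.finite(d0)) return(0L)
  # once inside, the zone can be occupied on every remaining move when it
  # contains two adjacent cells; otherwise on alternating moves
  two_adjacent <- any(apply(nbr[zone, , drop = FALSE], 1,
                            function(r) any(r %in% zone)))
  remaining <- n_moves - d0
  if (remaining < 0) return(0L)
  if (two_adjacent) remaining + 1L else (remaining %/% 2L) + 1L
}

#' Time spent in the rich reward zone, as a proportion of the maximum
#'
#' Counts the prey's steps on rich-zone cells and divides by the maximum
#' attainable count for the environment - the count achieved by heading to
#' the zone by the shortest path (ignoring the predator) and staying on zone
#' cells for every remaining move.
#'
#' @param env A `ppenv` environment with a non-empty `rich_zone`.
#' @param traj Trajectory data.frame (prey rows used), or a vector of visited
#'   cell ids.
#' @return Proportion in `[0, 1]`.
#' @export
zone_occupancy <- function(env, traj) {
  if (length(env$rich_zone) == 0) stop("environment has no rich zone")
  if (is.data.frame(traj)) {
    pr <- traj[traj$actor == "prey", , drop = FALSE]
    ids <- trajectory_positions(env, pr)[-1]   # entered cells
  } else ids <- traj
  # denominator uses the full game's move budget, so being captured early
  # costs occupancy
  mx <- max_zone_steps(env, env$prey_start,
                       env$n_turns * env$moves_per_turn$prey)
  if (mx == 0) return(0)
  min(sum(ids %in% env$rich_zone) / mx, 1)
}

#' Accuracy of reward-weight ratings
#'
#' Mean absolute error between a subject's ratings and the calibrated true
#' weights (both on the \[-4, 4\] scale), with a permutation-style null of
#' uniform-random ratings for comparison.
#'
#' @param ratings Numeric vector (length 3, or matrix with 3 columns).
#' @param true_weights True weights; calibrated to \[-4, 4\] internally.
#' @param null_draws Monte-Carlo draws for the null distribution (0 to skip).
#' @param seed Integer seed for the null simulation.
#' @return List: `mae`, `null_mean`, `null_sd`, `p_better` (fraction of null
#'   draws with larger error than observed).
#' @export
rating_error <- function(ratings, true_weights, null_draws = 10000L,
                         seed = 1L) {
  truth <- calibrate_weights(true_weights)
  r <- matrix(ratings, ncol = length(truth))
  mae <- mean(abs(sweep(r, 2, truth)))
  out <- list(mae = mae, null_mean = NA_real_, null_sd = NA_real_,
              p_better = NA_real_)
  if (null_draws > 0) {
    set.seed(seed)
    null <- replicate(null_draws,
                      mean(abs(stats::runif(length(truth), -4, 4) - truth)))
    out$null_mean <- mean(null)
    out$null_sd <- stats::sd(null)
    out$p_better <- mean(null > mae)
  }
  out
}
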
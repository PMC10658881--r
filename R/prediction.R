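#' Observer models of predator action prediction
#'
#' Experiment-1 observers predict the predator's next move. The package
#' implements three policy-learning variants (recency-weighted learning of
#' action frequencies, a kernel-generalized variant that spreads each observed
#' action to adjacent directions on the action ring, and repeat-previous),
#' a goal-inference model (value iteration under the agent's reward weights,
#' softmax with temperature 1), and weighted combinations of the two
#' strategies governed by a weight `W` (1 = pure goal inference).
#'
#' @name action_prediction
NULL

PREDICTION_MODELS <- c("repeat", "policy", "policy_gen", "goal",
                       "combined", "combined_gen", "combined_repeat")

# learner codes used by the C++ likelihood; NA params are fixed, numbers are
# the fixed value; "free" marks estimated parameters
prediction_model_spec <- function(model) {
  switch(model,
    `repeat`        = list(learner = 3L, free = character(0), W = 0),
    policy          = list(learner = 1L, free = c("alpha", "lambda"), W = 0),
    policy_gen      = list(learner = 2L, free = c("alpha", "lambda"), W = 0),
    goal            = list(learner = 0L, free = character(0), W = 1),
    combined        = list(learner = 1L, free = c("alpha", "lambda", "W")),
    combined_gen    = list(learner = 2L, free = c("alpha", "lambda", "W")),
    combined_repeat = list(learner = 3L, free = "W", W = NULL),
    stop("unknown prediction model: ", model)
  )
}

PREDICTION_BOUNDS <- list(alpha = c(1e-6, 1), lambda = c(0, 3), W = c(0, 1))

#' Create an empty policy estimate
#'
#' Action-value estimates over the 6 canonical directions, initialized at
#' zero; estimates persist across games within a subject.
#'
#' @return A `pppolicy` list with `pi_hat` (named length-6 vector) and `n`
#'   (observations seen so far).
#' @export
new_policy_estimate <- function() {
  structure(list(pi_hat = stats::setNames(numeric(6), HEX_DIRECTIONS), n = 0L),
            class = "pppolicy")
}

action_ring_kernel <- function(lscale) {
  i <- (seq_len(6) - 1) / 6
  d <- abs(outer(i, i, "-"))
  d <- pmin(d, 1 - d)
  k <- exp(-d^2 / (2 * lscale^2))
  k / rowSums(k)
}

#' Update a policy estimate from an observed action
#'
#' Delta-rule update `pi(a) <- pi(a) + alpha_t (target(a) - pi(a))` with a
#' decaying learning rate `alpha_t = alpha * n^-lambda`, where `n` counts
#' observations. The target is the one-hot observed action, or - for the
#' generalizing learner - that one-hot convolved with a squared-exponential
#' kernel over the ring of 6 directions (angles normalized to `[0, 1)`,
#' minimal circular distance) and renormalized to unit mass.
#'
#' @param est A `pppolicy` estimate.
#' @param observed Observed direction label.
#' @param params List with `alpha` (learning rate in (0, 1]), `lambda`
#'   (decay >= 0) and, when generalizing, `lscale` (length scale, default
#'   0.02, the value fixed during fitting).
#' @param generalize Smooth the update target over adjacent actions?
#' @return The updated `pppolicy`.
#' @export
update_policy <- function(est, observed, params, generalize = FALSE) {
  stopifnot(inherits(est, "pppolicy"))
  a <- match(observed, HEX_DIRECTIONS)
  if (is.na(a)) stop("unknown direction: ", observed)
  n <- est$n + 1L
  alpha_t <- params$alpha * n^(-params$lambda)
  target <- numeric(6)
  if (generalize) {
    lscale <- if (is.null(params$lscale)) 0.02 else params$lscale
    target <- action_ring_kernel(lscale)[a, ]
  } else {
    target[a] <- 1
  }
  est$pi_hat <- est$pi_hat + alpha_t * (target - est$pi_hat)
  est$n <- n
  est
}

#' Goal-inference action prediction
#'
#' Solves the agent's MDP under its (known or hypothesized) reward weights by
#' value iteration and converts the Q values at `state` into a prediction of
#' its next action with a softmax (temperature 1 by default).
#'
#' @param env A `ppenv` environment.
#' @param weights Reward weights (trees, red ground, prey).
#' @param state Predator cell `c(col, row)`.
#' @param prey_at Prey cell.
#' @param discount Discount factor (default 0.9).
#' @param temperature Softmax temperature (default 1).
#' @param values Optional precomputed `ppvalues` for this prey position.
#' @return Named probability vector over the available directions.
#' @export
predict_goal_inference <- function(env, weights, state, prey_at,
                                   discount = 0.9, temperature = 1,
                                   values = NULL) {
  if (is.null(values)) {
    mdp <- build_mdp(env, weights, prey_at, discount)
    values <- value_iteration(mdp)
  }
  action_probabilities(values, state, action_rule("softmax", temperature))
}

#' Combine goal-inference and policy-learning predictions
#'
#' Both inputs are min-max rescaled to `[0, 1]` over the available actions
#' (a constant input rescales to the zero vector), mixed as
#' `W * goal + (1 - W) * policy`, and renormalized to a categorical
#' distribution (uniform if the mixture is identically zero).
#'
#' @param goal Named probability vector over available directions.
#' @param policy A `pppolicy` estimate, or a named numeric vector of policy
#'   values.
#' @param W Weight on goal inference in `[0, 1]`.
#' @return Named probability vector over the available directions.
#' @export
combine_predictions <- function(goal, policy, W) {
  stopifnot(W >= 0, W <= 1)
  pol6 <- if (inherits(policy, "pppolicy")) policy$pi_hat else policy
  p <- pol6[names(goal)]
  rescale <- function(x) {
    rng <- range(x)
    if (diff(rng) <= 0) return(numeric(length(x)))
    (x - rng[1]) / diff(rng)
  }
  comb <- W * rescale(goal) + (1 - W) * rescale(p)
  s <- sum(comb)
  out <- if (s <= 0) rep(1 / length(comb), length(comb)) else comb / s
  stats::setNames(out, names(goal))
}

#' Precompute the trial-wise context for prediction-model fitting
#'
#' For every trial, computes the parameter-free goal-inference probabilities
#' (cached per game and prey position) and the availability mask; fitting
#' then only replays the cheap sequential learner.
#'
#' @param data Prediction data.frame for one subject, in task order, with
#'   columns `game`, `col`, `row` (predator state), `prey_col`, `prey_row`,
#'   `obs_action`, `pred_action`.
#' @param envs List of `ppenv` environments indexed by game number.
#' @param weights True reward weights used by the goal-inference component.
#' @param discount Discount factor (default 0.9).
#' @return A `ppredctx` list with matrices `goal`, `avail` (T x 6) and
#'   integer vectors `obs`, `pred`.
#' @export
prediction_context <- function(data, envs, weights, discount = 0.9) {
  T <- nrow(data)
  goal <- matrix(0, T, 6, dimnames = list(NULL, HEX_DIRECTIONS))
  avail <- matrix(0L, T, 6, dimnames = list(NULL, HEX_DIRECTIONS))
  cache <- new.env(parent = emptyenv())
  for (t in seq_len(T)) {
    g <- data$game[t]
    env <- envs[[g]]
    key <- paste(g, data$prey_col[t], data$prey_row[t])
    vt <- cache[[key]]
    if (is.null(vt)) {
      mdp <- build_mdp(env, weights, c(data$prey_col[t], data$prey_row[t]),
                       discount)
      vt <- value_iteration(mdp)
      cache[[key]] <- vt
    }
    p <- action_probabilities(vt, c(data$col[t], data$row[t]),
                              action_rule("softmax", 1))
    goal[t, names(p)] <- p
    avail[t, names(p)] <- 1L
  }
  structure(list(goal = goal, avail = avail,
                 obs = match(data$obs_action, HEX_DIRECTIONS),
                 pred = match(data$pred_action, HEX_DIRECTIONS)),
            class = "ppredctx")
}

prediction_nll <- function(ctx, learner, alpha, lambda, W, lscale = 0.02,
                           pred = NULL) {
  r <- prediction_loglik_cpp(ctx$goal, ctx$avail, ctx$obs,
                             if (is.null(pred)) ctx$pred else pred,
                             learner, alpha, lambda, W, lscale)
  r
}

#' Trial-wise choice probabilities of a prediction model
#'
#' @param ctx A `ppredctx` context.
#' @param model Model name (see [fit_prediction_model()]).
#' @param params Named list/vector with any of `alpha`, `lambda`, `W`.
#' @return T x 6 matrix of predicted-action probabilities.
#' @export
prediction_model_probs <- function(ctx, model, params = list()) {
  spec <- prediction_model_spec(model)
  W <- if (!is.null(spec$W)) spec$W else params[["W"]]
  alpha <- if (model == "repeat") 1 else params[["alpha"]]
  lambda <- if (model == "repeat") 0 else params[["lambda"]]
  lscale <- if (is.null(params[["lscale"]])) 0.02 else params[["lscale"]]
  if (is.null(alpha)) alpha <- 1
  if (is.null(lambda)) lambda <- 0
  if (is.null(W)) W <- 0.5
  r <- prediction_nll(ctx, spec$learner, alpha, lambda, W, lscale = lscale,
                      pred = ctx$obs)
  colnames(r$probs) <- HEX_DIRECTIONS
  r$probs
}

#' Fit an action-prediction model by maximum likelihood
#'
#' Minimizes the negative log likelihood of the participant's predicted
#' actions (Bernoulli of the categorical model distribution) with a seeded
#' differential-evolution optimizer over the model's free parameters
#' (`alpha` in (0, 1], `lambda` in [0, 3], `W` in [0, 1]; the kernel length
#' scale is fixed at 0.02). The policy learner updates on the agent's
#' *observed* actions; the likelihood is evaluated per single move. Reports
#' BIC `k log N + 2 (-L)` and the modal-prediction accuracy against the
#' agent's actual actions.
#'
#' @param data Prediction data.frame (see [prediction_context()]); ignored if
#'   `context` is supplied.
#' @param model One of `"repeat"`, `"policy"`, `"policy_gen"`, `"goal"`,
#'   `"combined"`, `"combined_gen"`, `"combined_repeat"`.
#' @param envs,weights,discount Passed to [prediction_context()].
#' @param context Optional precomputed `ppredctx`.
#' @param seed RNG seed for the optimizer.
#' @param n_gen Differential-evolution generations (default 60).
#' @param lscale Kernel length scale of the generalizing learners (fixed,
#'   not estimated; default 0.02).
#' @return One-row data.frame: `model`, `alpha`, `lam`, `W`, `neg_loglik`,
#'   `bic`, `accuracy`, `converged`.
#' @export
fit_prediction_model <- function(data = NULL, model, envs = NULL,
                                 weights = NULL, discount = 0.9,
                                 context = NULL, seed = 1L, n_gen = 60L,
                                 lscale = 0.02) {
  model <- match.arg(model, PREDICTION_MODELS)
  ctx <- if (is.null(context))
    prediction_context(data, envs, weights, discount) else context
  if (length(ctx$obs) < 1) stop("at least one trial is required")
  spec <- prediction_model_spec(model)
  free <- spec$free
  k <- length(free)
  N <- length(ctx$pred)
  eval_par <- function(par) {
    p <- list(alpha = 1, lambda = 0, W = if (!is.null(spec$W)) spec$W else NA)
    p[free] <- par
    prediction_nll(ctx, spec$learner, p$alpha, p$lambda, p$W,
                   lscale = lscale)$neg_loglik
  }
  pars <- c(alpha = NA_real_, lambda = NA_real_, W = NA_real_)
  converged <- TRUE
  if (k == 0) {
    p <- list(alpha = 1, lambda = 0, W = spec$W)
    res <- prediction_nll(ctx, spec$learner, p$alpha, p$lambda, p$W,
                          lscale = lscale)
    nll <- res$neg_loglik
  } else {
    lower <- vapply(free, function(f) PREDICTION_BOUNDS[[f]][1], 0)
    upper <- vapply(free, function(f) PREDICTION_BOUNDS[[f]][2], 0)
    opt <- de_optimize(eval_par, lower, upper, seed = seed, n_gen = n_gen)
    converged <- opt$converged
    p <- list(alpha = 1, lambda = 0, W = if (!is.null(spec$W)) spec$W else NA)
    p[free] <- opt$par
    pars[free] <- opt$par
    res <- prediction_nll(ctx, spec$learner, p$alpha, p$lambda, p$W,
                          lscale = lscale)
    nll <- res$neg_loglik
  }
  data.frame(model = model, alpha = pars["alpha"], lam = pars["lambda"],
             W = if (!is.null(spec$W)) spec$W else pars["W"],
             neg_loglik = nll, bic = k * log(N) + 2 * nll,
             accuracy = res$accuracy, converged = converged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate an observer's predictions from a prediction model
#'
#' Samples a predicted action on every trial from the model's trial-wise
#' choice probabilities (which depend only on the agent's observed actions
#' and the parameters, not on earlier sampled predictions).
#'
#' @param ctx A `ppredctx` context.
#' @param model Model name.
#' @param params Named parameter list.
#' @param seed RNG seed.
#' @return Integer vector of predicted actions (1..6 canonical directions).
#' @export
simulate_predictions <- function(ctx, model, params = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- prediction_model_probs(ctx, model, params)
  apply(probs, 1, function(p) sample.int(6, 1, prob = p))
}
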
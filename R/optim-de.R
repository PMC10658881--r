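# Compact seeded differential evolution (DE/rand/1/bin) for the low-dimensional
# box-bounded maximum-likelihood fits in this package. Populations are kept
# small because every objective here has <= 3 parameters.
de_optimize <- function(fn, lower, upper, n_pop = 15L, n_gen = 60L,
                        f_weight = 0.8, crossover = 0.9, seed = NULL,
                        tol = 1e-8, patience = 15L) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  pop <- matrix(stats::runif(n_pop * d, rep(lower, each = n_pop),
                             rep(upper, each = n_pop)), n_pop, d)
  val <- apply(pop, 1, fn)
  stale <- 0L
  best_prev <- min(val)
  for (g in seq_len(n_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample.int(n_pop, 3)
      trial <- pop[idx[1], ] + f_weight * (pop[idx[2], ] - pop[idx[3], ])
      keep <- stats::runif(d) < crossover
      keep[sample.int(d, 1)] <- TRUE
      trial <- ifelse(keep, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      v <- fn(trial)
      if (v <= val[i]) { pop[i, ] <- trial; val[i] <- v }
    }
    if (best_prev - min(val) < tol) stale <- stale + 1L else stale <- 0L
    best_prev <- min(val)
    if (stale >= patience) break
  }
  b <- which.min(val)
  list(par = pop[b, ], value = val[b], converged = stale >= patience)
}
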
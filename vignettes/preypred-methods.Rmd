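---
title: "Modeling predator-prey avoidance on hexagonal gridworlds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling predator-prey avoidance on hexagonal gridworlds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preypred)
```

`preypred` implements a family of computational models of how an observer can
infer a threatening agent's preferences from its movements, predict its next
actions, and plan their own movements to collect reward while avoiding
capture. The setting is a turn-based game on a hexagonal gridworld: a
predator ("the agent") and a prey (the participant's avatar) alternate
turns; the prey collects coins worth 100 points and loses 1000 points if the
two agents ever co-locate.

This vignette describes the models, the assumptions behind them, the tunable
parameters, and the numerical choices the implementation makes. Everything
quantitative stated here is computed by the package's test suite or by
`scripts/acceptance.R`; the vignette itself states no empirical results.

## The task as a feature-based MDP

The world is a `width x height` (default 21 x 10) flat-top hexagonal grid in
odd-q offset coordinates ((0,0) top-left, odd columns shifted half a cell
down; the six direction offsets are fixed constants in the code). Removed
cells act as walls. Each passable cell carries a binary feature vector
`f(s) = (trees, red ground, prey)`; the prey feature follows the prey's
current cell, so feature maps are time-varying. The predator's reward for
taking action `a` in state `s` is

`R(s, a) = f(s') . r`

where `s'` is the (deterministic) entered state and `r` a weight vector over
the three features. In the ground-truth agent `r` is an indicator of a single
preferred feature. The predator solves its MDP by value iteration

`V(s) <- max_a [ R(s, a) + g V(s') ]`

with discount `g = 0.9` and at most 500 sweeps (early exit when the maximal
value change drops below 1e-6), assuming the prey stays still; it re-solves
at the start of each of its turns with the prey at its current cell. Actions
are chosen by a max rule or, for the unpredictable agent, a softmax with
temperature 1. The max rule breaks exact Q ties uniformly at random under the
run's seed (the default, which keeps seeded runs reproducible without a
directional bias); `action_rule(tie_break = "first")` provides a fully
deterministic variant. The predator is forced to move on every step.

## Action-prediction models

Observers predicting the predator's next move are modeled as mixtures of two
strategies:

* **Policy learning** - a recency-weighted estimate of the agent's action
  frequencies over the six canonical directions, updated by a delta rule
  with learning rate `alpha * n^-lambda` (`alpha` in (0, 1], decay
  `lambda >= 0`, `n` the number of observations; estimates persist across
  games). A *generalizing* variant first convolves the one-hot observed
  action with a squared-exponential kernel over the action ring (directions
  at angles 0 deg, 60 deg, ..., normalized to [0, 1), minimal circular
  distance) and renormalizes the target to unit mass. The kernel length
  scale is fixed at 0.02 during fitting; at that value, under this metric,
  smoothing is nearly a delta - the scale is configurable because the
  metric's units are a genuine degree of freedom. A *repeat* variant pins
  `alpha = 1` with no decay.
* **Goal inference** - solve the agent's MDP under its true weights and pass
  the Q values at its current state through a softmax (temperature 1).

A combined model min-max rescales each component over the available actions
to [0, 1] (a constant component rescales to zero), mixes them with weight
`W` on goal inference, and renormalizes to a categorical distribution
(uniform when the mixture is identically zero). The pure models are
evaluated through the same pipeline with `W` fixed at 0 or 1, which makes
the combined model nest them exactly - a property the test suite checks.
Rescaling is applied per trial.

Fitting minimizes the negative log likelihood of the *participant's
predicted* actions (the learner updates on the *agent's observed* actions)
with a small seeded differential-evolution optimizer over box bounds
`alpha` in (0, 1], `lambda` in [0, 3], `W` in [0, 1]; reported accuracy is
the model's modal prediction scored against the agent's actual moves, and
BIC is `k log N + 2(-L)`.

## Inverse reinforcement learning of reward weights

Five estimators infer `r` from an observed predator trajectory; all report
weights calibrated to the rating scale [-4, 4] by dividing by the largest
absolute entry and multiplying by 4 (zero vectors pass through).

* **Occupancy** - per-feature counts of the visited states, with the feature
  map re-derived each step so the prey feature moves.
* **Direction** - feature counts along the ray obtained by repeating the
  observed action to the grid edge; rays also stop at walls, reading "end of
  the grid" as the end of the traversable line.
* **Relative direction** - the observed ray's normalized counts minus the
  normalized counts pooled over the other available directions; all-zero
  vectors normalize to zero rather than NaN.
* **MaxEnt** (infinite-horizon maximum causal entropy) - gradient-based
  feature matching: soft value iteration (log-sum-exp backup) under the
  current weight estimate, a softmax policy (temperature 1), its stationary
  state-visitation distribution, and a gradient step on the weights along
  the difference between observed and expected feature frequencies, with
  learning rate `alpha * k^-lambda` (defaults `alpha = 2`,
  `lambda = 0.1`, chosen for stable convergence on toy problems). The
  visitation update is implemented as mass-conserving power iteration to
  the stationary distribution (initialized at the trajectory's first state,
  tolerance 1e-4): a literal cumulative update cannot converge in an
  infinite-horizon MDP, and the stationary reading makes expected and
  observed feature frequencies directly comparable. The outer loop stops
  when the feature mismatch falls below 1e-3 - under a softmax policy the
  expected occupancy of an avoided feature is strictly positive, so a much
  tighter tolerance never fires - or when the gradient has been constant
  for five iterations (an unmatchable feature, e.g. the moving prey frozen
  in its static map), or after 1000 iterations. The static feature map uses
  the prey's position at the first observed step; this is exactly why the
  estimator cannot track a prey-preferring agent.
* **HypTest** (hypothesis-testing Bayesian IRL) - the likelihood of each
  observed action is a softmax (temperature 0.083) of Q values computed
  from the successor representation: `Q(s, a) = M({s,a}, .) . R`, with `M`
  the discounted expected state-action occupancy under a uniform policy on
  the objective transitions (discount 0.9, matching the forward model) and
  `R` rebuilt each step for the prey's movements; steps enter the
  likelihood independently. The prior is a flat generalized Beta on
  [-1, 1] per weight; the posterior is approximated by seeded random-walk
  Metropolis (2000 retained draws after 500 warm-up iterations, reflecting
  proposals with SD 0.15; draws outside the prior support are rejected).
  The point estimate is the calibrated posterior mean.

When estimates are scored for whether they "identify" the preferred
feature, the package requires the top calibrated weight to be *positive*:
an all-negative estimate (which MaxEnt produces on feature-free
trajectories) expresses no preference and identifies nothing.

Agreement between model predictions and observed ratings is summarized by
the squared Pearson correlation, its adjusted form
`1 - (1 - R^2)(n - 1)/(n - p - 1)`, and a Gaussian-residual BIC
`n log(RSS/n) + p log(n)` (the rating likelihood is not otherwise
specified).

## Interactive planning

The prey's own decision problem is a joint MDP over both agents' positions
(210^2 = 44,100 position states on the wall-free default grid), too large
for dynamic programming, so planners use UCT tree search. The tree covers
the prey's future moves; predator moves inside simulations are environment
stochasticity drawn from the opponent model:

* `mcts` - the predator does not exist in simulations;
* `mcts_rand` - uniform random predator moves;
* `mcts_rw` - moves from the value-iteration policy under the agent's true
  reward weights (max rule, or softmax with temperature `opp_temperature`).

Rollouts use a uniform random prey policy; simulated returns are 100 per
coin (consumed once per simulation) minus `1000 * theta` on capture, where
`theta >= 0` is the threat-sensitivity parameter; simulation depth is the
remaining moves of the game. Because UCT's exploration constant is scale
sensitive, returns are min-max normalized to [0, 1] within each tree and a
single constant `c = sqrt(2)` is used. The root action with most visits is
played. The default budget of 1000 simulations per decision was chosen so
that toy problems with enumerable optima are solved reliably at desk scale;
recovery studies reduce it to 200 to keep full-scale runs tractable and
record that in their report.

**Likelihood estimation.** Planner likelihoods have no closed form, so the
package uses inverse binomial sampling: simulate the model at a choice's
context until it reproduces the observed choice; a first match at draw K
contributes minus the (K-1)-th harmonic number, and contributions are
averaged over independent repetitions (default 16). Choices are scored per
single prey move, conditioning on the subject's actual preceding moves.
Simulation is capped at `K_max` draws (default 2500) with the contribution
floored at the corresponding harmonic sum; estimates are flagged when every
repetition hits the cap on some trial. Acceptance-scale runs use
`K_max = 50` and 4 repetitions: an off-model choice is floored either way,
so model discrimination is unaffected while runtime drops by orders of
magnitude.

**Parameter estimation.** In place of neural posterior estimation, the
package estimates `(opp_temperature, theta)` by grid search over the IBS
log likelihood or by rejection sampling: simulate parameter draws, summarize
each simulated dataset by rich-zone occupancy and capture rate, and keep the
draws whose summaries fall nearest the data's.

## Behavioral statistics

Prediction accuracy (Bernoulli, logit link) and confidence (Beta,
logit-mean/concentration link) are regressed on an intercept, trial and game
number (z-scored within dataset) with per-subject coefficients in a
non-centered hierarchy `beta_s = mu + sigma * eps_s`, `eps_s ~ N(0, 1)`;
priors are Normal(0, 1) on group means, HalfNormal(1) on group SDs and
Gamma(2, 0.1) on the Beta concentration (the original analysis reports
neither priors nor links, so group-level coefficients are treated as
recovery targets, not exact-match targets). Sampling runs in JAGS; fits are
flagged when any group-level split-chain Rhat exceeds 1.05. Confidence is
squeezed from [0, 1] to the open interval by `y(n-1)/n + 1/(2n)`.

Zone occupancy divides the prey's steps on rich-zone cells by the maximum
attainable count - reach the zone by the shortest path ignoring the
predator, then occupy zone cells every remaining move - using the full
game's move budget, so being captured early costs occupancy. Rating error
is the mean absolute difference from the calibrated true weights, with a
uniform-random-rating null simulated for comparison.

## The synthetic-data generator

No human data ships with the package; generators emulate the three
experiments' structure so every pipeline stage is testable.

**Environments.** Five archetypes are produced with seed-jittered layouts
and verified properties (bounded retries, error with diagnostics on
failure): `random` scatters walls (10% of cells), eight single-cell trees,
eight red cells and eight coins, with start cells at hex distance >= 10
from each other and the predator >= 7 from every feature - the walls match
the task's walled grids, and the separations give pursuit and approach
phases long enough to be informative about preferences; `approach` and
`avoid` share one geometry in which the rich coins fill a single-row walled
corridor with the predator at its east mouth, and differ only in tree
placement, which either pulls the predator's verified greedy route away
from the corridor (safe) or straight through it (unsafe); `decoupled`
separates the predator's preference from the features it occupies en route;
`practice` walls the two agents into disjoint regions so capture is
impossible. Approach/avoid verification simulates the tree-preferring
max-rule predator and checks whether its route intersects the zone.

**Simulated subjects.** Observation games (experiment 1 structure: prey one
move per turn, predator two, ten turns) use a pursuit simulator in which
the prey evades tangentially - it picks uniformly among moves that do not
reduce its distance to the predator - because a stationary or
randomly-drifting prey would make the prey feature effectively static and
mask the distinction between estimators that can and cannot track it.
Observers emit predictions from the combined model with per-subject
parameters drawn from population distributions (`W ~ Beta(8.7, 1.3)`,
mirroring the strong goal-inference reliance the original study reports;
`alpha ~ U(0.2, 0.9)`, `lambda ~ U(0, 1)`), report the model probability of
their prediction as confidence, and rate weights as calibrated truth plus
Gaussian noise (SD 0.5) rounded to the 9-point scale. Planner subjects
(experiment 2: 4/6 moves, 2 turns; experiment 3: 2 x 3 design crossing
short 1/2 x 12 and long 4/8 x 3 horizons with predator predictability) use
MCTS-RW with threat sensitivities drawn from the condition-specific
distributions reported for the fitted human sample (predictable:
|N(0.56, 0.49)|; unpredictable: |N(0.93, 0.58)|) and 5% uniform decision
noise. In the "reducible uncertainty" condition the simulated subjects plan
with the true weights from the outset - the generator emulates the
condition's game structure, not the inference process participants would
run there.

**What passing tests do and do not show.** The generator reproduces the
experiments' *structure* (turn schedules, schemas, archetype constraints,
condition labels) and produces behavior from the package's own models plus
noise. Tests that recover parameters or rank models on these data therefore
validate the estimation machinery - identifiability, correctness of the
likelihoods, and the direction of qualitative effects - but cannot certify
that human participants behave like the simulated subjects, nor reproduce
the original study's human-data statistics (those require the deposited
behavioral data).

## Numerical choices and problem sizes

* Value iteration and soft value iteration stop at a 1e-6 maximal value
  change or 500/300 sweeps; values warm-start across re-plans.
* The SR matrix rows are obtained by sparse LU solves of
  `(I - g P_u)^T x = e_i` for exactly the state-action pairs a fit needs.
* Degenerate inputs are defined away or flagged rather than propagated:
  states with no actions keep value zero, constant prediction components
  rescale to zero, zero-variance predictions flag the rating fit, an
  estimate with no positive weight identifies no feature, and a HypTest fit
  with no observations returns the prior.
* The recovery harness simulates and fits the kernel-generalizing
  prediction models at length scale 0.15, where generalization visibly
  spreads mass to adjacent actions: at the fitting default of 0.02 the
  kernel is numerically a delta, the generalizing models coincide exactly
  with their parents, and their recovery would be ill-posed.
* The acceptance studies run at fixed desk scales chosen as the package's
  own benchmark sizes: 20 random 5x5 worlds for the value-iteration oracle;
  50 seeded pursuit games per preference condition (20 predator moves
  each); 12 observer datasets of 500 trials for mixing-weight recovery; 20
  seeded games per archetype for entry rates and 8 per archetype for IBS
  model comparison; 50 games per threat-sensitivity level; and recovery at
  40 (prediction), 150 (IRL) and 80 (planning) datasets per generating
  model, the planning family at the reduced MCTS budget.

## Known limitations

* The hex layout (flat-top, odd-q) is one of several consistent choices; all
  models are invariant to it, but serialized coordinates are only
  meaningful under this convention.
* MaxEnt's learning-rate schedule and the action-kernel's distance units are
  under-determined by the original description; both are pinned to
  documented defaults and exposed as arguments.
* The HypTest likelihood evaluates a greedy agent through a uniform-policy
  successor representation at a sharp softmax temperature; on trajectories
  dominated by tie-broken orbiting around a reached feature, a few percent
  of fits pin a spurious weight at the prior boundary. This is a property
  of the model class, not of the sampler.
* Opponent models are first-order only: the simulated predator never models
  the prey's planning.
* The rejection-based parameter estimator uses two summary statistics;
  posterior spread from it is indicative, not calibrated.
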
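# Reward computation, sampling strategies, and bandit state.
#
# Rewards are 1 - RMSE/U with U = 100 (the items' value range), so every
# reward lies in [0, 1].  Five samplers are supported: ucb1 and thompson
# (genuine bandit strategies that see only the chosen arm's reward),
# random, and the two evaluation oracles optimal and worst, which see all
# arms' per-step rewards and bound every realizable strategy from above
# and below.

SAMPLERS <- c("ucb1", "thompson", "random", "optimal", "worst")
CONFIGURATIONS <- c("CWB", "SWB", "CEB", "SEB")

#' Root mean squared error between two value vectors
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return `sqrt(mean((actual - predicted)^2))`.
#' @export
compute_rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1) {
    stop("actual and predicted must have equal length >= 1")
  }
  sqrt(mean((actual - predicted)^2))
}

#' Prediction reward, normalized to [0, 1]
#'
#' `1 - RMSE(actual, predicted) / U`, where `U` is the upper bound of the
#' error (largest minus smallest attainable value; 100 for the 0-100 EMA
#' items).  For single-item targets the RMSE reduces to the absolute
#' error.
#'
#' @param actual,predicted Value vectors with entries in `[0, U]`.
#' @param U Error normalizer, `> 0` (default 100).
#' @return Reward in `[0, 1]`; 1 exactly when the prediction is perfect.
#' @export
compute_reward <- function(actual, predicted, U = 100) {
  if (U <= 0) stop("U must be positive")
  1 - compute_rmse(actual, predicted) / U
}

#' Create an empty per-arm bandit tally
#'
#' Holds the pull count `N_t(a)` and the reward sum (whose ratio is the
#' average reward `Q(a)`) plus the sum of squared rewards used by the
#' Thompson posterior.
#'
#' @return A list with `pulls`, `reward_sum`, `reward_sumsq`.
#' @export
new_arm_state <- function() {
  list(pulls = 0L, reward_sum = 0, reward_sumsq = 0)
}

#' UCB1 index of one arm
#'
#' `Q(a) + sqrt(2 log(t) / N_t(a))`: average reward plus an exploration
#' bonus that grows with the round counter `t` and shrinks with the arm's
#' pull count.  A never-pulled arm scores `Inf` so each arm is tried once
#' before the index takes over.
#'
#' @param state An arm tally from [new_arm_state()].
#' @param t Total rounds played in this bandit cell (`>= 1`).
#' @return The UCB1 score.
#' @export
ucb1_score <- function(state, t) {
  stopifnot(t >= 1)
  if (state$pulls == 0L) return(Inf)
  state$reward_sum / state$pulls + sqrt(2 * log(t) / state$pulls)
}

#' Thompson draw of an arm's expected reward
#'
#' The reward distribution is modelled as a normal whose mean and variance
#' blend a prior (mean 0.5, variance 1, pseudo-count 1) with the arm's
#' sample mean and sample sum of squares; the posterior-mean draw has
#' variance `var_hat / (pulls + pseudo-count)`, so it concentrates as the
#' arm accumulates pulls.  Draws are used only for ranking and are not
#' clipped.
#'
#' @param state An arm tally.
#' @param prior List with `mean`, `var`, `count` (defaults 0.5, 1, 1).
#' @return One draw from the arm's posterior over its expected reward.
#' @export
thompson_sample <- function(state, prior = list(mean = 0.5, var = 1, count = 1)) {
  n <- state$pulls
  c0 <- prior$count
  mean_hat <- (c0 * prior$mean + state$reward_sum) / (c0 + n)
  ss <- if (n > 0L) max(state$reward_sumsq - state$reward_sum^2 / n, 0) else 0
  var_hat <- (c0 * prior$var + ss) / (c0 + n)
  stats::rnorm(1, mean_hat, sqrt(var_hat / (c0 + n)))
}

#' Choose an arm among the currently available ones
#'
#' `ucb1` maximizes [ucb1_score()]; `thompson` maximizes one
#' [thompson_sample()] draw per arm; `random` picks uniformly; the oracles
#' `optimal` / `worst` pick the arm with the maximal / minimal current
#' reward.  Only the oracles may read `rewards`; the realizable samplers
#' ignore it.  Ties are broken by the fixed arm order global <
#' entity_centric < neighborhood (for `thompson`, draws are almost surely
#' distinct).
#'
#' @param sampler One of `"ucb1"`, `"thompson"`, `"random"`, `"optimal"`,
#'   `"worst"`.
#' @param states Named list of arm tallies, one per arm kind.
#' @param available Non-empty character vector of available arm kinds.
#' @param rewards Named per-arm current rewards; required for the oracles,
#'   ignored otherwise.
#' @param t Round counter for `ucb1`.
#' @param prior Thompson prior, see [thompson_sample()].
#' @return The chosen arm kind.
#' @export
select_arm <- function(sampler, states, available, rewards = NULL, t = 1,
                       prior = list(mean = 0.5, var = 1, count = 1)) {
  sampler <- match.arg(sampler, SAMPLERS)
  available <- ARM_KINDS[ARM_KINDS %in% available]  # fixed tie-break order
  if (length(available) == 0) stop("no arm available; step should be warm-up")
  if (sampler %in% c("optimal", "worst")) {
    if (is.null(rewards)) stop(sampler, " sampler requires per-arm rewards")
    r <- unlist(rewards[available])
    idx <- if (sampler == "optimal") which.max(r) else which.min(r)
    return(available[idx])
  }
  switch(sampler,
    random = available[.rand_int(length(available))],
    ucb1 = {
      s <- vapply(available, function(a) ucb1_score(states[[a]], max(t, 1)), 0)
      available[which.max(s)]
    },
    thompson = {
      s <- vapply(available, function(a) thompson_sample(states[[a]], prior), 0)
      available[which.max(s)]
    }
  )
}

.rand_int <- function(n) 1L + floor(stats::runif(1) * n) %% n

#' Record the round's outcome in the bandit tallies
#'
#' Realizable samplers (`ucb1`, `thompson`, `random`) observe only the
#' chosen arm's reward: its tally alone advances.  The oracles observe all
#' available arms' rewards and advance every available arm's tally — that
#' convention is what allows an oracle run to seed warm starts.
#'
#' @param cell A bandit cell (list with `states` and round counter `t`).
#' @param sampler Sampler label.
#' @param chosen Chosen arm kind.
#' @param rewards Named per-arm rewards for the available arms.
#' @param available Available arm kinds this round.
#' @return The updated cell.
#' @export
update_sampler_state <- function(cell, sampler, chosen, rewards, available) {
  upd <- if (sampler %in% c("optimal", "worst")) available else chosen
  for (a in upd) {
    r <- rewards[[a]]
    if (is.na(r) || r < 0 || r > 1) stop("reward out of [0,1]: ", r)
    s <- cell$states[[a]]
    s$pulls <- s$pulls + 1L
    s$reward_sum <- s$reward_sum + r
    s$reward_sumsq <- s$reward_sumsq + r^2
    cell$states[[a]] <- s
  }
  cell$t <- cell$t + 1L
  cell
}

#' Assemble a bandit run configuration
#'
#' The four configurations cross two axes: contextual (`C*`: one bandit
#' per study group, predictors scoped per group) vs simple (`S*`: one
#' population-wide bandit), and whole-vector (`*WB`: a single decision for
#' the full 6-item vector) vs ensemble (`*EB`: six per-item bandits).
#'
#' @param configuration `"CWB"`, `"SWB"`, `"CEB"`, or `"SEB"`.
#' @param sampler Sampling strategy (default `"thompson"`).
#' @param m,n,k Arm activation thresholds (defaults 30, 5, 4).
#' @param U Reward normalizer (default 100).
#' @param seed Master seed; per-cell random streams are derived from it.
#' @param warm_start_steps Number of initial scored observations driven by
#'   the optimal oracle to seed the sampler's tallies (0, 70 or 140).
#' @param learner [learner_spec()] for the arms' regressors.
#' @param thompson_prior Prior for [thompson_sample()].
#' @return A `bandit_config` list.
#' @export
bandit_config <- function(configuration = c("CEB", "CWB", "SWB", "SEB"),
                          sampler = "thompson",
                          m = 30, n = 5, k = 4, U = 100, seed = 1,
                          warm_start_steps = 0,
                          learner = learner_spec(),
                          thompson_prior = list(mean = 0.5, var = 1, count = 1)) {
  configuration <- match.arg(configuration)
  sampler <- match.arg(sampler, SAMPLERS)
  if (U <= 0) stop("U must be positive")
  if (warm_start_steps < 0) stop("warm_start_steps must be >= 0")
  structure(
    list(configuration = configuration, sampler = sampler,
         m = m, n = n, k = k, U = U, seed = as.integer(seed),
         warm_start_steps = as.integer(warm_start_steps),
         learner = learner, thompson_prior = thompson_prior,
         contextual = substr(configuration, 1, 1) == "C",
         ensemble = substr(configuration, 2, 2) == "E"),
    class = "bandit_config"
  )
}

#' Instantiate the bandit cells for a configuration
#'
#' A *cell* is one independent bandit: its own per-arm tallies, round
#' counter, and derived random stream.  Cells are keyed by
#' (context, target): contextual configurations have one context per study
#' group, simple ones a single context `"all"`; ensemble configurations
#' have one target per item, whole-vector ones the single target
#' `"whole"`.
#'
#' @param config A [bandit_config()].
#' @param groups Group labels present in the data (default `c("A", "B")`).
#' @return A named list of cells; names are `"<context>|<target>"`.
#' @export
make_bandit <- function(config, groups = c("A", "B")) {
  stopifnot(inherits(config, "bandit_config"))
  contexts <- if (config$contextual) groups else "all"
  targets <- if (config$ensemble) ema_items() else "whole"
  keys <- as.vector(outer(contexts, targets, paste, sep = "|"))
  cells <- vector("list", length(keys))
  names(cells) <- keys
  for (i in seq_along(keys)) {
    cells[[i]] <- list(
      context = sub("\\|.*", "", keys[i]),
      target = sub(".*\\|", "", keys[i]),
      states = stats::setNames(lapply(ARM_KINDS, function(a) new_arm_state()),
                               ARM_KINDS),
      t = 0L,
      rng = make_rng_stream(derive_seed(config$seed, i))
    )
  }
  cells
}

# ---- deterministic child random streams ------------------------------------

#' Derive a child seed from a master seed
#'
#' @param seed Master seed.
#' @param index Positive stream index.
#' @return A deterministic 31-bit child seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

#' Create an isolated random stream
#'
#' Wraps a saved `.Random.seed` so that independent bandit cells consume
#' independent, reproducible randomness regardless of evaluation order.
#'
#' @param seed Integer seed for the stream.
#' @return An environment holding the stream state; use [with_rng()].
#' @export
make_rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  env
}

#' Evaluate an expression under a stream's saved random state
#'
#' @param stream A stream from [make_rng_stream()].
#' @param expr Expression to evaluate.
#' @return The expression's value; the stream state is advanced, the
#'   global random state restored.
#' @export
with_rng <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}
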
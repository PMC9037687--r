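---
title: "Bandit-driven model selection for EMA streams: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bandit-driven model selection for EMA streams: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emabandit)
```

This vignette is the package's account of its science: the prediction
protocol, the bandit model, the parameters that matter, what the
synthetic cohort generator does and does not emulate, and the choices we
made where the design was genuinely open.

## The stream and its preparation

All users' EMA answer events are merged into one stream sorted by
calendar time; the sorted positions are the time steps, so there are no
missing steps by construction. Two details are underdetermined by
sorting alone and are fixed as follows:

- **Tie-break.** Equal timestamps are ordered by `(timestamp, entity_id,
  original row index)`. Real EMA timestamps have second resolution and
  ties are rare; a composite key makes every run reproducible anyway.
- **Missing answers.** A missing item value is replaced by the same
  user's previous filled value for that item (carry-forward). A missing
  value at a user's *first* observation has no predecessor; the default
  policy imputes the running mean of that item over all globally earlier
  observations, falling back to the scale midpoint 50 when the stream is
  empty. The running mean is unbiased under no information about the
  user; it is configurable (`first_value_policy`) because real EMA items
  are often zero-inflated and a practitioner may prefer a constant.

Step indices are 0-based throughout. Contextual configurations
additionally carry a group-local step index per sub-stream; simple
configurations consume the global index. The package keeps both because
a per-group bandit naturally counts its own rounds while a single bandit
counts the merged stream — the two indexations are not interchangeable
and both are exposed in the records.

## Arms, activation and the fallback

Each arm holds six per-item incremental learners per scope; a single
bandit decision applies to the whole 6-vector (whole-vector mode) or per
item (ensemble mode). We deliberately implement whole-vector prediction
as six per-item learners sharing one decision rather than demanding a
multi-target learner: it preserves the configuration semantics while
keeping the learner contract minimal (any scalar incremental regressor
conforms).

Activation is rule-based with the global arm as fallback. Its exact
counting convention matters for reproducing invocation counts, so we fix
it explicitly:

- the **global** arm is usable once its scope (the whole population, or
  one group in contextual mode) has *processed* `m = 30` observations —
  the first scored global prediction is therefore the 31st observation;
- the **entity-centric** arm activates *on the user's `n = 5`-th
  observation* (four processed plus the current arrival). `m` must
  exceed `n`, since a population model needs more data to generalize;
  `n` must stay below the shortest user history (12 in the motivating
  data, enforced by the generator);
- the **neighborhood** arm needs the entity condition plus at least
  `k = 4` other users in scope with ≥ `n` observations each (`k·n = 20`
  neighbour observations).

A step where no arm is available is *warm-up*: the observation trains
the learners but no bandit decision is recorded, and warm-up steps are
excluded from reward curves and invocation denominators (the records
keep them flagged, so either accounting can be recovered).

Neighbour similarity is not specified by the activation rules, so we
define it from stream data only: Euclidean distance between per-user
running means of the six filled items, refreshed at every observation of
the querying user, ties broken by user id. An observation trains the
neighbourhood learner of every user *currently* listing its owner as a
neighbour (as-of-now membership); neighbour-set drift never retrains
retroactively, which keeps learning strictly incremental.

## The learner

The learner contract requires (a) a defined prediction before any
training (the scale midpoint 50), and (b) O(1) cost per update. The
default spec `"adaptive_rls"` is an online ridge regression (recursive
least squares, ridge penalty 1, intercept included) over a minimal
autoregressive encoding — the user's previous filled 6-vector (scope
mean for a user without history), the user's step index, and a 0/1
group indicator in simple mode — wrapped in an adaptive-windowing drift
detector: absolute errors enter a bounded window (cap 100) and when some
head/tail split of the window has sub-means differing by more than a
Hoeffding-style cut at confidence `delta = 0.002`, the model and window
reset. The check runs every fifth update; the bounded window keeps the
cost constant either way. `"rls"` (no drift handling) and `"mean"`
(running target mean) are provided for tests and ablations; predictions
of every arm are clipped to [0, 100], which guarantees rewards in
[0, 1].

## Rewards and samplers

The reward of a prediction is `1 − RMSE/U` with `U = 100`, the items'
value range; for per-item targets RMSE reduces to absolute error. UCB1
scores available arms by `Q(a) + sqrt(2 log(t) / N_t(a))` with an
infinite sentinel for never-pulled arms (each arm is tried once), where
`t` is the cell's own round counter. Thompson sampling needs a reward
distribution; "normal" leaves the posterior unspecified, so we fix an
empirical-Bayes blend: prior mean 0.5, prior variance 1, pseudo-count 1,
posterior-mean draws with variance `var_hat / (pulls + 1)`. This gives
well-behaved cold starts (wide draws around mid-reward) and
concentration as pulls accumulate; the prior is configurable.

Two conventions follow the standard partial-information bandit contract:
`ucb1`, `thompson` and `random` observe only the chosen arm's reward and
must not read the per-step reward map, while the `optimal` and `worst`
oracles see all available arms' rewards and advance *every* available
arm's tally. The all-arms convention is what makes a warm start
well-defined: driving the first 70 (or 140) scored observations with the
optimal oracle leaves tallies for every arm, which then seed the target
sampler. Ties are broken by the fixed arm order global < entity-centric
< neighborhood everywhere.

A per-cell round counter, and one derived random stream per bandit cell
(child seeds derived deterministically from the master seed), make runs
reproducible regardless of how many cells a configuration has and of any
other use of R's global RNG.

## The evaluation protocol

Every observation is processed as: refresh neighbours → encode features
→ determine available arms → all arms predict → per-arm rewards → the
sampler chooses → tallies update → **all arms learn**. Training all
arms at every step (not only the chosen one) is required for the
evaluation outputs to be well-defined: per-arm error tables report all
three arms on the same steps, and the optimal/worst oracles need every
arm's prediction. A consequence we exploit: arm predictions do not
depend on the sampler, so `run_prequential()` factors into
`arm_reward_trace()` (the expensive predict/learn pass) and
`run_sampler()` (the cheap bandit replay), and several samplers can be
compared on an identical trace — which is also how the per-step
dominance chain (optimal ≥ any realizable sampler ≥ worst) is asserted
in the tests.

## What the synthetic generator emulates — and what it does not

The generator exists because the motivating clinical data are
request-only. It reproduces the features the method's behaviour depends
on, each with a stated default:

| parameter | default | meaning |
|---|---|---|
| group sizes | A: 11, B: 10 | a 21-user two-group cohort |
| history lengths | log-uniform on [12, 490] | heavy-tailed activity; minimum matches the shortest observed history (12) |
| `baseline_dispersion` | 60 | spread of per-user "preferred" levels around mid-scale |
| `phi` | 0.7 | AR(1) pull toward the user's baseline |
| `sigma` | 8 | innovation scale (stationary within-user sd ≈ 11) |
| innovation correlations | +0.6 (S02–S03, S06–S07), −0.4 (S04 vs S05/S06/S07) | the reported sign structure |
| `miss_rate` | 0.05 | independent per-item missingness |
| `b_shift` | 0.35 | group-B S05–S07 baselines pulled toward 0 |
| `b_activity` | 1.5 | group B answers more often |
| `interarrival_days` | 2 | exponential gaps between a user's answers |

Values are AR(1) around the user baseline with multivariate-normal
innovations (Cholesky of the target correlation matrix, repaired to the
nearest positive-definite matrix if a user-supplied target is
infeasible), started from the stationary distribution and clipped to
[0, 100]. The `baseline_dispersion` knob is the mechanism behind the
global-vs-local question: at 0 all users are exchangeable and the global
arm should dominate; at large dispersion the entity arm should win for
long-history users. The tests assert exactly this directional behaviour
rather than any real-data number.

Deliberately **not** emulated: the multimodal marginal shapes of real
items (e.g. zero-inflation, trimodal S04), calendar effects (the method
consumes only the ordered index), intervention/tip effects, and any
static-questionnaire structure (carried as opaque metadata only).
Passing tests therefore certify the mechanism — activation, rewards,
sampler behaviour, the idiosyncrasy effect — not predictive performance
on clinical data.

One measurement choice deserves a note: the correlation-sign check
centres each user at their own mean before pooling. With independent
per-user baselines the between-user variance attenuates pooled raw
correlations toward zero (by roughly the within/total variance ratio,
≈ 0.3 at the defaults), which would put genuinely realized −0.4
innovation correlations inside the ±0.1 dead zone. Centring measures
the within-user association the generator is supposed to realize;
`center_entities = FALSE` restores the raw pooled computation.

## Numerical and scale choices

- Tolerances: learner sanity demands convergence within 1 scale unit on
  a constant stream after 20 updates; arithmetic identities (RMSE, UCB1)
  are checked against brute-force oracles at 1e−12.
- Degenerate inputs: an empty group yields an empty sub-stream, not an
  error; an entity with zero scored steps is omitted from error tables
  with a message; a reward outside [0, 1] or an empty available-arm set
  at selection time is a contract violation and stops the run.
- Problem sizes in the test suite are chosen to exercise the study
  conditions at desk scale: dominance is verified on five full
  default-spec cohorts (≈ 2 500–4 000 observations each) in all four
  configurations; the idiosyncrasy experiment uses ten 10-user cohorts
  with five 150-observation and five 16-observation users so that both
  history bins are populated; best-arm identification uses 2 000-round
  stationary bandits over ten seeds.

## Known limitations

- The default learner is a drift-aware linear model, not a tree; with
  strongly non-linear user dynamics the arms would all underfit equally,
  which biases none of the comparisons but caps absolute accuracy. The
  learner spec is the intended extension point.
- Neighbour profiles are running means over a user's whole history; a
  user whose level drifts keeps their old profile's influence.
- The warm-start counter is global across contexts, matching a
  cohort-level "first 70 observations" reading; a per-group warm start
  can be emulated by running groups separately.
- `optimal`/`worst` are evaluation oracles, not achievable policies;
  their invocation tables describe per-step best/worst arms, not a
  realizable strategy's behaviour.
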
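# Shared in-code fixtures for the test suite.

# Long-format EMA data frame; `values` is a list of 6-vectors (NA allowed).
ema_df <- function(user_id, timestamp, group, values) {
  v <- do.call(rbind, values)
  colnames(v) <- ema_items()
  data.frame(user_id = user_id,
             timestamp = as.POSIXct(timestamp, tz = "UTC"),
             group = group, v, stringsAsFactors = FALSE)
}

# Hourly timestamps starting 2024-01-01 09:00 UTC.
hourly <- function(n, start = "2024-01-01 09:00:00") {
  as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1)
}

# One-entity data frame with constant (or supplied) item vectors.
const_df <- function(n, value = 50, user = "u1", group = "A") {
  ema_df(rep(user, n), hourly(n), rep(group, n),
         replicate(n, rep(value, 6), simplify = FALSE))
}

prepared <- function(df, ...) forward_fill(order_stream(as_ema_stream(df)), ...)

# Predictor state over a small registry, for direct arm-level tests.
tiny_state <- function(ids, groups, mode = "simple", m = 30, n = 5, k = 4,
                       spec = learner_spec("mean")) {
  new_predictor_state(
    data.frame(entity_id = ids, group = groups, stringsAsFactors = FALSE),
    mode = mode, m = m, n = n, k = k, spec = spec)
}

# Feed `vecs` (list of 6-vectors) as consecutive observations of entity e,
# running the same refresh/feature/learn sequence as the prequential loop.
feed <- function(st, e, vecs) {
  for (y in vecs) {
    refresh_neighbors(st, e)
    x <- feature_vector(st, e)
    arm_learn(st, e, y, x)
  }
  invisible(st)
}

# A small synthetic cohort shared by evaluation tests (cheap to trace).
small_cohort <- function(seed = 42, n_a = 3, n_b = 3, lengths = 40) {
  generate_cohort(synthetic_spec(
    n_a = n_a, n_b = n_b,
    history_lengths = list(A = lengths, B = lengths),
    seed = seed))
}
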
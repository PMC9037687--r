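# Synthetic EMA cohort generator.
#
# Emulates the statistical structure of a two-group tinnitus EMA cohort:
# every user answers six 0-100 items with their own "preferred" level per
# item (idiosyncratic baselines), values evolve as an AR(1) pulled toward
# the baseline with cross-correlated innovations (loudness and distress
# move together, stress and exhaustion move together, mood runs against
# stress/exhaustion/limitations), history lengths are heavy-tailed, group
# B is the more active group with its stress-block items shifted toward 0,
# and individual answers go missing at random.

#' Specify a synthetic EMA cohort
#'
#' @param n_a,n_b Users per study group (defaults 11 and 10, a cohort of
#'   21).
#' @param hist_range History-length range; lengths are drawn log-uniformly
#'   over it (default `c(12, 490)`), so most users have short histories
#'   and a few are very active.
#' @param history_lengths Optional list with elements `A` and/or `B` of
#'   explicit per-user lengths, overriding the draw.
#' @param baseline_dispersion Spread (units of the 0-100 scale) of the
#'   per-user baseline centres around the midpoint; 0 makes all users
#'   exchangeable (default 60).
#' @param phi AR(1) pull toward the baseline, in `[0, 1)` (default 0.7).
#' @param sigma Innovation standard deviation in scale units (default 8).
#' @param corr_targets 6x6 innovation correlation matrix (default: +0.6
#'   for S02-S03 and S06-S07, -0.4 for S04 against S05/S06/S07, 0
#'   elsewhere).
#' @param miss_rate Per-item missingness probability (default 0.05).
#' @param b_shift Multiplier applied to group-B baselines of S05-S07,
#'   shifting them toward 0 (default 0.35).
#' @param b_activity Multiplier on group-B history lengths — B is the more
#'   active group (default 1.5; lengths stay clipped to `hist_range`).
#' @param interarrival_days Mean of the exponential inter-arrival time
#'   between a user's consecutive answers, in days (default 2).
#' @param seed Generator seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_a = 11, n_b = 10,
                           hist_range = c(12, 490),
                           history_lengths = NULL,
                           baseline_dispersion = 60,
                           phi = 0.7, sigma = 8,
                           corr_targets = default_corr_targets(),
                           miss_rate = 0.05,
                           b_shift = 0.35,
                           b_activity = 1.5,
                           interarrival_days = 2,
                           seed = 1) {
  if (n_a + n_b <= 0) stop("at least one group must have users")
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate must lie in [0, 1)")
  if (hist_range[1] < 12) stop("minimum history length is 12")
  structure(
    list(n_a = n_a, n_b = n_b, hist_range = hist_range,
         history_lengths = history_lengths,
         baseline_dispersion = baseline_dispersion,
         phi = phi, sigma = sigma, corr_targets = corr_targets,
         miss_rate = miss_rate, b_shift = b_shift, b_activity = b_activity,
         interarrival_days = interarrival_days, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default innovation correlation targets
#'
#' Sign pattern: tinnitus loudness (S02) and distress (S03) positively
#' correlated (+0.6); stress (S06) and exhaustion (S07) positively
#' correlated (+0.6); mood (S04) negatively correlated with S05, S06 and
#' S07 (-0.4); all other off-diagonals 0.
#'
#' @return A 6x6 correlation matrix with item dimnames.
#' @export
default_corr_targets <- function() {
  items <- ema_items()
  R <- diag(6)
  dimnames(R) <- list(items, items)
  R["S02", "S03"] <- R["S03", "S02"] <- 0.6
  R["S06", "S07"] <- R["S07", "S06"] <- 0.6
  for (it in c("S05", "S06", "S07")) R["S04", it] <- R[it, "S04"] <- -0.4
  R
}

# Cholesky factor of the (repaired, if necessary) correlation target.
.corr_chol <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) stop("correlation targets not repairable to positive definite")
  }
  chol(R)
}

#' Generate one user's sequence of item vectors
#'
#' AR(1) around the user's baseline with multivariate-normal innovations
#' realizing the target correlation pattern:
#' `x_t = baseline + phi * (x_{t-1} - baseline) + sigma * L' z_t`,
#' started from the stationary distribution and clipped to `[0, 100]`.
#'
#' @param baseline Numeric 6-vector of the user's preferred levels.
#' @param phi AR(1) coefficient in `[0, 1)`.
#' @param sigma Innovation standard deviation.
#' @param corr_targets 6x6 innovation correlation matrix.
#' @param length Number of observations (`>= 1`).
#' @return A `length x 6` matrix with item column names.
#' @export
generate_entity_stream <- function(baseline, phi, sigma, corr_targets,
                                   length) {
  stopifnot(length >= 1, length(baseline) == 6)
  L <- .corr_chol(corr_targets)
  z <- matrix(stats::rnorm(length * 6), length, 6)
  innov <- sigma * (z %*% L)
  x <- matrix(NA_real_, length, 6, dimnames = list(NULL, ema_items()))
  x[1, ] <- baseline + innov[1, ] / sqrt(1 - phi^2)
  if (length > 1) {
    for (t in 2:length) {
      x[t, ] <- baseline + phi * (x[t - 1, ] - baseline) + innov[t, ]
    }
  }
  pmin(pmax(x, 0), 100)
}

#' Randomly blank raw item values
#'
#' Sets each raw item value to missing independently with probability
#' `rate`, except that a user's first observation always retains at least
#' one item (so the stream never starts fully unobserved for a user).
#'
#' @param stream An (unfilled) `ema_stream`.
#' @param rate Missingness probability in `[0, 1)`.
#' @return The stream with missing raw entries; any `fill_*` columns are
#'   dropped.
#' @export
inject_missingness <- function(stream, rate) {
  stopifnot(inherits(stream, "ema_stream"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  obs <- stream$obs
  items <- stream$items
  if (rate > 0 && nrow(obs) > 0) {
    v <- as.matrix(obs[, items, drop = FALSE])
    mask <- matrix(stats::runif(length(v)) < rate, nrow(v), ncol(v))
    first_rows <- vapply(split(seq_len(nrow(obs)), obs$entity_id),
                         function(ix) ix[which.min(obs$timestamp[ix])], 0L)
    for (fr in first_rows) {
      if (all(mask[fr, ])) mask[fr, sample.int(6, 1)] <- FALSE
    }
    v[mask] <- NA_real_
    obs[, items] <- v
  }
  obs <- obs[, setdiff(names(obs), paste0("fill_", items)), drop = FALSE]
  stream$obs <- obs
  stream$filled <- FALSE
  stream
}

#' Generate a full synthetic EMA cohort
#'
#' Draws per-user baselines, history lengths and arrival times per the
#' spec, simulates each user's AR(1) item sequence, interleaves the users
#' into one calendar-ordered stream, injects missingness, and returns the
#' ordered, forward-filled stream together with the generating ground
#' truth (for parameter-recovery tests).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `stream` (ordered, filled `ema_stream`) and `truth`
#'   (per-user baselines, lengths, `phi`, `sigma`, the correlation
#'   targets).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  ids <- c(if (spec$n_a > 0) sprintf("A%02d", seq_len(spec$n_a)),
           if (spec$n_b > 0) sprintf("B%02d", seq_len(spec$n_b)))
  groups <- stats::setNames(substr(ids, 1, 1), ids)

  draw_len <- function(n) {
    round(exp(stats::runif(n, log(spec$hist_range[1]),
                           log(spec$hist_range[2]))))
  }
  lengths <- stats::setNames(integer(length(ids)), ids)
  for (g in c("A", "B")) {
    gi <- ids[groups == g]
    if (length(gi) == 0) next
    len <- if (!is.null(spec$history_lengths[[g]])) {
      rep_len(spec$history_lengths[[g]], length(gi))
    } else {
      v <- draw_len(length(gi))
      if (g == "B") v <- round(v * spec$b_activity)
      v
    }
    lengths[gi] <- pmin(pmax(len, spec$hist_range[1]), spec$hist_range[2])
  }

  d <- spec$baseline_dispersion
  baselines <- matrix(stats::runif(length(ids) * 6, 50 - d / 2, 50 + d / 2),
                      length(ids), 6, dimnames = list(ids, ema_items()))
  baselines <- pmin(pmax(baselines, 0), 100)
  b_users <- ids[groups == "B"]
  baselines[b_users, c("S05", "S06", "S07")] <-
    baselines[b_users, c("S05", "S06", "S07")] * spec$b_shift

  origin <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
  rows <- list()
  for (e in ids) {
    len <- lengths[[e]]
    vals <- generate_entity_stream(baselines[e, ], spec$phi, spec$sigma,
                                   spec$corr_targets, len)
    gaps <- stats::rexp(len, rate = 1 / spec$interarrival_days)
    ts <- origin + round(86400 * (stats::runif(1, 0, 14) + cumsum(gaps)))
    rows[[e]] <- data.frame(user_id = e, timestamp = ts,
                            group = unname(groups[[e]]),
                            vals, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  stream <- as_ema_stream(df)
  stream <- inject_missingness(stream, spec$miss_rate)
  stream <- forward_fill(order_stream(stream))
  list(stream = stream,
       truth = list(baselines = baselines, lengths = lengths,
                    phi = spec$phi, sigma = spec$sigma,
                    corr_targets = spec$corr_targets, groups = groups))
}

#' Check a stream's inter-item correlation signs
#'
#' Computes the pooled Pearson correlation matrix of the filled item
#' values — by default after centring each user at their own mean, so the
#' within-user association is measured rather than between-user baseline
#' spread — and compares its signs against a target pattern.  Entries with
#' `|r|` below the dead zone count as zero.  The check passes when every
#' non-zero target cell has the matching sign outside the dead zone.
#'
#' @param stream An ordered, filled `ema_stream` with at least 30
#'   observations.
#' @param targets Target correlation (or sign) matrix; only its signs are
#'   used (default [default_corr_targets()]).
#' @param dead_zone Magnitude below which a correlation counts as zero
#'   (default 0.1).
#' @param center_entities Centre each user's values at their own mean
#'   before pooling (default `TRUE`).
#' @return List with `corr` (the pooled matrix), `signs` (dead-zoned sign
#'   matrix), `target_signs`, and `pass`.
#' @export
validate_correlation_signs <- function(stream,
                                       targets = default_corr_targets(),
                                       dead_zone = 0.1,
                                       center_entities = TRUE) {
  stopifnot(inherits(stream, "ema_stream"), isTRUE(stream$filled))
  v <- as.matrix(stream$obs[, paste0("fill_", stream$items), drop = FALSE])
  colnames(v) <- stream$items
  if (nrow(v) < 30) stop("need at least 30 filled observations")
  if (center_entities) {
    for (e in unique(stream$obs$entity_id)) {
      ix <- stream$obs$entity_id == e
      v[ix, ] <- sweep(v[ix, , drop = FALSE], 2,
                       colMeans(v[ix, , drop = FALSE]))
    }
  }
  corr <- suppressWarnings(stats::cor(v))
  corr[is.na(corr)] <- 0          # zero-variance column => no association
  signs <- sign(corr) * (abs(corr) >= dead_zone)
  diag(signs) <- 1
  target_signs <- sign(targets)
  off <- upper.tri(corr)
  pass <- all(signs[off][target_signs[off] != 0] ==
              target_signs[off][target_signs[off] != 0])
  list(corr = corr, signs = signs, target_signs = target_signs, pass = pass)
}
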
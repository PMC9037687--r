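# Prequential (predict-then-learn) evaluation of a configured bandit.
#
# Protocol per observation, in time-step order: (1) refresh the owner's
# neighbour set and determine the available arms; (2) every arm predicts;
# (3) per-arm rewards are computed against the revealed truth; (4) the
# sampler chooses an arm under its information contract; (5) the chosen
# (or, for oracles, every available) arm's tally advances; (6) ALL arms
# learn from the truth regardless of the choice; (7) a record is appended.
# Steps where no arm is available yet are warm-up: train-only, unscored.
#
# Because step (6) is choice-independent, the arms' predictions do not
# depend on the sampler.  The loop is therefore factored into
# arm_reward_trace() (the expensive predict/learn pass, run once) and
# run_sampler() (the cheap bandit simulation over the trace), which lets
# several samplers be compared on identical footing.

#' Run the predict-then-learn pass over a stream
#'
#' Produces, for every observation, each arm's clipped 6-item prediction
#' and the arm-availability flags.  All three arms predict at every step
#' (unscored predictions are kept for the per-arm error tables); all three
#' learn from every observation.
#'
#' @param stream An ordered, filled [as_ema_stream()] object.
#' @param config A [bandit_config()]; its `contextual` flag sets the
#'   predictor scoping, `m`/`n`/`k` the activation thresholds, and
#'   `learner` the regressor spec.
#' @return A `reward_trace` list: observation metadata, per-arm prediction
#'   matrices (`n x 6` each), the actual value matrix, the availability
#'   matrix, and the `scored` flag vector.
#' @export
arm_reward_trace <- function(stream, config) {
  stopifnot(inherits(stream, "ema_stream"), isTRUE(stream$filled))
  obs <- stream$obs
  items <- stream$items
  n <- nrow(obs)
  actual <- as.matrix(obs[, paste0("fill_", items), drop = FALSE])
  colnames(actual) <- items
  st <- new_predictor_state(
    stream$entities,
    mode = if (config$contextual) "contextual" else "simple",
    m = config$m, n = config$n, k = config$k, spec = config$learner
  )
  preds <- stats::setNames(
    lapply(ARM_KINDS, function(a) matrix(NA_real_, n, 6,
                                         dimnames = list(NULL, items))),
    ARM_KINDS)
  avail <- matrix(FALSE, n, 3, dimnames = list(NULL, ARM_KINDS))
  ids <- obs$entity_id
  for (i in seq_len(n)) {
    e <- ids[i]
    refresh_neighbors(st, e)
    x <- feature_vector(st, e)
    av <- arm_availability(st, e)
    avail[i, av] <- TRUE
    for (a in ARM_KINDS) preds[[a]][i, ] <- arm_predict(st, a, e, x)
    arm_learn(st, e, actual[i, ], x)
  }
  structure(
    list(entity_id = ids,
         group = obs$group,
         global_step = obs$global_step,
         entity_step = obs$entity_step,
         context = if (config$contextual) obs$group else rep("all", n),
         actual = actual,
         preds = preds,
         avail = avail,
         scored = rowSums(avail) > 0,
         predictor_state = st,
         contextual = config$contextual,
         m = config$m, n = config$n, k = config$k,
         learner = config$learner),
    class = "reward_trace"
  )
}

# per-arm rewards for every observation: a list of n x n_targets matrices
.trace_rewards <- function(trace, config) {
  lapply(trace$preds, function(p) {
    err <- p - trace$actual
    if (config$ensemble) {
      1 - abs(err) / config$U
    } else {
      matrix(1 - sqrt(rowMeans(err^2)) / config$U, ncol = 1,
             dimnames = list(NULL, "whole"))
    }
  })
}

#' Simulate a sampling strategy over a reward trace
#'
#' Replays the bandit decisions of `config$sampler` on the per-arm rewards
#' of a trace.  If `config$warm_start_steps > 0`, the first that many
#' scored observations are driven by the optimal oracle (which advances
#' every available arm's tally); the resulting tallies then seed the
#' target sampler, which continues under its own information contract.
#'
#' @param trace A [arm_reward_trace()] result.
#' @param config A [bandit_config()] whose `configuration` must agree with
#'   the trace's contextual flag.
#' @return A `run_report` list: `records` (one row per scored-or-warm-up
#'   observation and target), `cells` (final bandit tallies),
#'   `warm_start_state` (tallies at the oracle/sampler hand-over, `NULL`
#'   for a cold run), the `trace`, and the `config`.
#' @export
run_sampler <- function(trace, config) {
  stopifnot(inherits(trace, "reward_trace"), inherits(config, "bandit_config"))
  if (!identical(trace$contextual, config$contextual)) {
    stop("trace was built for a ", if (trace$contextual) "contextual"
         else "simple", " configuration")
  }
  rewards <- .trace_rewards(trace, config)
  targets <- colnames(rewards[[1]])
  n <- length(trace$entity_id)
  n_scored <- sum(trace$scored)
  if (config$warm_start_steps >= n_scored && config$warm_start_steps > 0) {
    stop("warm_start_steps (", config$warm_start_steps,
         ") must be smaller than the number of scored observations (",
         n_scored, ")")
  }
  groups <- sort(unique(trace$group))
  cells <- make_bandit(config, groups = groups)
  n_t <- length(targets)
  total_rows <- n * n_t
  rec <- list(
    obs_index = integer(total_rows), global_step = integer(total_rows),
    entity_id = character(total_rows), context = character(total_rows),
    target = character(total_rows),
    avail_global = logical(total_rows), avail_entity = logical(total_rows),
    avail_nbr = logical(total_rows),
    reward_global = numeric(total_rows), reward_entity = numeric(total_rows),
    reward_nbr = numeric(total_rows),
    chosen = character(total_rows), chosen_reward = numeric(total_rows),
    warm_up = logical(total_rows), phase = character(total_rows)
  )
  warm_state <- NULL
  scored_seen <- 0L
  row <- 0L
  for (i in seq_len(n)) {
    ctx <- trace$context[i]
    av_flags <- trace$avail[i, ]
    av <- ARM_KINDS[av_flags]
    is_warmup <- length(av) == 0L
    in_warm_start <- !is_warmup && scored_seen < config$warm_start_steps
    sampler_eff <- if (in_warm_start) "optimal" else config$sampler
    for (j in seq_len(n_t)) {
      tg <- targets[j]
      r <- stats::setNames(
        vapply(ARM_KINDS, function(a) rewards[[a]][i, j], 0), ARM_KINDS)
      chosen <- NA_character_
      chosen_reward <- NA_real_
      if (!is_warmup) {
        key <- paste0(ctx, "|", tg)
        cell <- cells[[key]]
        chosen <- if (sampler_eff %in% c("optimal", "worst")) {
          select_arm(sampler_eff, cell$states, av, rewards = r, t = cell$t)
        } else {
          with_rng(cell$rng,
                   select_arm(sampler_eff, cell$states, av, t = cell$t,
                              prior = config$thompson_prior))
        }
        chosen_reward <- r[[chosen]]
        cells[[key]] <- update_sampler_state(cell, sampler_eff, chosen, r, av)
      }
      row <- row + 1L
      rec$obs_index[row] <- i
      rec$global_step[row] <- trace$global_step[i]
      rec$entity_id[row] <- trace$entity_id[i]
      rec$context[row] <- ctx
      rec$target[row] <- tg
      rec$avail_global[row] <- av_flags[[1]]
      rec$avail_entity[row] <- av_flags[[2]]
      rec$avail_nbr[row] <- av_flags[[3]]
      rec$reward_global[row] <- r[["global"]]
      rec$reward_entity[row] <- r[["entity_centric"]]
      rec$reward_nbr[row] <- r[["neighborhood"]]
      rec$chosen[row] <- chosen
      rec$chosen_reward[row] <- chosen_reward
      rec$warm_up[row] <- is_warmup
      rec$phase[row] <- if (is_warmup) "warm_up"
                        else if (in_warm_start) "warm_start" else "main"
    }
    if (!is_warmup) {
      scored_seen <- scored_seen + 1L
      if (config$warm_start_steps > 0L &&
          scored_seen == config$warm_start_steps) {
        warm_state <- lapply(cells, function(c) c[c("context", "target",
                                                    "states", "t")])
      }
    }
  }
  structure(
    list(records = as.data.frame(rec, stringsAsFactors = FALSE),
         cells = cells,
         warm_start_state = warm_state,
         trace = trace,
         config = config),
    class = "run_report"
  )
}

#' Run a full prequential bandit evaluation
#'
#' Convenience wrapper: [arm_reward_trace()] followed by [run_sampler()].
#'
#' @param stream An ordered, filled `ema_stream`.
#' @param config A [bandit_config()].
#' @return A `run_report`; see [run_sampler()].
#' @export
run_prequential <- function(stream, config) {
  run_sampler(arm_reward_trace(stream, config), config)
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$records
  scored <- r[!r$warm_up, ]
  cat(sprintf("<run_report> %s / %s, %d scored decision(s), %d warm-up row(s)\n",
              x$config$configuration, x$config$sampler,
              nrow(scored), sum(r$warm_up)))
  if (nrow(scored) > 0) {
    cat("  mean chosen reward:", round(mean(scored$chosen_reward), 4), "\n")
    tab <- table(scored$chosen)
    cat("  invocations:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = " "), "\n")
  }
  invisible(x)
}

#' Arm invocation counts per context and target
#'
#' Counts how often each arm was chosen, per bandit cell, with relative
#' shares (percent of the cell's scored decisions).  For ensemble runs an
#' extra `"(item average)"` row per context gives each arm's invocation
#' count summed over the six items and divided by 6, the per-arm average
#' used to compare ensemble against whole-vector runs.
#'
#' @param report A `run_report`.
#' @return Data frame with columns `context`, `target`, `arm`, `absolute`,
#'   `relative` (percent).
#' @export
invocation_table <- function(report) {
  r <- report$records
  r <- r[!r$warm_up, , drop = FALSE]
  if (nrow(r) == 0) stop("report has no scored decisions")
  out <- list()
  for (ctx in sort(unique(r$context))) {
    for (tg in unique(r$target)) {
      sub <- r[r$context == ctx & r$target == tg, , drop = FALSE]
      if (nrow(sub) == 0) next
      abs_cnt <- vapply(ARM_KINDS, function(a) sum(sub$chosen == a), 0L)
      out[[length(out) + 1L]] <- data.frame(
        context = ctx, target = tg, arm = ARM_KINDS,
        absolute = as.integer(abs_cnt),
        relative = 100 * abs_cnt / nrow(sub),
        stringsAsFactors = FALSE)
    }
    if (report$config$ensemble) {
      sub <- r[r$context == ctx, , drop = FALSE]
      abs_cnt <- vapply(ARM_KINDS, function(a) sum(sub$chosen == a), 0L)
      out[[length(out) + 1L]] <- data.frame(
        context = ctx, target = "(item average)", arm = ARM_KINDS,
        absolute = abs_cnt / 6,
        relative = 100 * abs_cnt / nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average cumulative reward per context
#'
#' The running mean of the chosen rewards over scored observations (the
#' per-observation reward of an ensemble run is the mean of its six
#' per-item chosen rewards); warm-up observations are excluded from the
#' index.
#'
#' @param report A `run_report`.
#' @return Data frame with columns `context`, `scored_step` (0-based),
#'   `reward` (that observation's chosen reward) and `avg_cum_reward`.
#' @export
avg_cumulative_reward <- function(report) {
  r <- report$records
  r <- r[!r$warm_up, , drop = FALSE]
  if (nrow(r) == 0) stop("report has no scored decisions")
  per_obs <- stats::aggregate(chosen_reward ~ context + obs_index, data = r,
                              FUN = mean)
  per_obs <- per_obs[order(per_obs$context, per_obs$obs_index), ]
  out <- lapply(split(per_obs, per_obs$context), function(d) {
    data.frame(context = d$context,
               scored_step = seq_len(nrow(d)) - 1L,
               reward = d$chosen_reward,
               avg_cum_reward = cumsum(d$chosen_reward) / seq_len(nrow(d)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-entity, per-item average absolute prediction error
#'
#' For every entity with at least one scored observation: the mean
#' absolute error of each arm's prediction per item (every arm predicts at
#' every step, so all three columns cover the same steps), a
#' `"combined"` row averaging over the six items, and the error of the
#' sampler's chosen predictions (`chosen` column; for whole-vector runs
#' the chosen arm applies to every item).
#'
#' @param report A `run_report`.
#' @return Data frame with columns `entity_id`, `n_obs` (history length),
#'   `n_scored`, `item` (an item name or `"combined"`), `global`,
#'   `entity_centric`, `neighborhood`, `chosen`.
#' @export
per_entity_error_table <- function(report) {
  trace <- report$trace
  items <- colnames(trace$actual)
  rec <- report$records
  rec <- rec[!rec$warm_up, , drop = FALSE]
  # chosen prediction per (obs, item)
  n <- nrow(trace$actual)
  chosen_pred <- matrix(NA_real_, n, 6, dimnames = list(NULL, items))
  for (i in seq_len(nrow(rec))) {
    oi <- rec$obs_index[i]
    cols <- if (rec$target[i] == "whole") items else rec$target[i]
    chosen_pred[oi, cols] <- trace$preds[[rec$chosen[i]]][oi, cols]
  }
  out <- list()
  skipped <- character(0)
  for (e in unique(trace$entity_id)) {
    rows <- which(trace$entity_id == e & trace$scored)
    n_obs <- sum(trace$entity_id == e)
    if (length(rows) == 0) { skipped <- c(skipped, e); next }
    err <- function(p) colMeans(abs(p[rows, , drop = FALSE] -
                                    trace$actual[rows, , drop = FALSE]))
    tab <- data.frame(
      entity_id = e, n_obs = n_obs, n_scored = length(rows),
      item = c(items, "combined"),
      stringsAsFactors = FALSE)
    for (a in ARM_KINDS) {
      v <- err(trace$preds[[a]])
      tab[[a]] <- c(v, mean(v))
    }
    v <- err(chosen_pred)
    tab$chosen <- c(v, mean(v))
    out[[length(out) + 1L]] <- tab
  }
  if (length(skipped) > 0) {
    message("omitting entity(ies) with zero scored steps: ",
            paste(skipped, collapse = ", "))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a run report's artifacts to CSV
#'
#' Writes `records.csv` (one row per observation and target),
#' `invocations.csv`, `reward_curve.csv` and `entity_errors.csv` into
#' `outdir`.  Output is deterministic for a fixed (stream, config, seed).
#'
#' @param report A `run_report`.
#' @param outdir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(records = file.path(outdir, "records.csv"),
             invocations = file.path(outdir, "invocations.csv"),
             reward_curve = file.path(outdir, "reward_curve.csv"),
             entity_errors = file.path(outdir, "entity_errors.csv"))
  fmt <- function(d) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(x) round(x, 10))
    d
  }
  utils::write.csv(fmt(report$records), files[["records"]], row.names = FALSE)
  utils::write.csv(fmt(invocation_table(report)), files[["invocations"]],
                   row.names = FALSE)
  utils::write.csv(fmt(avg_cumulative_reward(report)), files[["reward_curve"]],
                   row.names = FALSE)
  utils::write.csv(fmt(per_entity_error_table(report)),
                   files[["entity_errors"]], row.names = FALSE)
  invisible(files)
}

#' Plot the average cumulative reward curves
#'
#' One line per context, base graphics.
#'
#' @param report A `run_report`.
#' @param ... Passed to [graphics::plot()].
#' @return The curve data, invisibly.
#' @export
plot_reward_curve <- function(report, ...) {
  cur <- avg_cumulative_reward(report)
  ctxs <- unique(cur$context)
  graphics::plot(NULL, xlim = range(cur$scored_step),
                 ylim = range(cur$avg_cum_reward),
                 xlab = "scored time step", ylab = "average cumulative reward",
                 main = sprintf("%s / %s", report$config$configuration,
                                report$config$sampler), ...)
  for (i in seq_along(ctxs)) {
    d <- cur[cur$context == ctxs[i], ]
    graphics::lines(d$scored_step, d$avg_cum_reward, col = i, lwd = 2)
  }
  graphics::legend("bottomright", legend = ctxs, col = seq_along(ctxs),
                   lwd = 2, bty = "n")
  invisible(cur)
}
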
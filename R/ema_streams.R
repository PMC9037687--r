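# Stream container and stream-preparation operations for multivariate EMA data.
#
# An EMA stream is the chronologically ordered sequence of all users'
# answer events.  Six numeric items (S02..S07, each on a 0-100 scale) are
# carried per event; missing answers are forward-filled per user so that
# downstream incremental learners always see complete vectors.

#' Item names carried by every EMA stream
#'
#' The six numeric EMA items used for prediction, in fixed order.
#' Categorical items (S01, S08) are outside the prediction task and are
#' ignored on ingestion.
#'
#' @return Character vector of length 6.
#' @export
ema_items <- function() c("S02", "S03", "S04", "S05", "S06", "S07")

#' Construct an EMA stream from a data frame
#'
#' Validates and wraps a long-format table of EMA answer events.  Rows whose
#' group label is not `A` or `B` are dropped (ungrouped users and the
#' unused third study group are excluded from the prediction task).
#'
#' @param df Data frame with columns `user_id`, `timestamp` (POSIXct or
#'   ISO-8601 string), `group`, and the six items of [ema_items()].
#'   Missing item values are `NA`.
#' @return An object of class `ema_stream`: a list with elements `obs`
#'   (the observation table), `entities` (per-user registry), `items`,
#'   `n_dropped` (rows removed by the group filter), and the flags
#'   `ordered` and `filled`.
#' @export
as_ema_stream <- function(df) {
  need <- c("user_id", "timestamp", "group", ema_items())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!inherits(df$timestamp, "POSIXct")) {
    raw <- as.character(df$timestamp)
    ts <- as.POSIXct(rep(NA_real_, length(raw)), origin = "1970-01-01",
                     tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
      still <- is.na(ts)
      if (!any(still)) break
      ts[still] <- as.POSIXct(raw[still], tz = "UTC", format = fmt)
    }
    bad <- which(is.na(ts) & !is.na(raw))
    if (length(bad) > 0) {
      stop("unparseable timestamp in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    df$timestamp <- ts
  }
  if (anyNA(df$timestamp)) {
    stop("missing timestamp in row(s): ",
         paste(utils::head(which(is.na(df$timestamp)), 5), collapse = ", "))
  }
  for (it in ema_items()) {
    v <- df[[it]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      df[[it]] <- v
    }
    out_of_range <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(out_of_range) > 0) {
      stop(sprintf("item %s outside [0,100] in row(s): %s", it,
                   paste(utils::head(out_of_range, 5), collapse = ", ")))
    }
  }
  keep <- !is.na(df$group) & df$group %in% c("A", "B")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropped %d observation(s) with group outside {A, B}",
                    n_dropped))
  }
  obs <- df[keep, need, drop = FALSE]
  names(obs)[names(obs) == "user_id"] <- "entity_id"
  obs$entity_id <- as.character(obs$entity_id)
  obs$.row <- seq_len(nrow(df))[keep]
  rownames(obs) <- NULL
  structure(
    list(obs = obs,
         entities = NULL,
         items = ema_items(),
         n_dropped = n_dropped,
         ordered = FALSE,
         filled = FALSE),
    class = "ema_stream"
  )
}

#' Read an EMA stream from CSV
#'
#' @param path Path to a UTF-8 CSV with header columns `user_id`,
#'   `timestamp` (ISO-8601), `group`, `S02`..`S07`; missing cells empty or
#'   `NA`.  Extra columns (e.g. categorical items) are ignored.
#' @param column_map Optional named character vector mapping the required
#'   names to the file's column names, e.g. `c(user_id = "uid")`.
#' @return An unordered, unfilled [as_ema_stream()] object.
#' @export
read_ema_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "NaN"))
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df)) stop("column_map names absent column: ", src)
      names(df)[names(df) == src] <- std
    }
  }
  as_ema_stream(df)
}

#' Sort a stream chronologically and assign step indices
#'
#' Observations are sorted ascending by timestamp; equal timestamps are
#' broken by entity id and then by original row index so that runs are
#' reproducible.  The sorted positions become the global time steps
#' `0..N-1` (no gaps); each user additionally receives their own 0-based
#' `entity_step`, and the per-user registry records each entity's group and
#' arrival step.
#'
#' @param stream An `ema_stream`.
#' @return The stream with `global_step`, `entity_step` and an `entities`
#'   registry; `ordered` set to `TRUE`.
#' @export
order_stream <- function(stream) {
  stopifnot(inherits(stream, "ema_stream"))
  obs <- stream$obs
  if (anyDuplicated(obs[, c("entity_id", "timestamp")]) > 0) {
    warning("duplicate (entity_id, timestamp) pairs; deterministic tie-break applied")
  }
  ord <- order(obs$timestamp, obs$entity_id, obs$.row)
  obs <- obs[ord, , drop = FALSE]
  n <- nrow(obs)
  obs$global_step <- if (n > 0) 0:(n - 1) else integer(0)
  obs$entity_step <- stats::ave(rep(1L, n), obs$entity_id,
                                FUN = function(x) seq_along(x) - 1L)
  rownames(obs) <- NULL
  first <- !duplicated(obs$entity_id)
  entities <- data.frame(
    entity_id = obs$entity_id[first],
    group = obs$group[first],
    arrival_step = obs$global_step[first],
    n_obs = as.integer(table(obs$entity_id)[obs$entity_id[first]]),
    stringsAsFactors = FALSE
  )
  rownames(entities) <- NULL
  stream$obs <- obs
  stream$entities <- entities
  stream$ordered <- TRUE
  stream
}

#' Forward-fill missing item values
#'
#' A missing value is replaced by the same user's most recent filled value
#' for that item.  A missing value at a user's first observation has no
#' predecessor; it is imputed by `first_value_policy`:
#' \describe{
#'   \item{`"running_mean"`}{(default) the running mean of that item's
#'     filled values over all globally earlier observations, or 50 (the
#'     scale midpoint) if nothing has been seen yet.}
#'   \item{`"midpoint"`}{always 50.}
#'   \item{a number}{that constant.}
#' }
#' Filled values are stored in `fill_S02`..`fill_S07`; raw values are left
#' untouched.
#'
#' @param stream An ordered `ema_stream`.
#' @param first_value_policy `"running_mean"`, `"midpoint"`, or a numeric
#'   constant in `[0, 100]`.
#' @return The stream with complete `fill_*` columns; `filled = TRUE`.
#' @export
forward_fill <- function(stream, first_value_policy = "running_mean") {
  stopifnot(inherits(stream, "ema_stream"), isTRUE(stream$ordered))
  obs <- stream$obs
  items <- stream$items
  n <- nrow(obs)
  raw <- as.matrix(obs[, items, drop = FALSE])
  filled <- raw
  last_seen <- list()                        # entity -> last filled 6-vector
  run_sum <- numeric(length(items))          # running sums of filled values
  run_n <- 0L
  const_policy <- if (is.numeric(first_value_policy)) {
    stopifnot(first_value_policy >= 0, first_value_policy <= 100)
    first_value_policy
  } else NA_real_
  for (i in seq_len(n)) {
    e <- obs$entity_id[i]
    v <- raw[i, ]
    miss <- is.na(v)
    if (any(miss)) {
      prev <- last_seen[[e]]
      if (!is.null(prev)) {
        v[miss] <- prev[miss]
      } else if (!is.na(const_policy)) {
        v[miss] <- const_policy
      } else if (identical(first_value_policy, "midpoint") || run_n == 0L) {
        v[miss] <- 50
      } else {
        v[miss] <- (run_sum / run_n)[miss]
      }
    }
    filled[i, ] <- v
    last_seen[[e]] <- v
    run_sum <- run_sum + v
    run_n <- run_n + 1L
  }
  colnames(filled) <- paste0("fill_", items)
  obs <- obs[, setdiff(names(obs), paste0("fill_", items)), drop = FALSE]
  stream$obs <- cbind(obs, as.data.frame(filled))
  stream$filled <- TRUE
  stream
}

#' Partition a stream by study group
#'
#' Splits an ordered, filled stream into one sub-stream per group,
#' preserving relative order; each sub-stream gains a group-local step
#' index `group_step` running `0..N_g - 1`.  An absent group yields an
#' empty sub-stream.
#'
#' @param stream An ordered, filled `ema_stream`.
#' @return Named list of `ema_stream`, one per group in `c("A", "B")`.
#' @export
split_by_group <- function(stream) {
  stopifnot(inherits(stream, "ema_stream"), isTRUE(stream$ordered))
  out <- list()
  for (g in c("A", "B")) {
    sub <- stream
    sub$obs <- stream$obs[stream$obs$group == g, , drop = FALSE]
    n_g <- nrow(sub$obs)
    sub$obs$group_step <- if (n_g > 0) 0:(n_g - 1) else integer(0)
    rownames(sub$obs) <- NULL
    sub$entities <- stream$entities[stream$entities$group == g, , drop = FALSE]
    rownames(sub$entities) <- NULL
    out[[g]] <- sub
  }
  out
}

#' Write an ordered, filled stream back to CSV for audit
#'
#' @param stream An ordered, filled `ema_stream`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ema_csv <- function(stream, path) {
  stopifnot(inherits(stream, "ema_stream"))
  obs <- stream$obs
  obs$timestamp <- format(obs$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  obs$.row <- NULL
  names(obs)[names(obs) == "entity_id"] <- "user_id"  # the ingest dialect
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ema_stream <- function(x, ...) {
  cat(sprintf("<ema_stream> %d observations, %d entities%s%s\n",
              nrow(x$obs),
              if (is.null(x$entities)) length(unique(x$obs$entity_id))
              else nrow(x$entities),
              if (isTRUE(x$ordered)) ", ordered" else "",
              if (isTRUE(x$filled)) ", filled" else ""))
  if (!is.null(x$entities)) {
    tab <- table(x$entities$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}
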
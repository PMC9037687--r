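# The three prediction arms and their activation rules.
#
# Arms: a global learner over all entities in scope (one per study group in
# contextual mode), an entity-centric learner per user, and a neighbourhood
# learner per user that also trains on the user's k nearest neighbours.
# Each arm holds six per-item incremental learners; a single bandit choice
# applies to the whole vector (or, in ensemble mode, per item).
#
# Activation (rule-based, with the global arm as fallback): the global arm
# becomes usable once its scope has processed m observations; the
# entity-centric arm from the user's n-th observation onward; the
# neighbourhood arm once the entity arm is usable AND at least k other
# entities in scope each have at least n processed observations.

ARM_KINDS <- c("global", "entity_centric", "neighborhood")

#' Create the mutable predictor state for a run
#'
#' @param entities Registry data frame with columns `entity_id` and
#'   `group` (as produced by [order_stream()]).
#' @param mode `"contextual"` (arms scoped per group) or `"simple"`
#'   (one population-wide scope; the group enters the feature vector
#'   instead).
#' @param m Observations the global arm's scope needs before the arm is
#'   scored (default 30).
#' @param n Observations a user needs before the entity-centric arm is
#'   scored for them (default 5); also the per-neighbour requirement of the
#'   neighbourhood arm.
#' @param k Number of nearest neighbours (default 4).
#' @param spec [learner_spec()] used for every per-item learner.
#' @return A `predictor_state` environment.
#' @export
new_predictor_state <- function(entities, mode = c("contextual", "simple"),
                                m = 30, n = 5, k = 4,
                                spec = learner_spec()) {
  mode <- match.arg(mode)
  stopifnot(m > n)  # the global arm must generalize over more data
  st <- new.env(parent = emptyenv())
  st$mode <- mode
  st$items <- ema_items()
  st$m <- m; st$n <- n; st$k <- k
  st$spec <- spec
  st$n_features <- if (mode == "simple") 8L else 7L
  st$group_of <- stats::setNames(entities$group, entities$entity_id)
  st$entity_ids <- entities$entity_id
  st$gl <- list()                      # scope -> list of 6 learners
  st$el <- new.env(parent = emptyenv())   # entity -> 6 learners
  st$nl <- new.env(parent = emptyenv())   # entity -> 6 neighbourhood learners
  st$cnt_scope <- new.env(parent = emptyenv())
  st$cnt_entity <- new.env(parent = emptyenv())
  st$cnt_nbr <- new.env(parent = emptyenv())   # neighbourhood train counts
  st$profile <- new.env(parent = emptyenv())   # entity -> list(sum, n)
  st$scope_mean <- new.env(parent = emptyenv())  # scope -> list(sum, n)
  st$prev <- new.env(parent = emptyenv())      # entity -> last filled vector
  st$neighbors <- new.env(parent = emptyenv()) # entity -> char vector
  st$nbr_dist <- new.env(parent = emptyenv())
  st$reverse <- new.env(parent = emptyenv())   # entity -> who lists it
  class(st) <- "predictor_state"
  st
}

.scope_of <- function(st, entity_id) {
  if (st$mode == "contextual") unname(st$group_of[[entity_id]]) else "all"
}

.get_count <- function(envir, key) {
  v <- envir[[key]]
  if (is.null(v)) 0L else v
}

.get_learners <- function(st, arm, entity_id) {
  if (arm == "global") {
    sc <- .scope_of(st, entity_id)
    if (is.null(st$gl[[sc]])) {
      st$gl[[sc]] <- lapply(st$items, function(i)
        make_learner(st$spec, st$n_features))
    }
    st$gl[[sc]]
  } else {
    store <- if (arm == "entity_centric") st$el else st$nl
    ls <- store[[entity_id]]
    if (is.null(ls)) {
      ls <- lapply(st$items, function(i) make_learner(st$spec, st$n_features))
      store[[entity_id]] <- ls
    }
    ls
  }
}

#' Encode the learner input for one upcoming observation
#'
#' The encoding is the minimal autoregressive choice: the user's previous
#' filled 6-vector (or, for a user with no history yet, the running mean
#' vector of the user's scope, midpoint 50 if the scope is empty), followed
#' by the user's 0-based step index, followed — in simple mode only — by a
#' 0/1 group indicator (A = 0, B = 1).
#'
#' @param st A `predictor_state`.
#' @param entity_id User to encode for.
#' @return Numeric vector of length 7 (contextual) or 8 (simple).
#' @export
feature_vector <- function(st, entity_id) {
  prev <- st$prev[[entity_id]]
  if (is.null(prev)) {
    sc <- .scope_of(st, entity_id)
    sm <- st$scope_mean[[sc]]
    prev <- if (is.null(sm) || sm$n == 0L) rep(50, 6) else sm$sum / sm$n
  }
  x <- c(prev, .get_count(st$cnt_entity, entity_id))
  if (st$mode == "simple") {
    x <- c(x, if (identical(unname(st$group_of[[entity_id]]), "B")) 1 else 0)
  }
  unname(x)
}

# entities in scope, other than entity_id, with >= n processed observations
.eligible_neighbors <- function(st, entity_id) {
  sc <- .scope_of(st, entity_id)
  cand <- st$entity_ids[st$entity_ids != entity_id]
  if (st$mode == "contextual") {
    cand <- cand[st$group_of[cand] == sc]
  }
  cand[vapply(cand, function(e) .get_count(st$cnt_entity, e), 0L) >= st$n]
}

#' Which arms may be scored for this user right now?
#'
#' @param st A `predictor_state`.
#' @param entity_id User about to be predicted.
#' @return Character vector, a subset of
#'   `c("global", "entity_centric", "neighborhood")`; empty means the step
#'   is warm-up (train-only, no bandit decision).
#' @export
arm_availability <- function(st, entity_id) {
  sc <- .scope_of(st, entity_id)
  avail <- character(0)
  if (.get_count(st$cnt_scope, sc) >= st$m) avail <- c(avail, "global")
  # the current arrival is the user's (cnt+1)-th observation
  entity_ok <- .get_count(st$cnt_entity, entity_id) + 1L >= st$n
  if (entity_ok) {
    avail <- c(avail, "entity_centric")
    if (length(.eligible_neighbors(st, entity_id)) >= st$k) {
      avail <- c(avail, "neighborhood")
    }
  }
  avail
}

#' Recompute a user's k nearest neighbours
#'
#' Similarity is the Euclidean distance between per-user running means of
#' the six filled items; only users with at least `n` processed
#' observations are eligible, a user is never their own neighbour, and
#' distance ties are broken by entity id.  The reverse index (who lists
#' this user as a neighbour) is kept in sync.
#'
#' @param st A `predictor_state`.
#' @param entity_id User whose neighbour set to refresh.
#' @return The new neighbour ids, invisibly.
#' @export
refresh_neighbors <- function(st, entity_id) {
  cand <- .eligible_neighbors(st, entity_id)
  old <- st$neighbors[[entity_id]]
  if (length(cand) == 0) {
    new <- character(0)
  } else {
    p0 <- st$profile[[entity_id]]
    q <- if (is.null(p0)) rep(50, 6) else p0$sum / p0$n
    d <- vapply(cand, function(e) {
      p <- st$profile[[e]]
      sqrt(sum((q - p$sum / p$n)^2))
    }, 0)
    ord <- order(d, cand)
    new <- cand[ord][seq_len(min(st$k, length(cand)))]
    st$nbr_dist[[entity_id]] <- d[ord][seq_len(min(st$k, length(cand)))]
  }
  for (e in setdiff(old, new)) {
    st$reverse[[e]] <- setdiff(st$reverse[[e]], entity_id)
  }
  for (e in setdiff(new, old)) {
    st$reverse[[e]] <- c(st$reverse[[e]], entity_id)
  }
  st$neighbors[[entity_id]] <- new
  invisible(new)
}

#' Query one arm for a whole-vector prediction
#'
#' @param st A `predictor_state`.
#' @param arm One of `"global"`, `"entity_centric"`, `"neighborhood"`.
#' @param entity_id User to predict for.
#' @param x Feature vector from [feature_vector()].
#' @return Named numeric 6-vector, each component clipped to `[0, 100]`.
#'   A never-trained arm returns its learners' default (midpoint 50).
#' @export
arm_predict <- function(st, arm, entity_id, x) {
  arm <- match.arg(arm, ARM_KINDS)
  ls <- .get_learners(st, arm, entity_id)
  p <- vapply(ls, predict_one, 0, x = x)
  p <- pmin(pmax(p, 0), 100)
  names(p) <- st$items
  p
}

#' Train every arm on a completed observation
#'
#' The observation updates (a) the global learner of the user's scope,
#' (b) the user's entity-centric learner, (c) the user's own neighbourhood
#' learner and the neighbourhood learner of every user currently listing
#' this user as a neighbour (as-of-now membership; neighbour-set changes
#' never retrain retroactively).  Counters, running profiles, scope means
#' and the previous-vector cache are advanced afterwards.
#'
#' @param st A `predictor_state`.
#' @param entity_id Owner of the observation.
#' @param y Filled 6-vector (the truth revealed after prediction).
#' @param x The feature vector the observation was predicted from.
#' @return The state, invisibly.
#' @export
arm_learn <- function(st, entity_id, y, x) {
  stopifnot(length(y) == 6, !anyNA(y))
  items6 <- seq_len(6)
  gl <- .get_learners(st, "global", entity_id)
  el <- .get_learners(st, "entity_centric", entity_id)
  for (j in items6) {
    learn_one(gl[[j]], x, y[j])
    learn_one(el[[j]], x, y[j])
  }
  for (e in unique(c(entity_id, st$reverse[[entity_id]]))) {
    nlrn <- .get_learners(st, "neighborhood", e)
    for (j in items6) learn_one(nlrn[[j]], x, y[j])
    st$cnt_nbr[[e]] <- .get_count(st$cnt_nbr, e) + 1L
  }
  sc <- .scope_of(st, entity_id)
  st$cnt_scope[[sc]] <- .get_count(st$cnt_scope, sc) + 1L
  st$cnt_entity[[entity_id]] <- .get_count(st$cnt_entity, entity_id) + 1L
  p <- st$profile[[entity_id]]
  st$profile[[entity_id]] <-
    if (is.null(p)) list(sum = y, n = 1L) else list(sum = p$sum + y, n = p$n + 1L)
  sm <- st$scope_mean[[sc]]
  st$scope_mean[[sc]] <-
    if (is.null(sm)) list(sum = y, n = 1L) else list(sum = sm$sum + y, n = sm$n + 1L)
  st$prev[[entity_id]] <- y
  invisible(st)
}
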
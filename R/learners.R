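# Incremental (stream) regressors behind the three prediction arms.
#
# Contract: a learner predicts before it has seen any example (it returns a
# defined default, the scale midpoint 50), and each learn step costs O(1)
# in the length of the history.  Learners are mutable environments so that
# the prequential loop updates them in place.
#
# Three specs are provided:
#   "mean"         running mean of the targets (ignores features)
#   "rls"          online ridge regression (recursive least squares)
#   "adaptive_rls" rls wrapped in an adaptive-windowing drift detector that
#                  resets the model when the recent error level shifts
#                  (the default, mirroring drift-adaptive stream learners)

#' Describe an incremental learner
#'
#' @param name One of `"mean"`, `"rls"`, `"adaptive_rls"`.
#' @param ... Spec parameters.  For `"rls"`: `lambda` (ridge penalty,
#'   default 1).  For `"adaptive_rls"` additionally `delta` (drift
#'   confidence, default 0.002) and `window` (error-window cap, default
#'   100).
#' @return A `learner_spec` list used by [make_learner()].
#' @export
learner_spec <- function(name = c("adaptive_rls", "rls", "mean"), ...) {
  name <- match.arg(name)
  params <- list(...)
  defaults <- switch(name,
    mean = list(),
    rls = list(lambda = 1),
    adaptive_rls = list(lambda = 1, delta = 0.002, window = 100L)
  )
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults), class = "learner_spec")
}

#' Create a fresh incremental learner
#'
#' @param spec A [learner_spec()].
#' @param n_features Feature-vector length the learner will be fed
#'   (ignored by `"mean"`).
#' @return A mutable learner environment; query with [predict_one()] and
#'   update with [learn_one()].
#' @export
make_learner <- function(spec = learner_spec(), n_features = 8L) {
  stopifnot(inherits(spec, "learner_spec"))
  l <- new.env(parent = emptyenv())
  l$kind <- spec$name
  l$n_features <- as.integer(n_features)
  if (spec$name == "mean") {
    l$n <- 0L
    l$s <- 0
  } else {
    d <- n_features + 1L                       # leading intercept
    l$w <- c(50, numeric(n_features))          # fresh learner predicts 50
    l$P <- diag(d) / spec$params$lambda
    if (spec$name == "adaptive_rls") {
      l$delta <- spec$params$delta
      l$win_cap <- as.integer(spec$params$window)
      l$errs <- numeric(0)
      l$lambda <- spec$params$lambda
      l$n_drift <- 0L
      l$n_seen <- 0L
    }
  }
  class(l) <- c(paste0("learner_", spec$name), "learner")
  l
}

#' Predict one target value
#'
#' @param l A learner from [make_learner()].
#' @param x Numeric feature vector of length `n_features`.
#' @return A single numeric prediction (unclipped; arm-level code clips to
#'   the item scale).
#' @export
predict_one <- function(l, x) {
  if (l$kind == "mean") {
    if (l$n == 0L) 50 else l$s / l$n
  } else {
    sum(l$w * c(1, x))
  }
}

#' Learn from one example
#'
#' Updates the learner in place; cost is independent of how many examples
#' it has already seen.
#'
#' @param l A learner from [make_learner()].
#' @param x Numeric feature vector.
#' @param y Numeric target.
#' @return The learner, invisibly.
#' @export
learn_one <- function(l, x, y) {
  if (l$kind == "mean") {
    l$n <- l$n + 1L
    l$s <- l$s + y
    return(invisible(l))
  }
  xb <- c(1, x)
  w <- l$w
  P <- l$P
  if (l$kind == "adaptive_rls") {
    err <- abs(y - sum(w * xb))
    errs <- c(l$errs, err)
    if (length(errs) > l$win_cap) errs <- errs[-1]
    l$errs <- errs
    n_seen <- l$n_seen + 1L
    l$n_seen <- n_seen
    # the window check runs every 5th update; the bounded window keeps the
    # per-call cost O(1) either way
    if (n_seen %% 5L == 0L && .adwin_drift(errs, l$delta)) {
      w <- c(50, numeric(l$n_features))
      P <- diag(l$n_features + 1L) / l$lambda
      l$errs <- numeric(0)
      l$n_drift <- l$n_drift + 1L
    }
  }
  Px <- drop(P %*% xb)
  k <- Px / (1 + sum(xb * Px))
  l$w <- w + k * (y - sum(w * xb))
  l$P <- P - tcrossprod(k, Px)
  invisible(l)
}

# Adaptive-windowing drift check over a bounded window of absolute errors:
# flag drift when some head/tail split of the window has sub-means that
# differ by more than the Hoeffding-style cut for confidence delta.
# Errors are scaled by 100 (the item range) so the [0,1]-bound behind the
# cut applies.
.adwin_drift <- function(errs, delta) {
  n <- length(errs)
  if (n < 20L) return(FALSE)
  e <- errs / 100
  cs <- cumsum(e)
  total <- cs[n]
  splits <- 10:(n - 10L)                      # require 10 points per side
  n0 <- splits
  n1 <- n - splits
  m0 <- cs[splits] / n0
  m1 <- (total - cs[splits]) / n1
  m_harm <- 1 / (1 / n0 + 1 / n1)
  cut <- sqrt(log(2 * n / delta) / (2 * m_harm))
  any(abs(m0 - m1) > cut)
}
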
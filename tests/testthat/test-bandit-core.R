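test_that("RMSE matches hand arithmetic and rejects length mismatches", {
  expect_equal(compute_rmse(c(10, 20), c(10, 20)), 0)
  expect_equal(compute_rmse(c(0, 0), c(100, 100)), 100)
  expect_equal(compute_rmse(c(10, 20), c(13, 24)), sqrt((9 + 16) / 2),
               tolerance = 1e-15)
  expect_equal(compute_rmse(c(10, 20), c(13, 24)), 3.535533905932738,
               tolerance = 1e-12)
  expect_error(compute_rmse(1:3, 1:2), "equal length")
})

test_that("reward is 1 - RMSE/U, bounded in [0,1], and 1 only for perfect predictions", {
  expect_equal(compute_reward(c(40, 40), c(40, 40)), 1)
  expect_equal(compute_reward(0, 100), 0)
  expect_equal(compute_reward(c(10, 20), c(13, 24)), 1 - sqrt(12.5) / 100,
               tolerance = 1e-15)
  expect_equal(compute_reward(c(10, 20), c(13, 24)), 0.9646446609406726,
               tolerance = 1e-12)
  expect_error(compute_reward(1, 1, U = 0), "positive")
  set.seed(1)
  for (i in 1:200) {
    a <- runif(6, 0, 100); p <- runif(6, 0, 100)
    r <- compute_reward(a, p)
    expect_true(r >= 0 && r <= 1)
    expect_identical(r == 1, all(a == p))
  }
})

test_that("UCB1 score: average plus exploration bonus, sentinel for unpulled arms", {
  s <- new_arm_state()
  expect_identical(ucb1_score(s, 5), Inf)
  s$pulls <- 2L; s$reward_sum <- 1.0
  expect_equal(ucb1_score(s, 10), 0.5 + sqrt(2 * log(10) / 2), tolerance = 1e-15)
  expect_equal(ucb1_score(s, 10), 2.0174271293851465, tolerance = 1e-12)
  s$pulls <- 1L; s$reward_sum <- 0.7
  expect_equal(ucb1_score(s, 1), 0.7)  # ln 1 = 0: pure exploitation
})

test_that("Thompson draws are seed-reproducible and concentrate with data", {
  fresh <- new_arm_state()
  d1 <- { set.seed(12); thompson_sample(fresh) }
  d2 <- { set.seed(12); thompson_sample(fresh) }
  expect_identical(d1, d2)

  loaded <- list(pulls = 10000L, reward_sum = 9000, reward_sumsq = 8100)
  set.seed(13)
  draws <- replicate(1000, thompson_sample(loaded))
  expect_lt(sd(draws), 0.02)
  expect_equal(mean(draws), 0.9, tolerance = 0.01)
})

test_that("Thompson ranking of identical arms is symmetric", {
  s <- list(pulls = 50L, reward_sum = 30, reward_sumsq = 20)
  states <- list(global = s, entity_centric = s)
  set.seed(14)
  wins <- replicate(2000, select_arm("thompson", states,
                                     c("global", "entity_centric")))
  frac <- mean(wins == "global")
  expect_gt(frac, 0.46)
  expect_lt(frac, 0.54)
})

test_that("select_arm honours each sampler's contract and the fixed tie order", {
  states <- setNames(lapply(1:3, function(i) new_arm_state()),
                     c("global", "entity_centric", "neighborhood"))
  r <- list(global = 0.8, entity_centric = 0.9, neighborhood = 0.7)
  av <- names(states)
  expect_equal(select_arm("optimal", states, av, rewards = r), "entity_centric")
  expect_equal(select_arm("worst", states, av, rewards = r), "neighborhood")
  expect_error(select_arm("optimal", states, av), "requires")
  expect_error(select_arm("ucb1", states, character(0)), "warm-up")
  # ucb1: one never-pulled arm wins on the sentinel
  states$global$pulls <- 5L; states$global$reward_sum <- 5
  states$neighborhood$pulls <- 5L; states$neighborhood$reward_sum <- 5
  expect_equal(select_arm("ucb1", states, av, t = 10), "entity_centric")
  # all-equal tallies: fixed order global < entity_centric < neighborhood
  eq <- setNames(lapply(1:3, function(i) {
    list(pulls = 4L, reward_sum = 2, reward_sumsq = 1)
  }), av)
  expect_equal(select_arm("ucb1", eq, av, t = 9), "global")
  # availability is respected
  expect_equal(select_arm("ucb1", eq, c("entity_centric", "neighborhood"),
                          t = 9), "entity_centric")
})

test_that("realizable samplers ignore oracle rewards (sampler isolation)", {
  states <- setNames(lapply(1:3, function(i) {
    list(pulls = 3L, reward_sum = runif(1), reward_sumsq = 0.2)
  }), c("global", "entity_centric", "neighborhood"))
  av <- names(states)
  r <- list(global = 0, entity_centric = 1, neighborhood = 0.5)
  for (smp in c("ucb1", "thompson", "random")) {
    set.seed(21)
    without_r <- select_arm(smp, states, av, t = 5)
    set.seed(21)
    with_r <- select_arm(smp, states, av, rewards = r, t = 5)
    expect_identical(without_r, with_r, label = smp)
  }
})

test_that("tally updates follow the chosen-only vs all-arms (oracle) convention", {
  cell <- list(states = setNames(lapply(1:3, function(i) new_arm_state()),
                                 c("global", "entity_centric", "neighborhood")),
               t = 0L)
  r <- list(global = 0.8, entity_centric = 0.6, neighborhood = 0.4)
  av <- names(r)
  c1 <- update_sampler_state(cell, "ucb1", "global", r, av)
  expect_equal(c1$states$global$pulls, 1L)
  expect_equal(c1$states$global$reward_sum, 0.8)
  expect_equal(c1$states$entity_centric$pulls, 0L)
  expect_equal(c1$t, 1L)
  c2 <- update_sampler_state(cell, "optimal", "global", r, av)
  expect_equal(sapply(c2$states, `[[`, "pulls"),
               c(global = 1L, entity_centric = 1L, neighborhood = 1L))
  expect_equal(c2$states$neighborhood$reward_sum, 0.4)
  expect_error(update_sampler_state(cell, "ucb1", "global",
                                    list(global = 1.2), "global"),
               "out of \\[0,1\\]")
})

test_that("the four configurations key their bandit cells correctly", {
  expect_length(make_bandit(bandit_config("CEB")), 12)  # 2 groups x 6 items
  expect_length(make_bandit(bandit_config("SEB")), 6)
  expect_length(make_bandit(bandit_config("CWB")), 2)
  cells <- make_bandit(bandit_config("SWB"))
  expect_length(cells, 1)
  expect_equal(cells[[1]]$context, "all")
  expect_equal(cells[[1]]$target, "whole")
  expect_error(bandit_config("XXX"))
  expect_error(bandit_config("SWB", U = -1), "positive")
})

test_that("ucb1 pulls every available arm once before exploiting", {
  cells <- make_bandit(bandit_config("SWB", sampler = "ucb1", seed = 2))
  cell <- cells[[1]]
  av <- c("global", "entity_centric", "neighborhood")
  chosen <- character(3)
  for (i in 1:3) {
    chosen[i] <- select_arm("ucb1", cell$states, av, t = cell$t)
    cell <- update_sampler_state(cell, "ucb1", chosen[i],
                                 setNames(as.list(rep(0.5, 3)), av), av)
  }
  expect_setequal(chosen, av)
})

test_that("derived random streams are independent of global RNG use", {
  s1 <- make_rng_stream(derive_seed(99, 1))
  s2 <- make_rng_stream(derive_seed(99, 1))
  a <- with_rng(s1, rnorm(3))
  runif(10)  # interleaved global RNG traffic must not matter
  b <- with_rng(s2, rnorm(3))
  expect_identical(a, b)
  expect_false(identical(with_rng(s1, rnorm(1)), a[1]))
  expect_false(derive_seed(1, 1) == derive_seed(1, 2))
  expect_false(derive_seed(1, 1) == derive_seed(2, 1))
})
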
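# A hand-built whole-vector trace with two usable arms and controlled
# rewards: global always scores 0.2, entity-centric 0.9.
constant_trace <- function(n = 10, warmup = 0) {
  actual <- matrix(100, n, 6, dimnames = list(NULL, ema_items()))
  preds <- list(
    global = matrix(20, n, 6),          # reward 1 - 80/100 = 0.2
    entity_centric = matrix(90, n, 6),  # reward 0.9
    neighborhood = matrix(0, n, 6)      # reward 0 (kept unavailable)
  )
  avail <- matrix(rep(c(TRUE, TRUE, FALSE), each = n), n, 3,
                  dimnames = list(NULL, c("global", "entity_centric",
                                          "neighborhood")))
  if (warmup > 0) avail[seq_len(warmup), ] <- FALSE
  structure(
    list(entity_id = rep("u1", n), group = rep("A", n),
         global_step = 0:(n - 1), entity_step = 0:(n - 1),
         context = rep("all", n), actual = actual, preds = preds,
         avail = avail, scored = rowSums(avail) > 0,
         contextual = FALSE, m = 30, n = 5, k = 4,
         learner = learner_spec("mean")),
    class = "reward_trace")
}

test_that("the global arm first scores at observation 31 (m = 30)", {
  # a single 40-observation user: the entity arm opens at the 5th
  # observation, the global arm at the 31st, the neighbourhood arm never
  co <- generate_cohort(synthetic_spec(n_a = 1, n_b = 0, baseline_dispersion = 0,
                                       history_lengths = list(A = 40), seed = 1))
  cfg <- bandit_config("SWB", sampler = "optimal",
                       learner = learner_spec("mean"))
  rep <- run_prequential(co$stream, cfg)
  r <- rep$records
  expect_equal(sum(r$warm_up), 4)                       # before the 5th obs
  expect_equal(min(r$obs_index[r$avail_global]), 31)    # the 31st observation
  expect_false(any(r$avail_nbr))
  expect_true(all(is.na(r$chosen[r$warm_up])))
  expect_true(all(r$chosen[!r$warm_up & r$obs_index < 31] == "entity_centric"))
})

test_that("the entity arm is first scored at each entity's 5th observation", {
  co <- small_cohort(seed = 2)
  cfg <- bandit_config("SWB", sampler = "optimal",
                       learner = learner_spec("mean"))
  tr <- arm_reward_trace(co$stream, cfg)
  first_avail <- tapply(seq_along(tr$entity_id), tr$entity_id, function(ix) {
    min(tr$entity_step[ix][tr$avail[ix, "entity_centric"]])
  })
  expect_true(all(first_avail == 4))  # 0-based step 4 = 5th observation
})

test_that("identical stream, config and seed reproduce the report exactly", {
  co <- small_cohort(seed = 3)
  cfg <- bandit_config("CEB", sampler = "thompson", seed = 17)
  r1 <- run_prequential(co$stream, cfg)
  r2 <- run_prequential(co$stream, cfg)
  expect_identical(r1$records, r2$records)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_run_report(r1, d1); write_run_report(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("oracle dominance holds at every scored step on a real cohort", {
  co <- small_cohort(seed = 4)
  cfg <- function(s) bandit_config("SWB", sampler = s, seed = 5,
                                   learner = learner_spec("mean"))
  tr <- arm_reward_trace(co$stream, cfg("optimal"))
  runs <- lapply(c("optimal", "ucb1", "thompson", "random", "worst"),
                 function(s) run_sampler(tr, cfg(s))$records)
  names(runs) <- c("optimal", "ucb1", "thompson", "random", "worst")
  sc <- !runs$optimal$warm_up
  for (s in c("ucb1", "thompson", "random")) {
    expect_true(all(runs$optimal$chosen_reward[sc] >=
                    runs[[s]]$chosen_reward[sc] - 1e-12), label = s)
    expect_true(all(runs[[s]]$chosen_reward[sc] >=
                    runs$worst$chosen_reward[sc] - 1e-12), label = s)
  }
})

test_that("invocations count every scored decision exactly once", {
  co <- small_cohort(seed = 6)
  rep <- run_prequential(co$stream, bandit_config("CEB", sampler = "random",
                                                  seed = 8))
  inv <- invocation_table(rep)
  r <- rep$records[!rep$records$warm_up, ]
  for (ctx in unique(r$context)) {
    for (tg in unique(r$target)) {
      cell <- inv[inv$context == ctx & inv$target == tg, ]
      expect_equal(sum(cell$absolute), sum(r$context == ctx & r$target == tg))
      expect_equal(sum(cell$relative), 100, tolerance = 0.5)
    }
  }
  avg <- inv[inv$target == "(item average)" & inv$context == "A", ]
  expect_equal(sum(avg$absolute) * 6, sum(r$context == "A"))
})

test_that("average cumulative reward is the running mean over scored steps", {
  fake <- structure(list(records = data.frame(
    context = "all", obs_index = 1:2, target = "whole",
    chosen_reward = c(1.0, 0.5), warm_up = FALSE)), class = "run_report")
  cur <- avg_cumulative_reward(fake)
  expect_equal(cur$avg_cum_reward, c(1.0, 0.75))
  const <- structure(list(records = data.frame(
    context = "all", obs_index = 1:5, target = "whole",
    chosen_reward = 0.6, warm_up = FALSE)), class = "run_report")
  expect_equal(avg_cumulative_reward(const)$avg_cum_reward, rep(0.6, 5))
})

test_that("per-entity errors: the optimal sampler's column is at most every arm's", {
  co <- small_cohort(seed = 7)
  rep <- run_prequential(co$stream, bandit_config("SWB", sampler = "optimal",
                                                  seed = 9))
  tab <- per_entity_error_table(rep)
  comb <- tab[tab$item == "combined", ]
  for (i in seq_len(nrow(comb))) {
    expect_lte(comb$chosen[i],
               min(comb$global[i], comb$entity_centric[i],
                   comb$neighborhood[i]) + 1e-9)
  }
  expect_true(all(tab$n_obs >= tab$n_scored))
  expect_setequal(unique(tab$item), c(ema_items(), "combined"))
})

test_that("a zero-step warm start is a no-op and a seeded one replays oracle tallies", {
  tr <- constant_trace(n = 50)
  cold <- run_sampler(tr, bandit_config("SWB", sampler = "ucb1", seed = 4,
                                        warm_start_steps = 0))
  cold2 <- run_sampler(tr, bandit_config("SWB", sampler = "ucb1", seed = 4,
                                         warm_start_steps = 0))
  expect_identical(cold$records, cold2$records)
  expect_null(cold$warm_start_state)

  warm <- run_sampler(tr, bandit_config("SWB", sampler = "ucb1", seed = 4,
                                        warm_start_steps = 10))
  ws <- warm$warm_start_state[[1]]
  # oracle convention: every available arm's tally advances each round
  expect_equal(ws$states$global$pulls, 10L)
  expect_equal(ws$states$entity_centric$pulls, 10L)
  expect_equal(ws$states$neighborhood$pulls, 0L)
  expect_equal(ws$states$global$reward_sum, 10 * 0.2)
  expect_equal(ws$states$entity_centric$reward_sum, 10 * 0.9)
  expect_equal(warm$records$phase[1:10], rep("warm_start", 10))
})

test_that("warm-started UCB exploits the seeded tallies where cold UCB explores", {
  tr <- constant_trace(n = 20)
  cold <- run_sampler(tr, bandit_config("SWB", sampler = "ucb1", seed = 4))
  # cold: both arms unpulled -> sentinel tie resolved to the global arm
  expect_equal(cold$records$chosen[1], "global")
  warm <- run_sampler(tr, bandit_config("SWB", sampler = "ucb1", seed = 4,
                                        warm_start_steps = 5))
  first_main <- which(warm$records$phase == "main")[1]
  # seeded Q: entity 0.9 vs global 0.2; bonus equal -> entity wins immediately
  expect_equal(warm$records$chosen[first_main], "entity_centric")
  expect_error(run_sampler(tr, bandit_config("SWB", sampler = "ucb1",
                                             warm_start_steps = 20)),
               "warm_start_steps")
})

test_that("whole-vector and ensemble rewards agree with their definitions", {
  tr <- constant_trace(n = 5)
  whole <- run_sampler(tr, bandit_config("SWB", sampler = "optimal"))
  expect_equal(unique(whole$records$reward_global), 0.2)
  ens <- run_sampler(tr, bandit_config("SEB", sampler = "optimal"))
  expect_equal(nrow(ens$records), 5 * 6)
  expect_equal(unique(ens$records$reward_entity), 0.9)  # |90-100|/100
  expect_true(all(ens$records$chosen[!ens$records$warm_up] == "entity_centric"))
})
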
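test_that("block schedules realise exact per-block counts", {
  cond <- task_condition("D6", 0.75, delay_set = 6, schedule_kind = "block")
  set.seed(1)
  sch <- build_schedule(cond)
  expect_equal(nrow(sch), 40)
  expect_equal(sum(sch$is_reward_trial), 30)
  expect_equal(sum(!sch$is_reward_trial), 10)
  expect_equal(sum(sch$light == "blue"), 20)
  expect_equal(sum(sch$light == "yellow"), 20)
  # every consecutive block of 8 holds 3 + 1 trials per light
  for (blk in split(seq_len(40), rep(1:5, each = 8))) {
    sub <- sch[blk, ]
    expect_equal(sum(sub$light == "blue" & sub$is_reward_trial), 3)
    expect_equal(sum(sub$light == "blue" & !sub$is_reward_trial), 1)
  }
  # variable-delay blocks use each delay once per light
  cond3 <- task_condition("D2-6-10", 0.75, delay_set = c(2, 6, 10),
                          schedule_kind = "block")
  sch3 <- build_schedule(cond3)
  expect_equal(sort(unique(sch3$scheduled_delay_s)), c(2, 6, 10))
  expect_equal(unname(table(sch3$scheduled_delay_s)), rep(10, 3),
               ignore_attr = TRUE)
  expect_error(task_condition("bad", 0.75, schedule_kind = "block", n_trials = 30),
               "divisible by 8")
  expect_error(task_condition("bad", 0.5, schedule_kind = "block"), "75%")
})

test_that("bernoulli schedules split light in half and respect the reward rate", {
  cond <- task_condition("all-reward", 1, n_trials = 40)
  set.seed(2)
  sch <- build_schedule(cond)
  expect_equal(sum(!sch$is_reward_trial), 0)
  expect_equal(sum(sch$light == "blue"), 20)
  # same seed, same schedule
  set.seed(7); a <- build_schedule(task_condition("c", 0.75))
  set.seed(7); b <- build_schedule(task_condition("c", 0.75))
  expect_identical(a, b)
  # omission fraction within binomial 99% bounds at ~10^3 trials
  set.seed(3)
  cond75 <- task_condition("c75", 0.75, n_trials = 40)
  n_om <- sum(!dplyr::bind_rows(lapply(1:25, function(i) build_schedule(cond75)))$is_reward_trial)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.25)
  expect_gte(n_om, bounds[1])
  expect_lte(n_om, bounds[2])
})

test_that("trial outcomes follow the task rules", {
  cond <- task_condition("c", 0.75)
  # an agent with prior ~1 waits out any 3 s delay: all reward trials rewarded
  patient <- agent_config(prior_source = "fixed", prior_fixed = 0.999,
                          early_withdrawal_rate = 0)
  set.seed(4)
  sch <- build_schedule(cond)
  tr <- simulate_trials(sch, patient, cond)
  rewarded <- tr[tr$is_reward_trial, ]
  expect_true(all(rewarded$outcome == "rewarded"))
  expect_equal(rewarded$waiting_time_s, rewarded$scheduled_delay_s)
  # an agent with prior 0 quits almost immediately: reward trials all error out
  hasty <- agent_config(prior_source = "fixed", prior_fixed = 0,
                        early_withdrawal_rate = 0)
  tr2 <- simulate_trials(sch, hasty, cond)
  err <- tr2[tr2$is_reward_trial, ]
  expect_true(all(err$outcome == "reward_wait_error"))
  expect_true(all(err$waiting_time_s < err$scheduled_delay_s))
  # omission waits of the hasty agent are geometric(1/2) on the tau grid
  set.seed(5)
  om_cond <- task_condition("om", 0.75, n_trials = 40)
  many <- do.call(rbind, lapply(1:250, function(i) {
    simulate_trials(build_schedule(om_cond), hasty, om_cond)
  }))
  om <- many$waiting_time_s[many$outcome == "omission_quit"]
  expect_gt(length(om), 2000)
  expect_equal(mean(om), 0.2, tolerance = 0.02)
  expect_true(all(abs(om / 0.1 - round(om / 0.1)) < 1e-9))
})

test_that("simulate_trial applies the same rules to a single template", {
  cond <- task_condition("c", 0.75)
  template <- tibble::tibble(trial_index = 1L, light = "yellow",
                             is_reward_trial = TRUE, scheduled_delay_s = 3)
  set.seed(6)
  rec <- simulate_trial(template, agent_config(early_withdrawal_rate = 0), cond)
  expect_equal(nrow(rec), 1)
  expect_true(rec$outcome %in% c("rewarded", "reward_wait_error"))
  expect_error(simulate_trial(template[0, ], agent_config(), cond), "one-row")
})

test_that("cohorts have the promised size, block counts and reproducibility", {
  cond <- task_condition("75pct-1pellet", 0.75)
  log <- simulate_cohort(cond, agent_config(), n_mice = 2, tests_per_mouse = 3,
                         seed = 11)
  expect_equal(nrow(log), 2 * 3 * 40)
  expect_equal(dplyr::n_distinct(log$test_id), 6)
  log2 <- simulate_cohort(cond, agent_config(), n_mice = 2, tests_per_mouse = 3,
                          seed = 11)
  expect_identical(log, log2)
  # block cohort: exact omission counts carry through the simulation
  d6 <- task_condition("D6", 0.75, delay_set = 6, schedule_kind = "block")
  agent6 <- agent_config(belief = moment_matched_belief(6), early_withdrawal_rate = 0)
  log6 <- simulate_cohort(d6, agent6, n_mice = 3, tests_per_mouse = 4, seed = 12)
  expect_equal(sum(log6$outcome == "omission_quit"), 3 * 4 * 10)
  expect_error(simulate_cohort(list(), agent_config()), "empty design")
})

test_that("trial logs round-trip through CSV and invalid files are rejected", {
  log <- simulate_cohort(task_condition("c", 0.75), agent_config(),
                         n_mice = 2, tests_per_mouse = 3, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(log, path)
  back <- read_trial_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log), tolerance = 1e-9)
  # header is the fixed schema
  expect_identical(
    strsplit(readLines(path, n = 1), ",")[[1]],
    c("mouse_id", "test_id", "condition", "trial_index", "light",
      "is_reward_trial", "scheduled_delay_s", "outcome", "waiting_time_s"))
  # unknown outcome enum
  bad <- make_toy_log()
  bad$outcome[3] <- "eaten"
  expect_error(validate_trial_log(bad), "row 3.*outcome|unknown outcome")
  # rewarded trial must wait exactly the scheduled delay
  bad2 <- make_toy_log()
  bad2$waiting_time_s[1] <- 2.7
  expect_error(validate_trial_log(bad2), "exactly the scheduled delay")
  bad3 <- make_toy_log()[, -4]
  expect_error(validate_trial_log(bad3), "missing column")
})

test_that("per-mouse heterogeneity perturbs behaviour only when requested", {
  cond <- task_condition("c", 0.75)
  base <- simulate_cohort(cond, agent_config(), n_mice = 3, tests_per_mouse = 2,
                          seed = 31)
  jit <- simulate_cohort(cond, agent_config(), n_mice = 3, tests_per_mouse = 2,
                         mouse_sd_sigma = 0.2, seed = 31)
  expect_false(isTRUE(all.equal(base$waiting_time_s, jit$waiting_time_s)))
})
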
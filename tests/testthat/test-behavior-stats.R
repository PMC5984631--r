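toy_summary <- function(blue, yellow, test_id = "t1") {
  tibble::tibble(
    mouse_id = "m01", test_id = test_id, condition = "c",
    light = c("blue", "yellow"), n_trials = c(5L, 5L),
    mean_wait_s = c(blue, yellow), sem_s = c(0.1, 0.1)
  )
}

test_that("omission filtering keeps the boundary and drops quick withdrawals", {
  log <- make_toy_log()
  log <- dplyr::bind_rows(log, log, log, log, log)
  log$trial_index <- seq_len(nrow(log))
  om <- which(log$outcome == "omission_quit")[1:5]
  log$waiting_time_s[om] <- c(0.8, 1.4, 1.5, 2.0, 6.0)
  log$outcome[-om] <- "rewarded"
  log$is_reward_trial[-om] <- TRUE
  log$scheduled_delay_s[-om] <- 3
  log$waiting_time_s[-om] <- 3
  log$outcome[om] <- "omission_quit"
  log$is_reward_trial[om] <- FALSE
  log$scheduled_delay_s[om] <- NA
  parts <- filter_omission_trials(log)
  expect_equal(nrow(parts$kept), 3)
  expect_equal(nrow(parts$excluded), 2)
  expect_setequal(parts$kept$waiting_time_s, c(1.5, 2.0, 6.0))
  # min_wait = 0 keeps everything; reward trials never appear
  all_kept <- filter_omission_trials(log, min_wait = 0)
  expect_equal(nrow(all_kept$kept), 5)
  expect_equal(nrow(all_kept$excluded), 0)
  none <- filter_omission_trials(log[log$outcome == "rewarded", ])
  expect_equal(nrow(none$kept), 0)
  expect_equal(nrow(none$excluded), 0)
})

test_that("waiting summaries report mean and standard error per cell", {
  kept <- tibble::tibble(
    mouse_id = "m01", test_id = "t1", condition = "c",
    light = c("blue", "blue", "yellow", "yellow"),
    outcome = "omission_quit",
    waiting_time_s = c(4, 6, 5, 5)
  )
  s <- summarize_waiting(kept)
  blue <- s[s$light == "blue", ]
  expect_equal(blue$mean_wait_s, 5)
  expect_equal(blue$sem_s, 1)
  expect_warning(summarize_waiting(kept[c(1, 3, 4), ]), "single-trial")
})

test_that("waiting-time ratios divide activation by no-activation means", {
  expect_equal(waiting_time_ratio(toy_summary(5, 5))$ratio, 1)
  expect_equal(waiting_time_ratio(toy_summary(5, 4))$ratio, 1.25)
  # the published population means for the 75% one-pellet test
  r <- waiting_time_ratio(toy_summary(7.89, 6.95))$ratio
  expect_equal(r, 7.89 / 6.95)
  expect_equal(round(r, 4), 1.1353)
  # a test missing one light is dropped with a warning
  half <- toy_summary(5, 4)[1, ]
  expect_warning(out <- waiting_time_ratio(dplyr::bind_rows(toy_summary(5, 4), half |>
    dplyr::mutate(test_id = "t2"))), "missing a light")
  expect_equal(nrow(out), 1)
  expect_error(waiting_time_ratio(toy_summary(5, 0)), "zero mean yellow")
})

test_that("rank test matches explicit summation and collapses to Kruskal-Wallis", {
  # fixed 2x2 design, 3 replicates per cell, distinct values
  d <- tibble::tibble(
    y = c(1.2, 1.5, 1.1, 2.3, 2.1, 2.6, 0.7, 0.9, 0.8, 3.1, 2.9, 3.4),
    a = rep(rep(c("a1", "a2"), each = 3), 2),
    b = rep(c("b1", "b2"), each = 6)
  )
  fit <- scheirer_ray_hare(d, y ~ a * b)
  orc <- oracle_rank_anova_balanced(d$y, d$a, d$b)
  tt <- tidy(fit)
  expect_equal(tt$statistic[tt$term == "a"], orc$H_a, tolerance = 1e-12)
  expect_equal(tt$statistic[tt$term == "b"], orc$H_b, tolerance = 1e-12)
  expect_equal(tt$statistic[tt$term == "a:b"], orc$H_ab, tolerance = 1e-12)
  expect_equal(tt$df, c(orc$df_a, orc$df_b, orc$df_ab))
  expect_equal(tt$p.value, pchisq(tt$statistic, tt$df, lower.tail = FALSE))
  # constant observations carry no information
  dc <- d; dc$y <- 1
  tc <- tidy(scheirer_ray_hare(dc, y ~ a * b))
  expect_equal(tc$statistic, rep(0, 3))
  expect_equal(tc$p.value, rep(1, 3))
  # single-factor form equals the tie-corrected Kruskal-Wallis statistic
  set.seed(8)
  for (i in 1:5) {
    g <- sample(c("g1", "g2", "g3"), 30, replace = TRUE)
    y <- round(rnorm(30), 1)  # rounding forces ties
    h <- tidy(scheirer_ray_hare(tibble::tibble(y = y, g = g), y ~ g))
    kw <- kruskal.test(y, factor(g))
    expect_equal(h$statistic, unname(kw$statistic), tolerance = 1e-12)
    expect_equal(h$p.value, kw$p.value, tolerance = 1e-12)
  }
  expect_error(scheirer_ray_hare(tibble::tibble(y = 1:4, g = "g1"), y ~ g),
               "at least 2")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.004, m = 10), 0.04)
  expect_equal(bonferroni_adjust(0.2, m = 10), 1)
  expect_equal(bonferroni_adjust(c(0.01, 0.3), m = 2), c(0.02, 0.6))
  expect_equal(bonferroni_adjust(0.3, m = 1), 0.3)
  expect_error(bonferroni_adjust(0.5, m = 0), ">= 1")
  expect_error(bonferroni_adjust(c(0.1, 0.2, 0.3), m = 2), "at least the number")
})

test_that("standard group tests give exact landmark results", {
  mw <- group_tests(c(1, 2, 3), c(10, 11, 12), kind = "mann_whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p.value, 0.1)   # minimal exact two-sided p at n = m = 3
  pt <- group_tests(c(2, 4, 6), c(2, 4, 6), kind = "paired_t")
  expect_equal(pt$statistic, 0)
  expect_equal(pt$p.value, 1)
  kw <- group_tests(list(c(1, 1), c(1, 1), c(1, 1)), kind = "kruskal_wallis")
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)
  expect_error(group_tests(1:3, 1:4, kind = "paired_t"), "equal lengths")
})

test_that("bootstrap LRT rejects bad input and is seed-reproducible", {
  tb <- simulate_ratio_table(120, n_mice = 4, seed = 5)
  expect_error(bootstrap_lrt_random_effect(tb, ratio ~ rp + ep, n_boot = 0),
               ">= 1")
  expect_error(bootstrap_lrt_random_effect(tb[tb$mouse_id == "m01", ],
                                           ratio ~ rp + ep), ">= 2 mice")
  b1 <- bootstrap_lrt_random_effect(tb, ratio ~ rp + ep, n_boot = 29, seed = 9)
  b2 <- bootstrap_lrt_random_effect(tb, ratio ~ rp + ep, n_boot = 29, seed = 9)
  expect_equal(tidy(b1), tidy(b2))
  expect_gt(b1$p.value, 0)
  expect_lte(b1$p.value, 1)
  g <- glance(b1)
  expect_true(all(c("mouse_sd", "residual_sd") %in% names(g)))
})

test_that("stimulated cohorts wait longer on blue omission trials at 75%", {
  # replicate cohorts: the blue mean should exceed the yellow mean nearly always
  wins <- vapply(1:20, function(s) {
    log <- simulate_cohort(task_condition("c75", 0.75), agent_config(),
                           n_mice = 2, tests_per_mouse = 3, seed = 100 + s)
    kept <- filter_omission_trials(log)$kept
    m <- tapply(kept$waiting_time_s, kept$light, mean)
    m["blue"] > m["yellow"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("timing-uncertainty conditions order the simulated ratios as D2-6-10 > D4-6-8 > D6", {
  conds <- list(
    task_condition("D6", 0.75, delay_set = 6, schedule_kind = "block"),
    task_condition("D4-6-8", 0.75, delay_set = c(4, 6, 8), schedule_kind = "block"),
    task_condition("D2-6-10", 0.75, delay_set = c(2, 6, 10), schedule_kind = "block")
  )
  means <- vapply(conds, function(cond) {
    agent <- agent_config(belief = moment_matched_belief(cond$delay_set),
                          early_withdrawal_rate = 0)
    log <- simulate_cohort(cond, agent, n_mice = 6, tests_per_mouse = 10, seed = 77)
    ratios <- suppressWarnings(
      waiting_time_ratio(summarize_waiting(filter_omission_trials(log)$kept)))
    mean(ratios$ratio)
  }, numeric(1))
  expect_true(means[3] > means[2])
  expect_true(means[2] > means[1])
})

test_that("ratio plots build", {
  tb <- simulate_ratio_table(40, seed = 3)
  r <- tibble::tibble(condition = as.character(tb$rp[1:20]), ratio = tb$ratio[1:20])
  expect_s3_class(plot_waiting_ratios(r), "ggplot")
})
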
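#' Task condition for the sequential tone-food waiting task
#'
#' Describes one test configuration: the programmed reward probability, the
#' pellet count, the reward-delay schedule and how trials are scheduled.
#' `schedule_kind = "bernoulli"` draws the reward/omission state per trial
#' (experiment-1 style, fixed 3 s delay); `schedule_kind = "block"` realises
#' the 8-trial block design (three rewarded and one omission trial per light
#' condition per block, block order randomised, repeated `n_trials / 8`
#' times), which presumes a 75% reward probability.
#'
#' @param name Condition label, e.g. `"75pct-1pellet"` or `"D2-6-10"`.
#' @param reward_probability Programmed reward probability, in (0, 1\].
#' @param pellets Pellet count per rewarded trial.
#' @param delay_set Possible reward delays, seconds.
#' @param delay_weights Selection weights over `delay_set` (default uniform).
#' @param schedule_kind `"bernoulli"` or `"block"`.
#' @param n_trials Trials per test (default 40).
#' @param session_limit Session time limit in seconds (default 3000); the
#'   simulated schedule is truncated once cumulative waiting exceeds it.
#' @return A `task_condition` object.
#' @export
task_condition <- function(name, reward_probability, pellets = 1,
                           delay_set = 3, delay_weights = NULL,
                           schedule_kind = c("bernoulli", "block"),
                           n_trials = 40, session_limit = 3000) {
  schedule_kind <- match.arg(schedule_kind)
  if (!is.finite(reward_probability) || reward_probability <= 0 ||
      reward_probability > 1) {
    abort("`reward_probability` must lie in (0, 1].")
  }
  if (any(delay_set <= 0)) abort("all delays must be > 0.")
  if (n_trials <= 0) abort("`n_trials` must be > 0.")
  if (is.null(delay_weights)) delay_weights <- rep(1 / length(delay_set), length(delay_set))
  if (length(delay_weights) != length(delay_set)) {
    abort("`delay_weights` must match `delay_set`.")
  }
  if (schedule_kind == "block") {
    if (n_trials %% 8 != 0) abort("block scheduling requires `n_trials` divisible by 8.")
    if (!length(delay_set) %in% c(1L, 3L)) {
      abort("block scheduling supports 1 or 3 distinct delays per block.")
    }
    if (abs(reward_probability - 0.75) > 1e-9) {
      abort("the 8-trial block design realises a 75% reward probability.")
    }
  }
  structure(
    list(name = name, reward_probability = reward_probability, pellets = pellets,
         delay_set = delay_set, delay_weights = delay_weights / sum(delay_weights),
         schedule_kind = schedule_kind, n_trials = as.integer(n_trials),
         session_limit = session_limit),
    class = "task_condition"
  )
}

#' Model-driven agent configuration
#'
#' Binds a timing belief, a decision policy and a stimulation prior mapping
#' into the agent that behaves in the simulated task. The baseline prior is
#' the programmed reward probability of the condition (`prior_source =
#' "programmed"`) or a fixed override; on blue-light (stimulation) trials the
#' prior passes through `mapping`. Rare early withdrawals — quick removals of
#' the nose unrelated to the decision process — are injected at
#' `early_withdrawal_rate` with waiting times uniform on
#' (0, `early_withdrawal_max`).
#'
#' @param belief A [timing_belief()].
#' @param policy A [decision_policy()].
#' @param mapping A [stim_mapping()]; applied only on blue trials.
#' @param prior_source `"programmed"` or `"fixed"`.
#' @param prior_fixed Fixed baseline prior when `prior_source = "fixed"`.
#' @param early_withdrawal_rate Probability of an early withdrawal per trial,
#'   in \[0, 1) (default 0.005).
#' @param early_withdrawal_max Upper bound of early-withdrawal waiting times,
#'   seconds (default 1.5, matching the analysis exclusion threshold).
#' @return An `agent_config` object.
#' @export
agent_config <- function(belief = timing_belief(3, 2),
                         policy = decision_policy(),
                         mapping = stim_mapping("polynomial"),
                         prior_source = c("programmed", "fixed"),
                         prior_fixed = NULL,
                         early_withdrawal_rate = 0.005,
                         early_withdrawal_max = 1.5) {
  prior_source <- match.arg(prior_source)
  if (!is_timing_belief(belief)) abort("`belief` must be a timing_belief.")
  if (!inherits(policy, "decision_policy")) abort("`policy` must be a decision_policy.")
  if (!inherits(mapping, "stim_mapping")) abort("`mapping` must be a stim_mapping.")
  if (early_withdrawal_rate < 0 || early_withdrawal_rate >= 1) {
    abort("`early_withdrawal_rate` must lie in [0, 1).")
  }
  if (early_withdrawal_max <= 0) abort("`early_withdrawal_max` must be > 0.")
  if (prior_source == "fixed") {
    if (is.null(prior_fixed)) abort("`prior_source = \"fixed\"` requires `prior_fixed`.")
    check_probability(prior_fixed, "prior_fixed")
  }
  structure(
    list(belief = belief, policy = policy, mapping = mapping,
         prior_source = prior_source, prior_fixed = prior_fixed,
         early_withdrawal_rate = early_withdrawal_rate,
         early_withdrawal_max = early_withdrawal_max),
    class = "agent_config"
  )
}

agent_prior <- function(agent, condition) {
  if (agent$prior_source == "fixed") agent$prior_fixed else condition$reward_probability
}

#' Build a trial schedule for one test
#'
#' Produces the trial templates (light condition, reward/omission state,
#' scheduled delay) for a single test of `condition`. Uses R's RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' Block scheduling yields exact counts — per 8-trial block, each light gets
#' three rewarded trials (the three delays of the schedule, or the fixed
#' delay thrice) and one omission trial, order randomised within block.
#' Bernoulli scheduling draws the reward state independently per trial with
#' the condition's reward probability and applies blue light to a randomly
#' chosen half of the trials.
#'
#' @param condition A [task_condition()].
#' @return A tibble with columns `trial_index`, `light` (`"yellow"`/`"blue"`),
#'   `is_reward_trial`, `scheduled_delay_s` (`NA` on omission trials).
#' @export
build_schedule <- function(condition) {
  if (!inherits(condition, "task_condition")) abort("`condition` must be a task_condition.")
  n <- condition$n_trials
  if (condition$schedule_kind == "block") {
    delays <- if (length(condition$delay_set) == 1L) {
      rep(condition$delay_set, 3)
    } else {
      condition$delay_set
    }
    block <- tibble::tibble(
      light = rep(c("blue", "yellow"), each = 4L),
      is_reward_trial = rep(c(TRUE, TRUE, TRUE, FALSE), 2L),
      scheduled_delay_s = rep(c(delays, NA_real_), 2L)
    )
    out <- purrr::map(seq_len(n %/% 8L), function(b) {
      block[sample.int(8L), ]
    })
    out <- dplyr::bind_rows(out)
  } else {
    n_blue <- n %/% 2L
    light <- sample(c(rep("blue", n_blue), rep("yellow", n - n_blue)))
    is_reward <- runif(n) < condition$reward_probability
    delay <- ifelse(
      is_reward,
      condition$delay_set[sample.int(length(condition$delay_set), n, replace = TRUE,
                                     prob = condition$delay_weights)],
      NA_real_
    )
    out <- tibble::tibble(light = light, is_reward_trial = is_reward,
                          scheduled_delay_s = delay)
  }
  out$trial_index <- seq_len(nrow(out))
  dplyr::select(out, "trial_index", "light", "is_reward_trial", "scheduled_delay_s")
}

# Sample quit times (seconds, on the tau grid) from a quit-time distribution.
# The vanishing survival mass at the horizon is assigned to the horizon itself.
sample_quit_times <- function(n, dist) {
  policy <- attr(dist, "policy")
  k <- sample.int(nrow(dist) + 1L, n, replace = TRUE,
                  prob = c(dist$p_quit, attr(dist, "p_wait_tail")))
  pmin(k, nrow(dist)) * policy$tau
}

#' Simulate the trials of one schedule
#'
#' Runs the model-driven agent through a schedule. The agent's quit time on
#' every trial is drawn from its quit-time distribution (yellow trials use
#' the baseline prior, blue trials the stimulation-mapped prior), or replaced
#' by an early withdrawal with the configured probability. Outcomes follow
#' the task rules: on a reward trial a quit beyond the scheduled delay yields
#' `rewarded` with waiting time equal to the delay, an earlier quit yields
#' `reward_wait_error` at the quit time; omission trials end with
#' `omission_quit` at the quit time. The schedule is truncated once
#' cumulative waiting exceeds the condition's session limit.
#'
#' @param schedule Tibble from [build_schedule()].
#' @param agent An [agent_config()].
#' @param condition The [task_condition()] the schedule realises.
#' @return A tibble of trial records: `trial_index`, `light`,
#'   `is_reward_trial`, `scheduled_delay_s`, `outcome`, `waiting_time_s`.
#' @export
simulate_trials <- function(schedule, agent, condition) {
  if (!inherits(agent, "agent_config")) abort("`agent` must be an agent_config.")
  p_yellow <- agent_prior(agent, condition)
  p_blue <- stim_prior_map(p_yellow, agent$mapping)
  d_yellow <- quit_time_distribution(p_yellow, agent$belief, agent$policy)
  d_blue <- quit_time_distribution(p_blue, agent$belief, agent$policy)
  n <- nrow(schedule)
  quit <- numeric(n)
  blue <- schedule$light == "blue"
  quit[blue] <- sample_quit_times(sum(blue), d_blue)
  quit[!blue] <- sample_quit_times(sum(!blue), d_yellow)
  early <- runif(n) < agent$early_withdrawal_rate
  quit[early] <- runif(sum(early), 0, agent$early_withdrawal_max)

  out <- schedule
  out$outcome <- dplyr::case_when(
    !out$is_reward_trial ~ "omission_quit",
    quit > out$scheduled_delay_s ~ "rewarded",
    TRUE ~ "reward_wait_error"
  )
  out$waiting_time_s <- ifelse(out$outcome == "rewarded", out$scheduled_delay_s, quit)
  keep <- cumsum(out$waiting_time_s) <= condition$session_limit
  out[keep, , drop = FALSE]
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_trials()] for one trial template.
#'
#' @param template One-row tibble with `trial_index`, `light`,
#'   `is_reward_trial`, `scheduled_delay_s`.
#' @inheritParams simulate_trials
#' @return A one-row trial-record tibble.
#' @export
simulate_trial <- function(template, agent, condition) {
  if (!is.data.frame(template) || nrow(template) != 1L) {
    abort("`template` must be a one-row data frame.")
  }
  simulate_trials(template, agent, condition)
}

#' Simulate a cohort of mice across task conditions
#'
#' Generates a full trial log for a factorial design: every mouse performs
#' `tests_per_mouse` tests of every condition. Optional per-mouse
#' heterogeneity applies multiplicative log-normal jitter to the agent's
#' `beta` and belief `sigma`; both default to 0 (mice statistically
#' exchangeable).
#'
#' @param conditions A [task_condition()] or list of them.
#' @param agent An [agent_config()] shared by all mice.
#' @param n_mice Number of mice.
#' @param tests_per_mouse Tests per mouse per condition.
#' @param mouse_sd_beta,mouse_sd_sigma Standard deviations of the per-mouse
#'   log-normal multipliers on `beta` and belief `sigma` (default 0).
#' @param seed Optional integer seed; when supplied the log is a pure
#'   function of (design, seed) and the caller's RNG state is untouched.
#' @return A trial-log tibble with columns `mouse_id`, `test_id`,
#'   `condition`, `trial_index`, `light`, `is_reward_trial`,
#'   `scheduled_delay_s`, `outcome`, `waiting_time_s`.
#' @examples
#' cond <- task_condition("75pct-1pellet", 0.75)
#' log <- simulate_cohort(cond, agent_config(), n_mice = 2,
#'                        tests_per_mouse = 2, seed = 1)
#' @export
simulate_cohort <- function(conditions, agent = agent_config(), n_mice = 6,
                            tests_per_mouse = 20, mouse_sd_beta = 0,
                            mouse_sd_sigma = 0, seed = NULL) {
  if (inherits(conditions, "task_condition")) conditions <- list(conditions)
  if (length(conditions) == 0 || n_mice < 1 || tests_per_mouse < 1) {
    abort("empty design: need >= 1 condition, mouse and test.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  mouse_ids <- sprintf("m%02d", seq_len(n_mice))
  beta_mult <- exp(rnorm(n_mice, 0, mouse_sd_beta))
  sigma_mult <- exp(rnorm(n_mice, 0, mouse_sd_sigma))
  logs <- purrr::imap(setNames(seq_len(n_mice), mouse_ids), function(i, mid) {
    ag <- agent
    if (mouse_sd_beta > 0 || mouse_sd_sigma > 0) {
      ag$policy$beta <- agent$policy$beta * beta_mult[i]
      ag$belief <- timing_belief(agent$belief$mu,
                                 agent$belief$sigma * sigma_mult[i],
                                 agent$belief$weight)
    }
    per_cond <- purrr::map(conditions, function(cond) {
      per_test <- purrr::map(seq_len(tests_per_mouse), function(j) {
        trials <- simulate_trials(build_schedule(cond), ag, cond)
        trials$test_id <- sprintf("%s_%s_t%02d", mid, cond$name, j)
        trials
      })
      out <- dplyr::bind_rows(per_test)
      out$condition <- cond$name
      out
    })
    dplyr::bind_rows(per_cond)
  })
  out <- dplyr::bind_rows(logs, .id = "mouse_id")
  dplyr::select(out, "mouse_id", "test_id", "condition", "trial_index", "light",
                "is_reward_trial", "scheduled_delay_s", "outcome", "waiting_time_s")
}

trial_log_columns <- c("mouse_id", "test_id", "condition", "trial_index", "light",
                       "is_reward_trial", "scheduled_delay_s", "outcome",
                       "waiting_time_s")

#' Validate a trial log
#'
#' Checks the schema and the task invariants: known light and outcome codes,
#' nonnegative times, rewarded trials wait exactly the scheduled delay,
#' reward wait errors wait less than it, omission trials have no scheduled
#' delay. Errors name the first offending row.
#'
#' @param log A trial-log data frame.
#' @param tol Numeric tolerance for the rewarded-trial identity (covers
#'   text round-trips).
#' @return The validated log, invisibly coerced to a tibble.
#' @export
validate_trial_log <- function(log, tol = 1e-6) {
  missing <- setdiff(trial_log_columns, names(log))
  if (length(missing)) {
    abort(sprintf("trial log is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  log <- tibble::as_tibble(log)
  fail <- function(rows, what) {
    if (any(rows)) abort(sprintf("trial log row %d: %s", which(rows)[1], what))
  }
  fail(!log$light %in% c("yellow", "blue"), "light must be 'yellow' or 'blue'")
  fail(!log$outcome %in% c("rewarded", "omission_quit", "reward_wait_error"),
       "unknown outcome")
  fail(!is.finite(log$waiting_time_s) | log$waiting_time_s < 0,
       "waiting_time_s must be a nonnegative number")
  fail(log$outcome == "omission_quit" &
         (log$is_reward_trial | !is.na(log$scheduled_delay_s)),
       "omission trials must have is_reward_trial FALSE and no scheduled delay")
  fail(log$outcome != "omission_quit" &
         (!log$is_reward_trial | is.na(log$scheduled_delay_s)),
       "reward-trial outcomes require is_reward_trial TRUE and a scheduled delay")
  fail(log$outcome == "rewarded" &
         abs(log$waiting_time_s - log$scheduled_delay_s) > tol,
       "rewarded trials must wait exactly the scheduled delay")
  fail(log$outcome == "reward_wait_error" &
         log$waiting_time_s >= log$scheduled_delay_s,
       "reward wait errors must wait less than the scheduled delay")
  invisible(log)
}

#' Read / write trial logs as CSV
#'
#' The on-disk schema is the fixed header `mouse_id,test_id,condition,`
#' `trial_index,light,is_reward_trial,scheduled_delay_s,outcome,`
#' `waiting_time_s`, with empty `scheduled_delay_s` on omission trials.
#' Both directions validate the log; waiting times round-trip at full
#' double precision.
#'
#' @param path File path.
#' @param log A trial-log tibble.
#' @return `read_trial_log()` returns the validated tibble;
#'   `write_trial_log()` returns `log` invisibly.
#' @export
read_trial_log <- function(path) {
  log <- readr::read_csv(
    path,
    col_types = readr::cols(
      mouse_id = readr::col_character(),
      test_id = readr::col_character(),
      condition = readr::col_character(),
      trial_index = readr::col_integer(),
      light = readr::col_character(),
      is_reward_trial = readr::col_logical(),
      scheduled_delay_s = readr::col_double(),
      outcome = readr::col_character(),
      waiting_time_s = readr::col_double()
    ),
    na = ""
  )
  missing <- setdiff(trial_log_columns, names(log))
  if (length(missing)) {
    abort(sprintf("'%s' is missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  validate_trial_log(log)
  log
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(log, path) {
  validate_trial_log(log)
  readr::write_csv(log[trial_log_columns], path, na = "")
  invisible(log)
}

#' Simulate a factorial table of waiting-time ratios
#'
#' Direct generator of per-test waiting-time ratios with a known
#' fixed-effect and mouse-random-effect structure, for calibration and power
#' studies of the factorial statistics (rank test, bootstrap likelihood-ratio
#' test). Each test contributes one row:
#' `ratio = intercept + rp_effect + ep_effect + mouse_intercept + noise`.
#'
#' @param n_tests Total number of tests (rows).
#' @param n_mice Number of mice; tests are assigned to mice cyclically.
#' @param rp_levels,ep_levels Factor levels for reward probability (percent)
#'   and expected pellets.
#' @param rp_effects,ep_effects Named numeric vectors of level effects added
#'   to the intercept (default all zero — a null table).
#' @param intercept Baseline ratio (default 1).
#' @param mouse_sd S.d. of the mouse random intercept (default 0).
#' @param resid_sd Residual s.d. of per-test ratios (default 0.05).
#' @param seed Optional integer seed.
#' @return A tibble: `ratio`, `rp` (factor), `ep` (factor), `mouse_id`.
#' @export
simulate_ratio_table <- function(n_tests = 200, n_mice = 6,
                                 rp_levels = c(25, 50, 75),
                                 ep_levels = c(0.25, 0.5, 0.75, 1.5),
                                 rp_effects = NULL, ep_effects = NULL,
                                 intercept = 1, mouse_sd = 0, resid_sd = 0.05,
                                 seed = NULL) {
  if (n_tests < 1 || n_mice < 1) abort("`n_tests` and `n_mice` must be >= 1.")
  if (!is.null(seed)) withr::local_seed(seed)
  rp <- factor(sample(rp_levels, n_tests, replace = TRUE), levels = rp_levels)
  ep <- factor(sample(ep_levels, n_tests, replace = TRUE), levels = ep_levels)
  mouse <- factor(sprintf("m%02d", rep_len(seq_len(n_mice), n_tests)))
  b_rp <- (rp_effects %||% setNames(rep(0, length(rp_levels)), rp_levels))[as.character(rp)]
  b_ep <- (ep_effects %||% setNames(rep(0, length(ep_levels)), ep_levels))[as.character(ep)]
  u <- rnorm(n_mice, 0, mouse_sd)[as.integer(mouse)]
  tibble::tibble(
    ratio = intercept + unname(b_rp) + unname(b_ep) + u + rnorm(n_tests, 0, resid_sd),
    rp = rp, ep = ep, mouse_id = mouse
  )
}
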
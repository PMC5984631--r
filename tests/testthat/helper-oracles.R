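# Independent oracles. These re-derive model quantities from first principles
# (their own formulas, step-by-step simulation, explicit summation) and never
# call the package's recursion/statistics internals they are used to check.

# Step-by-step Monte-Carlo agent: at each epoch t_k = k * tau an alive trial
# recomputes the posterior from scratch and continues with the softmax
# probability; returns the quit step (0 = still waiting at the horizon).
oracle_mc_quit_steps <- function(n, p_reward, mu, sigma, weight = 1,
                                 beta = 50, tau = 0.1, horizon = 60,
                                 reward_magnitude = 1) {
  n_steps <- round(horizon / tau)
  quit_step <- integer(n)
  alive <- rep(TRUE, n)
  for (k in seq_len(n_steps)) {
    idx <- which(alive)
    if (!length(idx)) break
    t_k <- k * tau
    L <- sum(weight * (1 - pnorm((t_k - mu) / sigma)))
    post <- if (p_reward == 1) as.numeric(L > 0) else {
      p_reward * L / (p_reward * L + (1 - p_reward))
    }
    p_wait <- 1 / (1 + exp(-beta * reward_magnitude * post))
    quits <- runif(length(idx)) > p_wait
    quit_step[idx[quits]] <- k
    alive[idx[quits]] <- FALSE
  }
  quit_step
}

# Empirical quit-mass histogram over the tau grid from Monte-Carlo quit steps.
oracle_mc_quit_mass <- function(quit_step, n_steps) {
  c(tabulate(quit_step[quit_step > 0], nbins = n_steps),
    sum(quit_step == 0)) / length(quit_step)
}

# Mixture survival via numeric integration of the density (independent of
# pnorm-based evaluation in the package).
oracle_mixture_survival <- function(t, weight, mu, sigma) {
  dens <- function(x) {
    out <- 0
    for (i in seq_along(weight)) out <- out + weight[i] * dnorm(x, mu[i], sigma[i])
    out
  }
  1 - integrate(dens, -Inf, t, rel.tol = 1e-12)$value
}

# Two-way rank ANOVA by explicit summation (balanced designs): midrank the
# response, then classic sums of squares from cell/margin means.
oracle_rank_anova_balanced <- function(y, a, b) {
  r <- rank(y)
  n <- length(r)
  rbar <- mean(r)
  ss <- function(split_means, counts) sum(counts * (split_means - rbar)^2)
  ma <- tapply(r, a, mean); na <- tapply(r, a, length)
  mb <- tapply(r, b, mean); nb <- tapply(r, b, length)
  mab <- tapply(r, list(a, b), mean); nab <- tapply(r, list(a, b), length)
  ss_a <- ss(ma, na)
  ss_b <- ss(mb, nb)
  ss_cells <- sum(nab * (mab - rbar)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ms_total <- sum((r - rbar)^2) / (n - 1)
  list(
    H_a = ss_a / ms_total, H_b = ss_b / ms_total, H_ab = ss_ab / ms_total,
    df_a = nlevels(factor(a)) - 1, df_b = nlevels(factor(b)) - 1,
    df_ab = (nlevels(factor(a)) - 1) * (nlevels(factor(b)) - 1)
  )
}

# Direct per-trial likelihood: multiply the wait/quit factors step by step
# with freshly computed posteriors (no recursion, no vector cumprod).
oracle_trial_negloglik <- function(outcome, time_s, p_reward, mu, sigma,
                                   beta = 50, tau = 0.1) {
  k_end <- round(time_s / tau)
  logp <- 0
  for (k in seq_len(k_end)) {
    t_k <- k * tau
    L <- 1 - pnorm((t_k - mu) / sigma)
    post <- p_reward * L / (p_reward * L + (1 - p_reward))
    pw <- 1 / (1 + exp(-beta * post))
    if (k < k_end) {
      logp <- logp + log(pw)
    } else if (outcome == "rewarded") {
      logp <- logp + log(pw)   # censored: still waiting through the delay
    } else {
      logp <- logp + log(1 - pw)
    }
  }
  -logp
}

# Small well-formed trial log built by hand for IO/validation tests.
make_toy_log <- function() {
  tibble::tibble(
    mouse_id = "m01",
    test_id = "m01_toy_t01",
    condition = "toy",
    trial_index = 1:5,
    light = c("yellow", "blue", "yellow", "blue", "yellow"),
    is_reward_trial = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    scheduled_delay_s = c(3, 3, NA, NA, 3),
    outcome = c("rewarded", "reward_wait_error", "omission_quit",
                "omission_quit", "rewarded"),
    waiting_time_s = c(3, 2.5, 7.2, 8.4, 3)
  )
}
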
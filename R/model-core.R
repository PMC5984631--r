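#' Belief about the timing of reward delivery
#'
#' Constructs the agent's internal model of *when* a reward arrives on a
#' reward trial. The canonical belief is a single Gaussian \eqn{N(t; \mu,
#' \sigma^2)}; a mixture of Gaussians is supported so that multi-modal delay
#' schedules (e.g. delays drawn from \{2, 6, 10\} s) can be represented either
#' exactly or through a moment-matched single component.
#'
#' @param mu Numeric vector of component means, in seconds.
#' @param sigma Numeric vector of component standard deviations, in seconds
#'   (all strictly positive).
#' @param weight Mixture weights; must be positive and sum to 1 (within
#'   1e-9). Defaults to equal weights.
#'
#' @return A `timing_belief`: a tibble with columns `weight`, `mu`, `sigma`.
#' @examples
#' timing_belief(mu = 3, sigma = 2)
#' timing_belief(mu = c(2, 6, 10), sigma = c(0.5, 0.5, 0.5))
#' @export
timing_belief <- function(mu, sigma, weight = NULL) {
  if (length(sigma) == 1L && length(mu) > 1L) sigma <- rep(sigma, length(mu))
  if (is.null(weight)) weight <- rep(1 / length(mu), length(mu))
  if (length(mu) != length(sigma) || length(mu) != length(weight)) {
    abort("`mu`, `sigma` and `weight` must have equal lengths.")
  }
  if (!all(is.finite(mu)) || !all(is.finite(sigma)) || !all(is.finite(weight))) {
    abort("timing belief parameters must be finite.")
  }
  if (any(sigma <= 0)) abort("every `sigma` must be > 0.")
  if (any(weight <= 0)) abort("every mixture `weight` must be > 0.")
  if (abs(sum(weight) - 1) > 1e-9) abort("mixture weights must sum to 1 (within 1e-9).")
  out <- tibble::tibble(weight = as.numeric(weight), mu = as.numeric(mu),
                        sigma = as.numeric(sigma))
  class(out) <- c("timing_belief", class(out))
  out
}

is_timing_belief <- function(x) inherits(x, "timing_belief")

#' Moment-matched Gaussian belief for a delay schedule
#'
#' Fits a single-Gaussian timing belief to a discrete delay schedule by
#' matching its mean and variance. A baseline internal timing noise
#' `timing_sd` is added in quadrature, so a fixed delay (schedule variance
#' zero) still yields a valid belief: the agent's interval timing is never
#' noiseless.
#'
#' @param delays Numeric vector of scheduled delays, seconds.
#' @param weights Selection probabilities for each delay (default uniform).
#' @param timing_sd Baseline timing noise s.d., seconds (default 2).
#' @return A single-component [timing_belief()].
#' @examples
#' moment_matched_belief(c(2, 6, 10))   # mu = 6, sigma = sqrt(32/3 + 4)
#' @export
moment_matched_belief <- function(delays, weights = NULL, timing_sd = 2) {
  if (is.null(weights)) weights <- rep(1 / length(delays), length(delays))
  weights <- weights / sum(weights)
  m <- sum(weights * delays)
  v <- sum(weights * (delays - m)^2)
  timing_belief(mu = m, sigma = sqrt(v + timing_sd^2))
}

#' Wait-or-quit decision policy
#'
#' Bundles the softmax inverse temperature, the interval between successive
#' wait-or-quit decisions, the modelling horizon and an optional reward
#' magnitude multiplier. Defaults are the values used throughout the model:
#' `beta = 50`, `tau = 0.1` s.
#'
#' @param beta Inverse temperature (unitless, >= 0). Larger values make the
#'   agent quit more deterministically once the posterior reward probability
#'   has decayed.
#' @param tau Decision interval in seconds (> 0).
#' @param horizon Maximum modelled waiting time, seconds; must be an integer
#'   multiple of `tau`.
#' @param reward_magnitude Reward size in pellets. Scales the softmax
#'   argument (`beta * reward_magnitude * posterior`); the default 1 leaves
#'   the unit-reward model untouched.
#' @return A `decision_policy` object.
#' @export
decision_policy <- function(beta = 50, tau = 0.1, horizon = 60,
                            reward_magnitude = 1) {
  if (!is.finite(beta) || beta < 0) abort("`beta` must be finite and >= 0.")
  if (!is.finite(tau) || tau <= 0) abort("`tau` must be finite and > 0.")
  if (!is.finite(horizon) || horizon < tau) abort("`horizon` must be finite and >= `tau`.")
  if (!is.finite(reward_magnitude) || reward_magnitude <= 0) {
    abort("`reward_magnitude` must be finite and > 0.")
  }
  n_steps <- horizon / tau
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    abort("`horizon` must be an integer multiple of `tau`.")
  }
  structure(
    list(beta = beta, tau = tau, horizon = horizon,
         reward_magnitude = reward_magnitude, n_steps = as.integer(round(n_steps))),
    class = "decision_policy"
  )
}

#' @export
print.decision_policy <- function(x, ...) {
  cat(sprintf(
    "<decision_policy> beta = %g, tau = %g s, horizon = %g s, reward magnitude = %g\n",
    x$beta, x$tau, x$horizon, x$reward_magnitude))
  invisible(x)
}

#' Survival likelihood of a reward trial
#'
#' Probability, under the timing belief, that the reward has *not yet* been
#' delivered by time `t` on a reward trial: \eqn{1 - \sum_i w_i \Phi((t -
#' \mu_i)/\sigma_i)}. On a no-reward trial the corresponding likelihood is
#' identically 1.
#'
#' @param belief A [timing_belief()].
#' @param t Time(s) since waiting began, seconds; any finite real.
#' @return Numeric vector in (0, 1), nonincreasing in `t`.
#' @examples
#' survival_likelihood(timing_belief(3, 2), 3)  # 0.5 at the mean
#' @export
survival_likelihood <- function(belief, t) {
  if (!is_timing_belief(belief)) abort("`belief` must be a timing_belief.")
  if (!all(is.finite(t))) abort("`t` must be finite.")
  # complementary cdf componentwise to avoid cancellation at large t
  out <- 0
  for (i in seq_len(nrow(belief))) {
    out <- out + belief$weight[i] *
      pnorm(t, belief$mu[i], belief$sigma[i], lower.tail = FALSE)
  }
  out
}

#' Posterior probability of a reward trial given no reward by time t
#'
#' Bayes' rule over the hidden trial state (reward vs. no-reward) with the
#' survival likelihood for the reward state and likelihood 1 for the
#' no-reward state:
#' \deqn{P(\mathrm{reward} \mid t) = \frac{p \, (1 - f(t))}{p \, (1 - f(t)) + (1 - p)}}
#' where `p` is the prior reward probability and `f` the cumulative timing
#' belief.
#'
#' @param p_reward Prior probability of a reward trial, in \[0, 1\].
#' @inheritParams survival_likelihood
#' @return Numeric vector in \[0, 1\]; nonincreasing in `t`, nondecreasing in
#'   `p_reward`.
#' @examples
#' posterior_reward(0.75, timing_belief(3, 2), 3)  # 0.6
#' @export
posterior_reward <- function(p_reward, belief, t) {
  check_probability(p_reward, "p_reward")
  L <- survival_likelihood(belief, t)
  if (p_reward == 1) return(as.numeric(L > 0))
  p_reward * L / (p_reward * L + (1 - p_reward))
}

#' Softmax probability of continuing to wait
#'
#' With value of waiting \eqn{V(wait|t) = r \cdot P(reward|t)} and value of
#' quitting 0, the softmax choice probability is
#' \eqn{P(wait|t) = 1 / (1 + \exp(-\beta r P(reward|t)))}.
#'
#' @param posterior Posterior reward probability/ies, in \[0, 1\].
#' @param policy A [decision_policy()] supplying `beta` and
#'   `reward_magnitude`.
#' @return Numeric vector in \[0.5, 1\]; exactly 0.5 when the posterior is 0
#'   or `beta` is 0.
#' @export
wait_probability <- function(posterior, policy = decision_policy()) {
  if (!inherits(policy, "decision_policy")) abort("`policy` must be a decision_policy.")
  if (!all(is.finite(posterior)) || any(posterior < 0) || any(posterior > 1)) {
    abort("`posterior` must lie in [0, 1].")
  }
  1 / (1 + exp(-policy$beta * policy$reward_magnitude * posterior))
}

#' Distribution of the time of quitting
#'
#' Runs the sequential wait-or-quit recursion on the grid \eqn{t_k = k\tau}:
#' \deqn{P_{wait}(0) = 1,\quad P_{wait}(t) = P_{wait}(t-\tau) P(wait|t),\quad
#'       P_{quit}(t) = P_{wait}(t-\tau) (1 - P(wait|t)).}
#' The posterior entering each decision is evaluated at the epoch's own time
#' \eqn{t_k}. Residual survival mass beyond the horizon is retained as the
#' `p_wait_tail` attribute; a warning is raised if it exceeds `tail_warn`.
#'
#' @inheritParams posterior_reward
#' @param policy A [decision_policy()].
#' @param tail_warn Warn if the survival mass left at the horizon exceeds
#'   this bound (default 1e-6).
#' @return A `quit_time_distribution`: a tibble with columns `time` (s),
#'   `p_wait_step` (the per-epoch continue probability \eqn{P(wait|t_k)}),
#'   `p_quit` (quit mass at \eqn{t_k}) and `p_wait` (survival through
#'   \eqn{t_k}), plus attributes `p_wait_tail`, `p_reward`, `belief`,
#'   `policy`. Quit mass and tail sum to 1 within 1e-9 by construction.
#' @examples
#' d <- quit_time_distribution(0.75, timing_belief(3, 2), decision_policy())
#' quit_time_stats(d)
#' @export
quit_time_distribution <- function(p_reward, belief, policy = decision_policy(),
                                   tail_warn = 1e-6) {
  check_probability(p_reward, "p_reward")
  if (!is_timing_belief(belief)) abort("`belief` must be a timing_belief.")
  if (!inherits(policy, "decision_policy")) abort("`policy` must be a decision_policy.")
  k <- seq_len(policy$n_steps)
  t_k <- k * policy$tau
  post <- posterior_reward(p_reward, belief, t_k)
  p_wait_step <- wait_probability(post, policy)
  surv <- cumprod(p_wait_step)
  p_quit <- c(1, surv[-length(surv)]) * (1 - p_wait_step)
  tail <- surv[length(surv)]
  stopifnot(abs(sum(p_quit) + tail - 1) < 1e-9)
  if (tail > tail_warn) {
    warn(sprintf(
      "survival mass %.3g remains at the horizon (%g s); consider a longer horizon.",
      tail, policy$horizon))
  }
  out <- tibble::tibble(time = t_k, p_wait_step = p_wait_step,
                        p_quit = p_quit, p_wait = surv)
  attr(out, "p_wait_tail") <- tail
  attr(out, "p_reward") <- p_reward
  attr(out, "belief") <- belief
  attr(out, "policy") <- policy
  class(out) <- c("quit_time_distribution", class(out))
  out
}

#' Scalar summaries of a quit-time distribution
#'
#' @param dist A [quit_time_distribution()], or any data frame with columns
#'   `time` and `p_quit` (tail mass then taken from the `p_wait_tail`
#'   attribute, default 0).
#' @param probs Quantile levels to report (default quartiles).
#' @param tail_tol If the survival mass at the horizon exceeds this bound the
#'   mean is flagged as truncated (`truncated = TRUE` in the output).
#' @return A one-row tibble: `mean`, `median`, one column per requested
#'   quantile (`q25`, `q50`, ...), `p_wait_tail`, `truncated`. The mean is
#'   normalised by the total quit mass; the median (and quantiles) are the
#'   smallest grid times whose cumulative quit mass reaches the level.
#' @export
quit_time_stats <- function(dist, probs = c(0.25, 0.5, 0.75), tail_tol = 1e-6) {
  if (!is.data.frame(dist) || !all(c("time", "p_quit") %in% names(dist))) {
    abort("`dist` must have columns `time` and `p_quit`.")
  }
  tail <- attr(dist, "p_wait_tail") %||% 0
  mass <- sum(dist$p_quit)
  if (mass <= 0) abort("all-zero quit mass: no quit-time statistics exist.")
  cum <- cumsum(dist$p_quit)
  qs <- vapply(probs, function(q) dist$time[match(TRUE, cum >= q)], numeric(1))
  out <- tibble::tibble(
    mean = sum(dist$time * dist$p_quit) / mass,
    median = dist$time[match(TRUE, cum >= 0.5)]
  )
  for (i in seq_along(probs)) out[[sprintf("q%g", 100 * probs[i])]] <- qs[i]
  out$p_wait_tail <- tail
  out$truncated <- tail > tail_tol
  out
}

#' Serotonin-stimulation prior mapping
#'
#' The hypothesised effect of serotonin neuron activation is an
#' overestimation of the prior reward probability. Three mappings are
#' provided: `"polynomial"` (\eqn{p' = p + p^2 - p^3}), `"fixed_target"`
#' (\eqn{p' = \max(p, target)}, e.g. the 0.75 to 0.95 boost), and
#' `"identity"` (no stimulation effect).
#'
#' @param kind One of `"polynomial"`, `"fixed_target"`, `"identity"`.
#' @param target Target prior for `"fixed_target"` (probability).
#' @return A `stim_mapping` object.
#' @export
stim_mapping <- function(kind = c("polynomial", "fixed_target", "identity"),
                         target = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed_target") {
    if (is.null(target)) abort("`fixed_target` mapping requires a `target`.")
    check_probability(target, "target")
  }
  structure(list(kind = kind, target = target), class = "stim_mapping")
}

#' Apply a stimulation prior mapping
#'
#' @param p Prior reward probability/ies in \[0, 1\].
#' @param mapping A [stim_mapping()].
#' @return Mapped prior(s), in \[0, 1\].
#' @examples
#' stim_prior_map(0.75, stim_mapping("polynomial"))     # 0.890625
#' stim_prior_map(0.75, stim_mapping("fixed_target", 0.95))
#' @export
stim_prior_map <- function(p, mapping = stim_mapping("polynomial")) {
  if (!inherits(mapping, "stim_mapping")) abort("`mapping` must be a stim_mapping.")
  if (!all(is.finite(p)) || any(p < 0) || any(p > 1)) abort("`p` must lie in [0, 1].")
  switch(mapping$kind,
    polynomial   = p + p^2 - p^3,
    fixed_target = pmax(p, mapping$target),
    identity     = p
  )
}

#' Stimulation effect on mean quit time across prior or timing-uncertainty levels
#'
#' For each level, computes the quit-time distribution without and with the
#' stimulation prior boost and summarises the shift in mean quit time.
#' `vary = "prior"` sweeps the prior reward probability and boosts it through
#' `mapping`; `vary = "sigma"` sweeps the timing-uncertainty `sigma` at a
#' fixed pair of priors (`prior_pair`, default 0.75 without and 0.95 with
#' stimulation).
#'
#' @param levels Prior probabilities (`vary = "prior"`) or sigma values in
#'   seconds (`vary = "sigma"`).
#' @param belief Baseline [timing_belief()]; for `vary = "sigma"` it must be
#'   a single Gaussian whose `mu` is retained while `sigma` is swept.
#' @param policy A [decision_policy()].
#' @param mapping A [stim_mapping()] (used by `vary = "prior"`).
#' @param vary `"prior"` or `"sigma"`.
#' @param prior_pair Length-2 vector `c(no_stim, stim)` of priors used when
#'   `vary = "sigma"`.
#' @return A `stim_effect_curve` tibble: `level`, `mean_no_stim_s`,
#'   `mean_stim_s`, `shift_s`, `ratio`.
#' @examples
#' stim_effect_curve(c(0.25, 0.5, 0.75), timing_belief(3, 2))
#' @export
stim_effect_curve <- function(levels, belief = timing_belief(3, 2),
                              policy = decision_policy(),
                              mapping = stim_mapping("polynomial"),
                              vary = c("prior", "sigma"),
                              prior_pair = c(0.75, 0.95)) {
  vary <- match.arg(vary)
  if (length(levels) == 0) abort("`levels` must be nonempty.")
  rows <- purrr::map(levels, function(lev) {
    if (vary == "prior") {
      d0 <- quit_time_distribution(lev, belief, policy)
      d1 <- quit_time_distribution(stim_prior_map(lev, mapping), belief, policy)
    } else {
      if (nrow(belief) != 1L) abort("`vary = \"sigma\"` needs a single-Gaussian belief.")
      b <- timing_belief(belief$mu, lev)
      d0 <- quit_time_distribution(prior_pair[1], b, policy)
      d1 <- quit_time_distribution(prior_pair[2], b, policy)
    }
    m0 <- quit_time_stats(d0)$mean
    m1 <- quit_time_stats(d1)$mean
    tibble::tibble(level = lev, mean_no_stim_s = m0, mean_stim_s = m1,
                   shift_s = m1 - m0, ratio = m1 / m0)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stim_effect_curve", class(out))
  attr(out, "vary") <- vary
  out
}

# shared validation helper
check_probability <- function(p, name) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
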
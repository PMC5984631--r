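#' Specification of a model fit
#'
#' Declares which model parameters are free, their box bounds, and the fixed
#' values of the rest. Fittable parameters are `mu`, `sigma` (timing belief,
#' seconds), `beta` (inverse temperature) and the prior reward probabilities
#' `p_reward_yellow` / `p_reward_blue`. If `p_reward_blue` is neither free
#' nor fixed it is derived from `p_reward_yellow` through `mapping`
#' (identity by default, i.e. tied equal). `beta` defaults to fixed: at
#' high inverse temperature it is only weakly identified jointly with the
#' prior.
#'
#' @param free Character vector of free parameter names.
#' @param lower,upper Named numeric vectors overriding the default bounds
#'   (mu: \[0.5, 20\] s, sigma: \[0.2, 10\] s, beta: \[1, 200\],
#'   probabilities: \[0.001, 0.999\]).
#' @param fixed Named list overriding default fixed values
#'   (mu = 3, sigma = 2, beta = 50, p_reward_yellow = 0.75).
#' @param tau Decision interval, seconds (fixed during fitting).
#' @param horizon Modelling horizon, seconds (fixed during fitting).
#' @param mapping A [stim_mapping()] linking the blue-light prior to the
#'   yellow one when `p_reward_blue` is neither free nor fixed. Fitting data
#'   that contain stimulation trials with the mapping that generated them
#'   (e.g. `"polynomial"`) is what separates the prior from the timing
#'   belief: the two light conditions share (`mu`, `sigma`) but differ in
#'   prior by a known function.
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(free = c("mu", "sigma", "p_reward_yellow"),
                     lower = NULL, upper = NULL, fixed = NULL,
                     tau = 0.1, horizon = 60,
                     mapping = stim_mapping("identity")) {
  all_pars <- c("mu", "sigma", "beta", "p_reward_yellow", "p_reward_blue")
  if (length(free) < 1) abort("at least one parameter must be free.")
  if (!all(free %in% all_pars)) {
    abort(sprintf("unknown parameter(s): %s",
                  paste(setdiff(free, all_pars), collapse = ", ")))
  }
  lo <- c(mu = 0.5, sigma = 0.2, beta = 1, p_reward_yellow = 1e-3, p_reward_blue = 1e-3)
  hi <- c(mu = 20, sigma = 10, beta = 200, p_reward_yellow = 0.999, p_reward_blue = 0.999)
  lo[names(lower)] <- unlist(lower)
  hi[names(upper)] <- unlist(upper)
  if (any(!is.finite(lo[free])) || any(!is.finite(hi[free])) ||
      any(lo[free] >= hi[free])) {
    abort("bounds must be finite and ordered (lower < upper).")
  }
  fx <- list(mu = 3, sigma = 2, beta = 50, p_reward_yellow = 0.75)
  fx[names(fixed)] <- fixed
  fx <- fx[setdiff(names(fx), free)]
  probs <- intersect(c("p_reward_yellow", "p_reward_blue"), names(fx))
  for (p in probs) check_probability(fx[[p]], p)
  structure(
    list(free = free, lower = lo[free], upper = hi[free], fixed = fx,
         tau = tau, horizon = horizon, mapping = mapping),
    class = "fit_spec"
  )
}

# assemble full parameter set (free values + fixed) as a named list
full_params <- function(theta, spec) {
  pars <- as.list(spec$fixed)
  pars[spec$free] <- as.list(unname(theta))
  pars
}

# precompute per-light grid counts so the likelihood is a dot product
prepare_quit_counts <- function(log, spec) {
  k_max <- as.integer(round(spec$horizon / spec$tau))
  per_light <- function(lt) {
    sub <- log[log$light == lt, , drop = FALSE]
    quit <- sub$waiting_time_s[sub$outcome %in% c("omission_quit", "reward_wait_error")]
    cens <- sub$scheduled_delay_s[sub$outcome == "rewarded"]
    snap <- function(t) pmin(pmax(as.integer(round(t / spec$tau)), 1L), k_max)
    list(
      quit = if (length(quit)) tabulate(snap(quit), nbins = k_max) else integer(k_max),
      cens = if (length(cens)) tabulate(snap(cens), nbins = k_max) else integer(k_max)
    )
  }
  list(yellow = per_light("yellow"), blue = per_light("blue"), k_max = k_max)
}

nll_from_counts <- function(pars, counts, spec) {
  belief <- timing_belief(pars$mu, pars$sigma)
  policy <- decision_policy(beta = pars$beta, tau = spec$tau, horizon = spec$horizon)
  p_blue <- pars$p_reward_blue %||%
    stim_prior_map(pars$p_reward_yellow, spec$mapping %||% stim_mapping("identity"))
  total <- 0
  for (lt in c("yellow", "blue")) {
    cnt <- counts[[lt]]
    if (sum(cnt$quit) + sum(cnt$cens) == 0) next
    p <- if (lt == "yellow") pars$p_reward_yellow else p_blue
    d <- suppressWarnings(quit_time_distribution(p, belief, policy))
    iq <- cnt$quit > 0
    ic <- cnt$cens > 0
    total <- total - sum(cnt$quit[iq] * log(d$p_quit[iq])) -
      sum(cnt$cens[ic] * log(d$p_wait[ic]))
  }
  if (is.nan(total)) Inf else total
}

#' Negative log-likelihood of a trial log under the waiting model
#'
#' Each trial contributes one factor of the quit-time process: omission
#' quits and reward wait errors at waiting time `t` contribute
#' \eqn{-\log P_{quit}(\hat t)} with \eqn{\hat t} snapped to the nearest
#' grid point; rewarded trials are right-censored at the scheduled delay `d`
#' and contribute \eqn{-\log P_{wait}(d)}. Blue-light trials use the blue
#' prior (tied to the yellow prior unless supplied).
#'
#' @param params Named list or vector of parameter values (must cover the
#'   spec's free parameters; fixed values are taken from the spec).
#' @param log A trial-log tibble.
#' @param spec A [fit_spec()].
#' @return The negative log-likelihood; `Inf` (not an error) if any trial
#'   has zero model probability.
#' @export
quit_time_negloglik <- function(params, log, spec = fit_spec()) {
  if (nrow(log) == 0) abort("`log` is empty.")
  validate_trial_log(log)
  pars <- as.list(spec$fixed)
  pars[names(params)] <- as.list(unname(unlist(params)))
  missing <- setdiff(spec$free, names(pars))
  if (length(missing)) {
    abort(sprintf("missing value(s) for free parameter(s): %s",
                  paste(missing, collapse = ", ")))
  }
  nll_from_counts(pars, prepare_quit_counts(log, spec), spec)
}

#' Maximum-likelihood fit of the waiting model to a trial log
#'
#' Minimises [quit_time_negloglik()] over the spec's free parameters with
#' multi-start bounded optimisation (`L-BFGS-B`), starting points from a
#' seeded Latin hypercube over the bounds. After fitting, each free
#' parameter is perturbed to detect flat directions of the likelihood
#' (structural non-identifiability), which are reported in the result.
#'
#' @param log A trial-log tibble.
#' @param spec A [fit_spec()].
#' @param n_starts Number of Latin-hypercube starts (default 8).
#' @param maxit Iteration budget per start (default 200); `maxit = 0`
#'   returns the best starting point unoptimised.
#' @param nll_tol Convergence tolerance on the negative log-likelihood
#'   (default 1e-8).
#' @param seed Optional integer seed for the start design.
#' @return A `waiting_fit` object with elements `estimates` (named vector),
#'   `nll`, `convergence`, `flat` (names of flat parameters), `starts`
#'   (per-start tibble), `n_obs`, `spec`. Supports [tidy()] and [glance()].
#' @export
fit_model <- function(log, spec = fit_spec(), n_starts = 8, maxit = 200,
                      nll_tol = 1e-8, seed = NULL) {
  validate_trial_log(log)
  n_om <- sum(log$outcome != "rewarded")
  if (n_om < 100) {
    warn(sprintf("only %d non-censored (quit) trials; estimates may be unstable.", n_om))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  counts <- prepare_quit_counts(log, spec)
  d <- length(spec$free)
  big <- 1e10
  obj <- function(theta) {
    v <- nll_from_counts(full_params(theta, spec), counts, spec)
    if (!is.finite(v)) big else v
  }
  starts <- lhs::randomLHS(n_starts, d)
  starts <- sweep(sweep(starts, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  colnames(starts) <- spec$free

  runs <- purrr::map(seq_len(n_starts), function(i) {
    theta0 <- starts[i, ]
    if (maxit == 0) {
      return(list(par = theta0, value = obj(theta0), convergence = NA_integer_,
                  error = NA_character_))
    }
    res <- tryCatch(
      optim(theta0, obj, method = "L-BFGS-B", lower = spec$lower,
            upper = spec$upper,
            control = list(maxit = maxit, factr = nll_tol / .Machine$double.eps)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      list(par = theta0, value = NA_real_, convergence = 99L,
           error = "optimiser error")
    } else {
      list(par = res$par, value = res$value, convergence = res$convergence,
           error = NA_character_)
    }
  })
  start_tbl <- dplyr::bind_rows(purrr::map(runs, function(r) {
    tibble::tibble(nll = r$value, convergence = r$convergence, error = r$error)
  }))
  ok <- which(is.finite(start_tbl$nll))
  if (length(ok) == 0) {
    abort(paste0("all optimisation starts failed:\n",
                 paste(utils::capture.output(print(start_tbl)), collapse = "\n")))
  }
  best <- runs[[ok[which.min(start_tbl$nll[ok])]]]
  est <- setNames(as.numeric(best$par), spec$free)

  # flat-likelihood probe: a parameter whose perturbation leaves the NLL
  # unchanged is structurally non-identified on this data set
  flat <- character(0)
  for (p in spec$free) {
    step <- 0.01 * (spec$upper[p] - spec$lower[p])
    delta <- 0
    for (s in c(-step, step)) {
      th <- est
      th[p] <- min(max(th[p] + s, spec$lower[p]), spec$upper[p])
      delta <- max(delta, abs(obj(th) - best$value))
    }
    if (delta < 1e-6) flat <- c(flat, p)
  }
  if (length(flat)) {
    warn(sprintf("likelihood is flat in: %s (non-identifiable on this data).",
                 paste(flat, collapse = ", ")))
  }
  structure(
    list(estimates = est, nll = best$value, convergence = best$convergence,
         flat = flat, starts = start_tbl, n_obs = nrow(log), spec = spec),
    class = "waiting_fit"
  )
}

#' @export
print.waiting_fit <- function(x, ...) {
  cat("<waiting_fit> NLL =", format(x$nll, digits = 8),
      "| convergence =", x$convergence, "\n")
  print(round(x$estimates, 5))
  if (length(x$flat)) cat("flat (non-identified):", paste(x$flat, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.waiting_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = as.numeric(x$estimates),
    lower = as.numeric(x$spec$lower),
    upper = as.numeric(x$spec$upper),
    at_bound = x$estimates <= x$spec$lower + 1e-8 | x$estimates >= x$spec$upper - 1e-8,
    identifiable = !names(x$estimates) %in% x$flat
  )
}

#' @exportS3Method generics::glance
glance.waiting_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, convergence = x$convergence,
                 n_starts = nrow(x$starts), n_obs = x$n_obs,
                 n_flat = length(x$flat))
}

#' Parameter-recovery experiment
#'
#' Simulates trial logs from known parameters, refits the model to each, and
#' tabulates bias and root-mean-square error per free parameter. The
#' simulated task is a single Bernoulli-scheduled condition with the
#' stimulation prior boost applied on blue-light trials (polynomial mapping
#' by default, matching the fit spec) and without early withdrawals. The
#' stimulated trials are essential for identification: a single prior
#' condition leaves (`mu`, `sigma`, `p_reward`) on a curved likelihood
#' ridge, whereas two priors linked by a known mapping pin all three.
#'
#' @param true Named list of generating parameters: `mu`, `sigma`, `beta`,
#'   `p_reward`, and optionally `delay` (scheduled reward delay, default 3 s).
#' @param free Parameters to re-estimate (default `mu`, `sigma`,
#'   `p_reward_yellow`).
#' @param n_trials Trials per simulated log.
#' @param n_reps Number of simulate-fit replicates.
#' @param n_starts Starts per fit (default 8).
#' @param mapping A [stim_mapping()] used both to generate the blue-light
#'   trials and to tie the blue prior during fitting (default polynomial).
#' @param seed Optional integer seed; the whole experiment is a pure
#'   function of it.
#' @return A tibble with one row per parameter: `parameter`, `true`,
#'   `mean_estimate`, `bias`, `rmse`, `n_reps`, `n_trials`; the per-replicate
#'   estimates are attached as attribute `"estimates"`.
#' @export
parameter_recovery_experiment <- function(true = list(mu = 3, sigma = 2, beta = 50,
                                                      p_reward = 0.75),
                                          free = c("mu", "sigma", "p_reward_yellow"),
                                          n_trials = 2000, n_reps = 50,
                                          n_starts = 8,
                                          mapping = stim_mapping("polynomial"),
                                          seed = NULL) {
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  if (!is.null(seed)) withr::local_seed(seed)
  delay <- true$delay %||% 3
  cond <- task_condition("recovery", true$p_reward, delay_set = delay,
                         n_trials = n_trials, session_limit = Inf)
  agent <- agent_config(
    belief = timing_belief(true$mu, true$sigma),
    policy = decision_policy(beta = true$beta),
    mapping = mapping,
    early_withdrawal_rate = 0
  )
  spec <- fit_spec(free = free,
                   fixed = list(mu = true$mu, sigma = true$sigma, beta = true$beta,
                                p_reward_yellow = true$p_reward)[
                     setdiff(c("mu", "sigma", "beta", "p_reward_yellow"), free)],
                   mapping = mapping)
  truth <- c(mu = true$mu, sigma = true$sigma, beta = true$beta,
             p_reward_yellow = true$p_reward,
             p_reward_blue = stim_prior_map(true$p_reward, mapping))
  ests <- purrr::map(seq_len(n_reps), function(r) {
    sched <- build_schedule(cond)
    log <- simulate_trials(sched, agent, cond)
    log$mouse_id <- "m01"
    log$test_id <- sprintf("rec_t%03d", r)
    log$condition <- cond$name
    fit <- suppressWarnings(fit_model(log, spec, n_starts = n_starts))
    fit$estimates
  })
  est_mat <- do.call(rbind, ests)
  out <- tibble::tibble(
    parameter = free,
    true = as.numeric(truth[free]),
    mean_estimate = colMeans(est_mat),
    bias = colMeans(est_mat) - as.numeric(truth[free]),
    rmse = sqrt(colMeans(sweep(est_mat, 2, truth[free])^2)),
    n_reps = n_reps,
    n_trials = n_trials
  )
  attr(out, "estimates") <- tibble::as_tibble(est_mat)
  out
}
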
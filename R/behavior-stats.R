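#' Extract analysable omission trials
#'
#' Keeps omission-quit trials whose waiting time reaches `min_wait` seconds
#' and separates the rare quick withdrawals below it, which are excluded from
#' every waiting-time analysis. The boundary itself is kept ("within 1.5 s"
#' read as strictly below). Non-omission trials appear in neither output.
#'
#' @param log A trial-log tibble (see [simulate_cohort()]).
#' @param min_wait Exclusion threshold, seconds (default 1.5).
#' @param verbose Report kept/excluded counts as a message.
#' @return A list with tibbles `kept` and `excluded`.
#' @export
filter_omission_trials <- function(log, min_wait = 1.5, verbose = FALSE) {
  omission <- dplyr::filter(log, .data$outcome == "omission_quit")
  kept <- dplyr::filter(omission, .data$waiting_time_s >= min_wait)
  excluded <- dplyr::filter(omission, .data$waiting_time_s < min_wait)
  if (verbose) {
    message(sprintf("omission trials: %d kept, %d excluded (< %g s)",
                    nrow(kept), nrow(excluded), min_wait))
  }
  list(kept = kept, excluded = excluded)
}

#' Per-test waiting-time summaries by light condition
#'
#' Mean and s.e.m. of omission waiting times for every (mouse, test, light)
#' cell. Single-trial cells get `sem = 0` and a warning, since their spread
#' is unobservable.
#'
#' @param kept Tibble of retained omission trials
#'   (from [filter_omission_trials()]).
#' @return A tibble: `mouse_id`, `test_id`, `condition`, `light`, `n_trials`,
#'   `mean_wait_s`, `sem_s`.
#' @export
summarize_waiting <- function(kept) {
  if (nrow(kept) == 0) abort("no omission trials to summarise.")
  out <- kept |>
    dplyr::group_by(.data$mouse_id, .data$test_id, .data$condition, .data$light) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_wait_s = mean(.data$waiting_time_s),
      sem_s = ifelse(dplyr::n() > 1, sd(.data$waiting_time_s) / sqrt(dplyr::n()), 0),
      .groups = "drop"
    )
  if (any(out$n_trials == 1)) {
    warn(sprintf("%d degenerate single-trial cell(s): sem set to 0.",
                 sum(out$n_trials == 1)))
  }
  out
}

#' Per-test waiting-time ratios
#'
#' The waiting-time ratio of a test is its mean omission waiting time under
#' serotonin activation (blue light) divided by that without activation
#' (yellow light). Tests missing either light cell are dropped with a
#' warning; a zero yellow mean is an error.
#'
#' @param summary Output of [summarize_waiting()].
#' @return A tibble: `mouse_id`, `test_id`, `condition`, `n_blue`,
#'   `n_yellow`, `mean_blue_s`, `mean_yellow_s`, `ratio`.
#' @export
waiting_time_ratio <- function(summary) {
  wide <- summary |>
    tidyr::pivot_wider(
      id_cols = c("mouse_id", "test_id", "condition"),
      names_from = "light",
      values_from = c("n_trials", "mean_wait_s")
    )
  for (col in c("n_trials_blue", "n_trials_yellow", "mean_wait_s_blue",
                "mean_wait_s_yellow")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  incomplete <- is.na(wide$mean_wait_s_blue) | is.na(wide$mean_wait_s_yellow)
  if (any(incomplete)) {
    warn(sprintf("%d test(s) missing a light condition; dropped from ratios.",
                 sum(incomplete)))
    wide <- wide[!incomplete, , drop = FALSE]
  }
  if (any(wide$mean_wait_s_yellow == 0)) {
    abort("zero mean yellow waiting time: ratio undefined.")
  }
  tibble::tibble(
    mouse_id = wide$mouse_id, test_id = wide$test_id, condition = wide$condition,
    n_blue = wide$n_trials_blue, n_yellow = wide$n_trials_yellow,
    mean_blue_s = wide$mean_wait_s_blue, mean_yellow_s = wide$mean_wait_s_yellow,
    ratio = wide$mean_wait_s_blue / wide$mean_wait_s_yellow
  )
}

#' Scheirer-Ray-Hare rank test
#'
#' Nonparametric analogue of (one- or two-way) ANOVA: all observations are
#' rank-transformed (midranks for ties), the ANOVA sums of squares are
#' computed on the ranks (sequential, via [stats::aov()]), and each effect's
#' statistic \eqn{H = SS_{effect} / MS_{total}} with \eqn{MS_{total} =
#' SS_{total}/(N-1)} is referred to the chi-square distribution with the
#' effect's degrees of freedom. With a single factor the statistic equals the
#' tie-corrected Kruskal-Wallis H.
#'
#' @param data A data frame of observations.
#' @param formula `response ~ A + B` (main effects), `response ~ A * B`
#'   (with interaction) or `response ~ A` (single factor). Explanatory
#'   variables are treated as factors and must each have at least two
#'   observed levels.
#' @return An `srh_test` object; [tidy()] returns one row per term with
#'   columns `term`, `df`, `statistic`, `p.value`.
#' @examples
#' tb <- simulate_ratio_table(60, seed = 1)
#' scheirer_ray_hare(tb, ratio ~ rp + ep)
#' @export
scheirer_ray_hare <- function(data, formula) {
  vars <- all.vars(formula)
  if (length(vars) < 2 || length(vars) > 3) {
    abort("`formula` must be response ~ A, response ~ A + B or response ~ A * B.")
  }
  y <- data[[vars[1]]]
  if (is.null(y) || !is.numeric(y)) abort("the response must be a numeric column.")
  df <- data.frame(.rank = rank(y))
  for (v in vars[-1]) {
    f <- factor(data[[v]])
    if (nlevels(droplevels(f)) < 2) {
      abort(sprintf("factor `%s` must have at least 2 observed levels.", v))
    }
    df[[v]] <- droplevels(f)
  }
  rhs <- deparse(formula[[3]])
  fit <- aov(as.formula(paste(".rank ~", rhs)), data = df)
  tab <- suppressWarnings(anova(fit))  # constant ranks trip the perfect-fit warning
  terms <- setdiff(rownames(tab), "Residuals")
  ms_total <- sum((df$.rank - mean(df$.rank))^2) / (nrow(df) - 1)
  # constant responses carry no rank information: every H is 0 by convention
  h <- if (ms_total < 1e-12) rep(0, length(terms)) else tab[terms, "Sum Sq"] / ms_total
  out <- tibble::tibble(
    term = terms,
    df = tab[terms, "Df"],
    statistic = h,
    p.value = pchisq(h, tab[terms, "Df"], lower.tail = FALSE)
  )
  structure(list(table = out, ms_total = ms_total, n = nrow(df),
                 formula = formula),
            class = "srh_test")
}

#' @export
print.srh_test <- function(x, ...) {
  cat("Scheirer-Ray-Hare rank test (", deparse(x$formula), ", N = ", x$n, ")\n",
      sep = "")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.srh_test <- function(x, ...) x$table

#' Bonferroni adjustment by an explicit comparison count
#'
#' Multiplies each p-value by `m` and caps at 1, as when `m` pairwise tests
#' are performed and significance requires `p * m < 0.05`.
#'
#' @param pvals Numeric vector of p-values.
#' @param m Number of comparisons in the family; must be at least
#'   `length(pvals)`.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (m < 1) abort("`m` must be >= 1.")
  if (m < length(pvals)) abort("`m` must be at least the number of comparisons performed.")
  pmin(1, pvals * m)
}

#' Standard two-group and k-group tests
#'
#' Thin wrapper over the standard routines used in the behavioural analysis:
#' Mann-Whitney U ([stats::wilcox.test()]), paired t ([stats::t.test()]) and
#' Kruskal-Wallis ([stats::kruskal.test()]); all two-sided. Degenerate
#' constant inputs (identical paired vectors, identical groups) return a
#' zero statistic with p = 1 rather than an error.
#'
#' @param a First sample; for `kind = "kruskal_wallis"`, a list of samples.
#' @param b Second sample (ignored for Kruskal-Wallis).
#' @param kind `"mann_whitney"`, `"paired_t"` or `"kruskal_wallis"`.
#' @return A one-row tibble: `statistic`, `p.value`, `method`.
#' @export
group_tests <- function(a, b = NULL,
                        kind = c("mann_whitney", "paired_t", "kruskal_wallis")) {
  kind <- match.arg(kind)
  res <- switch(kind,
    mann_whitney = {
      if (length(a) < 1 || length(b) < 1) abort("both samples must be nonempty.")
      ht <- stats::wilcox.test(a, b)
      list(ht$statistic, ht$p.value, "Mann-Whitney U")
    },
    paired_t = {
      if (length(a) != length(b)) abort("paired t requires equal lengths.")
      if (length(a) < 2) abort("paired t requires n >= 2.")
      d <- a - b
      if (all(d == 0)) list(0, 1, "paired t") else {
        ht <- stats::t.test(a, b, paired = TRUE)
        list(ht$statistic, ht$p.value, "paired t")
      }
    },
    kruskal_wallis = {
      if (!is.list(a) || length(a) < 2) abort("Kruskal-Wallis needs a list of >= 2 samples.")
      if (length(unique(unlist(a))) == 1) list(0, 1, "Kruskal-Wallis") else {
        ht <- stats::kruskal.test(a)
        list(ht$statistic, ht$p.value, "Kruskal-Wallis")
      }
    })
  tibble::tibble(statistic = as.numeric(res[[1]]), p.value = as.numeric(res[[2]]),
                 method = res[[3]])
}

# ML log-likelihood of a gaussian linear model refitted to response y,
# given the QR decomposition of its design matrix.
lm_loglik_ml <- function(qr_x, y) {
  n <- length(y)
  rss <- sum(qr.resid(qr_x, y)^2)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

#' Parametric-bootstrap likelihood-ratio test for a mouse variance component
#'
#' Tests whether the variance of the mouse random intercept is zero. Because
#' the null value sits on the boundary of the parameter space, the
#' chi-square reference for the likelihood-ratio statistic is invalid; the
#' null distribution is instead built by a parametric bootstrap: simulate
#' responses from the fitted fixed-effects-only model, refit both models to
#' each bootstrap sample and compare the observed statistic with the
#' bootstrap statistics.
#'
#' Both models are fitted by maximum likelihood (the mixed model with
#' [lme4::lmer()], REML off; the null with [stats::lm()]); bootstrap refits
#' reuse the mixed-model structure via [lme4::refit()]. The reported p-value
#' uses add-one smoothing, `(1 + #\{LRT* >= LRT\}) / (n_boot + 1)`.
#'
#' @param data A ratio table: one row per test with the response, the fixed
#'   factors and a mouse identifier (e.g. from [simulate_ratio_table()] or
#'   [waiting_time_ratio()] joined with condition levels).
#' @param fixed Fixed-effects formula, e.g. `ratio ~ rp + ep`.
#' @param group Name of the grouping (mouse) column; default `"mouse_id"`.
#' @param n_boot Number of bootstrap samples (default 1000; must be >= 1).
#' @param max_fail_frac Abort if more than this fraction of bootstrap refits
#'   fails to converge (default 0.05).
#' @param seed Optional integer seed.
#' @return A `boot_lrt` object; [tidy()] gives `statistic`, `p.value`,
#'   `n_boot`; [glance()] adds the variance estimates and failure count.
#' @export
bootstrap_lrt_random_effect <- function(data, fixed, group = "mouse_id",
                                        n_boot = 1000, max_fail_frac = 0.05,
                                        seed = NULL) {
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  if (!group %in% names(data)) abort(sprintf("grouping column `%s` not found.", group))
  if (dplyr::n_distinct(data[[group]]) < 2) abort("need >= 2 mice.")
  if (!is.null(seed)) withr::local_seed(seed)
  data <- as.data.frame(data)
  data[[group]] <- factor(data[[group]])

  alt_formula <- as.formula(paste(deparse(fixed[[2]]), "~", deparse(fixed[[3]]),
                                  "+ (1 |", group, ")"))
  alt <- suppressMessages(lme4::lmer(alt_formula, data = data, REML = FALSE))
  null <- lm(fixed, data = data)
  obs <- max(0, 2 * (as.numeric(logLik(alt)) - as.numeric(logLik(null))))

  qr_x <- null$qr
  mu_hat <- fitted(null)
  sigma_hat <- sqrt(sum(residuals(null)^2) / null$df.residual)
  n <- nrow(data)

  boot <- numeric(n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    y_star <- mu_hat + rnorm(n, 0, sigma_hat)
    ll_null <- lm_loglik_ml(qr_x, y_star)
    fit_b <- tryCatch(
      suppressWarnings(suppressMessages(lme4::refit(alt, y_star))),
      error = function(e) NULL
    )
    if (is.null(fit_b)) {
      failed <- failed + 1L
      boot[b] <- NA_real_
    } else {
      boot[b] <- max(0, 2 * (as.numeric(logLik(fit_b)) - ll_null))
    }
  }
  if (failed / n_boot > max_fail_frac) {
    abort(sprintf("bootstrap refit failed in %d of %d samples (> %g%%).",
                  failed, n_boot, 100 * max_fail_frac))
  }
  boot_ok <- boot[!is.na(boot)]
  p <- (1 + sum(boot_ok >= obs)) / (length(boot_ok) + 1)
  structure(
    list(statistic = obs, p.value = p, n_boot = length(boot_ok), failed = failed,
         boot_stats = boot_ok, alt = alt, null = null),
    class = "boot_lrt"
  )
}

#' @export
print.boot_lrt <- function(x, ...) {
  cat(sprintf(
    "Parametric-bootstrap LRT for the mouse variance component\n  LRT = %.4g, p = %.4g (%d bootstrap samples, %d failed)\n",
    x$statistic, x$p.value, x$n_boot, x$failed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.boot_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value, n_boot = x$n_boot)
}

#' @exportS3Method generics::glance
glance.boot_lrt <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$alt))
  tibble::tibble(
    statistic = x$statistic, p.value = x$p.value, n_boot = x$n_boot,
    n_failed = x$failed,
    mouse_sd = vc$sdcor[1], residual_sd = vc$sdcor[nrow(vc)]
  )
}
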
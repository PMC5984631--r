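# waitbayes

Tools for modelling *patience*: how long an agent keeps waiting for a
delayed, probabilistic reward before giving up, and how serotonin neuron
activation changes that.

In the sequential tone-food waiting task, a mouse nose-pokes at a reward
site and food arrives after a delay on a fraction *p* of trials; on
omission trials the animal's waiting time until it quits is the
measurement. Optogenetic activation of dorsal raphe serotonin neurons
lengthens waiting at high reward probability and under uncertain reward
timing. `waitbayes` implements the Bayesian account of this behaviour and
everything needed to study it at the desk:

* **Decision model** — a Bayesian agent with a Gaussian (or mixture) belief
  $N(t; \mu, \sigma^2)$ about reward timing. Having seen no reward by time
  $t$, the posterior of a reward trial is
  $P(\mathrm{reward}\mid t) = p(1-f(t)) / [p(1-f(t)) + (1-p)]$, a softmax
  with inverse temperature $\beta$ converts it into a wait-or-quit choice
  every $\tau$ seconds, and the recursion
  $P_{wait}(t) = P_{wait}(t-\tau)P(\mathrm{wait}\mid t)$ yields the full
  quit-time distribution. Serotonin activation is modelled as a prior boost
  $p \mapsto p + p^2 - p^3$ (or a fixed target such as 0.75 → 0.95).
* **Task simulator** — trial logs for the tone-food task (Bernoulli or
  8-trial block schedules, multi-pellet conditions, variable delays, rare
  early withdrawals, per-mouse cohorts), the synthetic stand-in for the
  unavailable raw animal data.
* **Behavioural statistics** — omission-trial extraction with the 1.5 s
  exclusion rule, per-test waiting-time ratios, the Scheirer–Ray–Hare rank
  test, Bonferroni-corrected pairwise tests, and a parametric-bootstrap
  likelihood-ratio test for the mouse-level variance component.
* **Inference** — maximum-likelihood fitting of $(\mu, \sigma, p)$ to
  censored quit-time data with multi-start bounded optimisation and
  parameter-recovery diagnostics.

Everything is data-frame-first and pipe-friendly; fitted objects support
`tidy()`/`glance()`, and result types have `autoplot()` methods.

## A worked example

The model's headline prediction — the stimulation effect on waiting is
largest at high reward probability:

```r
library(waitbayes)

stim_effect_curve(c(0.25, 0.50, 0.75),
                  belief = timing_belief(mu = 3, sigma = 2),
                  policy = decision_policy(beta = 50, tau = 0.1))
#> # A tibble: 3 × 5
#>   level mean_no_stim_s mean_stim_s shift_s ratio
#>   <dbl>          <dbl>       <dbl>   <dbl> <dbl>
#> 1  0.25           5.27        5.60   0.332  1.06
#> 2  0.5            6.59        7.08   0.490  1.07
#> 3  0.75           7.58        8.35   0.762  1.10
```

The `shift_s` column is the increase in mean quit time caused by the prior
boost $p' = p + p^2 - p^3$: about 0.76 s at $p = 0.75$, more than double
the shift at $p = 0.25$ — patience is promoted most where reward confidence
is already high.

A miniature end-to-end analysis on simulated data:

```r
cond  <- task_condition("75pct-1pellet", reward_probability = 0.75)
log   <- simulate_cohort(cond, agent_config(), n_mice = 6,
                         tests_per_mouse = 20, seed = 1)
kept  <- filter_omission_trials(log)$kept        # drops waits < 1.5 s
ratio <- waiting_time_ratio(summarize_waiting(kept))
#> Warning messages:
#> 1: 4 degenerate single-trial cell(s): sem set to 0.
#> 2: 2 test(s) missing a light condition; dropped from ratios.
mean(ratio$ratio)
#> [1] 1.107301
```

(The warnings are the pipeline flagging sparse cells: with ~10 omission
trials per 40-trial test, some tests have a one-trial light cell, and an
occasional test lacks one light entirely and is dropped from the ratios.)

Each test's waiting-time ratio divides its mean omission waiting time on
blue-light (activation) trials by that on yellow-light trials; a mean
around 1.10 says activation lengthened waiting by ~10% in this condition.

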
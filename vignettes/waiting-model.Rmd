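---
title: "A Bayesian decision model of waiting, its simulator, and the behavioural statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian decision model of waiting, its simulator, and the behavioural statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(waitbayes)
library(dplyr)
```

## The decision problem

An animal nose-pokes at a reward site and must decide, moment by moment,
whether to keep waiting for a delayed food reward or to give up. Rewards
arrive only on a fraction *p* of trials (the reward probability), and when
they arrive, their timing is variable. In optogenetic experiments, dorsal
raphe serotonin neurons can be stimulated during the delay, and their
activation prolongs waiting — but only under some conditions. This package
implements a normative account of that behaviour: a Bayesian agent that
tracks the posterior probability that the current trial will be rewarded and
quits when that posterior no longer justifies waiting, together with the
hypothesis that serotonin acts by inflating the agent's *prior* reward
probability.

## The model

Each trial has a hidden state, reward or no-reward. The agent holds a belief
about reward timing on reward trials — by default a Gaussian
$N(t;\mu,\sigma^2)$; `timing_belief()` also accepts mixtures so that
discrete delay schedules (e.g. delays drawn from $\{2, 6, 10\}$ s) can be
represented exactly or through a moment-matched single component. Having
waited to time $t$ without reward, the likelihood of a reward trial is the
survival function $1 - f(t;\mu,\sigma^2)$ (cumulative belief $f$), while a
no-reward trial has likelihood 1. Bayes' rule gives

$$P(\mathrm{reward}\mid t) =
  \frac{p\,(1 - f(t))}{p\,(1 - f(t)) + (1 - p)}.$$

The value of waiting is the posterior itself (a unit reward is at stake;
`reward_magnitude` scales it for multi-pellet sessions), the value of
quitting is zero, and a softmax with inverse temperature $\beta$ turns the
value into a choice at every decision epoch $t_k = k\tau$:

$$P(\mathrm{wait}\mid t) = \frac{1}{1 + e^{-\beta\,r\,P(\mathrm{reward}\mid t)}}.$$

The distribution of quitting times then follows the recursion
$P_{wait}(0) = 1$, $P_{wait}(t) = P_{wait}(t-\tau)\,P(wait\mid t)$,
$P_{quit}(t) = P_{wait}(t-\tau)\,(1 - P(wait\mid t))$, implemented in
`quit_time_distribution()`. Serotonin stimulation is modelled as a prior
boost, `stim_mapping()`: the polynomial $p' = p + p^2 - p^3$, a fixed target
$\max(p, 0.95)$, or the identity (no effect).

```{r headline}
curve <- stim_effect_curve(c(0.25, 0.50, 0.75), timing_belief(3, 2))
curve
```

The shift in mean quit time is largest at $p = 0.75$: a prior boost matters
most when the prior is already high, because the posterior then stays near
the softmax's sensitive range for longer. Sweeping the timing uncertainty
instead (`vary = "sigma"`) shows the boost's effect growing with $\sigma$:
a wider belief has a longer survival tail, so the same prior increase holds
the posterior up for longer.

## Parameters, units and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `mu`, `sigma` | timing belief, seconds | 3, 2 | the worked example's values |
| `beta` | softmax inverse temperature | 50 | near-deterministic quitting once the posterior decays |
| `tau` | decision interval, s | 0.1 | fine enough that the grid does not shape the distribution |
| `horizon` | modelled waiting limit, s | 60 | at `beta = 50` the residual survival mass is far below 1e-6 in every condition used here; a warning reports any violation |
| `reward_magnitude` | pellets at stake | 1 | the unit-reward model; >1 scales the softmax argument only |

Decisions are evaluated *at* each epoch $t_k$ (the literal reading of the
recursion); probabilities are computed in linear space with the
complementary Gaussian cdf to avoid cancellation at large $t$, and every
distribution is checked to conserve mass to 1e-9.

## What the synthetic cohort emulates

`simulate_cohort()` stands in for the raw animal data, which are not
deposited. It reproduces the task's statistical structure:

* **Conditions.** Reward probability $\in \{0.25, 0.50, 0.75\}$, pellet
  count $\in \{1, 2, 3\}$, delays fixed (3, 6, 10 s) or drawn from
  $\{4,6,8\}$ or $\{2,6,10\}$ s; 40 trials per test; a 3000 s session limit
  enforced by truncation.
* **Scheduling.** Experiment-1 style tests draw the reward state per trial
  (Bernoulli) with blue light on a random half of trials; experiment-2
  style tests use the 8-trial block (three rewarded + one omission trial
  per light condition, order randomised within block, five blocks).
* **Agents.** The baseline prior equals the programmed reward probability
  (perfect calibration — the animals' subjective prior is unobservable, and
  this is the neutral choice); blue-light trials pass the prior through the
  stimulation mapping. Waiting times are draws from the model's quit-time
  distribution; rewarded trials end at the scheduled delay (the quit time is
  censored), earlier quits on reward trials are reward wait errors.
* **Contaminants.** Rare early withdrawals (rate 0.005, uniform below
  1.5 s) exercise the analysis exclusion rule, mirroring the handful of
  sub-1.5 s omission trials the experiments report.
* **Heterogeneity.** Per-mouse log-normal jitter on `beta` and `sigma` is
  available but defaults to off, consistent with the finding that
  between-mouse variability of the waiting-time ratio is not significant.

What it does **not** emulate: nose-poke mechanics and the 500 ms grace
period (absorbed into the quit event), tone-delay waiting, inter-trial
intervals, food consumption, session-to-session learning, or any departure
of real mice from the model itself. Passing tests therefore show that the
pipeline recovers the patterns *the model generates*, not that mice obey
the model.

For fixed-delay schedules the moment-matched belief would have
$\sigma = 0$; `moment_matched_belief()` adds a baseline internal timing
noise (default 2 s, the example belief's own $\sigma$) in quadrature, since
interval timing is never noiseless. The ordering of simulated
uncertainty-condition effects (D2-6-10 > D4-6-8 > D6) is preserved for any
common baseline noise.

## The behavioural analysis pipeline

Omission trials are the measurement: `filter_omission_trials()` drops
waiting times below 1.5 s (the boundary itself is kept; the threshold is
configurable), `summarize_waiting()` gives per-test means with standard
errors, and `waiting_time_ratio()` forms each test's ratio of blue-light to
yellow-light mean waiting. Ratios are per test and then averaged — the
convention that matches reported per-test counts — rather than a ratio of
grand means; the two differ slightly (e.g. 7.89/6.95 = 1.1353 as a ratio of
population means).

`scheirer_ray_hare()` implements the rank-transform factorial test:
midranks, ANOVA sums of squares on the ranks (sequential, via `aov()`),
$H = SS_{effect}/MS_{total}$ referred to $\chi^2$ with the effect's degrees
of freedom. With one factor it reduces to the tie-corrected Kruskal–Wallis
statistic, which is one of the test suite's cross-checks; no tie correction
beyond midranks is applied. `bonferroni_adjust()` multiplies by an explicit
family size *m*. Plain two-group tests delegate to `wilcox.test()`,
`t.test()` and `kruskal.test()`.

`bootstrap_lrt_random_effect()` tests whether the mouse-level variance
component is zero. The null value lies on the boundary of the parameter
space, so the usual $\chi^2$ reference is invalid; instead responses are
simulated from the fitted fixed-effects-only model, both models are refitted
to every bootstrap sample (maximum likelihood; `lme4::refit()` reuses the
mixed-model structure for speed), and the p-value is the smoothed exceedance
fraction $(1 + \#\{LRT^* \ge LRT\})/(n_{boot}+1)$. Singular fits under the
null are expected and benign (they contribute $LRT^* \approx 0$); refits
that error out are counted, and more than 5% of failures aborts the test.

## Fitting the model to data

`fit_model()` maximises the censored quit-time likelihood: omission quits
and reward wait errors at $t$ contribute $\log P_{quit}(\hat t)$ with
$\hat t$ snapped to the $\tau$-grid (the model lives on the grid, and
simulated data do too), rewarded trials contribute the censoring term
$\log P_{wait}(d)$ at the scheduled delay. Optimisation is multi-start
L-BFGS-B (8 Latin-hypercube starts over the bounds, NLL tolerance 1e-8),
and a post-fit perturbation probe flags parameters in which the likelihood
is flat.

One design point deserves emphasis. From a *single* prior condition, the
triple ($\mu$, $\sigma$, $p$) at $\beta = 50$ is only weakly identified:
quitting happens in a narrow time window, and a curved ridge of parameter
combinations produces nearly the same quit-time law, so the maximum
likelihood estimate can sit far from the generating values even at 2000
trials. Data that include stimulation trials break this degeneracy — the
two light conditions share ($\mu$, $\sigma$) while their priors are linked
by the known mapping — so `fit_spec()` carries a `mapping` that derives the
blue prior from the yellow one (identity, i.e. tied equal, by default), and
`parameter_recovery_experiment()` simulates the stimulated task. $\beta$
stays fixed during fitting by default for the same reason: it trades off
against the prior almost perfectly at high values.

```{r recovery, eval = FALSE}
parameter_recovery_experiment(
  true = list(mu = 3, sigma = 2, beta = 50, p_reward = 0.75),
  n_trials = 2000, n_reps = 50, seed = 1
)
```

## Numerical and design choices

* **Degenerate inputs.** A prior of 0 (or $\beta = 0$) gives the exact
  geometric law with per-step continue probability 1/2 and mean quit time
  $2\tau$ — a closed-form anchor used throughout the tests. Constant
  responses give $H = 0$, $p = 1$ in the rank test; identical paired
  vectors give $t = 0$, $p = 1$ rather than an error.
* **Problem sizes.** The test suite checks the recursion against a
  $10^5$-trial step-by-step Monte-Carlo agent at five parameter settings
  (total variation < 0.01), runs the rank test's size study at 2000
  replicates of 60 tests, the bootstrap calibration and power studies at
  100 repetitions each with 199 bootstrap samples over 200-test tables, and
  parameter recovery at 50 replicates of 2000 trials. These sizes make the
  Monte-Carlo error small relative to every asserted margin.
* **Cohort scale.** The end-to-end pattern check simulates 6 mice with 20
  tests per condition — the order of the reported per-condition test counts.

## Known limitations

* The model's absolute quit times are not calibrated to any animal's
  absolute waiting times; only qualitative patterns (orderings, shifts)
  are meaningful.
* The prior-boost model predicts a small positive ratio effect at low
  reward probabilities (about 6% at $p = 0.25$ under the polynomial
  mapping), where the animal data show a null; the model reproduces where
  the effect is *largest*, not its exact null structure.
* The Gaussian belief is an idealisation for multi-modal delay schedules;
  mixtures are supported but the analyses here use moment-matched
  Gaussians.
* No hierarchical (per-mouse) fitting and no posterior inference over
  parameters; the fitting module is maximum likelihood only.
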
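---
title: "Models and methods behind motorcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motorcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorcomp)
library(dplyr)
```

motorcomp simulates and analyses a competitive reaching game in which a
player chooses where to aim under an asymmetric reward: the closer the reach
endpoint lands to a boundary line (30 cm from the start), the more points it
earns — up to 100 at the line — but any endpoint beyond the line, or within a
7 cm dead zone, earns nothing. Because motor noise makes the endpoint
stochastic, choosing an aim point is a risk/reward decision, and the game
behaves like a continuous "chicken game" when two players compete for the
higher 10-trial block total.

This vignette explains the model, the synthetic-data generator, the analysis
pipeline, and the numerical and design choices, in that order.

## The expected-gain model

A reach aimed at $E$ lands at $e \sim N(E, \sigma^2)$, where $\sigma$ is the
player's motor SD (assumed constant across aim points). With gain function
$G(e)$, the expected gain of an aim point is

$$\mathrm{EG}(E) = \int G(e)\, N(e; E, \sigma^2)\, de,$$

and the risk-neutral optimal aim point is $E^*(\sigma) = \arg\max_E
\mathrm{EG}(E)$. A player aiming above $E^*$ is *risk-seeking* (chasing large
one-trial scores at a higher chance of overshooting), below it
*risk-averse*. **Risk-sensitivity** is the observed mean endpoint minus
$E^*(\hat\sigma)$, with $\hat\sigma$ the observed endpoint SD in the same
trial window.

The exact shape of the published gain curve is not recoverable from the
task description, so the package defaults to a linear ramp — $G(e) =
100\,(e-7)/23$ on $(7, 30]$, zero elsewhere — and accepts any tabulated
piecewise-linear alternative through `gain_function(shape = "tabulated")`,
so conclusions can be checked for robustness against the assumed curvature.

Because $G$ is piecewise linear and zero outside $(\mathrm{dead\ zone},
\mathrm{boundary}]$, $\mathrm{EG}$ reduces to Gaussian partial moments over
each linear segment and is evaluated in closed form — exact to machine
precision, with no quadrature tolerance to tune. The test suite nevertheless
cross-checks it against a dense trapezoid quadrature at $10^{-4}$ points.
`optimal_aim()` maximises $\mathrm{EG}$ by bounded scalar search restarted
over three sub-brackets (the expected gain is flat near zero aim, so a
single bracket can stall), breaking ties towards the larger aim. Because the
simulator queries $E^*$ tens of thousands of times, common noise levels
($\sigma \in [0.05, 5]$ cm) are served from a per-gain-function monotone
spline accurate to about $5\times10^{-7}$ cm; the tests validate the served
values against an exhaustive grid search.

```{r gain-curves}
optimal_aim(c(0.5, 1.5, 3))
```

Less noise moves the optimum towards the boundary; for typical human
variability (1–2 cm) the optimum sits 2–3 cm short of it.

## The virtual opponent

The opponent is defined entirely by a risk coefficient $\alpha$ and the
player's own variability: its endpoints are drawn from
$N(\alpha E^*(\hat\sigma), \hat\sigma^2)$, where $\hat\sigma$ is the sample
SD of the player's last 40 reaches, re-estimated before each competitive
block (or frozen at the baseline estimate in the `exp4` protocol). With
$\alpha = 1$ the opponent is an optimal risk-neutral player of matched
accuracy; $\alpha < 1$ makes it risk-averse. The preset schedules follow the
five study protocols (`opponent_schedule()`); the risk-averse schedule holds
$\alpha = 1$ for blocks 1–4 and then declines to 0.925. The source protocol
states the decline verbally as "steps of 0.15", which is arithmetically
inconsistent with the stated endpoint of 0.925 starting from 1; the package
interpolates linearly (steps of 0.015), the only reading consistent with
both printed endpoints, and the schedule is user-overridable.

## The synthetic subject

No human data ships with the package; a generative subject model
(`subject_model()`) reproduces the statistical structure the analysis is
designed to detect, and is explicitly a synthetic stand-in rather than a
cognitive theory. Its components, with defaults and sources:

* **Baseline bias** `baseline_bias = 1.0` cm, drawn per subject with
  between-subject SD `baseline_bias_sd = 0.65` cm. Risk-seeking baselines of
  roughly 0.7–1.2 cm, with a printed between-subject SD of 0.65 cm, are the
  study's reported values; 1.0 cm is the midpoint of the group means.
* **Motor noise** `sigma0 = 1.5` cm, shrinking by `sigma_decay = 0.98` per
  block of practice (floor 0.5 cm). With this decay the SD falls to about
  0.72x over a 22-block session, matching the study's reported practice
  effect (0.73x), and it makes the risk-neutral opponent's aim climb across
  blocks, as described for the live task. At $\sigma_0 = 1.5$ the baseline
  aim $E^* + b \approx 28.1$ cm reproduces the reported ~27.9 cm baselines.
* **First-block inhibition** `inhibition = 1.0` cm decaying linearly to zero
  over `inhibition_decay_trials = 5` trials: the transient endpoint decrease
  (reported 0.7–1.2 cm over the first five competitive trials) at
  competition onset.
* **Two-slope opponent response** `slope_neg = 0.21`, `slope_pos = 0.63`
  (the study's estimated regression slopes): within each competitive block
  the subject shifts its aim by `slope(x) * x`, where `x` is the opponent's
  *realised* block-mean endpoint minus the subject's own *measured* baseline
  mean. The realised-endpoint convention matters: the player only ever
  observes actual reaches, and it makes the generative covariate identical
  to the regressor the analysis later computes, so slope recovery is
  unbiased. (Driving the response off the hidden programmed aim instead
  attenuates the measured right-half slope by roughly a third through
  errors-in-variables — a useful reminder of what the block-mean regression
  can and cannot estimate on real data.)
* **Aim jitter** `response_noise = 0.3` cm of block-to-block aim wobble,
  chosen so that the scatter of block means around the two-slope line
  roughly matches the published relative-aim scatter once the unavoidable
  10-trial sampling noise ($\sigma/\sqrt{10} \approx 0.47$ cm) is added.

What the generator does *not* emulate: trial-level learning within a block,
reaction times and timeouts, win-stay/lose-shift trial dynamics, and any
coupling from block outcomes back to strategy. Passing recovery tests
therefore show that the pipeline measures what the generator encodes — not
that humans follow this generative rule.

```{r cohort}
run <- run_experiment("exp1b", n_subjects = 8, seed = 1)
cohort_risk_sensitivity(run$trials, "baseline") |>
  summarise(mean_rs = mean(risk_sensitivity))
```

## The session simulator

`run_experiment()` walks the protocol's sessions block by block: individual
blocks are 10 scored reaches; competitive blocks alternate subject and
opponent reaches strictly (subject first) and record both 10-trial totals
and the winner, with ties kept as ties (the live task defines no tie rule,
so none is invented). The observation protocol shows the opponent without
competing (the subject model ignores it, matching the study's null result);
the threshold protocol replaces the opponent with a target total equal to
the opponent's expected block score, `10 * EG(alpha * E*, sigma)`, rounded
to the nearest integer point since displayed scores were integers. Blocks
and trials are 1-based throughout. Endpoints are logged at 4-decimal (0.1
micrometre) precision, which is what makes CSV round-trips bit-exact.

Each subject runs on a deterministic child seed derived from the root seed,
so enlarging a cohort never changes existing subjects and equal seeds give
byte-identical tables.

## The analysis pipeline

`compute_aim_points()` produces the three aim-point indices: $A_i$ (mean
endpoint of the 50 baseline trials; a "last 50 individual-task trials before
competition" variant is selectable for the practice/presentation designs),
and per competitive block $A_c$ (subject) and $A_o$ (opponent).
`relative_aims()` maps them to the scatter of $y = A_c - A_i$ against
$x = A_o - A_i$, dropping block 1 by default because the inhibition
transient contaminates it.

`split_slopes()` fits OLS lines separately left and right of $x = 0$ — the
point where the opponent aims exactly at the subject's own individual-task
aim, which is where the two halves of the published scatter are divided;
the split is configurable. `bootstrap_permutation_slopes()` resamples the
pooled points with replacement (50,000 times by default), refits both
slopes per resample, and reports percentile CIs plus a permutation-style
p-value: the fraction of resamples in which the left slope is at least as
large as the right slope. "At least" (rather than strictly larger) is the
conservative tie reading and is switchable; ties at numerical precision
count as ties. Resamples leaving fewer than three points on a side are
redrawn and counted. Whether resampling should respect subject clustering
is genuinely open; free resampling is the default because the pooled points
are what the published analysis intermingled, and the alternative can be
had by resampling subjects upstream.

`fit_linear_quadratic()` compares $y = \beta_0 x + \beta_1$ against
$y = \beta_0 x + \beta_1 x^2 + \beta_2$ with AIC, BIC and AICc computed from
the full Gaussian log-likelihood (constants included, so magnitudes are
comparable with other software; only differences matter for selection) and
$k$ counting coefficients plus the residual variance.

`paired_cohens_d()` implements
$d = (m_1 - m_2)/\sqrt{s_1^2 + s_2^2 - 2 r s_1 s_2}$, and
`required_sample_size()` inverts the exact noncentral-$t$ power of a
matched-pairs test by scanning $n$ upward:

```{r power}
d <- paired_cohens_d(1.15, 0.65, -0.01, 0.70, 0.38)
round(d, 2)
required_sample_size(round(d, 2), alpha = 0.05, power = 0.80)
```

No multiple-testing correction is applied anywhere, matching the per-test
reporting style of the source analyses.

## Chance of winning

`chance_of_winning()` estimates by Monte Carlo the probability that one
player's 10-trial total beats another's, given both aims and SDs; a
closed form is out of reach because the gain nonlinearity makes block totals
non-Gaussian. Ties take half credit by default, which preserves the exact
complementarity $P(A \text{ beats } B) + P(B \text{ beats } A) = 1$ used as
a test invariant; a strict-win mode exists. `winning_grid()` sweeps
candidate aims across observed block contexts and averages the estimates in
half-open 0.25 cm bins of the relative-aim plane — the map on which a
risk-averse opponent's beatable region widens triangularly as $\alpha$
falls below 1.

## Problem sizes and replication counts

The recovery and calibration properties are checked on synthetic cohorts at
the study's own scale: the risk-averse arm (8 subjects) pooled with its
risk-neutral companion (9 subjects, baseline bias 0.68 cm — that group's
reported mean), 11 analysed blocks each, giving 187 scatter points per
replicate. The suite uses 100 replicate cohorts at 2,000 bootstrap
resamples for slope recovery, 400 replicate cohorts at 500 resamples for
type-I calibration (the calibration estimate carries binomial noise of
about $\pm 0.015$ at 200 replicates, so the larger count halves it), and
10,000 Monte-Carlo repetitions for win-probability checks. These counts are
the package's chosen balance between statistical resolution and a test
suite that runs in minutes.

## Known limitations

* The two-slope subject is a measurement target, not a theory of the
  player; in particular it cannot express the win-stay/lose-shift dynamics
  discussed for the real game.
* With the default generative settings, the detection power of the
  bootstrap/permutation slope comparison on a single pooled synthetic study
  is only moderate (roughly half of replicates reject at 0.05): with a
  +1 cm baseline bias, opponents at $\alpha \le 1$ rarely aim above a
  subject's baseline, so the right half-plane is sparsely populated near
  the split and the right-slope estimate is noisy. The published human
  scatter, with its wider right-half support, is correspondingly more
  favourable to the test than these synthetic conditions.
* Opponent and subject act through block-level aims; within-block
  sequential effects (momentum, feedback reactions) are not modelled.
* The win-probability map treats each block context independently and
  ignores any correlation between consecutive blocks.
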
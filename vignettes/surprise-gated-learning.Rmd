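---
title: "Surprise-gated learning in changepoint estimation tasks: models and methods"
author: "fiplearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprise-gated learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiplearn)
```

## The scientific problem

People are far more responsive to an abrupt change in their environment
than to the same total change delivered as a sequence of small steps — the
"frog in the pan" (FIP) effect. `fiplearn` studies this effect in a
predictive-inference setting: on every trial an agent predicts a target
value on a 0–50 scale, observes the realized target, and revises its
estimate. Writing $PE_t = \text{target}_t - \text{estimate}_t$ for the
signed prediction error and
$\text{update}_{t+1} = \text{estimate}_{t+1} - \text{estimate}_t$ for the
belief revision, the delta rule

$$\text{update}_{t+1} = \alpha \cdot PE_t$$

defines the learning rate $\alpha$ as the proportionality between revision
and error. The FIP hypothesis, in this vocabulary, is that the *effective*
learning rate is larger when the error is large enough to be surprising —
i.e. on abruptly changed trials — than when the same total change arrives
gradually.

Human data for this task are not redistributable, so the package is built
as a closed loop: a task generator, a generative cohort of agents whose
update rule embodies the fitted models, and the full inference battery.
Every estimator is validated by parameter recovery — simulate from known
parameters, refit, and compare.

## Task design

Both blocks contain 100 trials of Gaussian targets with SD 1.7. In the
*gradual* block the generating mean follows
25 (20 trials), 30, 35, 30, 25, 20, 15, 20, 25 in 10-trial segments: the
overall change of ten points is delivered through an inserted intermediate
distribution, so consecutive distributions overlap heavily. In the
*abrupt* block the mean jumps by ten points in a single step at trials 30,
50, 70 and 90. Trials are labelled with four conditions — randomly
fluctuating trials of each block (the gradual-block ones are the baseline
everywhere), gradually changed trials (21–30, 41–50, 61–70, 81–90 of the
gradual block), and the four abruptly changed trials.

```{r schedules}
canonical_schedule("abrupt")
```

Two design parameters deserve comment:

* **Smoothness constraint** (`max_step`, default 6): the gradual block must
  not contain an incidental jump that participants would experience as
  abrupt (with ten-point jumps as the abrupt reference, a gap of ten
  between consecutive gradual-block targets would defeat the design).
  Draws violating the constraint are resampled from the segment Gaussian
  truncated to the admissible window, which preserves reproducibility and
  cannot stall. Six units keeps all gradual deltas well below the
  ten-point abrupt jump while remaining feasible between adjacent
  N($\mu$, 1.7) and N($\mu \pm 5$, 1.7) segments.
* **Trend realization** (`trend_realization`): with the default `"iid"`
  every trial of a segment is an independent draw from the segment
  Gaussian, exactly as the schedule table states; the "fluctuating upward
  trend" of a gradually increased run is carried by the rising segment
  means. An alternative `"sorted"` realization reorders each drifting
  segment's draws monotonically (plus N(0, 0.5) jitter). We made `"iid"`
  the default after observing that sorting turns the ten draws into order
  statistics whose local variability is far below the nominal SD of 1.7,
  which makes gradually changed trials *smoother* than fluctuating ones
  and inverts the observed descriptive ordering of mean absolute errors
  between those conditions. Targets are clipped to the bar and rounded to
  one decimal (the response bar's click resolution is not otherwise
  constrained).

## Generative agents

`simulate_agent()` starts each block at the bar midpoint (estimate 25 —
the first segment's mean, so the first trial's error is small; the first
trial contributes no paired update to any model in any case) and applies

$$\text{update} = \mathrm{sign}(PE)\, m(|PE|) + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma_u),$$

with estimates clipped to the 0–50 bar and the *realized* estimate change
stored, so estimates always telescope exactly. The mean function $m$ comes
in two modes:

* **linear** (condition-dependent): $m(|PE|) = a_c + \alpha_c |PE|$ with
  per-condition intercepts $a_c$ = 1.017, 1.039, 0.756, 2.548 and learning
  rates $\alpha_c$ = 0.528, 0.533, 0.595, 0.693 (baseline, gradually
  changed, fluctuating-abrupt, abruptly changed) — the condition
  composites of the fitted condition-by-error model.
* **segmented** (surprise-gated): a continuous broken line
  $m(|PE|) = \beta_0 + \beta_1 |PE| + \delta \,(|PE| - \psi)_+$ with
  defaults $\beta_0 = 0.916$, $\beta_1 = 0.536$, $\delta = 0.536$,
  $\psi = 5.337$: below the breakpoint the learning rate is $\beta_1$,
  above it surprise raises the rate by $\delta$.

The mean function operates on the *absolute* error and is applied with the
error's sign; this matches descriptive summaries, which are on the
absolute scale, while keeping the signed dynamics coherent. At $PE = 0$
the direction is undefined and is drawn at random — the magnitude
$m(0) > 0$ still applies, so the absolute update stays on the generative
line even at a zero error (a degenerate input that does occur, e.g. when
the block's first target equals the midpoint initialization).

Further generative components, all tunable:

* `p_no_update` (default 0.05): a minority of trials show no belief
  revision at all; the update is exactly zero. The probability is a
  calibration choice — only the existence of such trials, not their rate,
  is documented behaviorally — and it is applied uniformly across trials
  because nothing more specific is known.
* Participant heterogeneity: each agent draws one intercept perturbation
  (SD 0.3), one slope perturbation (SD 0.1) and one latency intercept
  (SD 0.15 s). These spreads are calibration, not measured quantities: no
  per-participant variance components are published for this task, so the
  recovery harness is the place where their adequacy is quantified.
* `update_noise_sd` (default 1.5 target units): trial-level update noise,
  calibrated so the simulated condition SDs of absolute updates bracket
  the published descriptive SDs (~1.6–2.4).
* Reaction times: condition-mean based, with means 0.883, 0.850, 0.855,
  1.105 s — surprise enters through the raised abrupt mean; there is no
  mechanistic latency process to copy. Trial noise is Gaussian
  (SD 0.3 s); with probability `p_lapse` (0.02) an exponential slow tail
  (mean 2 s) is added, which is what exercises the 3-second exclusion
  rule; latencies are floored at 0.15 s. The letter-discrimination
  response itself is always correct — error trials are out of scope.

Block order is counterbalanced deterministically (even-indexed agents see
the abrupt block first). Each agent receives fresh target draws; all
randomness derives from the cohort seed through fixed substreams, so any
stage can be rerun in isolation and a cohort is byte-reproducible.

## Trial metrics

`build_analysis_table()` pairs each trial's error with the *following*
update (row $t$ carries $PE_t$ and $\text{update}_{t+1}$; the last trial
of a block has no paired update and is dropped from update models), adds
absolute transforms, the guarded empirical rate
$\text{update}/PE$ (undefined below $|PE| = 10^{-9}$ — the ratio against a
zero error carries no information), applies the latency exclusion, and
codes the baseline-referenced condition factor with explicit dummies.
The exclusion reads "longer than 3 seconds" strictly: 3.00 s is kept,
3.01 s is excluded. Model fits use absolute error and absolute update;
signed columns are retained for diagnostics.

## The inference battery

All update and latency models are linear mixed models with a participant
random intercept, estimated by maximum likelihood (`lme4`, REML off so
profile log-likelihoods are comparable), with Wald tests against a normal
reference. Random slopes and random changepoints are deliberately not
fitted: the random structure documented for this task is participant-level
only, and the recovery harness quantifies what the simplification costs on
synthetic data. On noise-free cohorts the variance components are
unidentifiable (residual variance numerically zero); the fits then fall
back to ordinary least squares, flagged `engine = "ols"` — coefficients
are exact and this is what the identifiability checks exercise.

* `fit_condition_lr_model()`: absolute update on absolute error ×
  condition; composite per-condition learning rates are the shared slope
  plus the interaction.
* `fit_quadratic_model()`: adds a squared-error term; a positive
  significant coefficient is the nonlinearity signature that motivates
  the broken line.
* `fit_segmented_model()`: the package's own broken-line estimator (see
  below).
* `fit_threshold_logistic()`: the odds that $|PE|$ exceeds a threshold
  (default: the estimated breakpoint 5.337, the natural choice absent a
  stated rounding) per condition. Abrupt trials exceed the threshold
  almost surely, so quasi-separation is detected and flagged rather than
  silently reported; the stable reproducible facts are the sign and
  dominance of the abrupt coefficient, not its magnitude.
* `fit_rt_model()`: included latencies on condition.

### The segmented estimator

For fixed $\psi$ the broken line is linear in the basis
$(|PE|, (|PE| - \psi)_+)$, so the model reduces to an ordinary
two-regressor mixed fit; continuity at the knot is structural. The
breakpoint is estimated by profiling the ML log-likelihood over a $\psi$
grid. The searched range (1–12 absolute-error units) spans the gradual
(~2.5) and abrupt (~10.5) error regimes; the effective resolution is
0.05, implemented as a coarse pass (step 0.25) over the full range
followed by a fine pass (step 0.05) within ±0.5 of the coarse peak —
property tests verify this matches an exhaustive 0.05 grid. Candidates
with fewer than `min_side` observations on either side are skipped; a
boundary maximum and a near-flat profile (range under $10^{-4}$) raise
warnings, and ties resolve to the smallest maximizing $\psi$. The grid
winner is then polished by Muggeo-style linearization: refit with the gap
covariates $U = (x - \psi)_+$ and $V = -\mathbb{1}[x > \psi]$ and move
$\psi$ by $\hat\beta_V / \hat\beta_U$ until the step falls below
$10^{-6}$ (at most 30 iterations); the polished value is kept only if it
does not lose likelihood. Confidence intervals come from
profile-likelihood inversion ($\chi^2_1$ cutoff, interpolated between
grid points) or, optionally, a nonparametric bootstrap over participants.

```{r segmented-example, eval = FALSE}
up <- update_rule_params("segmented")
tab <- build_analysis_table(simulate_cohort(cohort_spec(n_agents = 30, seed = 2), up))
fit_segmented_model(tab)
```

### Parameter recovery

`run_recovery()` simulates cohorts from known parameters, refits the
matching model, and tabulates bias, RMSE and interval coverage per
parameter, with every replicate seed logged. Two regimes matter:

* **Noise-free**: refits recover the generative coefficients to numerical
  precision ($\le 10^{-6}$; the breakpoint to refinement precision). This
  is the package's identifiability guarantee.
* **Noisy defaults**: recovery is good but not unbiased. Because the
  fitted models regress the *absolute* update, whose conditional mean is
  $E\,|m + \varepsilon| = m + \text{folded-normal correction}$, the
  regression surface flattens wherever $m$ is small relative to
  $\sigma_u$: low-error slopes are attenuated, intercepts inflated, and
  the slope increment above the knot correspondingly overstated. The
  bias vanishes as $\sigma_u \to 0$ and does not affect the ordering
  conclusions (the FIP orderings hold in every default replicate), but at
  the default noise level the attenuation of small-error learning rates
  is of order 10–20%, and Wald intervals centred on biased estimates
  undercover. The test suite states the intended recovery bands and
  reports these deviations rather than hiding them; treat fitted
  low-error learning rates from absolute-value regressions as lower
  bounds.

## What the synthetic cohorts do and do not emulate

The generator reproduces the task structure exactly and the trial-level
moment structure approximately (regime separation of errors, updates and
latencies at cohort scale). It does not model: response error in the
letter task, within-session learning or fatigue drifts, heavy-tailed or
autocorrelated update noise, participant-specific breakpoints, or any
order effect beyond counterbalancing (order is simulated, not modelled).
Passing tests therefore certify the estimators and the pipeline on data
of known provenance — they do not certify that human cohorts satisfy the
generative assumptions.

## Numerical choices and problem sizes

Likelihood convergence tolerance is $10^{-8}$ (at most 200 optimizer
iterations); non-convergence is a flagged result, never a silent answer.
The test suite runs identifiability checks on 5–6-agent noise-free
cohorts, property checks on 20-agent cohorts, descriptive and ordering
checks on three full 109-agent cohorts, and stochastic recovery at 10
replicates of 109 agents per mode; the acceptance script uses 10
replicate cohorts per quantity. These sizes give Monte Carlo error
comfortably below the tolerance bands they are tested against.
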
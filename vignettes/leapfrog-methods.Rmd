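---
title: "Methods: simulating and analysing exploratory choice in the leapfrog task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing exploratory choice in the leapfrog task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leapfrog)
```

## The task and its two hazard regimes

The leapfrog task is a two-option repeated-choice environment built to
separate *how much* people explore from *when* they explore. The two options
start at 10 and 20 points. On any trial the currently lower option can jump
up by 20 points, overtaking the other; jumps therefore always hit the lower
option and strictly alternate sides, and the gap between the options is 10
points on every trial. A player sees only the payoff of the chosen option,
so the only way to find out whether the other option has jumped is to choose
it — every choice is effectively "exploit the best-known option" or
"explore the other one".

Two regimes govern when jumps happen:

* **independent** — a constant per-trial jump probability
  ($p = 0.075$ by default), so trial outcomes carry no sequential
  information;
* **dependent** — the hazard starts at $h_0 = 0.01$, grows by
  $\Delta h = 0.01$ per trial since the last jump, and resets when one
  occurs (capped at 1). Here a jump genuinely *is* more likely the longer
  it has been since the last one.

One design point is worth stating because the original task description
leaves it open: jumps are resolved at the *start* of a trial, before the
choice, so the reward paid and the correctness of the choice both refer to
post-jump values ("the truly higher option on that trial" is unambiguous).
Episode bookkeeping starts the since-jump counter at 1, so trial 1 carries
hazard $h_0$ in the dependent regime. Trial timing (response windows,
feedback durations, timeouts) is not simulated.

## Agents

All agents carry a running *favorite* — the option with the highest payoff
they have observed — and differ in when they abandon it for a look at the
other option.

**Reflexive** agents explore with a constant probability $\epsilon$ per
trial. They produce a flat exploration hazard: the probability of exploring
does not depend on how long they have been exploiting.

**Reflective** agents track a belief $q$: the probability that their
favorite has been overtaken. Because jumps strictly alternate sides, the
favorite has been overtaken exactly when an *odd* number of unobserved
jumps has occurred, so $q$ is a parity belief with the two-state recursion

$$q' = q\,(1 - h) + (1 - q)\,h,$$

where $h$ is the believed one-trial jump hazard. Starting below $1/2$, $q$
rises monotonically toward $1/2$ — uncertainty saturates, it never flips to
"certainly overtaken". The agent explores when $q \ge \theta$ and, with a
small lapse probability $\epsilon$ (default 0.02), inverts whatever the
threshold said. After an informative observation — an exploratory look, or
a payoff that exceeds the option's last known value and thereby reveals a
jump — $q$ resets to the believed one-step hazard, the residual uncertainty
about a jump on the trial just resolved.

The two reflective kinds differ only in the believed hazard:

* **ideal** — a constant $h$, defaulting to the environment's true
  parameter. In the dependent regime "the true parameter" is ambiguous; we
  use the ramp's marginal per-trial jump rate ($1/E[\text{interval}]
  \approx 0.082$), because a constant-belief agent that believed the reset
  value 0.01 would essentially never explore, which is neither ideal in any
  sense nor an interesting comparison model.
* **gambler's-fallacy** — a ramping hazard
  $\min(h_0 + \Delta h \cdot s_{obs}, 1)$ keyed to $s_{obs}$, the number of
  trials since the agent last *observed* a jump. In the independent regime
  this belief is false and mistimes exploration; in the dependent regime it
  matches the generative process.

This parity-threshold family is an approximation: the reference
ideal-actor definition for this task is not available to us, so the agents
are validated against the qualitative signatures they are meant to
reproduce (flat vs rising hazard curves; group-level regression effects),
not against a closed-form optimal policy. Agents have perfect memory of
last observed values, and the first observation of an option never counts
as an observed jump (there is nothing to compare against).

### Threshold calibration

$\theta$ has no stated value. We calibrate it by grid search
(`calibrate_theta()`) so that each reflective kind's exploration rate
matches the rate human cohorts show on this task — approximately 17% of
trials in the independent regime and 15–17% in the dependent one. Because
the fallacy agent's believed hazard ramps, its $q$ reaches any threshold
sooner, so it needs a higher $\theta$; and both kinds need separate values
under the dependent regime's slow post-jump hazard. The frozen defaults
are:

| kind | independent | dependent |
|---|---|---|
| ideal | 0.32 | 0.34 |
| fallacy | 0.415 | 0.355 |

Calibrating per kind *and* regime (rather than only for the ideal agent in
the independent regime) is a deliberate extension: exploration rate is the
dominant driver of task performance in this model family, and the printed
per-cell human exploration rates are part of the world the generator is
meant to emulate. With a single per-kind threshold the fallacy agent's
exploration collapses to ~0.10 in the dependent regime, contradicting those
rates and erasing the group-by-condition performance signature for reasons
that have nothing to do with belief quality.

## The analysis pipeline

**Labels.** A choice is *exploitive* iff it picks the option with the
highest reward observed so far by that participant (running per-option
maxima); anything else is *exploratory*. Trials before both options have
been observed are unlabelled (`NA`) and excluded downstream — the "highest
observed reward" is undefined there.

**Lag covariates.** `ell` counts trials since the last exploratory choice
(1 on the trial after an explore; before the first explore it counts from
the first labelled trial, with an exclusion variant behind a flag). `s_obs`
counts trials since the last *observed* jump, resetting to 0 on the trial
where a payoff exceeds the option's previous observed maximum; an
alternative reading counts exploratory choices rather than trials and is
exposed as `count = "explores"` — the source material is ambiguous between
the two, so both are available and the trial count is primary.

**Hazard curve.** Exploration rate by `ell`, pooled; lags with fewer than
5 at-risk trials are flagged low-support and excluded from plots and tests.

**Strategy classification.** Per participant, two Bernoulli models of the
explore indicator are compared by BIC ($-2\ell + k \ln n$, $n$ = labelled
trials): an intercept-only model (flat hazard, "reflexive") versus a
logit-linear model in `ell` with slope constrained $\ge 0$ (rising hazard,
"reflective"). The likelihood is trial-level; whether the original analysis
fit binned rates or trial-level likelihoods is not stated, so a
linear-probability variant is exposed behind `variant = "linear_prob"` for
sensitivity analysis. Numerical conventions: a negative unconstrained slope
is refit at 0 (where the likelihood equals the intercept model's, and the
intercept model wins by the $\ln n$ penalty); participants with 0% or 100%
exploration get a continuity correction of 0.5 successes/failures so the
log-likelihood stays finite; BIC ties break toward the simpler model.
The group contrast on classification counts is a Pearson chi-square without
continuity correction plus $\phi = \sqrt{\chi^2 / N}$ — this choice exactly
reproduces the printed worked example (counts 50/58 vs 35/52 give
$\chi^2 = 5.576$, $\phi = 0.225$).

**Trial-wise regressions.** Exploration (or correctness) is regressed on
`s_obs`, group, and their interaction, controlling for `ell` and its group
(and condition) interactions, with a participant random intercept
(`lme4::glmer`). When the mixed fit fails — or when speed matters, via
`method = "glm_cluster"` — the model falls back to a fixed-effects
logistic regression with participant-clustered errors. The clustered
covariance is a one-step cluster jackknife (approximate CR3) with a
$t(G-1)$ reference rather than the plain CR1 sandwich: null-cohort
simulation showed CR1 rejecting at 10–15% instead of 5% in this design
(the lag covariates trend within participants, giving single participants
high leverage; the implementation was cross-checked against an independent
one, so this is a property of the estimator, not a bug). The jackknife
holds the nominal level from roughly 40 clusters up, which is why the
type-I acceptance property is evaluated at 20 participants per group. No
multiple-testing correction is applied anywhere, matching the reporting
conventions this pipeline mirrors.

**Group contrasts.** Pooled-variance t tests (df $= n_1 + n_2 - 2$) with
pooled-SD Cohen's $d$; Welch behind a flag. The two-condition design uses
a between-subjects 2×2 ANOVA on per-participant summaries.

## The synthetic cohorts

`generate_cohort()` draws each participant's agent kind from a mixture,
jitters its parameters, runs a full episode, and attaches lognormal
reaction times. The built-in archetypes encode the emulated populations:

* **young-like** — 86% ideal reflective + 14% reflexive, median RT 432 ms;
* **old-like** — 67% fallacy reflective + 33% reflexive, median RT 593 ms.

Sample sizes default to the emulated designs (58/52 in the one-environment
study; 70/68/69/69 in the two-environment study). The mixture weights echo
observed classification fractions but are *synthetic calibration choices*:
no individual-level parameter estimates exist to validate them against.
Where nothing is stated we chose once and documented: per-agent jitter is
lognormal with SD 0.2 on $\epsilon$ and Gaussian with SD 0.02 on $\theta$
(truncated to (0.05, 0.45)) — enough heterogeneity that participants are
not clones, small enough that each kind keeps its signature; RTs are
lognormal with within-participant log-SD 0.35 and between-participant
log-SD 0.15 around the group median. RTs are decorative plumbing: they
carry no information about choices, and `median_rt()` exists to round-trip
the generator, not to model latencies. Reproducibility follows one rule:
every randomness consumer takes a seed, child seeds are derived from it,
and each participant gets their own stream, so cohorts are reproducible
participant by participant.

### What a green test does and does not establish

The generator reproduces, directionally, the qualitative pattern of the
emulated studies: young-like cohorts outperform old-like cohorts in the
independent regime with near-equal exploration rates; a positive
`s_obs` effect on exploration appears in the old-like group only; and the
performance gap present in the independent regime vanishes in the
dependent one. Green tests establish that the *pipeline* recovers the
signatures its generative models plant. They do not establish anything
about human data: headline human coefficients are not reproducible
(participant data are unavailable), effect magnitudes here are generally
larger than the printed ones, and the printed chi-square is reproduced
only as a worked example from its published counts.

Two caveats deserve emphasis. First, fallacy agents are usually classified
*reflexive* by the BIC comparison (~92%): their exploration is keyed to
`s_obs`, not to the lag since the last explore, so their `ell`-hazard is
flat even though the strategy is belief-based — the old-like cohort's
reflective-classified fraction is therefore lower than in the emulated
population, though the group contrast keeps its direction. Second,
between-participant heterogeneity induces a small spurious *negative*
`s_obs` effect in mixtures (participants who explore more see jumps more
often, so low `s_obs` co-occurs with high exploration propensity across
participants); the young-like directional check therefore requires "no
significant positive effect" rather than an exact null. A pure ideal
cohort without jitter shows the exact null, and the emulated young
population's printed effect was itself slightly negative and
nonsignificant.

## Known limitations

* The parity-threshold agents are approximations validated against
  qualitative signatures only; no claim is made that they match the
  unavailable reference models trial for trial.
* The fallacy agent at its calibrated threshold underperforms a
  dynamic-programming optimal actor; absolute performance levels are a
  property of this model family, and only directions and orderings are
  treated as meaningful.
* `glmer` convergence warnings on large simulated cohorts are common; the
  clustered fallback is the documented, tested route and the default for
  simulation-scale analyses.
* The explore-count reading of `s_obs` is implemented but untested against
  any published quantity; the source material is ambiguous about which
  counting the original analysis used.
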
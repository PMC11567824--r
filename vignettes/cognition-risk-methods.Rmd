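---
title: "Methods: simulating and analysing smartphone cognition cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing smartphone cognition cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogrisk)
library(dplyr)
```

`cogrisk` models a cross-sectional smartphone study design: a cohort of
adults (18–84) completes three gamified executive-function tasks and a
battery of self-report risk-factor questionnaires, and the analysis relates
13 risk factors to three objective cognitive measures and one binary
subjective memory complaint. This vignette documents the models, the
calibration choices, and what the simulation-based validation does and does
not establish.

## The cohort generator

`generate_cohort(effect_spec(...))` draws one row per participant.

**Demographics.** Age comes from a truncated normal on [18, 84]; the
underlying normal's parameters are solved numerically
(`Nelder-Mead` on the truncated-moment equations) so the *realized*
mean/SD match the targets (45.74 / 14.55 by default) rather than shrinking
under truncation. Gender is Bernoulli with 66.3% cisgender female,
reflecting the composition of volunteer smartphone cohorts; non-cisgender
categories are out of scope.

**Risk factors.** The 13 factors share an exchangeable Gaussian copula
(`copula_rho = 0.15` by default). Self-report risk factors correlate
positively but published correlation matrices for this battery are not
available at this level of detail, so the exchangeable strength is a free,
configurable parameter — a deliberately simple default, not an empirical
claim. Continuous scale totals are latent normals scaled to the target
mean/SD, rounded, and clipped to the admissible range; clipping shrinks
the SD of strongly skewed scales (hearing handicap loses roughly 15–20% of
its nominal SD, CES-D depression about 8%), which we accept and document
rather than distort the scale shape. Binary factors threshold the latent
normal at the target prevalence.

**Why effects are injected as marginal targets.** The default effect table
gives, for each (factor, outcome) pair, the association a single-factor
age+gender-adjusted regression should recover: a standardized beta for
continuous outcomes, a log OR for the subjective item. Because the factors
are mutually correlated, injecting those numbers as *direct* coefficients
would inflate every recovered marginal association (each factor would
inherit its neighbours' effects), and for the logistic outcome
non-collapsibility would additionally attenuate them. The generator
therefore back-solves the direct coefficients:

* continuous outcomes: solve the linear system `C b = m ∘ diag(C)` where
  `C` is the empirical covariance of the analysis-coded predictors, so the
  implied covariance-based marginal slopes equal the targets exactly
  in-sample;
* the subjective outcome: iterate a pseudo-true score equation — given
  candidate direct coefficients, compute the coefficient a single-factor
  logistic fit would converge to (Newton solve against the model-implied
  probabilities, no outcome draws needed) and nudge the direct coefficient
  by the discrepancy. Age × factor interaction coefficients join the same
  iteration, since non-collapsibility attenuates them too.

The back-solve uses the cohort's own realized predictors, so recovery is
exact up to outcome noise and confidence-interval coverage of injected
values is nominal. Below `n = 200` the system is ill-conditioned (13
predictors) and the generator falls back to direct injection; tiny cohorts
are for exercising interfaces, not recovery studies.

**Latent cognition and traits.** Each continuous outcome is a unit-variance
latent "worseness" variable: the back-solved factor effects, plus linear
and (re-standardized) quadratic standardized-age effects and a gender
contrast, plus a shared cognition factor and Gaussian noise that completes
the variance to 1 (`noise_sd = NULL`). The shared-factor loadings
(0.62 / 0.55 / 0.28) were chosen once so the three objective measures
correlate roughly like the reference pattern (working memory–flexibility
strongest at ~0.4, planning weaker), with the subjective item related only
through shared risk factors and hence weakly (≲0.2). Outcomes are emitted
on interpretable scales — accuracy-like `0.80 − 0.08·y`, seconds-like
`63.28 + 21.73·y`, index-like `0.27 − 0.33·y` — and `attach_task_traits()`
standardizes them into the traits the simulators consume. Note the
orientation consequence: `wm_trait` (ability) and `flex_trait` (deficit)
correlate *negatively* even though the underlying constructs correlate
positively; tests and analyses compare them on a common worseness
orientation.

**Subjective prevalence.** The logistic intercept is solved by `uniroot` so
the model-implied population prevalence equals the target (0.405 by
default); realized prevalence is then within binomial error for any target
in (0, 1).

## Task simulators and scoring

**Memory game.** 24 trials (2 binding conditions × 2 stimulus types × set
sizes 2/3/4 × 2 repeats) on a 20-cell grid, lives = targets. Each pick is
memory-driven with probability
`plogis(1.5 + 0.45·wm_trait − 0.3·(k−2) − 0.2·binding)` and otherwise a
uniform guess over unselected cells; at memory probability 0 this is
exactly the guessing chain that `chance_accuracy()` enumerates, which both
pins the simulator's null behaviour to a closed form and reproduces the
printed chance levels 0.07 / 0.12 / 0.17. The logistic constants were
calibrated once so a standard-normal trait population scores mean ≈ 0.80,
SD ≈ 0.09, matching the reference descriptives. The per-subject score is
the unweighted mean of per-trial accuracies (each trial counts equally
across set sizes); pooled-count accuracy is available via
`method = "pooled"` because the published scoring formula does not
disambiguate the two.

**Flexibility game.** Six runs, A-B-A-B-A-B. Log completion times are
normal with form locations `3.528` (A) and `4.0917` (B), a shared
flexibility-trait loading of 0.25, a person-level residual (SD 0.15)
linking the forms, and run noise (SD 0.16) — jointly giving a population B
mean/SD near 63.3 / 21.7 s. With probability 0.01 a run is "inattentive"
and multiplied by 6, landing beyond the censoring cut-offs. Scoring drops
runs at or above 100 s (A) / 300 s (B) — the cut is inclusive, so a run of
exactly 100 s is excluded — and averages the survivors; a form with no
survivors yields a flagged `NA` rather than an imputed value, since the
published rule does not cover that case. No B−A difference score is
computed (difference scores have poor reliability).

**Planning game.** 200 trials; two first-stage actions lead to their usual
second-stage state with probability 0.8; each state's good-outcome
probability follows a reflecting Gaussian random walk (SD 0.025) in
[0.25, 0.75]. These structural constants follow the canonical two-step
literature and are configurable. The agent is the direct logistic stay
model — the mirror image of the analysis model — rather than a full hybrid
Q-learner: that keeps parameter recovery well-posed (the estimand is
exactly the generative coefficient) at the cost of not modelling
second-stage learning dynamics, which the index regression never sees
anyway.

## The model-based index

`build_stay_table()` emits one row per consecutive trial pair with ±1
outcome and transition codes (so the interaction is orthogonal to the mains
under balance); `fit_stay_regression()` maximizes the ridge-penalized
(`1e-4`) logistic likelihood by IRLS. The ridge guarantees finite estimates
for all-stay/all-switch subjects, who are flagged `converged = FALSE`. The
published analysis is hierarchical; here per-subject ML plus optional
empirical-Bayes shrinkage (normal approximation, method-of-moments
between-subject variance) stands in, because the index's role is a
per-subject covariate rather than group inference — the estimator is
labelled, not claimed identical. Recovery at 200 trials: Spearman ≥ 0.6
between generative and estimated indices across agents spanning
`b_mb ∈ [0, 1.5]` (typically ≈ 0.9 in the test suite).

## The association suite

Preparation follows the published coding rules: orientation so higher =
worse/higher risk (education, SES, social network, exercise, accuracy and
the planning index are reversed), within-sample z-scoring of continuous
variables, 0/2 coding of binaries. The 0/2 coding makes a binary's SD equal
1 only at 50% prevalence (`2·sqrt(p(1−p))`, e.g. 0.982 at 40.5%); the
realized SDs are recorded on the prepared object rather than silently
assumed to be 1. Age enters association models as the standardized linear
term only; the quadratic term (square of standardized age, re-standardized)
appears in the descriptive models.

Choices the published description leaves open, decided here:

* **CI method:** Wald intervals for ORs (`exp(β ± 1.96·SE)`).
* **Binarization ties:** the worst `round(q·n)` participants are flagged
  using a stable sort on (score, participant id), so the flagged count is
  deterministic and exact even with mass ties at the boundary.
* **Depression-adjusted alpha:** the adjusted suite (12 factors × 4
  outcomes) is still judged at the primary per-outcome threshold
  `0.05/13 = 0.0038`, matching how those models are reported.
* **Interaction family:** `α = 0.05 / n_pairs` where the pairs are exactly
  the primary-suite significant (factor, outcome) combinations.

## Validation design and problem sizes

The test suite validates by simulation at sizes chosen to balance
Monte-Carlo resolution against desk-scale runtimes:

* CI coverage of injected effects: 200 cohorts of n = 3327, pooled over six
  representative factor–outcome pairs (binomial SE ≈ 0.6%), required in
  [0.92, 0.98];
* type-I error: 40 all-null cohorts of n = 600 → 2080 primary models,
  rejection at 0.05 required within ±0.01;
* index recovery: 100 agents × 200 trials;
* chance accuracy: million-draw Monte-Carlo against the exact enumeration
  on a 12-point (G, k, L) grid, within 3 standard errors.

## Limitations

The generator emulates marginal distributions, prevalences, an
exchangeable dependence structure, and target effect sizes — not real
data's measurement quirks: no missing data or attrition (the reference
design had none by construction), no item-level questionnaire structure,
symmetric latent normals where real scale totals are often zero-inflated or
skewed beyond what clipping induces, no practice, fatigue or device
effects in the task simulators, and a single common factor for
between-task correlation. Passing tests therefore demonstrate that the
*pipeline* is correct and well-calibrated under its stated generative
model, not that any particular real cohort satisfies that model. The
task-derived pipeline path (scores estimated from simulated trials) adds
realistic measurement noise and correspondingly attenuates associations
relative to the latent-outcome path used for calibration checks; that
attenuation is expected behaviour, visible in `run_pipeline()` output.
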
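# cogrisk

Simulation and association analysis for smartphone-based cognitive
assessment studies of modifiable dementia risk factors.

Large remote studies increasingly measure cognition with brief gamified
tasks — a visual working-memory binding game, a trail-making style
flexibility game, a two-step reinforcement-learning planning game — plus a
single-item subjective memory screener, and relate these outcomes to
self-report risk factors for dementia (depression, SES, education,
loneliness, hearing handicap, social network, exercise, smoking, tinnitus,
stroke, diabetes, hypertension, family history). `cogrisk` packages that
entire workflow as tested, reusable R code for methodologists and study
planners: a seeded synthetic-cohort generator with configurable effect
sizes, trial-level task simulators, the exact scoring rules (including the
chance-level accuracy enumeration and outlier censoring), per-subject
model-based planning indices, and the full standardized-coefficient
regression suite with per-outcome Bonferroni correction.

## The statistics at the core

**Chance-level accuracy of the memory game.** A trial presents `k` studied
symbols to find on a `G = 20` cell grid with `k` lives; it ends when all
targets are found or all lives are lost, and is scored as
`correct / (correct + errors)`. Under pure guessing the pick process is an
absorbing Markov chain over states `(c, e)` with
`P(correct pick) = (k − c) / (G − c − e)`. `chance_accuracy(G, k, L)`
enumerates this chain exactly: on the 20-cell grid the expected accuracy is
0.07, 0.12 and 0.17 (2 dp) for set sizes 2, 3 and 4.

**Model-based planning index.** On the two-step game, each trial's
stay/switch choice is regressed on the previous trial's outcome
(`o = ±1`) and its interaction with transition type (`τ = ±1`):

    logit P(stay) = β0 + βMF·o + βMB·o·τ

`βMF` captures the model-free tendency to repeat rewarded actions; `βMB` —
the model-based index — captures how that is qualified by knowledge of the
task's transition structure. Fits are per subject with a small ridge
penalty (finite under separation), optionally shrunk toward the cohort mean
by empirical Bayes.

**Association suite.** Variables are oriented so higher = worse/higher
risk, continuous variables z-scored within sample, binary variables coded
0/2 (so a 2-unit change plays the role of one SD), gender contrast-coded
with cisgender male as reference. Each of 13 risk factors is regressed
against each of 4 cognitive outcomes adjusted for age and gender (linear
for continuous outcomes, logistic with `OR = exp(β)` otherwise), plus
logistic reruns on objective scores binarized at the subjective-complaint
prevalence (40.5% by default), a depression-adjusted suite, and age ×
factor interaction models for previously significant pairs. Bonferroni
correction is per dependent variable: `α = 0.05/13 = 0.0038`, and
`0.05/31 = 0.0016` for a 31-pair interaction family.

## Worked example

```r
library(cogrisk)
library(dplyr)

cohort <- generate_cohort(effect_spec(n = 3327, seed = 1))
prep   <- prepare_cohort(cohort)
suite  <- run_primary_suite(prep)
glance(suite)
#> # A tibble: 1 × 4
#>   suite   n_models   alpha n_significant
#> 1 primary       91 0.00385            44

tidy(suite) |>
  filter(model_type == "primary", outcome == "subjective_memory") |>
  select(risk_factor, beta, or_value, ci_low, ci_high, significant) |>
  head(5)
#>        risk_factor  beta or_value ci_low ci_high significant
#> 1           stroke 0.631    1.880  1.373   2.576        TRUE
#> 2       depression 0.568    1.765  1.638   1.903        TRUE
#> 3              ses 0.559    1.749  1.620   1.887        TRUE
#> 4 hearing_handicap 0.462    1.587  1.476   1.706        TRUE
#> 5       loneliness 0.365    1.441  1.342   1.547        TRUE
```

The suite fits 52 single-factor models (13 factors × 4 outcomes) plus 39
binarized-objective logistic models; `beta` is the standardized (or log-OR)
coefficient for the factor adjusted for age and gender, and `significant`
flags `p < 0.0038`. The generator injected the default effect table, so
depression's recovered OR (1.77, CI 1.64–1.90) sits on its 1.82 target
within sampling error; results are sorted by effect size within outcome.

Trial-level simulation and scoring chain the same way:

```r
trials <- simulate_cohort_two_step(cohort[1:50, ], seed = 7)
indices <- estimate_cohort_indices(trials)
glance(indices)          # mean/SD of the model-based index
autoplot(suite)          # forest plot by outcome
```

`run_pipeline(run_config(seed = 1, n = 3327))` executes
simulate → score → index → associate → report into a directory of CSVs
with a JSON manifest; reruns with the same config are byte-identical. A
thin command-line wrapper lives at `inst/scripts/run_pipeline.R`.

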
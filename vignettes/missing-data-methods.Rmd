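---
title: "Evaluating single-imputation methods for OHCA association analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating single-imputation methods for OHCA association analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Out-of-hospital cardiac arrest (OHCA) registries routinely lose covariate
values — witness details, call times, patient age — while the core exposure
and outcome fields are comparatively complete. The scientific question
`ohcasim` addresses is methodological: *when a registry analyst fits a
multivariable logistic model of bystander CPR (BCPR) on an exposure (a
responder-app alert being issued) and confounders, how do complete-case
analysis and common single-imputation methods distort the estimated
log-odds coefficients?*

Because real registry data are access-restricted, the package builds a
synthetic stand-in cohort of N = 13,274 adult OHCA cases from published
stratum counts, introduces missing-at-random (MAR) missingness with a fully
documented mechanism, applies each missing-data method, refits the fixed
association model

```
bcpr ~ alert_issued + age + gender + witness_type + call_time +
       arrest_location + first_rhythm
```

and measures the standard simulation estimands per method, model term and
missingness proportion: bias, empirical SE, 95%-CI coverage, mean AIC and
RMSE, each with Monte-Carlo standard errors.

## The synthetic cohort: a stated world

Two generators are provided.

**Table-faithful mode** (`generate_table_faithful()`) reproduces, exactly,
every published count of the four (alert x BCPR) strata: stratum totals,
and each covariate's level counts within each stratum. Its purpose is
arithmetic fidelity: all published percentages (overall BCPR 65.3%,
alerted 85.6%, healthcare-witnessed 93.2%, ...) are recovered to the
printed digit. Two modelling choices fill gaps the published table leaves
open:

* *Age* is only published as median (Q1–Q3) per stratum. We sample from a
  log-normal matched to the printed median and interquartile ratio
  (`mu = log(median)`, `sigma = log(Q3/Q1) / (2 z_{0.75})`), truncated to
  the adult range [18, 110] by inverse-CDF sampling. Log-normal because
  ages here are positive and right-skewed; two printed quantile ratios pin
  the two parameters.
* *Within-stratum independence.* The table publishes only per-covariate
  margins within strata, so covariates are sampled independently within
  each stratum. This is a declared departure from the real registry, whose
  inter-covariate correlation structure is unknown to us. Consequences are
  discussed under *Limitations*.

**Model-based mode** (`generate_model_based()`) samples covariates from the
whole-cohort marginals, draws the exposure Bernoulli(6876/13,274), and
generates the outcome from the logistic model using the published
reference coefficients as the exact truth. The published analysis never
reports an intercept, so `calibrate_intercept()` solves
`mean(plogis(a + X beta)) = 0.653` (the published BCPR prevalence) by
monotone root-finding; the mean probability is strictly increasing in `a`,
so the root is unique, and the solver brackets it analytically and
tightens to prevalence error < 1e-8.

## The MAR amputation mechanism

One of age, witness type or call time is deleted per affected case —
never two — using a candidate-then-fire scheme: every case draws one
candidate pattern (defaults 0.2 / 0.4 / 0.4, honouring the statement that
age missingness is the rarer pattern), then missingness fires with
probability `plogis(shift + w z)`, where `z` is the centred, range-scaled
code of the pattern's driving covariate (gender for age; arrest location
for witness type and call time, with public locations more likely missing)
and `shift` is solved per pattern so the expected overall missing
proportion equals the target. The weight default 1.0 gives a missingness
odds ratio of about `e` between driver levels — a clear but moderate MAR
signal; the original study used an amputation tool whose weight settings
are not reported, so these are declared, configurable stand-ins.

The mechanism never reads the value being deleted, which makes it MAR by
construction; the test suite verifies this behaviourally (the own-value
effect in a missingness regression is null while the driver effect is
detectable, and deleted values are independent of missingness within
driver levels).

## The four imputers

* **Mean/mode (MM)** — observed-column mean (age) or mode (categoricals,
  ties to the earlier domain level). Known pathology: shrinks variance and
  ignores relationships; the suite asserts the variance shrinkage.
* **Missingness-indicator (MxI)** — age gaps are filled with 0 plus an
  `age_missing` indicator; categorical gaps become an explicit `missing`
  level, which is algebraically the same as fill-plus-indicator in the
  design matrix but simpler to book-keep.
* **Gower-distance KNN** — k = 5 donors by mixed-type Gower distance
  (range-scaled age, 0/1 mismatch for nominals, rank-scaled ordinal call
  time), donor median/mode fill, distance ties to the lower case id, mode
  ties to the earlier domain level. Deterministic given the table. The
  compiled kernel packs the nominal columns one byte each into a 64-bit
  word, so a pair distance is an XOR plus two numeric terms; a pure-R
  exhaustive oracle checks exact equality on small tables.
* **Iterative random forest (MF)** — the mean/mode-initialised,
  increasing-missingness-ordered, fit-and-refill loop of the classic
  forest imputer, stopped the first time the difference criterion
  (normalised squared change for age; changed-category proportion for the
  factors) fails to strictly decrease for every variable type present,
  returning the previous sweep's fill. No random-forest package is
  assumed: the forest is a compiled CART ensemble (bootstrap, random
  feature subsets, Gini/variance criteria) with histogram split search
  over at most 64 quantile bins per feature — an approximation that is
  exact for the dummy-coded and ordinal predictors and affects only the
  age split resolution. Defaults: 100 trees, `mtry = floor(sqrt(p))`,
  leaf size 5, depth cap 25, at most 10 sweeps.

Both machine-learning imputers include the outcome among the predictors by
default (`use_outcome = TRUE`), the standard choice so that imputation
preserves covariate–outcome association; it is configurable off for
sensitivity analyses. The original study does not state k, the forest
hyper-parameters, or the predictor set; all are declared defaults here.

## The association model

`fit_logistic()` is a plain IRLS maximum-likelihood fit with Wald SEs from
the inverse Fisher information, 95% CIs with the fixed 1.96 multiplier,
convergence when the score infinity-norm falls below 1e-8 (at most 100
iterations, with step-halving on deviance increase), and a separation
guard: coefficients running past |beta| = 15 with a non-vanishing gradient
are flagged unconverged, and the harness excludes and counts such
repetitions rather than silently absorbing them. AIC is `2k - 2 logLik`;
RMSE is the probability-scale `sqrt(mean((y - p)^2))` over the rows used
in the fit — the published study does not define its RMSE, so this
Brier-root definition is a declared choice and is used only qualitatively.

## Simulation designs: fixed reference versus fresh draws

A subtle design point decides what "coverage" can mean.

* **Fixed-reference design** (table-faithful mode, or any user-supplied
  cohort): one complete cohort is amputed repeatedly, mirroring how the
  original study treated its registry snapshot. The only meaningful truth
  is then the *reference fit* on that cohort, and empirical SEs measure
  amputation/imputation noise only.
* **Fresh-per-repetition design** (model-based mode): every repetition
  draws a new cohort from the outcome model, so bias and coverage are
  measured against the *exact generator coefficients* and Wald coverage is
  nominally 95% under the correctly specified model. With a single fixed
  cohort those estimands would be confounded by that cohort's own sampling
  deviation — shared by all repetitions, it drives coverage of the true
  parameter to 0 or 1 per term, and no nominal-coverage statement could
  hold.

`run_simulation()` selects the design from the cohort source; repetition
`r` always uses seed `base_seed + r`, so any repetition can be replayed
alone, and per-repetition rows stream to disk so interrupted runs resume.

## What a green test does and does not establish

The generator reproduces published margins, not the registry's joint
distribution: covariates are mutually independent given the stratum (or
entirely, in model-based mode). Method contrasts that depend on real
inter-covariate correlation — notably how much signal KNN neighbours or
forest predictors carry about a missing value — are therefore muted in
this world. Concretely, with independent covariates the donors of a KNN
query are nearly uninformative about a missing witness type beyond what
the outcome provides, so KNN imputation error adds repetition-to-repetition
noise that can exceed complete-case subsampling noise; and forest
predictions collapse towards the per-stratum mode, making MF behave much
like MM. The acceptance suite states the original study's qualitative
rankings as-is; where this synthetic world genuinely does not reproduce
them, the corresponding assertions are expected to fail honestly rather
than be weakened (see the test file).

Numerical conventions collected in one place: age CSV serialisation uses
17 significant digits (exact double round-trip); mode and vote ties break
towards the earlier domain level, distance ties towards the smaller case
id; the amputation and calibration root-finders use analytic brackets with
`uniroot` tolerance 1e-12; degenerate inputs (fully missing column, zero
donors, zero complete cases, single-class outcome) raise errors naming the
offending column, while k exceeding the donor pool and forest
non-convergence warn and proceed as documented.

## Limitations

Beyond the independence caveat above: the amputation weights and pattern
frequencies are stand-ins for unpublished settings; MCAR and MNAR
mechanisms, multiple imputation, survival outcomes and the alert-issuance
process are out of scope; and the histogram split search means the forest
is not bit-identical to any particular reference implementation (it is,
however, seeded, deterministic and tested against planted-signal oracles).
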
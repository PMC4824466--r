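---
title: "Profiling hospitals with case-mix-adjusted standardized risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling hospitals with case-mix-adjusted standardized risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospbench)
```

## The profiling problem

Quality registers compare hospitals on adverse-outcome indicators — here, a
binary indicator such as death or dependence in activities of daily living
(ADL) three months after a stroke. Two things make naive comparisons
misleading. First, hospitals admit different patients: an unfavourable
case-mix inflates a hospital's crude event rate without saying anything
about its care. Second, hospitals differ enormously in volume: with
conventional significance testing, a large hospital can be flagged for a
clinically irrelevant deviation while a seriously deviating small hospital
goes undetected.

`hospbench` implements a profiling workflow that addresses both issues: a
fixed-effects logistic regression adjusts for case-mix; *direct
standardization* puts every hospital on the same reference population; and
a decision rule separates the *clinically relevant margin* from the
*statistical confidence* demanded before flagging.

## The case-mix model

For patient $i$ with covariates $x_i$ treated in hospital $h(i)$,

$$\log\frac{p_i}{1-p_i} = \beta_0 + x_i'\beta + \sum_{h=2}^{m} I_h\,\psi_h,$$

with $I_h$ the hospital indicator and $\psi_h$ the hospital effect
(reference coding: $\psi_1 \equiv 0$). The default covariate set is age
(years), sex, level of consciousness at admission (alert / drowsy /
unconscious, an RLS-based severity proxy), stroke subtype (hemorrhagic /
ischemic / unspecified), smoking (no / yes / unknown — "unknown" is a
modelled level because baseline smoking is often unrecorded), atrial
fibrillation and diabetes. Hospital effects are assumed constant across
covariate values; no hospital–covariate interactions are fitted.

`fit_casemix_model()` maximises the likelihood by IRLS and returns the
coefficient vector with its observed-information covariance. Two numerical
choices matter downstream:

* **Convergence.** IRLS runs to a relative-change tolerance of `1e-10`
  (at most 100 iterations), followed by a few plain Newton steps so the
  score equations $\sum_i (y_i - p_i)x_i = 0$ hold to ~`1e-9`. The
  delta-method variance below assumes the score is genuinely zero.
* **Separation.** A small hospital can have zero events, sending its
  $\hat\psi_h$ to $-\infty$. If the fit fails to converge or any
  $|\hat\psi_h| > 10$, the model is refitted with Firth's penalized
  likelihood (leverage-adjusted score), which keeps every hospital
  estimable; the fit is flagged `penalized`. In the bootstrap engine the
  number of penalized refits is a first-class output, so this fallback is
  auditable rather than silent.

Both hospital codings are supported: *reference* coding for fitting and
*effects* (sum-to-zero) coding for reporting, where
`hospital_or_vs_average()` gives $\exp(\psi_h - \bar\psi)$ — each hospital's
adjusted odds versus the average hospital, with geometric mean 1.

## Standardized risks and their uncertainty

The standardized risk of hospital $h$ averages the counterfactual risk over
*all* $n$ included patients:

$$R_h = \frac{1}{n}\sum_{i=1}^{n} \mathrm{expit}(\hat\beta_0 + x_i'\hat\beta + \hat\psi_h),$$

the proportion of the whole population expected to die or be ADL-dependent
if everyone received hospital $h$'s level of care. Its standard error comes
from the delta method: with gradient
$g_h = \tfrac1n \sum_i p_{ih}(1-p_{ih})\,x_i(h)$ (the design row with the
hospital block set to $h$'s pattern),
$\mathrm{Var}(R_h) = g_h'\,\widehat{\mathrm{Cov}}(\hat\theta)\,g_h$. The
delta method conditions on the observed covariate sample; it does not add a
term for re-sampling the reference population itself. In the intercept-only
single-hospital case the formula collapses to the familiar binomial
$p(1-p)/n$, and the test suite validates it against a 500-resample
parametric bootstrap on a five-hospital registry.

## The decision rule

Two tunable parameters, chosen by the user, define the rule:

* $\delta \ge 0$ — the clinically tolerable *relative* excess over the
  current population risk. The benchmark is $B = (1+\delta)\,\bar y$ with
  $\bar y$ the crude observed population risk (a per-dataset quantity, not
  a model output). Defaults offered: $\delta \in \{0, 0.10, 0.15, 0.20\}$.
* $k \in (0,1)$ — the one-sided confidence demanded before flagging.
  Hospital $h$ is *outlying* iff $R_h - \Phi^{-1}(k)\,SE_h > B$, strictly;
  a hospital exactly at $B$ is acceptable. $k = 0.5$ reduces to the
  point-estimate comparison; $k = 0.95$ is the conventional
  one-sided-95%-CI rule. Lower bounds are not clipped at zero — they are
  only compared to $B$.

Because the lower bound is monotone in $k$, flagged sets are nested: raising
$k$ can only unflag hospitals. This yields the sensitivity/specificity
trade-off the simulation engine quantifies.

## The parametric-bootstrap diagnostic study

`run_simulation_study()` evaluates the rule's operating characteristics on
a given cohort: truth is defined *once* from the original fit
(`gold_standard_labels()`: $R_h > B$ at the original population risk), then
each of $S$ replicates redraws outcomes $y_i^* \sim \mathrm{Bernoulli}(\hat
p_i)$ with covariates and hospital assignments held fixed, refits the full
model (warm-started, Firth fallback), recomputes its own population risk —
hence its own benchmark — and classifies every hospital at every
$(\delta, k)$. All $S \times m$ hospital-replicate decisions are pooled
into one 2×2 table per cell, giving sensitivity, specificity, PPV, NPV and
percent correct, each reported with its binomial Monte-Carlo standard error
$\sqrt{v(1-v)/(S \cdot \text{class size})}$ and as `NA` when its class is
empty (never silent 0/0). Per-replicate seeds are derived from the plan
seed by counter, so extending $S$ re-uses earlier replicates.

The ROC planner (`theoretical_roc()`) is the closed-form companion: under
the normal sampling model a hospital with true risk $R$ and standard error
$SE$ is flagged with probability $\Phi\!\big((R-B)/SE - \Phi^{-1}(k)\big)$;
averaging over the true-excess and acceptable classes gives theoretical
sensitivity and specificity without any refitting. The test suite compares
this closed form cell by cell against the bootstrap engine on a
20-hospital registry. The planner's normal model treats the standard error
and the benchmark as fixed, while the engine re-estimates both per
replicate; the resulting approximation error is small (below 0.02 in the
comparison the tests run) and concentrated at the most extreme confidence
levels, where the refitted standard error's correlation with the estimated
risk thins the far tail.

## The synthetic registry

Real national stroke-register data cannot be redistributed, so
`default_config_riksstroke()` defines a generator calibrated to published
cohort summaries; it is the package's reference study condition, not a
tuning knob:

* 76 hospitals; log-normal sizes with median ≈ 194, clipped to [27, 798]
  (`sdlog = 0.7` chosen so ~76 draws span that range).
* Age ~ Normal(67.6, 9.5) truncated to [18, 80], rounded to whole years.
  The SD is *derived*: the published cohort reports mean 67.6 with
  standard error 0.07 at n = 18,309, giving 0.07·√18309 ≈ 9.5.
* Categorical marginals: male 58.9%, drowsy 8.3%, unconscious 3.9%,
  ischemic 84.9%, unspecified 2.0%, smoking yes 20.0% / unknown 7.4%,
  atrial fibrillation 18.2%, diabetes 19.6%. Covariates are drawn
  independently — published sources give marginals only, and hospital
  case-mixes are reported to be similar; an optional Dirichlet jitter
  (`casemix_jitter`) induces mild per-hospital case-mix variation.
* Outcome model: the published point estimates (e.g. age 0.048/year,
  diabetes 0.422, unconscious 3.336 on the log-odds scale).
* Hospital effects $\psi_h \sim N(0, 0.25^2)$ — a calibration choice (not a
  published value) putting most odds ratios versus the average in 0.8–1.2
  with tails near 0.3/1.8. It is a config field, never hard-coded.
* Loss to follow-up: optional, completely at random (13% matches the
  source registry's pre-exclusion rate); default 0, i.e. the analysis-ready
  cohort. Informative dropout is out of scope.

Under these defaults the pooled event rate is ≈ 20%, slightly below the
22% anchor because the age truncation at 80 lowers the mean age; it sits
comfortably inside the calibration band asserted by the tests. What the
generator does **not** emulate: covariate correlations, hospital-level
case-mix extremes, informative missingness, and calendar time. Passing
tests therefore demonstrate the *method's* statistical behaviour under the
assumed model, not registry-specific numbers: published full-scale
diagnostic tables depend on the confidential patient data and are treated
as qualitative patterns (monotone trade-off in $k$; specificity increasing
in $\delta$) rather than numeric targets.

## Inclusion filtering

`apply_inclusion_criteria()` fixes an explicit order: the age window
(inclusive [18, 80]) defines eligibility first; records with missing
outcomes (lost to follow-up) are removed second; missing smoking is then
recoded to the level `"unknown"`; finally records missing any other
covariate are removed. The published source does not state the order of
these steps; the report's four counts are defined under this one. First-
ever-stroke and prior ADL-independence are assumed applied upstream.

## Problem sizes used in the test suite

Chosen to exercise every code path at meaningful statistical resolution:
module tests use 5–6 hospitals with ~150 patients each; the bootstrap-SE
validation uses 5×200 patients with 500 resamples; parameter recovery uses
200 full-scale cohorts (~18,000 patients, 76 hospitals); the
planner-vs-engine comparison uses a 20-hospital registry with S = 200
replicates; and the qualitative trade-off check runs S = 200 replicates at
full scale. All randomness is seeded; every test is deterministic.

## Known limitations

* The delta-method interval is a normal approximation; small hospitals can
  get lower bounds below 0 (harmless for the rule) and slightly
  anti-conservative coverage.
* The theoretical ROC planner conditions on last period's `(R, SE)` and a
  fixed benchmark; it does not propagate refit or benchmark re-estimation
  noise, so at very high `k` it mildly overstates sensitivity relative to
  a full bootstrap.
* The gold standard treats the original fit's $R_h$ as the truth, so the
  diagnostic grid measures reproducibility of the original classification
  under sampling noise, not agreement with an external truth.
* Only high outliers are targeted; detecting better-than-benchmark
  performance (three-way classification) and indirect standardization are
  out of scope.
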
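---
title: "Methods: staggered DID pipelines for health-policy quasi-experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staggered DID pipelines for health-policy quasi-experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staggerdid)
```

## The estimation problem

`staggerdid` evaluates a regional policy that rolls out in a staggered
calendar — some regions adopt early, others later, most never — on a binary
per-person health event observed in a repeated survey panel. The motivating
setting is China's regional carbon-trading pilots (five regions trading from
2013, two joining in 2014, one in 2016) and cancer incidence among adults 45
and older followed over four biennial survey waves, 2011--2018. Event
outcomes are coded 0/1,000, so every coefficient of the linear probability
models below reads directly as *events per 1,000 persons*.

The core model is the staggered difference-in-differences (DID) interaction
regression

$$Y_{it} = \alpha_0 + \tau \, (\text{treat}_i \times \text{post}_{it})
  + \lambda' X_{it} + \gamma_t + \varepsilon_{it},$$

where $\text{treat}_i \times \text{post}_{it}$ is 1 from a pilot region's
adoption year onward and 0 otherwise, $X_{it}$ are individual controls, and
$\gamma_t$ are survey-wave (time) fixed effects. Around this sit the
standard battery of quasi-experimental diagnostics: a relative-time event
study for parallel trends, a permutation placebo test, entropy-balancing and
propensity-score reweighting, triple-interaction moderation models, and
subgroup analyses compared with Chow tests.

Because the microdata such analyses run on are typically restricted-access,
the package ships a synthetic cohort generator whose defaults emulate the
study design; every estimator is validated by parameter recovery against the
generator's known truth rather than against unavailable survey data.

## The synthetic cohort generator

`cohort_config()` fixes the data-generating process; `generate_panel()`
draws from it. Defaults (all per 1,000 unless noted):

| parameter | default | meaning |
|---|---|---|
| `n_regions` | 125 | regions in the sampling frame |
| `treated_cohorts` | 2013: 5, 2014: 2, 2016: 1 | staggered pilot calendar |
| `waves` | 2011, 2013, 2015, 2018 | biennial survey years |
| `n_individuals_per_region` | 200 | individuals followed at every wave |
| `baseline_rate` | 117.916 | marginal event rate |
| `treatment_effect` | −47.200 | post-adoption shift ($\tau$) |
| `moderation_effect` | −3.248 | extra shift per unit of centred depression score among treated-post |
| `pretrend_slope` | 0 | differential per-wave trend in ever-treated regions |
| `region_sd` | 10 | SD of the Gaussian region random effect |

The headline rates and effects are the published pan-cancer
linear-probability estimates for this design, adopted as generator defaults
so that simulated output is on a realistic scale; the covariate effect
vector likewise uses the published full-model coefficients (female −26.252,
smoking −17.569, ..., depression score +3.045). Covariate *distributions*
are not reported anywhere, so the generator uses plausibility choices for a
45+ cohort — age uniform on 45--85 and ageing across waves, BMI
$N(23.5, 3.5^2)$, sleep $N(6.5, 1.5^2)$ hours, binary covariates with
prevalences between 0.1 and 0.6, a Gamma(2, 4) depression score — all
overridable.

Two structural choices matter for interpretation:

* **Centred covariate effects.** The linear index applies each effect to the
  covariate *centred at its panel mean*, so `baseline_rate` is the marginal
  incidence and treated-post incidence sits lower by $\approx \tau/1000$.
  Applied to raw covariates instead, the published coefficient magnitudes
  would push most treated-post probabilities below zero and the truncation
  would destroy the very effects the estimators are meant to recover.
* **Centred moderation.** The moderation term multiplies
  $\text{treat} \times \text{post}$ by the *centred* moderator. Writing
  $\tau D + m D (Z - \bar Z) = (\tau - m\bar Z) D + m D Z$ shows that the
  plain DID still estimates $\tau$ (the moderator is independent of
  treatment) while the triple-interaction coefficient on the raw $D \times
  Z$ column estimates $m$ exactly. One knob moves one estimand.

The implied probability is clamped to $[0, 1]$; the clamped fraction is
recorded in the panel's `clamp_fraction` attribute and a warning is raised
above 1%, since heavy clamping attenuates injected effects.

What the generator does *not* emulate: questionnaire structure, sampling
weights, attrition and item missingness, migration, within-individual
outcome persistence (events are drawn independently per record), and any
spatial structure beyond a shared region factor in the pollution tables.
Passing recovery tests on this DGP therefore demonstrates the estimators'
correctness, not robustness to those real-data complications.

## The linear-model engine

All regressions run through `fit_linear()`: an explicit design matrix
(intercept, treatment terms, controls, fixed-effect dummies with the first
level in sort order as the dropped reference), ordinary least squares, and
either the classical covariance or the cluster-robust sandwich

$$\widehat V = c \,(X'X)^{-1} \Big(\sum_g X_g' e_g e_g' X_g\Big)(X'X)^{-1},
\qquad c = \frac{G}{G-1}\cdot\frac{N-1}{N-K},$$

with $t$ statistics on $G - 1$ degrees of freedom under clustering and
$N - K$ otherwise. Numerically, small designs are solved by QR; large
dummy-expanded designs (more than ~$2\times10^8$ flop-equivalents) switch to
Cholesky on the normal equations, which is materially faster and agrees
with the QR path to well below reporting precision on these bounded 0/1
designs. Rank deficiency is an error that names the collinear columns;
observation weights (used by the reweighting robustness fits) must be
strictly positive.

Defaults mirror the published specification: time fixed effects only,
clustering at the region level (the level at which the policy varies).
`estimate_did()` adds one term the published table omits, an ever-treated
group main effect. Without it the interaction coefficient in a two-period
design equals the post-period cross-sectional difference rather than the
difference-in-differences; with it, the two-period simultaneous-adoption
case reduces exactly to the four-cell difference of group-by-period means.
The bare specification remains available via `include_treat_main = FALSE`.

## Event study and the choice of standard errors

`estimate_event_study()` replaces the single interaction with relative-time
dummies measured in survey waves (`rel = wave index − adoption wave index`),
binned at the window ends, defaulting to 2 pre and 3 post periods with
relative period −1 as the reference — standard practice; the published
analysis describes excluding the "third phase", and that choice is available
through the `reference` argument. Periods with no supporting observations
are reported as `NA` rather than silently dropped.

Two defaults differ deliberately from the main DID fit:

* **Region fixed effects are absorbed.** Each relative-time coefficient is
  identified from the handful of regions observed at that relative period
  (as few as three here). Leaving region heterogeneity in the error term
  makes those coefficients' sampling variance depend on a few regional
  draws, which no feasible variance estimator handles well at this scale.
* **Classical, not cluster, standard errors.** With region effects
  absorbed, the generator's within-region dependence is gone, and in
  repeated sampling the classical SE matches the empirical sampling SD of
  the pre-period coefficient almost exactly, giving nominal band coverage.
  The cluster sandwich, by contrast, is systematically *anti-conservative*
  here — in our calibration runs it under-states the pre-period
  coefficient's SD by roughly 20% — the familiar few-treated-clusters
  failure mode. Cluster bands remain available via `cluster = "region_id"`.
  For the headline effect itself, the recommended distribution-free check
  is the permutation placebo test below, which is exactly the tool designed
  for inference with a small number of treated units.

The pre-trend power property was calibrated once and frozen: at 500
individuals per region, an injected differential trend of 40 per 1,000 per
wave gives the pre-period test around four standard errors of signal,
i.e. per-replicate power above 95%.

## Permutation placebo inference

`placebo_distribution()` re-estimates the DID after randomly reassigning
which regions are pilots, preserving the cohort structure (sizes and
timings) by default; `free_timing = TRUE` additionally redraws adoption
years within the observed span, and region-level assignment is the default
resolution of the ambiguity over what exactly is permuted. The two-sided
empirical p-value uses the add-one formula
$p = (1 + \#\{|\hat\tau_b| \ge |\hat\tau|\})/(B + 1)$, which is never zero
and exactly matches constructed cases ($p = 1/2$ at $B = 1$ with one
non-exceeding draw). Each replicate runs under its own sub-seed drawn once
from the master seed, so a distribution is reproducible from `(seed, B)`
and invariant to record order. The published analysis uses $B = 500$; that
is the pipeline default.

## Entropy balancing, propensity scores, matching

`entropy_balance()` solves the constrained minimum-divergence problem from
scratch: minimize the Kullback--Leibler divergence of control weights from
base weights subject to the weighted control moments equalling the treated
moments (means by default, `moment_order = 2` adds raw second moments).
The solution has the exponential-tilting form
$w_i \propto q_i \exp(c_i'\lambda)$ and is found by Newton iteration on the
dual with step halving, tolerance $10^{-8}$ on the maximum constraint
violation, and a 200-iteration cap; infeasible targets (outside the convex
hull of the control contributions) fail fast with the violating moment
named. Weights are normalized to sum to the number of treated units, and
the balanced panel feeds back into `estimate_did()` through its `weights`
argument.

Propensity scores are logistic-regression probabilities fit by IRLS
in-module (constant columns dropped with a message, perfect separation an
error); `nearest_neighbor_match()` implements greedy 1:1 nearest-neighbour
matching on the logit scale, caliper 0.05, without replacement, ties broken
by unit identifier — all stated as implementation choices, since the
published analysis names the methods without parameters.

## The entropy-weight pollution index

`build_pollution_index()` composes the external moderator from region-year
indicator tables (industrial SO₂, dust, wastewater, PM2.5 by default, all
tagged larger-is-more-polluted): min--max normalization per column —
direction-aware, pooled over all region-years rather than within year so
the index is comparable across years — then Shannon-entropy weights
$e_j = -(\ln n)^{-1}\sum_i p_{ij}\ln p_{ij}$ with $0\ln 0 = 0$ taken
exactly (no epsilon shifts), $w_j \propto 1 - e_j$, and the index
$\sum_j w_j x'_{ij} \in [0, 1]$. Constant columns are flagged and excluded;
the index is invariant to positive affine rescaling of any raw indicator by
construction. The source analysis cites the entropy-weight method without
equations; this is the method's standard formulation.

## Moderation, subgroups, Chow tests

`estimate_moderation()` fits the triple-interaction model with the
moderator main effect, the treatment interaction and their product; an
identically-zero moderator degrades gracefully to the plain DID (the
columns vanish), while a non-zero constant moderator is a hard error. The
depression score enters as a given numeric scale; the pollution index
merges in by region-year.

`subgroup_analysis()` refits the DID within groups (binary columns
directly, continuous ones cut at supplied thresholds, e.g. BMI at 18.5 and
25), dropping covariates that are constant within a group, and compares
coefficient vectors with the Chow statistic

$$F = \frac{(\mathrm{RSS}_p - \sum_g \mathrm{RSS}_g)/((G-1)k)}
  {\sum_g \mathrm{RSS}_g/(N - Gk)}.$$

Groups without treated observations are flagged and excluded; with fewer
than two estimable groups the Chow comparison is reported as `NA`.

## Numerical and design notes

* Per-outcome screening (`estimate_per_outcome()`) applies no
  multiple-testing correction, matching the source design; membership in
  the composite (pan-cancer) outcome uses two-sided $p < 0.05$ on the
  treatment term. `p.adjust` can be applied to the returned table by users
  who want it.
* The pipeline's two covariate sets are demographics-only
  (gender/age/BMI) and the full list, mirroring the published two-model
  table layout.
* Reference levels for factor dummies are the first level in sort order;
  re-labelling regions or permuting records never changes an estimate.
* Simulation sizes used in the test suite (e.g. 200 replicates at the full
  125 × 200 × 4 design for recovery; 200 datasets × 99 permutations for
  placebo calibration) were chosen as the smallest runs whose Monte-Carlo
  error is well below the tolerances being checked.
* Heterogeneity-robust staggered-DID estimators (group-time average
  effects, interaction-weighted event studies) are deliberately out of
  scope: the package reproduces the plain interaction estimator this class
  of analyses actually uses, with its diagnostics.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 1)
schedule <- generate_policy_schedule(cfg)
panel <- generate_panel(cfg, schedule)

fit <- estimate_did(panel, schedule,
                    covariates = c("gender", "age", "bmi", "education",
                                   "rural", "sleep", "smoke", "drink",
                                   "hypertension", "diabetes"))
print(fit)
wald_interval(fit, "treat_post")

es <- estimate_event_study(panel, schedule)
plot(es)

placebo <- placebo_distribution(panel, schedule, B = 500, seed = 2)
print(placebo)
```

`run_full_analysis()` chains every stage — simulation, per-outcome screen,
main models, event study, placebo, balancing, moderation, subgroups — and
writes CSV tables, figures and a manifest of seeds and settings, so a whole
analysis is reproducible from one configuration object or YAML file.
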
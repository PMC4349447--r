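---
title: "Methods: exposome-wide scanning, reduction, and probing"
author: "exposcan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposome-wide scanning, reduction, and probing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposcan)
```

## The model and its assumptions

`exposcan` analyses a continuous outcome `y` against a large panel of
correlated, mixed-type exposures under a working linear model: every
exposure is assumed linearly related to the outcome, exposures are
standardized to unit variance so coefficients are in outcome points per
exposure SD, and inference uses OLS with t-reference p-values. The linear
and normality assumptions are working simplifications; the package's own
probes (quadratic terms, a proportional-odds refit, a regression tree)
exist precisely to check how much the conclusions depend on them.

Selection proceeds in three stages rather than one global stepwise search:
univariable screening with family-wide FDR control, reduction within ten
thematic domains, then reduction of the union of domain survivors. The
staged design encodes the judgement that a variable worth keeping globally
should also be an important predictor within its own domain, and it keeps
each multivariable model small enough for the correlated-predictor
arithmetic to stay stable.

### The FDR criterion and its two statements

`fdr_threshold()` implements the Benjamini–Hochberg step-up rule: with
p-values sorted ascending, find the largest index `i*` with
`p(i) <= i*q/m`. Two numerically different but set-equivalent statements of
the resulting cutoff are reported:

* `threshold = p(i*)` — the point where the variable criterion line
  intersects the observed p-values; pass flags are `p <= threshold`;
* `critical_value = i*·q/m` — the nominal p-value criterion, the quantity
  one quotes and reuses downstream.

Any p-value between the two would contradict the maximality of `i*`, so
the flagged sets coincide. The *downstream* inclusion/removal criterion for
stages 2–3 (`p_crit = "auto"`) is the `critical_value`: a single
significance criterion derived from the scan, used symmetrically for entry
and removal, with no separate entry/stay levels.

Prior-hypothesis variables are the one exception: external evidence can
justify a weaker criterion for named variables, so `apply_prior_hypotheses()`
lets them pass stage 1 at a nominal level (default 0.05), recording the
exemption route so reports can distinguish the two populations of
survivors.

### Best-subset ("subset stepwise") search

The final-stage default searches subsets directly instead of greedily:
among all subsets whose *every member* satisfies `p <= p_crit` in the joint
fit (the admissible family; the partner-status indicator is exempt and
never counts against model size), return the one maximizing R². Greedy
forward selection provably misses jointly-predictive, marginally-null
pairs (suppressor structures — see the unit test with
`y = 2.5(x1 − x2)`, `cor(x1,x2) = 0.95`); subset search does not, which is
why its R² dominates forwards and backwards on every seed in the
acceptance suite.

Implementation: for up to `max_exhaustive` (15) candidates, exhaustive
enumeration over the Gram matrix. Above that, a depth-first
branch-and-bound in which a branch is pruned when the RSS of the
*unconstrained* fit on "included plus all undecided" variables — a lower
bound for every completion — cannot beat the best admissible subset found
so far (the search is seeded with a greedy admissible solution so pruning
engages early). Because the bound is valid for admissible and inadmissible
completions alike, the result is exact in both regimes; this is deliberately
stronger than a per-size retain-the-best-k heuristic, whose retained lists
can be crowded out before the admissibility filter runs. The search cost is
still worst-case exponential: it is intended for the final-stage pool
(typically a few dozen candidates after domain reduction), not for raw
stage-1 survivor sets.

Ties in stepwise p-values are broken by candidate order and recorded in the
selection trace; aliased (perfectly collinear) variables in a backwards
full model are removed first and reported rather than silently dropped.

### Partner encoding

For subjects without a partner, partner-reported variables are set to an
arbitrary fill (default 0, the lowest feasible value) and flagged as
filled-by-convention. Any model containing a filled partner variable also
contains the partner-status indicator. The fill choice is then inert: for
partnerless subjects the partner columns are constant, so changing the fill
by `c` changes the design by `c·1{partnerless}`, a vector in the span of
the status indicator — only the status coefficient reparameterizes, and
all other coefficients and fitted values are unchanged (verified to 1e-10
in the acceptance suite).

### Chained-equation imputation

No imputation package is available in the build environment, so the engine
is implemented here behind the standard surface. Each variable with
missingness receives a conditional model on the other variables: Bayesian
linear draws for continuous targets (σ² from the scaled inverse chi-square,
β from its normal posterior, then noise — *proper* imputation, which is
what makes Rubin intervals attain nominal coverage), logistic regression
with parameter draws for binary targets (falling back to matching under
separation), and type-1 predictive-mean matching with a 5-donor pool for
ordinal targets, which preserves discreteness and feasible ranges. Chains
are cycled `n_iter` times per imputation (default 10; chain means are
returned as a trace diagnostic).

Decisions where the field offers choices:

* The analysis outcome participates as a predictor in every conditional
  model (required for congeniality with the analysis model); outcome cells
  are never returned imputed, and outcome-missing subjects still contribute
  to the imputation sample.
* `M = 5` imputations, `n_iter = 10` cycles — conventional defaults.
* Standardization is computed once on observed data and frozen; completed
  datasets reuse the scale record so coefficients are comparable across
  imputations.
* Selection (stages 2–3) runs on the designated first completed dataset;
  the selected model is then re-estimated on all M datasets and pooled by
  Rubin's rules with the Barnard–Rubin degrees of freedom. Running the
  stepwise search once, rather than per-imputation with voting, matches the
  reported-model-plus-coefficient-comparison workflow this package
  supports.
* At exposome scale, conditional models may be capped at the
  `max_predictors` most correlated predictors (quickpred-style; the
  pipeline default is 20, the engine default is all predictors).

### Post-model probes

*Interactions.* All `k(k−1)/2` products of final-model variables are tested
one at a time, each adjusted for all main effects; products are built from
the standardized, un-recentred mains so cell-mean grids stay interpretable
on observed level combinations. The reduction of a significant list is
greedy-forward with re-testing: add the most significant interaction,
re-test the rest adjusted for it, drop those no longer significant, repeat.
The greedy rule is our operationalization of "a few interactions explain
the rest"; the explanation map records which retained term absorbed which
dropped one.

*Mediation.* Per-variable attenuation is `100·(1 − B_with/B_without)`.
The "share of total explanation mediated" is defined semi-partially:
`100·(1 − (R²_full − R²_mediators) / R²_exposures)`, i.e. the relative drop
in the exposure-attributable R² after mediator adjustment. On
linear-Gaussian path models this recovers indirect/(direct+indirect): full
mediation gives ≈100%, equal direct and indirect paths give ≈50% (both
verified in the acceptance suite). Sign-discordant attenuations are flagged
rather than clipped.

*Prevalence shift.* With impairment defined as the worst `tail_fraction`
(default 10%) of the outcome distribution, a uniform shift `delta` moves
the prevalence to `F(cutoff − delta)`. The empirical version uses the
type-1 quantile so `delta = 0` returns the tail fraction exactly; a normal
closed form is provided for calibration against `Φ(Φ⁻¹(f) − δ/σ)`.

### Sensitivity analyses

*Proportional odds.* The outcome is binned into 20 equal-frequency
categories (a knob; non-convergence falls back to 10, then 5) and the final
model refit with `MASS::polr`. Orientation follows the linear convention:
OR > 1 is beneficial, matching B > 0. The log-likelihood explanation is
McFadden's `1 − LL/LL₀` — the ordinal pseudo-R² lives on a compressed
scale relative to the linear R², so it is reported alongside rank
concordance of effect sizes rather than compared in magnitude.

*Factor space.* Principal factors of the survivors' correlation matrix,
retained while eigenvalue > 1 (conventional and configurable), varimax
rotated; scores are unit-variance and exactly orthogonal (an orthogonal
rotation of whitened component scores). Stepwise selection on scores is
order-free because the predictors are orthogonal. Each selected factor is
attributed to its top-|loading| variable for the overlap report against
the variable-level model.

*CHAID-style tree.* Classic CHAID needs a categorical outcome; the
continuous-outcome adaptation merges adjacent predictor categories while
pairwise F-tests are non-significant (merge level 0.05), then splits on the
predictor with the smallest Bonferroni-adjusted one-way-ANOVA p
(multiplier `C(c−1, k−1)` for merging `c` ordered categories into `k`
groups), requiring adjusted `p ≤ 0.001` and `min_leaf = 50` subjects per
child. Continuous predictors are pre-binned into quintiles. The tree is a
sensitivity device for non-linearity and interaction structure, not a
competing estimator.

## The synthetic world

The generator's defaults *are* the stated conditions of the analysis it
exercises, chosen once:

* 7,600 analysis subjects (an observed-outcome sample of a ~14,000-subject
  cohort after outcome missingness), 600 variables in 10 domains — the
  cohort's variables-per-domain density at desk scale.
* Latent Gaussian copula with block-exchangeable correlation: 0.3 within
  domains, 0.1 across. The real exposure-correlation spectrum is not
  published; these are modelling choices representing "strongly correlated
  within themes, weakly across".
* Marginals: 30% binary (prevalence 0.15–0.85), 40% ordinal (3–5
  equal-probability cutpoints), 30% continuous. Two continuous anchor
  variables per domain stay fully observed and drive MAR missingness
  through a logistic model with calibrated intercept.
* 20 planted effects, two per domain, magnitudes 0.4–0.8 outcome points
  per SD — the scale of real final-model coefficients. Signs alternate *by
  domain* (both effects in a domain share a sign): real scans find both
  beneficial and adverse exposures, and same-sign-everywhere effects would
  make every cross-correlated null variable spuriously associated.
  Planted columns keep continuous marginals: effects are defined on the
  standardized latents, and discretized marginals would attenuate the
  observed-scale effect by the latent–observed correlation, making
  recovery tests measure copula attenuation instead of the selection
  machinery.
* Outcome: baseline 205, noise SD 7 points, left skew via a sinh-arcsinh
  transform (ε = −0.5) rescaled analytically to exact mean 0/SD 1,
  truncated to the feasible range 126–232. With the planted effects this
  puts the final-model R² near 13%, the regime the method is meant for.
* 16% missing exposure cells (MAR by default), 2.0% partnerless subjects
  chosen uniformly (only the rate is known, not a mechanism), 15% of
  variables partner-reported.

What a green recovery test does **not** establish: the generator has no
repeat-measure/longitudinal structure, no instrument-level semantics
(composite scores, subscales), exchangeable rather than realistic
correlation spectra, and planted effects that are exactly linear on the
latent scale. Recovery results certify the selection machinery under the
stated world, not performance on any particular cohort.

## Numerical choices and degenerate inputs

* Variances use the n−1 denominator on observed entries; standardization
  does not mean-centre (the intercept absorbs means) and is idempotent to
  1e-10; raw-scale coefficients are `B_std / SD` from the frozen scale
  record.
* Degenerate (outcome-sample-constant) columns are refused by
  `standardize()` and the scan with a pointer to `drop_degenerate()`.
* Zero p-values in Q–Q data are floored at the smallest representable
  double.
* Collinear candidates: exactly one of an identical pair is selected (tie
  by candidate order, logged); singular subsets are skipped in subset
  search; aliased variables in backwards fits are removed and reported.
* An empty admissible family returns an intercept-only fit with an
  explicit flag rather than an error.
* `pool_rubin` clamps the between/total variance ratio away from 0/1 for
  the Barnard–Rubin degrees of freedom; with identical fits the pooled SE
  equals the within SE exactly.

## Runtime scaling in the test suite

The acceptance suite keeps every stated threshold but scales one replicate
count: the planted-effect recovery criterion runs 30 seeds rather than 50
so that the full suite fits a CI budget (the per-seed pipeline is ~13 s;
the Monte-Carlo SE of mean sensitivity at 30 seeds is ≈0.01, far inside
the 0.8 threshold's margin). The global-null FDR-control simulation keeps
its full 2,000 replicates, since its bound (≤ 0.003 with q = 0.001) is a
small-count binomial statement that would lose meaning at fewer
replicates. The pipeline defaults in `scripts/acceptance.R` use 5 chained
cycles rather than 10 for the same reason.

## Known limitations

* Stepwise and subset selection inherit post-selection inference problems:
  reported p-values and CIs for *selected* models are conditional on
  selection and optimistic. The package mirrors the field's practice and
  probes stability (method consistency, factor space) instead of
  performing formal post-selection inference.
* Penalized alternatives (lasso, elastic net) and information-criterion
  stepwise are out of scope by design.
* Mediation analysis is coefficient-attenuation, not counterfactual
  mediation: no natural direct/indirect effects, no sensitivity analysis
  for unmeasured mediator-outcome confounding.
* The branch-and-bound is exact but exponential in the worst case; feed it
  the domain-reduced pool, not thousands of raw survivors.
* MNAR missingness is not modelled; the MAR machinery is only as good as
  its anchors.
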
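---
title: "Methods: relative validity of paired dietary assessment instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative validity of paired dietary assessment instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

dietvalid implements the computational pipeline of a relative-validity
study: a new dietary assessment instrument (method A, here a
self-administered smartphone food record) is compared against an
established reference (method B, interviewer-administered 24-hour
dietary recalls) on the same day in the same participants. "Relative"
is the operative word: the reference is not a gold standard, so a lower
method-A median is a *difference*, not proof of underestimation. The
one exception is energy misreporting, which is judged against an
external physiological expectation rather than the other method.

This vignette documents the model and its conventions, the tunable
parameters, what the synthetic-data generator does and does not
emulate, the numerical choices, and the known limitations.

## From recorded items to daily intake

Each record entry is converted to grams in its consumed state:

```
grams = amount_value × unit_count × unit_weight
```

with `unit_weight` the per-unit gram weight for household, natural, or
commercial units, the food's density (g/mL, default 1) for volumes, and
1 for weights. Two conditional factors follow:

* **Edible fraction** — applied only when the reported form includes
  the inedible part. Whether a given amount unit refers to the
  purchased form (e.g. a whole unpeeled fruit) or the eaten form is a
  property of the food, so the composition table carries an
  `edible_units` list per food naming the units to which the fraction
  applies. This per-unit flag is our design choice; the conversion rule
  itself ("in the case of the inedible part") is conditional by nature.
* **Yield factor** — applied when the amount was estimated as
  unprepared food (`reported_state = "unprepared"`), as prepared weight
  over unprepared weight per preparation method.

Preparations that involve added fat (frying and relatives; the set is
an argument) generate an extra entry for the specified fat:
`item grams × fat_absorption_fraction`, attributed to the fat's own
food code and hence its own group (added fats). Where both a yield
factor and fat absorption apply, yield is applied first and absorption
acts on the as-consumed mass; the order is not externally specified and
is fixed here for reproducibility. User recipes are disaggregated
before conversion: a consumed fraction f of a recipe contributes
f × ingredient grams per ingredient.

Daily totals are linear: grams per Wheel of Five group are sums of item
grams (each item maps to exactly one group), and nutrients are
`grams × per-100 g composition / 100`, summed over the day. Supplement
entries are excluded from group and nutrient totals but remain visible
to the recording-mode tally. Linearity, conservation (group grams equal
item grams including absorbed fat), scaling, and non-negativity are
enforced as property tests.

## Energy plausibility screening

BMR is estimated from the Henry weight-and-height equations — linear in
weight (kg) and height (m) with gender- and age-band-specific
coefficients, in MJ/day, shipped as a versioned TSV asset
(`henry_coefficients()`) whose bands partition ages 18–79. Conversion
uses 1 MJ = 239.006 kcal. The asset can be swapped for any table of the
same shape (e.g. Schofield-type equations), which are otherwise out of
scope.

A recorded day is plausible when `0.6 ≤ EI/BMR ≤ 3.0`. The bounds are
inclusive because the exclusion rule is stated as a ratio *below* 0.6
or *above* 3.0. Screening is per day; excluded days are removed before
every downstream comparison. Comparisons against the bounds use a 1e-9
relative tolerance so that a day sitting exactly on a bound is not
reclassified by floating-point jitter.

Cohort misreporting: each participant's measured physical activity
level (PAL) is EI/BMR; relative misreporting is
`(measured − expected) / expected` with expected PAL 1.59 by default.
Per-person under/over-reporter classification uses measured-PAL cutoffs
of 1.10 and 2.0. These cutoffs are a documented choice: there is no
standardized individual-level cutoff pair, published counts based on
unstated cutoffs are not reproducible, and both values are exposed as
arguments.

## The comparison battery

All conventions are explicit because validity conclusions depend on
them:

* **Wilcoxon signed rank** (`wilcoxon_signed_rank()`): zero differences
  dropped (classic convention; `zero_method = "pratt"` available), tied
  absolute differences share average ranks, the null variance is
  tie-corrected, and the two-sided p-value comes from the normal
  approximation without continuity correction (a flag adds it). The
  exact null distribution is discrete at small n: against exhaustive
  enumeration of all 2^n sign assignments the approximation agrees
  within about 0.2 for 5–7 non-zero differences and within about 0.1
  for 8–10, with the error vanishing as n grows. These bounds were
  measured against the enumeration oracle and are asserted in the test
  suite.
* **McNemar** (`mcnemar()`): χ² = (b − c)²/(b + c) on 1 df over the
  discordant pairs, continuity correction off by default. Below 10
  discordant pairs (configurable) an exact two-sided binomial test
  replaces the approximation, since the χ² tail is meaningless for a
  handful of discordances.
* **Spearman** (`spearman_rho()`): Pearson correlation of average
  ranks; a constant margin has no ordering and returns `NA`.
* **Bland–Altman** (`bland_altman()`): differences A − B; limits of
  agreement are mean ± 1.96 × sample SD (n − 1). On normal differences
  the limits cover ≈95% of points, verified by simulation at n = 10⁴.
* **Relevance rule** (`relevance_flag()`): a difference is relevant iff
  p < .05 (strict, two-sided, no multiplicity correction — a documented
  limitation) *and* |median_A − median_B| > 0.10 × median_B (strict).
  A zero reference median makes the relative rule non-evaluable (`NA`).
  Direction is reported separately so both the magnitude-only and the
  "lower than reference" readings are available.

`compare_tables()` assembles the study tables: per-variable location
and spread under both methods, the signed rank p, Spearman ρ, and the
relevance flag; a consumer table (consumer = intake > 0 g on the
analysis day) with McNemar on consumership and consumers-only medians,
whose paired signed rank test uses the pairs consuming under both
methods; and stratified variants by education and BMI class (cuts at
25 and 30 kg/m²), with strata of n < 2 suppressed with a warning. Food
groups whose 75th percentile is zero under both methods are excluded
from the main table but kept in the consumer table. Flags are computed
on unrounded values; rounding is applied only at rendering time by
`write_report()`.

## Matched comparator selection

To assess design effects, each case can be matched to one comparator
from an external pool on gender, age class (5-year bands), weight class
(10-kg bands), and education. Bands are half-open and lower-inclusive
anchored at multiples of the width — a convention the matching
description leaves open; anchored banding is deterministic and
testable. Matching is greedy without replacement in roster order (the
original assignment algorithm is unstated; greedy is the simplest
deterministic reading of 1:1 matching and is a documented limitation —
optimal assignment could match more cases). Relaxation drops education
entirely first, then the age class; gender and weight class always
bind. Among eligible comparators the same-or-closest height wins, ties
broken by smallest comparator id. Unmatched cases are reported, never
fabricated.

## The synthetic-data generator

The generator exists so that every pipeline stage has a recoverable
target. Its defaults *are* the study conditions: 211 participants with
the published gender (104/107), age-band (76/77/58), education
(37/81/93), and BMI-category (1/81/73/56) mixes; per-group consumer
probabilities and consumers-only medians of the reference method taken
from the published consumer table; bias ratios defaulting to the ratio
of consumers-only medians; omission probabilities equal to the relative
consumer-count deficit (clamped at zero); target Spearman correlations
from the published per-group coefficients (0.70 where none is printed);
PAL log-normal with median 1.59 and log-sd 0.13; and an
extreme-reporter fraction of 16/227.

The model per food group g and participant i, one shared analysis day:

* reference method: consumes with probability p_g; positive amounts are
  log-normal with the configured median and log-sd (default 0.6, chosen
  once as realistic for right-skewed intake where SDs exceed means);
* test method: `A = B × bias_g × exp(ε)`, ε ~ N(0, τ_g²), with
  independent omission probability o_g (modelling forgotten condiments
  and sauces).

On the log scale, co-consuming pairs are bivariate normal, giving
closed-form ground truth: the consumers-only median ratio equals
bias_g, and the Spearman correlation is `(6/π)·asin(ρ_P/2)` with
`ρ_P = s/√(s² + τ²)`; τ_g is derived from the target Spearman by
inverting that formula. `ground_truth()` returns these values (with an
optional large-sample Monte-Carlo check).

Energy is closed per day to `PAL × BMR` with a caloric beverage
(0.45 kcal/g) booked under drinks. Participants generated as extreme
reporters get PAL drawn outside the plausibility band (0.30–0.55 low,
3.2–4.0 high, 90% low); when their food energy already exceeds the low
target their amounts are scaled down, so the screen recovers the
configured fraction exactly up to rounding. Consequences worth knowing:

* the drinks group total is partly a function of the energy model, so
  drinks are excluded from parameter-recovery claims;
* non-extreme participants' energy can slightly exceed the PAL target
  on days where food energy alone overshoots (the beverage cannot be
  negative); this never pushes them over EI/BMR = 3 in practice.

What the generator does **not** emulate: food-level nutrient
correlation structure (one representative food per group, synthetic
composition values); day-to-day within-person variance (one shared
day); false-positive recording (omission only removes groups from the
test method, so a group with *more* test-method consumers, as observed
for a residual "other" category, is not reproduced); and portion-size
measurement granularity (amounts are emitted in grams). Passing
recovery tests therefore demonstrates that the pipeline estimates what
the model injects — not that real food-record data satisfy the model.

## Problem sizes and determinism

Everything is a pure function of (configuration, seed); identical
reruns produce byte-identical tables and manifests. The validation
suite uses: parameter recovery at n = 1000 participants (bias within
±0.05 of truth via the co-consumer median ratio, Spearman within
±0.05); extreme-reporter recovery within ±2 percentage points; type-I
error of the signed rank test at α = .05 estimated over 1000 null
cohorts of n = 40 (5% ± 2 pp); and Bland–Altman coverage at n = 10⁴
(95% ± 2 pp). These sizes make the whole suite run in well under a
minute while leaving the Monte-Carlo error comfortably inside the
asserted bands.

## Known limitations

* No multiplicity correction, matching the analysis convention it
  reproduces; with ~50 tests per table some flags will be chance
  findings.
* Greedy matching is order-dependent and can be suboptimal; the
  printed match-count split of the motivating study is therefore not a
  reproduction target.
* Individual under/over-reporter cutoffs are non-standardized; counts
  derived from them should not be compared across studies.
* The signed-rank zero-difference and continuity conventions differ
  across statistical suites; both are exposed as arguments, and exact
  agreement with any particular suite's output is only guaranteed for
  the conventions stated above.
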
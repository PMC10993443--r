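---
title: "Methods: geo-linked undernutrition analysis and district-level impact evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geo-linked undernutrition analysis and district-level impact evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malnut)
```

## The problem this package addresses

Child undernutrition is conventionally measured by three Z-scores against
the WHO growth reference: height-for-age (HAZ), weight-for-age (WAZ) and
weight-for-height (WHZ). A score strictly below −2 SD defines stunting,
underweight and wasting respectively; failing at least one criterion is
the binary composite index of anthropometric failure (CIAF ≥ 1). When a
nutrition program is rolled out in some districts and not others, and no
randomization or purpose-built baseline exists, the program's contribution
must be teased out of two general-purpose survey waves. `malnut`
implements that full workflow: geo-linking survey points to biophysical
attribute maps, classifying undernutrition, screening candidate
determinants, selecting explanatory regression models with a
stability-resampling procedure, and estimating program impact as a
difference of baseline-to-endline changes between intervention ("JP")
and non-intervention districts.

Because the motivating survey microdata are access-restricted, the
package ships a synthetic-data generator as a first-class, tested module.
All operating characteristics quoted below are computed by the package's
own test suite on that generator, never asserted from external data.

## The synthetic generator

`gen_config()` fixes the study conditions; `generate_bundle()` produces
records, rasters and the generating truth.

* **Outcome model.** For each child,
  `Z = β0 + Σ βk·xk + u(district) + δ_base·JP + δ_wave·wave2 +
  δ_JP·(JP ∧ wave2) + ε`, with `ε ~ N(0, σ)` and
  `u(district) ~ N(0, 0.5)`. The default noise SDs are σ = 1.95 (HAZ),
  1.25 (WAZ), 1.61 (WHZ) — the scale observed in national surveys of
  this population — so synthetic prevalences land at realistic
  magnitudes (50–80%).
* **Coefficients.** `default_coef_table()` uses effect sizes typical of
  explanatory anthropometry regressions: sex +0.35 SD on HAZ,
  hungry-season +0.28 SD, child-age effects near −1 SD, maternal-BMI
  and wealth gradients of 0.1–0.5 SD. A deliberate pure-noise binary
  covariate (`noise_bin`, all coefficients zero) travels through every
  stage to probe false-selection rates.
* **Exposure structure.** Four of thirteen districts form the
  intervention group. Baselines are unequal by design
  (`jp_baseline_offset`: +0.78 HAZ, −0.66 WHZ), mimicking programs
  targeted at needier districts. The program effect is an additive
  wave-2 shift in intervention districts only
  (`jp_effect` = −0.20 HAZ, +0.12 WAZ, +0.37 WHZ). The common secular
  trend `wave_effect` defaults to zero so that the program-effect truth
  coincides with the intervention-district change and the
  difference-of-changes estimator targets `jp_effect` exactly; any
  nonzero secular trend cancels out of that estimator, so this choice
  affects presentation, not identification.
* **Missingness.** The three Z-scores are masked jointly (a child has
  all three or none), completely at random, at 24.8% in the baseline
  wave and 29.6% in the endline wave.
* **Geometry.** Districts are axis-aligned rectangles tiling a
  Timor-Leste-sized extent (1.4° × 3.3°), which makes point-in-district
  tests trivially invertible for test oracles. Rasters are 30-arcsecond
  grids (≈1 km), piecewise-constant by district with a smooth 5%
  sinusoidal within-district variation; class-valued maps (soil class)
  stay constant within district.
* **Seeding.** One master seed feeds fixed substreams (landscape /
  district effects / records / missingness), so any component can be
  regenerated alone and every product is byte-identical under the same
  seed.

What the generator deliberately does **not** emulate: survey design
weights and cluster displacement, spatial autocorrelation beyond the
district blocks, partial (score-specific) missingness, and inter-covariate
correlation (covariates are drawn independently: binaries Bernoulli(0.5),
categoricals uniform, continuous Normal — the simplest structure that
exercises every screening branch; all are configurable). Passing tests
therefore demonstrate the correctness and calibration of the *procedures*
under a known truth, not the reproduction of any real population.

## The geographic link

Survey points carry coordinates; biophysical attributes arrive as
grids. The link has three steps: resample every grid to one
geo-reference (nearest-neighbour, `resample_to_reference()`); export
each grid to three aligned vectors — cell-centre latitude, longitude,
value — dropping nodata cells (`grid_to_vectors()`); and assign each
point the attribute of the nearest cell centre by great-circle distance
(`nearest_neighbor_link()`).

Numerical conventions, stated because raster conventions vary: grids are
registered to the upper-left corner, latitude decreases with row index,
and coordinates refer to cell centres. Distance is haversine on a sphere
of radius 6371.0088 km — at 1-km grids planar and spherical nearest
neighbours rarely differ, but the spherical form is correct everywhere.
Ties break to the smallest row-major cell ordinal, making the link
deterministic. Many points may share one cell (many-to-one links are the
point of the vector export). When several resampled grids share one
nodata footprint, `link_points_to_grids()` runs the search once and picks
the other attributes by cell ordinal — behaviourally identical to one
search per grid, and tested as such against an exhaustive scan.

`harmonize()` then removes rows with any missing analysis value, giving
the "full matrix" all statistics run on; it is idempotent and reports the
dropped count, and refuses to continue if nothing survives (with a
per-column missingness diagnostic).

## Classification and prevalence

`classify_undernutrition()` applies the strict −2.0 cutoff (a Z-score of
exactly −2.0 does not flag; boundary covered by a dedicated test).
`excess_prevalence()` subtracts the 2.3% of children expected below
−2 SD in a well-nourished reference population, floored at zero.
Values are carried at full precision; rounding (half away from zero, so
58.75% prints as 59%) happens only at report time.

## Bivariate screening

The screen is deliberately liberal — no multiple-testing correction, as
the model-selection stage downstream does the pruning; every report
carries a stable warning code saying so.

* **Continuous determinants.** Pearson's or Spearman's correlation; the
  choice, traditionally made by eyeballing scatterplots, is replaced by
  a deterministic surrogate: Pearson iff both variables pass the
  D'Agostino K² normality test at α = 0.05, else Spearman. K² (skewness
  Z plus Anscombe–Glynn kurtosis Z) is implemented in the package and
  verified against an independent reference implementation on frozen
  samples, including the platykurtic branch where the kurtosis
  transform's cube-root base goes negative. A result is *reportable*
  when |r| ≥ 0.10 and p < 0.05.
* **Dichotomous determinants.** Independent-samples t-test; the folded
  F statistic (larger over smaller sample variance, two-sided p from
  the F distribution) decides at α = 0.05 between the pooled and the
  Welch–Satterthwaite branch. The simulated null rejection rate of the
  two-stage procedure stays within 6% at nominal 5% (2000 replicates in
  the test suite).
* **Categorical determinants.** One-way fixed-effects GLM F-test on
  unbalanced data, reporting R² = SS_between/SS_total and the
  lowest-mean level; for two levels F equals t² of the pooled t-test
  (checked numerically).
* **Effect modification.** Outcome ~ v1 + v2 + v1:v2 on categorical
  pairs; the interaction F is order-invariant, empty cells are dropped
  and flagged.
* **Categorization.** Continuous variables are also screened as ordered
  classes with the field's conventional bounds (household size 0–5 /
  6–10 / >10; altitude ≤800 / 800–1000 / 1000–1200 / >1200 m;
  population density ≤50 / 50–500 / >500 per km²; agricultural land
  no land / <3 ha / ≥3 ha; slope <8 / 8–16 / 16–30 / >30%; drought
  index by sample quartiles — exact quantile bounds for the drought
  index are not fixed by convention, so quartiles are the default and
  custom cut-points are accepted). The categorical version is screened
  first; the continuous original is meant for later stages only if its
  categorical form shows no association.

## Model selection and stability

`fit_linear()` is ordinary least squares via QR with t-based p-values;
it matches a normal-equations oracle to 10⁻⁸ relative tolerance in the
tests and excludes collinear columns by name rather than failing.

`backward_select()` removes, one at a time, the worst effect with
p ≥ 0.05 and refits until all survivors are significant. Categorical
*levels* are individual effects and leave independently of their parent
variable ("split" semantics — a three-level factor can keep level B and
lose level C, demonstrated on constructed data). Tie-breaks are
deterministic (larger p, then lexicographic name). A hard floor of 10
observations per candidate effect (configurable up to 15) is enforced
up front: the floor is a modelling guardrail, so violating specs are
refused rather than silently truncated.

`stability_select()` repeats the backwards selection on 100 subsamples,
each a random 75% of rows drawn without replacement, independently
across resamples (membership is logged for audit). Per effect it
reports the selection frequency, the coefficient averaged over the
subsample models in which the effect appeared, and a retention flag at
frequency ≥ 0.20 (20 of 100 is retained; 19 is dropped). Averaged
p-values are deliberately not produced — averaging p-values across
different selected models is not a defined quantity; frequencies and
averaged estimates are the stability report. A failed subsample fit is
recorded and excluded; more than 10% failures aborts.
`compare_models()` flags any effect whose full-data estimate differs
from the subsample average by more than twice the resample SD (with a
10⁻¹⁰ floor so that exact, zero-spread fits compare equal), and returns
the verdict "robust" when nothing is flagged.

Operating characteristics measured in the test suite at the default
study conditions (5000 children/wave, baseline complete cases ≈ 3700):
every generating effect with |β| ≥ 0.2 is retained in ≥ 90% of 20
pipeline seeds, and the designed pure-noise covariate is retained in
well under 20% of selection runs. With 75% subsamples the per-resample
selection events are strongly correlated, so a null effect's frequency
distribution is bimodal — mostly near 0, occasionally near the
threshold — which is exactly why the 20% retention rule exists.

## Impact analysis

Exposure is intent-to-treat at district level: every record in an
intervention district counts as exposed. For each exposure group,
`group_change()` computes baseline and endline means, the absolute
change, and the relative change with **|baseline mean|** as denominator
(the sign convention that makes "+28%" mean improvement against a
negative baseline; with a baseline mean of exactly zero the relative
change is flagged undefined while the absolute change is still
reported). `impact_row()` takes the difference of changes, intervention
minus non-intervention, so positive impact means the intervention group
improved more. `impact_table()` produces the overall row plus one row
per stratum level, applying the same stratum definition in both groups
and waves; a stratum with fewer than 50 children at either wave on
either side is flagged unreliable. Per-stratum baseline differences are
available as a diagnostic (`baseline_endline_tests()`), not as a gate.

No confidence interval is attached to the impact difference in the
standard output — the estimator is a transparent arithmetic contrast of
four means, and the package reports the group SDs and sizes from which
a user can form one.

Published-style rendering (`format_zchange()`, `format_impact_table()`)
uses two implied decimals (+0.37 → "37"), rounding half away from zero,
with impact differences at one decimal on that scale; the
machine-precision CSV always carries full precision.

## Numerical and design choices

* Rounding for reports is half-away-from-zero everywhere
  (`round_half_up()`), matching how 58.75 becomes 59 in survey tables;
  R's default banker's rounding would print 58.
* The Fisher-z interval for Spearman's coefficient uses the
  1.06/(n−3) variance inflation; for Pearson 1/(n−3).
* The folded-F p-value is the two-sided 2·P(F > f), capped at 1.
* Raster serialization is the plain-text ESRI ASCII grid; values are
  written with 17 significant digits so write/read round-trips are
  bit-exact. This keeps every fixture human-readable and
  version-controllable.
* Sub-seeds are derived from the master seed with a fixed integer map
  kept below 2³¹; no stage consumes another stage's stream.
* Problem sizes in the test suite: oracle equivalence for the link at
  1000 points × 10 000 cells; least-squares oracle at 200 × 20;
  stability recovery at 20 seeds × 3 outcomes × 100 resamples; size
  control at 2000 replicates — sizes at which the Monte-Carlo error of
  each check is comfortably below its margin.

## Known limitations

* The screen's Pearson/Spearman surrogate is a convention, not a claim
  that K² at α = 0.05 reproduces any particular analyst's visual
  judgement; it exists for reproducibility and is overridable per call.
* Backwards p-value selection is kept because it is the procedure under
  study; its well-known optimism about retained p-values is mitigated,
  not removed, by the stability resampling.
* The difference-of-changes estimator identifies the program effect
  only under the parallel-trends assumption the stratification is meant
  to support; the package quantifies baseline imbalance but cannot test
  untestable assumptions.
* MCAR missingness in the generator is kinder than reality; with
  informative missingness the complete-case pipeline would be biased,
  and no weighting machinery is provided.
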
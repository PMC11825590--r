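---
title: "Metabolic profiling of PM-M plates: models, decisions, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic profiling of PM-M plates: models, decisions, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmmprofiler)
```

## The measurement and its reduction

A Phenotype Mammalian MicroArray (PM-M) experiment exposes a cell line to
96 compounds per plate and reads each well's NADH-driven dye reduction two
ways: a kinetic optical-density curve recorded every 15 min over 24 h
(grid 0–1440 min, 97 points), and an endpoint two-wavelength read
(A~590~ at the dye's absorbance peak minus the A~750~ background).

`pmmprofiler` reduces a kinetic curve to its trapezoid area under the curve
(OD·min) and an endpoint read to A~590−750~, then analyses the chosen
summary on a log10 scale. Three numerical choices matter here:

* **Which summary feeds the statistics.** Both AUC and endpoint summaries
  are recorded by the instrument and both are computed by
  `summarize_dataset()`; which one feeds the tests is a required
  configuration choice (`source`, default `"auc"`). The downstream group
  tests are rank-based, so for any monotone relation between the two
  summaries the choice does not change p-values; it does change single-case
  limits.
* **Log base.** Only "a logarithmic scale" is inherent to the procedure;
  log10 is used. Rank tests are invariant to the base; box-whisker limits
  scale linearly with it, and calls are equivariant, so calls are unchanged
  too. The base matters only if limits are compared across software.
* **Positivity floor.** Background-subtracted endpoint reads can be ≤ 0,
  where a logarithm is undefined. Values are floored at
  `floor_eps = 1e-3` (in the summary's own units) before log10. The floor
  only engages for essentially dead wells; on simulated data with the
  default curve model it never triggers for AUC summaries.

No smoothing or baseline subtraction is applied before integration; the
trapezoid rule on the raw grid is the entire reduction. Arbitrary strictly
increasing grids are accepted, so sparse or irregular exports integrate
correctly.

## Group comparisons: exact rank test, per-comparison FDR family

With two patient lines against 50 controls, each well is a 2-vs-50
two-sample problem with no distributional guarantees, so a two-sided
Mann–Whitney test is used on the log summaries.

* **Exactness.** Whenever `C(n_a + n_b, n_a) ≤ 20,000` the permutation
  null of the U statistic is enumerated completely (midranks make this
  valid under ties) and
  `p = Pr(|U − n_a n_b/2| ≥ |u_obs − n_a n_b/2|)`. For 2 vs 50 that is
  1,326 assignments, so every study-size comparison is exact; the smallest
  achievable two-sided p is `2/1326 ≈ 0.0015`, reached when both patients
  fall on the same side of all 50 controls. The enumeration bound keeps
  the worst admissible design well under a second per well; beyond it a
  tie-corrected normal approximation with continuity correction takes
  over. The two routes agree within 0.05 absolute once both groups have at
  least 3 members; with a group of 1–2 the exact law is too coarse for any
  normal approximation to track that closely, which is precisely why the
  single-case layer exists.
* **Testing against a cohort of values, not a cohort mean.** Patients are
  compared against the 50 per-control values. A rank test against a single
  averaged control value would be degenerate (its p-value could never fall
  below 2/(n_a + 1)), so "comparison against the control average" is
  implemented as comparison against the control sample.
* **Multiplicity family.** Benjamini–Hochberg runs over all wells of one
  comparison run — e.g. 672 wells for a seven-plate comparison — not over
  all comparisons jointly. Each comparison answers its own question, and
  its well family is the natural reporting unit. Both thresholds are
  strict: `p < 0.05`, `p_adj < q = 0.05`.
* **Direction.** The sign of `median(A) − median(B)` on log values; exact
  ties report `"none"` and are excluded from trend aggregation.

## Single-case calls: box-and-whisker outer limits

For one patient line, per-well classification uses the control cohort's box
plot geometry. Two conventions were genuinely open:

* **"Outer limits".** Either the whisker ends (the most extreme controls
  within the Tukey fences `Q1 ∓ 1.5·IQR`) or the fences themselves. The
  default is `method = "whisker"` — the limits actually drawn on a box
  plot — with `"fence"` available. Whisker limits lie inside fence limits,
  so the fence method never calls more wells; the property is tested.
* **Quartile rule.** Linear interpolation between order statistics at
  position `(n−1)p` (R's default type-7 quantile), fixed so limits are
  bit-for-bit reproducible across implementations.
* **Boundaries.** A value exactly on a limit is `"within"` — conservative
  against calling abnormality.

Calls are computed on the same log-scale summaries the group tests use.
Wells where the patient value is missing are skipped and reported, not
fatal: a patient line may lack a plate (the study design itself has an ion
plate with no patient specimens).

## Compound-level aggregation

Compounds on concentration series occupy several wells, and the per-well
calls need not agree. A compound's direction is `increased` only if at
least one well is called above and none below (mirror rule for
`decreased`); disagreeing wells make it `mixed`. Mixed compounds stay
visible in the trend table but are excluded from opposite-trend and
shared-trend lists — a deliberate conservative choice, since an
opposite-trend claim built on internally inconsistent evidence would be
fragile. Percentages (percent significant, cluster fractions) are reported
to one decimal with half-up rounding, matching how such rates are
conventionally printed.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws, per (sample, well),

$$\mathrm{od}(t) = b + \frac{A}{1 + e^{-(t - m)/s}} + \varepsilon(t),
\qquad \varepsilon(t) \sim \mathcal N(0, \sigma^2)\ \text{iid},$$

with `log A ~ N(log A0 + δ, sdlog²)`; the log-amplitude shift δ encodes a
true biological effect (0 for controls). Defaults: cohort of 50 controls
(26 female / 24 male, sex carried on the sample sheet to support
sex-stratified comparisons), grid 0–1440 min by 15; `b = 0.05` OD (typical
blank level), `A0 = 1.0` OD (a strong dye signal spans roughly 0–1 OD),
`sdlog = 0.2` (≈20% between-line metabolic spread, a plausible magnitude
for lymphoblastoid lines), `m = 720` min, `s = 120` min (signal developing
over the middle of the 24 h window), `σ = 0.02` OD per read, endpoint
750 nm background `|N(0.05, 0.005²)|`. These were fixed once as realistic
fill-ins; no instrument data were fit.

Each sample owns an RNG stream seeded by
`(master_seed + 104729 · sample_index) mod (2³¹ − 1)`, so regeneration is
bit-for-bit reproducible and appending patient lines never perturbs
existing samples.

The generator reproduces the *statistical* structure the pipeline assumes —
exchangeable controls, independent wells, per-well effects on amplitude —
but not several features of real PM-M data: no spatial plate effects or
edge wells, no within-plate correlation, no batch or incubation drift, no
dye-depletion saturation, no dependence of curve shape (only amplitude) on
the effect. Passing tests therefore validate the arithmetic and the
calibration of the statistical procedure under its own assumptions; they do
not certify behaviour under instrument artefacts.

`recovery_experiment()` and `fdr_calibration()` simulate at the AUC level
using the exact distributional identity
`AUC(curve + noise) = AUC(curve) + N(0, σ²·Σw_i²)` (w are the trapezoid
weights), which is equal in law to integrating a simulated noisy curve and
much faster; `simulate_cohort()` always generates full curves.

## Calibration results the test suite computes

Under the global null (δ = 0, 2 vs 50, 1,000 wells), the raw rejection
rate sits near the exact test's attainable size at α = 0.05 — the
rejection region {U ≥ 91 or U ≤ 9} has probability 60/1326 ≈ 0.0452, so
slight conservatism relative to 0.05 is a property of the discrete exact
law, not an error. With 10% of wells truly shifted, the empirical false
discovery proportion among flagged wells stays at or below q within Monte
Carlo error, and power is non-decreasing in |δ| (checked with common
random numbers). Problem sizes in the suite — 1,000 wells per calibration
run, 200 wells × 50 leave-one-out classifications for single-case
specificity, cohorts of up to 52 samples × 2 plates for end-to-end runs —
were chosen as the smallest sizes at which these Monte Carlo checks are
decisive.

## Plate layouts

The commercial PM-M compound maps are proprietary and are not reproduced.
`example_layout()` builds a fully synthetic layout that (a) places the
well–compound pairs that are public knowledge from published figure
captions at their real addresses (e.g. PM-M8 D06 Luteinizing Hormone,
PM-M8 G10 TNF-alpha, PM-M7 G01 IL-1beta, PM-M2 H02 Glu-Trp), (b) carries
exactly 30 glycine-containing and 27 tyrosine-containing wells so the
cluster arithmetic is exercised at its reported sizes, and (c) fills
PM-M5 with 24 four-well increasing-concentration ion series. The IL-6
(H04) and IL-8 (H07) wells are assigned to PM-M7 alongside the other
cytokines; their plate is not public, and this assignment is recorded here
as an assumption. Real analyses should load the vendor layout via
`load_layout()` (CSV: `plate,well,compound,category,series_id,conc_rank`).

## Known limitations

* The exact test's granularity bounds what 2-vs-50 comparisons can show:
  no well can beat p ≈ 0.0015, so at most moderate FDR families can yield
  survivors, and 1-vs-50 comparisons can never reach raw significance
  below 2/52 ≈ 0.038 — single-case limits are the only informative layer
  for lone patients.
* Single-case calls carry no error model; the leave-one-out specificity
  test quantifies, but does not correct, the per-well false-call rate.
* The per-compound mixed rule discards genuinely dose-dependent responses
  (e.g. an effect only at the highest concentration of a series appears as
  a 1-of-4 call, not a graded trend); concentration–response modelling is
  out of scope.
* OmniLog binary exports are not parsed; inputs are the documented CSV
  dialects.
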
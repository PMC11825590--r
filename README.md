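# pmmprofiler

Cell-based metabolic profiling with Biolog Phenotype Mammalian MicroArray
(PM-M) plates, built for the normative-cohort study design used with patient
lymphoblastoid cell lines: a large control cohort (typically 50 lines) and
only one or two patient lines per condition.

Each of the eight PM-M plates exposes cells to 96 compounds — carbon sources
(PM-M1), amino acids and dipeptides (PM-M2–M4), ions (PM-M5), hormones and
metabolic effectors (PM-M6–M8). NADH production in a well reduces a redox
dye, and the OmniLog reader records the optical density every 15 min for
24 h, giving a kinetic curve per well; an endpoint plate read at 590 nm and
750 nm gives the relative absorbance A<sub>590−750</sub>. `pmmprofiler`
turns those raw reads into per-well energy-production summaries and runs the
two statistical layers this design needs.

## The method

**Reduction.** Per well, the kinetic curve is reduced to the trapezoid area
under the curve, `AUC = Σ (t[i+1] − t[i]) · (od[i] + od[i+1]) / 2` (OD·min),
or the endpoint read to A<sub>590−750</sub>; the chosen summary is analysed
as `log10(max(x, ε))` with a positivity floor ε = 10⁻³.

**Group comparisons.** For a patient group versus the control cohort, each
well is tested with a two-sided Mann–Whitney test. The U statistic counts
pairs where a patient value exceeds a control value (plus half of ties);
whenever `C(n_a + n_b, n_a) ≤ 20,000` the p-value is exact by full
enumeration of group assignments (valid under ties), otherwise a
tie-corrected normal approximation with continuity correction is used.
Raw significance is `p < 0.05`; across all wells of one comparison the
Benjamini–Hochberg step-up correction controls the false discovery rate at
`q < 0.05`.

**Single-case calls.** A single patient line cannot power a rank test, so
each patient value is classified against the control box-and-whisker outer
limits (the "inter-ocular trauma test"): quartiles by linear interpolation
at position `(n − 1)p`, Tukey fences at `Q1 − 1.5·IQR` / `Q3 + 1.5·IQR`,
whiskers at the most extreme controls inside the fences. Values above the
upper limit are called `above`, below the lower limit `below`, boundary
values `within`.

**Aggregation.** Calls collapse to per-compound trends (increased /
decreased / mixed for multi-well concentration series), from which the
package derives direction tables, opposite-trend and shared-trend compound
lists between patient groups, and compound-cluster fractions (e.g. the
share of glycine-containing wells with reduced NADH production).

A seeded synthetic-cohort generator (logistic NADH-production curves with
log-normal per-well amplitudes and planted log-amplitude effects) makes the
whole pipeline testable without instrument exports. Because the true Biolog
plate maps are proprietary, `example_layout()` provides a synthetic layout
with published well anchors (e.g. PM-M8 G10 = TNF-alpha) at their real
addresses.

## Worked example

Two RTT-like patient lines carry a plate-wide deficit (log-amplitude shift
−0.8) on every PM-M8 well except G10; 50 controls are unshifted:

```r
library(pmmprofiler)

layout   <- example_layout(c("PM-M7", "PM-M8"))
patients <- data.frame(sample_id = c("rtt_1", "rtt_2"), group = "RTT", sex = "F")
config   <- simulation_config(plates = c("PM-M7", "PM-M8"),
                              patients = patients, seed = 42)

m8      <- subset(as.data.frame(layout), plate == "PM-M8" & well != "G10")
effects <- rbind(effect_map("rtt_1", m8$plate, m8$well, -0.8),
                 effect_map("rtt_2", m8$plate, m8$well, -0.8))
cohort  <- simulate_cohort(config, layout, effects)

cmp <- comparison_spec("RTT-vs-control",
                       sample_selector(group = "RTT"),
                       sample_selector(group = "control"),
                       plates = c("PM-M7", "PM-M8"))
run <- run_profile(layout, kinetics = cohort$kinetics,
                   endpoint = cohort$endpoint, samples = cohort$samples,
                   comparisons = list(cmp))

res <- run$results[["RTT-vs-control"]]
str(percent_significant(res, "fdr"))
#> List of 3
#>  $ count  : int 95
#>  $ total  : int 192
#>  $ percent: num 49.5
```

95 of the 192 wells survive FDR control (49.5%): essentially the 95 planted
PM-M8 wells (two patients below all 50 controls reach the minimum exact
p = 2/C(52,2) ≈ 0.0015) plus the occasional false discovery that `q = 0.05`
permits. Each row carries the test detail:

```r
head(subset(res, fdr_sig,
            select = c(plate, well, compound, u_stat, p, p_adj, direction)), 3)
#>    plate well            compound u_stat       p   p_adj direction
#> 3  PM-M7  A03                 EGF      0 0.00151 0.00345 decreased
#> 89 PM-M7  H05 Substrate PM-M7-H05      2 0.00603 0.01259 decreased
#> 97 PM-M8  A01            Oxytocin      0 0.00151 0.00345 decreased
```

The single-case layer sees the same deficit in one patient line, and the
trend table aggregates both patients per compound:

```r
table(run$calls[["rtt_1"]]$call)
#>  above  below within
#>      3     93     96

trend_counts(run$trends, "RTT")
#> $increased
#> [1] 7
#> $decreased
#> [1] 101
#> $mixed
#> [1] 0
```

93 of the 95 shifted PM-M8 wells fall below the control whiskers for this
patient (the other two drew mild amplitudes), G10 and the unshifted PM-M7
plate stay almost entirely within.

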
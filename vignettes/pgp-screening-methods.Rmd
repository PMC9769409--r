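---
title: "Methods: PGP isolate screening, bonitur scoring and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PGP isolate screening, bonitur scoring and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgpscreen)
```

This vignette is the package's account of the science it implements: the
assays and their arithmetic, the bonitur selection scale, the campaign
summaries, the pot-trial statistics, and what the synthetic generators do
and do not emulate.

## The screening problem

A culturable-microbiome screening campaign isolates tens of candidate
strains (here, endophytic actinobacteria from plant tissue) and phenotypes
each one *in vitro* for plant-growth-promoting traits and antagonism
against a panel of fungal phytopathogens. The analysis has four stages:
quantify the raw assay readouts; summarise the campaign; combine the
per-isolate traits into a single selection score; and, for the selected
elite strains, analyse an *in vivo* pot trial.

Three tables describe a campaign: a **roster** (isolate code, tissue of
origin, genus where known), a **trait table** (per isolate: IAA µg/ml,
phosphate solubilization µg/ml, ammonia µmol/ml, siderophore %, and binary
flags for N₂ fixation, ACC deaminase and four hydrolytic enzymes), and an
**inhibition matrix** (isolate × pathogen percent inhibition). Cells carry
replicate summaries printed as `"v ± e"` (mean ± SE, n = 3).

**Not-detected (ND) is not zero.** An assay below detection carries
different information than a measured zero, so readers store ND as `NA`
and every downstream stage decides its meaning explicitly: scoring gives
ND zero points, prevalence counts an isolate positive iff detected,
extremes ignore ND. Coercing ND to 0 early would silently turn a detection
limit into a measurement.

## Assay arithmetic

* **Calibration.** Colorimetric assays (IAA via Salkowski reagent at
  530 nm, solubilized phosphate via molybdate at 650 nm, ammonia via
  Nessler reagent at 530 nm) are quantified against a standard series.
  `fit_standard_curve()` fits `absorbance = slope·c + intercept` by
  ordinary least squares with a **free intercept**: blank correction of
  readouts is not guaranteed, and forcing the line through the origin
  would bias every inverted concentration when it is not. A warning is
  emitted below r² = 0.98, a conventional acceptance bar for linear
  colorimetric curves. `concentration_from_absorbance()` inverts the line;
  negative concentrations (absorbance below the fitted blank) are flagged
  and accompanied by a censored-at-zero companion, never clamped in place
  — the negative value is exactly the QC signal one wants to see.
* **Dual-culture inhibition.** `percent_inhibition()` computes
  `100·(C−T)/C` from the control and test mycelium diameters. `T > C`
  (the fungus grew *better* next to the isolate) yields a negative
  percentage, allowed but flagged with a warning.
* **Siderophore.** The CAS-shuttle readout is `100·(Ar−As)/Ar` at 630 nm.
  The formula is implemented with the subtraction grouped — the only
  dimensionally sensible reading given that `Ar` is the reference
  absorbance and complete dye decolorization must map to 100%.
* **Chlorophyll.** The DMSO-extraction two-wavelength equations
  `Chla = 11.75·A663 − 2.35·A645` and `Chlb = 18.61·A645 − 3.96·A663`
  (mg per g fresh weight). Extreme absorbance ratios can drive one pigment
  negative; flagged, not clamped.

## The bonitur selection scale

The scale is additive with a maximum of 41 points under the default rules:

| component | points |
|---|---|
| IAA (µg/ml) | 1 for (0, 15], 2 for (15, 30], 3 for > 30 |
| Phosphate solubilization (µg/ml) | 1 for (0, 100], 2 for (100, 200], 3 for > 200 |
| ammonia, N₂ fixation, ACC deaminase, siderophore, chitinase | 1 each when positive/detected |
| each of 10 pathogens | 0 for ≤ 10%, 1 for (10, 30], 2 for (30, 60], 3 for (60, 100] |

Two conventions needed fixing where the published footnote is ambiguous
or contradictory, and both were fixed against the published score table
itself:

* **Bins are upper-inclusive.** The published table scores an exact 60%
  inhibition as 2 points, which pins the convention at the only boundary
  the data exercise; the same convention is applied to every bin.
* **The phosphate top bin starts above 200.** The footnote says "3 ≥ 300",
  which leaves 200–300 µg/ml unmapped, yet the published table assigns 3
  points to values of 213.2, 239.1 and 258.2. The implemented rule
  (200, ∞) → 3 is the only one consistent with those rows.

`rank_isolates()` uses dense ranking (tied totals share a rank, the next
distinct total takes the next integer), matching the published
1st/2nd/3rd/3rd/... column.

**The audit.** `audit_scores()` recomputes every score card from the raw
tables and compares cell-by-cell against the published score table, also
checking that each published row's points sum to its printed total.
Mismatches are *reported, never auto-corrected*: on the packaged campaign
the audit finds two published rows (DNLA13, VCRA2) that cannot be
reproduced from the campaign's own trait and inhibition tables (recomputed
totals of 31 against printed totals of 30 for both), and that VCRA2's
printed points sum to 28, not 30. The packaged fixtures keep the published
numbers verbatim; `inst/extdata/fixture_notes.md` lists every such
inconsistency.

The rule set is configuration (`bonitur_rules()`, YAML-serializable via
`read_bonitur_rules()`/`write_bonitur_rules()`), so other campaigns can
redefine thresholds, the binary-trait list, or point weights.

## Campaign summaries

Prevalence counts an isolate positive for a quantitative trait iff the
trait was detected, with no magnitude threshold — this is the rule under
which the recomputed counts equal the published ones exactly. Percentages
are **truncated** to two decimals by default because that is the
convention the published campaign's numbers follow (25/51 → 49.01%,
22/51 → 43.13%); half-up rounding is available via `rounding = "half_up"`.

The antagonism spectrum counts an isolate against a pathogen iff any
activity is present; broad-spectrum isolates inhibit every pathogen.
On the packaged campaign the matrix has 28 rows with at least one value
while the source's prose says 27 — the recomputed count is reported, the
discrepancy documented. Extremes return *all* attaining isolates on ties,
so results do not depend on row order.

## Pot-trial statistics

The trial design is a control arm plus inoculation treatments, two
harvests (35 and 70 days), five replicates per cell, nine vegetative
parameters (leaf count, shoot/root lengths, fresh/dry shoot and root
weights, chlorophyll a and b).

* **Summaries** are mean ± SE with SE = sd/√n (sample sd).
* **Fold change** is the ratio of treatment mean to control mean at the
  same timepoint, reported on the log2 scale so up- and down-regulation
  are symmetric about zero. Means of replicates are used, not
  per-replicate ratios, matching the "difference between means" design.
* **ANOVA** is the classic equal-variance one-way decomposition
  (F = MSB/MSW), run per parameter within each timepoint. Degenerate
  inputs are handled explicitly: zero within-group variance with unequal
  means reports F = ∞, p = 0; all-identical data reports F = 0, p = 1.
  No multiple-testing correction is applied across the nine parameters —
  the original analysis applies none — so the p-values are raw and the
  ANOVA table says so.
* **PCA** standardizes each parameter to zero mean and unit variance
  before eigendecomposition (i.e. PCA of the correlation matrix), because
  the parameters mix counts, centimetres, grams and mg/g; covariance-based
  PCA would let the largest-unit parameter dominate. Explained-variance
  percentages are non-increasing and sum to 100. A constant column cannot
  be standardized and raises an error naming the column.

## Synthetic data: what it emulates, and what it does not

The original raw data behind the trial figures (and the standard series
behind the calibrations) are not published, so seeded generators stand in.

`simulate_screen()` draws, per isolate: detection of each trait as an
independent Bernoulli at the campaign's published prevalence (e.g. IAA
27/51, phosphate 25/51); detected values **uniform** within the published
min–max (IAA 4.0–43.8 µg/ml, phosphate 61.1–289.7 µg/ml, ammonia
0.9–5.9 µmol/ml, siderophore 10–61.2%) — ranges are all the source
reports, so the flat distribution is a stated default, not an inference
(log-uniform is available); inhibition cells active independently at the
published cell rate (131/510) with values uniform in 26.1–92.2%; genus
and tissue multinomial at the published composition.

`simulate_trial()` builds each replicate value as
`control_mean × fold_change × noise` with lognormal multiplicative noise
of mean 1 and configurable coefficient of variation (default CV = 0.08, a
typical between-replicate scatter for greenhouse vegetative measurements;
CV = 0 reproduces the configuration exactly). Default fold changes
(1.6–2.6 across arms) sit inside the published 1.3–5.3 range, with the
consortium arm largest, as observed.

Deliberately **not** modelled, because the source gives no basis to
estimate them: correlation among traits, phylogenetic signal in trait
distributions, pathogen-specific inhibition profiles, and
parameter-specific trial fold changes. Consequently, passing tests on
synthetic campaigns demonstrate that the *pipeline* is correct and
calibrated (prevalences recovered, type-I error at nominal level, fold
changes recovered within sampling error), not that real campaigns look
like the generator. The published PC1 percentages (82.8%/84%) are likewise
not reproducible from printed data; the trial stage is instead validated
by properties (explained variances match a dense eigendecomposition to
1e-8 and sum to 100).

Determinism: one master integer seed with an independent derived substream
per component, so adding a generator never perturbs existing outputs, and
identical configs yield byte-identical CSV files through the writers.

## Numerical choices and problem sizes

* Percentage truncation to 2 dp (see above); half-up available.
* Score cards are pure integer arithmetic; no floating comparisons enter
  the ranking.
* OLS is delegated to `stats::lm`, ANOVA p-values to the F distribution
  via `stats::oneway.test`/`stats::pf`, PCA to `stats::prcomp`; the test
  suite cross-checks each against independent closed-form or
  eigendecomposition oracles.
* The test suite's simulation sizes are chosen for tight checks at
  interactive runtimes: 5,000 null trials for ANOVA calibration
  (rejection rate within ±0.01 of 0.05), 10,000 randomized profiles for
  the scoring bound, prevalence convergence at n = 10,000 within 2%.

## Known limitations

* The bonitur scale is the published additive one; no weighting
  optimization or multi-criteria decision analysis is offered.
* Post-hoc tests, mixed models and repeated-measures structure are out of
  scope — the implemented trial analysis mirrors the published one-way
  design.
* Diversity indices (Shannon, Chao) and rarefaction are not computed;
  composition summaries are plain counts and shares.
* The audit can only reconcile against what a published table prints; it
  cannot decide which of two inconsistent published numbers is the
  laboratory truth.
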
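---
title: "Constructing composite quality-of-care indices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing composite quality-of-care indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qocindex)
```

## The construction pipeline

`qocindex` builds facility-level composite quality scores in the
step-wise fashion recommended by the OECD composite-indicator handbook:
theoretical framework, metric selection, imputation, initial data
analysis, normalization, weighting and aggregation, sensitivity analysis,
and deconstruction. The framework is a *quality matrix*: quality
dimensions (effective, efficient, accessible/timely,
patient-centered/acceptable, equitable, safe) crossed with Donabedian's
structure / process / outcome. Two naming conventions are fixed here:
`patient_centered` stands for the patient-centered/acceptable pair and
`accessible` for accessible/timely, since each pair is one dimension of
the matrix. Indicator-to-cell assignment is **input data**, validated but
never recomputed — resolving ambiguous assignments is an expert-judgment
task that belongs upstream of any software.

Dimensions that no available indicator can populate are dropped wholesale
(`drop_unpopulated_dimensions()`); the motivating use case retains four
dimensions, giving 12 cells. Cell ordering is fixed (elements major,
dimensions minor, declaration order) so reports are reproducible.

### Ingestion and aggregation

Individual-level records (delivery observations, provider interviews,
exit interviews) are averaged within facility, excluding missing entries
from the mean; binary items therefore become proportions, re-binarized at
the **0.5-inclusive** cutoff (`>= 0.5` maps to 1). Facilities lacking any
required tool are excluded rather than imputed: a composite that claims
to draw on four instruments is not meaningful for a facility where one
instrument was never applied.

### Imputation

The default policy mirrors the base construction:

* **observation-tool gaps → 0.** Direct-observation instruments ask the
  observer to tick tasks as they happen; an unticked task is best read as
  "not observed". Alternatives `one` (benefit of the doubt: fills the
  other end of the outcome range) and `mode` are provided.
* **binary gaps → proxy, then mode.** A declared proxy indicator's value
  is copied *from the same facility*; the upstream description of proxy
  imputation ("a close substitute") does not state mechanics, and the
  same-facility copy is the only choice that preserves facility-level
  information. If the proxy is missing too, the sample mode is used.
  Mode ties between 0 and 1 resolve to **1**, mirroring the `>= 0.5`
  re-binarization convention.
* **continuous and ordinal gaps → sample mean.** The upstream convention
  is mode-for-binary / mean-for-continuous; facility-level ordinal values
  are already means of ratings (non-integer), so a mode is ill-defined
  and the mean is used for them as well.

One deliberate contract choice: the zero/one fill for observation items
is applied at the *facility* level (after aggregation), not at the record
level. When a facility-level observation value is missing at all, every
underlying record was missing, and the two placements coincide; when only
some records are missing, record exclusion from the mean governs. This
keeps every imputation decision in one module with full provenance
tracking (`observed`, `imputed_zero`, `imputed_one`, `imputed_mode`,
`imputed_mean`, `imputed_proxy` per entry). Multiple or model-based
imputation is deliberately out of scope: with ~26 facilities such methods
risk biasing the study in unknown ways, and a composite intended for
routine monitoring should be replicable without them.

### Internal consistency screening

Within every cell, all indicator pairs are correlated (Pearson
product-moment, which equals the phi coefficient for binary pairs). Pairs
with `r > 0.7` — **strictly** greater, one-sided — are flagged for human
review; nothing merges automatically. The one-sided rule follows the
stated screening convention; `absolute = TRUE` flags `|r| > 0.7` for
users who also want strong negative redundancy. Zero-variance columns are
excluded from flagging with a warning rather than erroring: a constant
indicator is a data-review issue, not a redundancy. Screening runs on the
imputed table (configurable by simply screening earlier); whether the
original analysis screened before or after imputation is unstated.

A reviewed merge map replaces the survivor by the **mean of the merged
columns, re-binarized at 0.5** when all merged indicators are binary.
This combination rule is a package decision (upstream, merging was a
judgment call without a stated formula); it is symmetric, idempotent for
identical columns, and consistent with every other binarization in the
pipeline.

## Normalization, weighting and aggregation

The scenario grammar has four slots; the base setting and the alternative
that swaps each slot are:

| slot | base | alternative |
|------|------|-------------|
| indicator normalization | cutoff binarization | `alt_a`: empirical min-max to [0,1] |
| indicator aggregation | additive (sum) | `alt_b`: geometric (product) |
| cell normalization | theoretical min-max | `alt_c`: z-score |
| cell aggregation | additive | `alt_d`: geometric |

Parameters that matter, with defaults and reasons:

* **Cutoffs.** Binary indicators need none. Fixed cutoffs carry units
  from the indicator map (e.g. `fixed:3` for at least three skilled birth
  attendants, per staffing norms; `fixed_le:<x>` for lower-is-better
  fixed rules). `median` resolves against the observed facility column —
  note the comparator is inclusive on the favourable side (`>=` for
  higher-better, `<=` for lower-better), so the median facility always
  satisfies its own cutoff (a waiting time exactly at the 20-minute
  median scores 1).
* **Orientation.** Lower-is-better columns flip through the cutoff
  comparator under binarization, are reflected (`max − x`) ahead of
  min-max, and flip `1 − x` if binary.
* **Cell min-max bounds default to theoretical**: each cell's raw score
  is divided by its possible maximum (the indicator count under additive
  aggregation). Rescaling exists precisely because cell maxima differ
  (6 to 19 indicators per cell), which implies division by the possible,
  not the observed, maximum; empirical min-max is available as an option.
* **Geometric aggregation is the plain product, not the geometric
  mean.** Only the product gives the documented all-or-nothing behaviour
  for binary inputs (any 0 zeroes the cell) and the 0–1 composite range
  of `alt_d`. After geometric indicator aggregation of binary inputs the
  cell's theoretical maximum is 1, so the subsequent cell min-max is a
  no-op and `alt_b` keeps the printed 0–12 composite scale.
* **Weights.** Equal by default. User weight tables are normalized to
  sum to the component count, so equal weights reproduce plain sums and
  the familiar 0–12 scale. Data-driven weighting (PCA,
  benefit-of-the-doubt) is deliberately unsupported: for indicators that
  measure adherence to universal care standards, statistically derived
  weights would reward what is easily measured locally and break
  cross-setting comparability.
* **Sample SD (n − 1)** is used for z-scores and confidence intervals;
  the upstream choice is unstated, and the sample estimator is the
  conventional default at n = 26. Recorded here so results are exactly
  reproducible.

Scale ranges per scenario: additive cells with min-max normalization give
[0, n cells]; geometric cells give [0, 1]; z-score normalization makes
the composite unbounded (reported as `"unbounded"`), and geometric
aggregation of z-scored cells is refused with an error pointing to a
non-negative normalization.

### Degenerate-input rules

All frozen, all warned about when hit: a constant column under
*empirical* min-max maps to 0.5 (the uninformative midpoint); under
z-scores it maps to 0; an all-tied score vector has undefined Spearman
rho (`NA`, flagged); a single-dimension matrix is legal but warned.

## Sensitivity analysis

Facilities are ranked in **descending** score order (rank 1 = best, the
league-table convention), ties receiving average ranks. Scenario
agreement is the tie-aware Spearman rho: Pearson correlation of the rank
vectors, which reduces to `1 − 6Σd²/(n(n²−1))` without ties; the
classical formula is exposed for comparison. Rank-shift diagnostics
(largest absolute shift; facilities moving more than k = 5 places)
accompany every coefficient because a high rho can hide individually
dramatic movers — exactly the facilities a geometric, non-compensable
construction penalizes. Point estimates only; no significance testing.

On the packaged fixture of published per-facility scores, the tie-aware
estimator reproduces the published base-vs-alternative coefficients for
the min-max, z-score and geometric-cell alternatives (and the
geometric-cell value holds under both estimators). The published
geometric-*indicator* coefficient is **not** reproducible from the
printed scores: 2-decimal rounding of that column induces artificial ties
(six facilities print 1.00), and no standard tie treatment recovers the
published value, so that coefficient is documented as excluded rather
than asserted. Pipeline rho values are computed on full-precision scores;
fixture regressions necessarily use the printed values.

## Deconstruction

Per-cell means of normalized scores with confidence intervals, element
totals (sum of the element's four cell means, range 0–4), and a composite
summary. The interval description upstream conflates two definitions
("95% confidence intervals, +/− 2 standard deviations"); both are
implemented — `normal_se` (mean ± 1.96·SD/√n, the default; published
interval widths at n = 26 are consistent with standard-error intervals)
and `two_sd` (mean ± 2·SD) — and every report names the method used. For
additive scenarios the sum of all cell means equals the mean composite
exactly (linearity), a property the test suite asserts. Z-score scenarios
have cell means of 0 by construction; reports flag this and carry the SD
column instead. Retransformation of z-scores for cross-scenario
comparability is out of scope. Per-indicator contributions (mean
normalized value × weight share of cell) show where each cell score comes
from; they sum exactly to the normalized cell mean under additive
aggregation.

## The synthetic-data generator

`generate_study()` emulates the *structure* of a multi-instrument
facility assessment, not any real data: 26 facilities (33 with dropout),
85 indicators on a 4 × 3 matrix, four source tools, roughly 3 delivery
observations, 3 provider interviews and 8 exit interviews per facility
(the scale of 82/81/204 records over 26 facilities). With a minimum of 6
indicators per cell and maxima spanning 6–19, the only 12-cell layout
summing to 85 is one 19-indicator cell plus eleven of 6; the large cell
is assigned to accessible/structure, the natural home of long
equipment/supply/drug checklists.

The generative model: latent facility quality `q` is logit-normal
(`plogis(rnorm(n, 0, quality_spread))`, spread 1 by default — a realistic
degree of facility heterogeneity, chosen once to give meaningful but not
extreme spread on the 0–12 composite scale). Binary individual-level items are Bernoulli with
success probability `plogis(a_cell + signal·(q − 0.5))`; the cell
intercepts (drawn once per study from U(−0.5, 1.5)) set each cell's
typical prevalence in roughly 0.38–0.82, matching the spread of published
cell means. The slope is **centered on q = 0.5** deliberately: with an
uncentered slope, raising the signal pushes whole items into ceiling
saturation, destroying item variance and making rank recovery
*non-monotone* in the signal — the centered form keeps prevalence stable
while separation grows, so "more signal, better recovery" holds
structurally. Inventory items are Bernoulli(q) directly. Three non-binary
indicators exercise every cutoff path: a Poisson staffing count (fixed
cutoff 3), a normal waiting time decreasing in quality (lower-better,
median cutoff), and a 1–5 ordinal satisfaction rating (median cutoff).
One observation-tool proxy pair exercises proxy imputation. Item
missingness is MCAR at 2% (completeness in such assessments is typically
high); whole-tool dropout removes one randomly chosen tool from chosen
facilities, to be caught by the completeness filter.

What a green test on synthetic data does **not** establish: real
assessments have non-random missingness (observer fatigue, tool-specific
skip patterns), correlated indicators beyond the single latent factor,
cluster effects by district or facility type, and ordinal items with
idiosyncratic distributions. The generator validates the *pipeline
mechanics and statistical conventions*, not field realism. The 0.8
median-rank-recovery threshold (20 seeds, strong signal, 20 records per
tool) was calibrated once against this generator and frozen; the test
suite recomputes the median at every run.

All randomness in the package lives in this module; every scoring
computation is deterministic.

## Known limitations

* Equal and user-supplied weights only; no PCA/DEA weighting (by design).
* No survey weights and no multiple imputation (by design, see above).
* Spearman rho is reported without uncertainty; with n ≈ 26 its sampling
  error is material, and discrete one-decision-at-a-time comparisons do
  not propagate joint construction uncertainty.
* The published geometric-indicator scores cannot be regenerated from
  their printed composites (see sensitivity section); acceptance
  assertions cover the reproducible quantities only.
* Ordinal aggregation uses the arithmetic mean of ratings before the
  median cutoff; the upstream choice for ordinal averaging is unstated.
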
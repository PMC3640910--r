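---
title: "AgNOR morphometry and survival analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AgNOR morphometry and survival analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agnortools)
```

## The measurement problem

Silver staining renders the argyrophilic nucleolar-organizer-region proteins
as dark dots inside cell nuclei. In breast carcinoma the number, size and
spatial arrangement of these AgNOR dots correlate with proliferative
activity, so a quantitative AgNOR profile is a candidate replacement for the
observer-dependent mitosis/pleomorphism components of conventional grading.
The measurement workflow this package implements is deliberately
*semi-automatic*: tumour nuclei are marked by a pathologist (a breast tumour
section contains several cell types, so fully automatic nucleus selection is
not attempted), and the software quantifies dots only inside those masks.

## Detection model

Within each nucleus mask, particles are connected components
(4-connectivity) of below-threshold pixels, filtered by a minimum area.

* **Threshold.** Per-nucleus Otsu on the within-mask intensity histogram by
  default, with a fixed global level as an override. Otsu assumes a bimodal
  histogram; on a particle-free nucleus it would split the noise in half, so
  a *contrast guard* rejects the dark class unless the two class means are
  at least `min_contrast = 20` grey levels apart (well below the nominal
  dot/nucleoplasm contrast of ~100, well above noise at realistic SDs).
  Binarization then happens at the *half-depth* level — midway between the
  dark class's core level (its 5% quantile) and the bright-class mean —
  rather than at the raw Otsu split. On a soft-edged dot this measures the
  50%-coverage contour (FWHM-style sizing), so the pixel area tracks `πr²`
  instead of fluctuating with however much of the anti-aliased rim falls
  below the split point; that stability matters because the conglomerate
  decision is an area *ratio*.
* **Minimum area.** Two pixels' area (`2 · calibration²`), suppressing
  single-pixel noise while keeping the smallest realistic dots (radius
  ≥ 0.3 µm ≈ 1.2 px at 0.25 µm/px, area ≈ 4.5 px).
* **Geometry conventions.** Pixel centres are 0-based `(row, col)`; areas
  are pixel counts × calibration²; centroids are unweighted pixel-centre
  means. Particles are reported sorted by descending area with a
  lexicographic `(y, x)` centroid tie-break, so output order is
  deterministic.
* **Radial position.** `d_norm` = (distance of the particle centroid from
  the nucleus centroid) / (centroid-to-boundary distance along the same
  ray). This is shape-independent, lies in `[0, 1)`, and is defined as 0
  for a particle at the centroid. On pixel masks the boundary distance is
  found by marching along the ray in quarter-pixel steps.

### Conglomerate correction

Dots lying very close together appear as one merged particle and must be
*counted accordingly*. The package makes that intent operational with an
area-ratio rule: with reference single-AgNOR area `A_ref` and factor
`κ = 1.5`,

* `A ≤ κ·A_ref` → count 1 (small particles never count as zero);
* otherwise → `max(2, round_half_up(A / A_ref))`.

`A_ref` is estimated once per case as the median area of particles not
exceeding `κ ×` (median of all areas) — a single exclusion pass that is
robust to the conglomerates themselves and deterministic. `κ = 1.5` sits
between the largest plausible size ratio of two lone dots drawn from a
narrow size distribution (~1.3 in area) and the smallest merged pair (~1.7
for two equal dots at 1.2 r spacing), so the decision boundary is
comfortably two-sided. Both `κ` and the estimator input are configurable.

## The case-level feature vector

Per nucleus: corrected count (sum of per-particle corrected counts),
per-mille area fractions `aᵢ/Σa × 1000`, their dispersion, the largest/total
ratio, and central/peripheral zone memberships. Case level:

| feature | aggregation |
|---|---|
| `nornbc_m` | mean corrected count per nucleus |
| `nor_k0..nor_k8` | % of nuclei with corrected count exactly k |
| `snar_r_v` | mean over nuclei of within-nucleus SD of area fractions |
| `mnrat2_m` | mean over nuclei of largest/total ratio (per mille) |
| `cent_r_v`, `bord_r_v` | SD across nuclei of central / peripheral proportion |
| `center_v` | SD of `d_norm`, central particles pooled across nuclei |
| `locat_v` | variance of `d_norm`, all particles pooled |

Design choices that were genuinely open:

* **Zones.** The central and peripheral zones are named but not defined in
  the literature the feature names come from; the package defaults to
  `d_norm ≤ 0.5` (central) and `d_norm ≥ 0.8` (peripheral), configurable
  through `zone_definition()`.
* **Within- vs across-nucleus dispersion.** The `_v` names are ambiguous
  between dispersion within a nucleus and across nuclei. The defaults —
  `snar_r_v` averages within-nucleus SDs, `cent_r_v`/`bord_r_v` are
  across-nucleus SDs of proportions, `locat_v` pools particles — are fixed,
  documented, and exercised by the test oracle.
* **Divisor conventions.** Pooled and within-nucleus dispersions use the
  population (divide-by-n) form so a single-particle nucleus has dispersion
  0 rather than an undefined value; across-nucleus dispersions use the
  sample SD, degrading to 0 below two nuclei.
* **Uniform k.** The count-class percentages are computed uniformly for
  k = 0..8 even though published tables omit some classes (`nor_k3` is
  absent there, and one table caption mislabels `nor_k1`); consumers select
  the columns they need.
* Nuclei with zero particles enter the count classes (as count 0) but are
  excluded from area/zone aggregates, where they carry no information;
  per-mille quantities stay unrounded internally.

## Synthetic data

### Images

Nuclei are ellipses (semi-major axis drawn from the scenario range, axis
ratio uniform in `[0.6, 1]`, random orientation) placed on a jittered grid
sized to hold them — or at random inside a user-supplied field, where
placement failure after bounded retries is an explicit error. AgNORs are
anti-aliased disks (pixel value = coverage-weighted blend), dark on a
lighter nucleus on a lighter background, with optional additive Gaussian
noise quantised to 8 bits. Conglomerates are synthesised by placing 2–3
dots with centre spacing `0.75 × (r₁+r₂)` so they merge into one connected
component; distinct placement events keep ≥ 2 px clearance so they never
merge accidentally. Ground truth records every true dot (area `πr²`, exact
elliptical-ray `d_norm`, conglomerate group, per-nucleus true count).

Two presets bracket the phenotypes of interest: `low_variability` (2–5
similar-sized, centrally placed dots per nucleus, 5% conglomerates) and
`high_variability` (0–12 dots, radii 0.3–0.8 µm, near-uniform radial
placement, 20% conglomerates). Their parameters are calibrated only to this
qualitative contrast — no distributional parameters for real cohorts are
published — and the dispersion features separate the two presets in ≥ 95 of
100 paired seeded runs (a property the test suite recomputes).

Determinism: every output is a pure function of `(scenario, seed)`; each
nucleus draws from its own substream (a fixed arithmetic mix of seed and
nucleus index), so enlarging a scenario does not perturb existing nuclei.
When a nucleus is too crowded for its drawn dot count, the radial constraint
is relaxed after 200 rejected placements (dots are pushed outward, as in
real crowded nuclei) and the candidate radius shrinks toward the range
minimum before placement fails loudly.

What the generator does **not** emulate: stain colour and chromatin
texture, irregular (non-elliptical) nucleus shapes, out-of-focus blur,
overlapping nuclei, and the other cell types of a real section. Passing
recovery tests on these images therefore validates the *measurement
arithmetic* — segmentation-to-feature bookkeeping, conglomerate correction,
positional statistics — not robustness to real-world stain and focus
variation.

### Cohorts

`generate_cohort()` draws covariates independently from configurable
marginals (ordinal clinical scores; truncated normals for AgNOR features on
their natural scales — invented, documented stand-ins, since no cohort
marginals are published) and simulates follow-up from an exponential
proportional-hazards model: event time `~ Exp(λ·exp(Σβx))`, censoring by an
administrative horizon and/or an independent exponential process, observed
deaths attributed to breast cancer with a configurable mixing proportion
(default 0.57, the published worked example's ratio of cause-specific to
overall deaths). `calibrate_baseline()` solves for `λ` matching a target
event fraction using the closed-form event probability, so study conditions
can be stated as "n cases, 33% events" rather than as a raw rate.

In `run_pipeline()`'s synthetic mode the hazard acts on the cohort's own
*measured* features, z-scored so a coefficient is a log hazard ratio per SD
(raw per-mille scales would otherwise dwarf ordinal covariates); the
pipeline defaults mirror the published study frame: 244 cases, overall
event fraction 81/244, follow-up horizon 247 months.

## Survival analysis

Kaplan–Meier estimation and Cox partial-likelihood maximisation are
delegated to the `survival` package; the package's own contributions are the
selection procedure, the endpoint handling and the reporting layer, and the
tests verify the KM curve against an independent risk-set enumeration.

* **Endpoints.** Overall survival (any death) and breast-cancer-specific
  survival (other-cause deaths censored at death). The overall event count
  is necessarily ≥ the cause-specific one on the same cohort.
* **Backward stepwise LR.** From the full model on the listwise-complete
  cases (fixed for the whole run), repeatedly remove the covariate with the
  largest likelihood-ratio p-value (model with vs without it, χ² on 1 df)
  while it exceeds `p_remove`. Default `p_remove = 0.10`: published tables
  of this procedure retain covariates at p = .097 and .081, so the
  historical removal threshold must be at least 0.10, which is also the
  classical default. Ties default to Breslow (the historical SPSS choice);
  Efron is selectable. `p_remove = 1` provably removes nothing; thresholds
  near 0 remove everything.
* **Case processing.** Events / censored / missing-value (listwise) /
  censored-before-the-earliest-event-in-stratum, the last being the SPSS
  exclusion of censored cases that cannot contribute to any risk set
  (single stratum by default). Percentages are of the grand total, rounded
  half away from zero to one decimal, rendered SPSS-style with the leading
  zero suppressed below 1 (".4%").

Numeric reproduction of the published stepwise significance tables is not
possible — they depend on an undeposited 244-patient dataset and the tables
report only significances — so the package validates the *procedure*:
worked-example case-processing arithmetic is reproduced exactly, and
selection behaviour is verified on cohorts with known hazard structure.

## Problem sizes in the test suite

The suite exercises: exact feature recovery on one noise-free 50-nucleus
field; 50-seed feature-oracle sweeps at 6 nuclei; 100 paired preset
comparisons at 25 nuclei (ground-truth level); hazard-ratio recovery in 50
replicates of n = 500; null-coefficient coverage in 100 replicates of
n = 200; stepwise retention in 50 replicates of n = 400 with the
18-covariate menu at 30% events; and 20 end-to-end pipeline runs of 40
cases × 12 nuclei. These sizes give the binomial pass criteria comfortable
margins while keeping a full run in the low minutes.

## Known limitations

* The conglomerate correction is an area-ratio heuristic; it cannot
  distinguish one genuinely large AgNOR from two merged average ones, and
  its accuracy degrades when the single-dot size distribution is wide.
* `nor_k0` is an exact linear combination of `nor_k1..nor_k8` whenever no
  nucleus exceeds 8 dots; the default stepwise menu therefore omits it, and
  near-collinearity among the remaining count classes can still make
  full-model coefficients unstable on small cohorts (selection itself is
  unaffected).
* `d_norm` on pixel masks inherits quarter-pixel ray-marching error, and
  `center_v` is conditional on the (configurable) central-zone definition;
  an alternative reading of that feature as 2-D positional scatter is not
  implemented.
* Cause-of-death attribution in the simulator is independent of covariates;
  competing-risks (Fine–Gray) modelling is out of scope.
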
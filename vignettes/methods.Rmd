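---
title: "Measuring femoral cartilage thickness and its detectable change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring femoral cartilage thickness and its detectable change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultracart)
```

## The measurement model

A transverse suprapatellar ultrasound view shows anterior femoral cartilage
as a band bounded above by the synovial–cartilage border and below by the
cartilage–bone border. `ultracart` starts where segmentation ends: two
x-monotone border polylines in pixel coordinates (y down), a manually
marked central point on the synovial border between the medial and lateral
condylar upslopes, a pixel→mm calibration (possibly anisotropic), and a
flag saying which x direction is medial.

Regions are vertical strips of the cartilage's medio-lateral x-extent. The
intercondylar region is the middle fraction (default 0.25) of the extent
*centered on the central point's x*; medial and lateral run from the cuts
to the extent ends. Only the central point's x is used — the partition is a
medio-lateral split — and a central point so eccentric that a cut would
leave the extent is an error, never a clamp. An alternative reading would
measure the 25% window along the bone-interface arc instead of the x-axis;
we use the x-extent because the outer regions are defined by the *image*
borders (vertical lines) in the source protocol, and we keep the window
parametric (`fraction`) so the choice is visible.

Per region, three quantities:

* **CSA** (mm²): both borders are clipped to the strip with interpolated
  vertices inserted at the cuts, joined into a closed polygon, and measured
  with the shoelace formula on millimetre coordinates. Because the cut
  vertices are interpolated identically from either side, strip areas add
  to the full-extent area exactly (tested to 1e-9 relative).
* **Bone-interface length** (mm): the clipped inferior polyline's segment
  lengths, each converted to mm component-wise before the Euclidean norm,
  so non-square pixels are handled correctly.
* **Mean thickness** (mm) `= CSA / length`. Note the denominator is an arc
  length: over curved bone the mean thickness is strictly below the mean
  vertical gap (arc ≥ chord). This matches the source technique, which
  divides regional CSA by regional cartilage length.

Correctness is checked against two independent oracles implemented by a
different algorithm than the production path: a sub-pixel column-sampling
integral for CSA (`oracle_region_csa`, 0.01-px default step) and a
dense-resampling sum for arc length (`oracle_bone_length`); agreement is
required to 0.1% and 1e-6 respectively on randomized phantoms.

### Degenerate inputs

Non-monotone borders, borders that touch or cross in the interior,
mismatched x-extents, central points outside the extent, and empty strips
are hard, classed errors. Because both borders are piecewise linear, the
vertical gap is linear between adjacent knots of the union grid, so
checking gap > 0 at interior knots (and ≥ 0 at the shared endpoints) is
exact, not a sampling heuristic.

## Reliability: ICC(2,k), SEM, MDC90

Test–retest reliability across `k` sessions uses the Shrout–Fleiss
two-way random-effects, absolute-agreement, average-measures form

$$\mathrm{ICC}(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$

computed longhand from the subject × session mean squares, with the
F-based Shrout–Fleiss confidence interval for the single-measure form
(Satterthwaite denominator df) stepped up to `k` measures by
Spearman–Brown. Repeated images within a session are averaged to one
session value first — the conventional reading when a protocol captures
three images per visit but reports a single thickness.

Precision statistics follow the musculoskeletal-ultrasound conventions:
`SEM = SD·√(1−ICC)` with SD the between-subject SD of session-1 values of
the reliability (healthy) sample, and `MDC90 = 1.654·SEM·√2`. Two
deliberate fidelity choices:

* The constant 1.654 is kept verbatim (the usual two-sided 90% z is 1.645;
  at thickness-scale SEMs the two round identically to 2 decimals). It is
  a parameter (`constant`, `--mdc-constant`) for users who prefer 1.645.
* `report_precision()` computes MDC90 from the SEM *rounded to the
  reporting precision* (0.0658 → 0.07 → 0.16), because that is how the
  published tables this field produces are assembled; the full-precision
  chain would give 0.154 → 0.15 for the medial region. Both full-precision
  and reported values are returned, and the core functions themselves never
  round.

Qualitative ICC bands are implemented half-open — poor [0, 0.5), moderate
[0.5, 0.75), good [0.75, 0.9), excellent [0.9, ∞) — closing the gaps the
verbal cut-offs (0.49/0.5, 0.89/0.9) leave, with boundaries assigned
upward.

## Responder classification

Per knee-region, the between-session change is labeled thickening when
`Δ > MDC90`, thinning when `Δ < −MDC90`, else no change; "exceeds" is
strict, so equality is no change. Cohort summaries report, per limb, the
percentage of participants with at least one thickening region and with at
least one thinning region; the categories are deliberately not exclusive
(a participant can contribute to both), which is the only counting rule
under which the two percentages are reportable separately. By design, the
MDC used for classification comes from the healthy test-retest analysis,
not from the longitudinal cohort itself.

Under a null cohort whose only between-session variation is measurement
error with SD equal to the SEM, `|Δ| ~ |N(0, 2·SEM²)|` and the exceedance
probability is `2(1 − Φ(1.654)) ≈ 9.8%` — the ~10% design property of
MDC90, which the acceptance suite verifies at 5000 simulated knees.

## Group statistics

The 2×2 limb × time repeated-measures ANOVA is decomposed longhand; each
effect is tested against its own subject × effect interaction with
(1, n−1) df. With two levels per factor sphericity is automatic, and
`F_limb` equals the squared paired-t statistic on time-averaged limb
differences (tested as an exact identity). The paired, pooled/Welch
independent t-tests and the 2×2 Fisher exact test wrap the classical
`stats` implementations behind a uniform result type; the Fisher p is
validated against exhaustive hypergeometric enumeration and the t-test
against a 10⁴-replicate null simulation. α = 0.05 two-sided throughout; no
multiplicity correction (none is standard in this design).

## What the synthetic data does and does not emulate

`make_phantom()` builds the inferior border from a flat, sloped, or
bicondylar profile and places the superior border a *vertical* thickness
above it. The vertical-offset convention makes flat-bone truth exact and
sloped-bone truth analytically derivable; it is a phantom convention, not
an anatomical claim about normal-direction thickness. Piecewise-regional
thickness steps are placed exactly at the region cuts so the noise-free
flat phantom recovers its stated truth to machine precision. Optional
Gaussian vertex jitter is seeded and deterministic.

`simulate_cohort()` draws
`y = μ_r + b + δ·1[s=2] + v + e` with independent normal components:
between-subject `b` (SD 0.38/0.61/0.36 mm by region), between-visit `v`
(default 0.04 mm), within-visit image repetition `e` (default 0.10 mm),
and an optional true-change mixture (fractions thickening/thinning at
±δ). Defaults mirror healthy suprapatellar magnitudes: regional means
2.16/2.57/2.04 mm and a session-mean SEM near 0.05–0.07 mm; the implied
population ICC is available in closed form
(`closed_form_icc2k`): `σ_b²/(σ_b² + (σ_v² + σ_e²/m)/k)`.

What this establishes — and does not: green geometry tests show the
measurement chain is exact on vector contours and stable under
rasterization; they say nothing about sonographer probe placement,
speckle, refraction artifacts, or segmentation quality, none of which are
modeled. Cohort tests validate the statistical machinery under normal
errors; heavy-tailed error and systematic rater drift are out of scope.

## Numerical and I/O conventions

* Coordinates are 0-based pixel centers, y-down; strips are closed
  intervals; conversion to mm precedes every norm/area.
* Rasterization is half-open toward the bone (pixel center in
  `[superior, inferior)`), and mask extraction returns the inferior border
  at the lower edge of the bottommost cartilage pixel: a band of integer
  pixel thickness round-trips exactly, any band within 1 px. Per-column
  extraction turns sloped borders into staircases, inflating arc length in
  proportion to slope, so the thickness round-trip bound holds for gentle
  slopes but degrades on steep condylar flanks (~8% length inflation at
  slope 0.5); prefer vector contours for curved bone.
* Mirror symmetry: mirroring the contour in x *and* flipping
  `medial_direction` preserves the anatomy, so regional metrics are
  unchanged; mirroring alone swaps medial and lateral exactly. Both are
  tested.
* ICC confidence bounds are always emitted (lo, hi) ordered.
* Reported tables round half-away-from-zero (`round_half_up`), matching
  published-table arithmetic; interchange CSVs carry full precision.
* ImageJ `.roi` outlines (polygon/freehand/traced) are split at the
  min-x/max-x vertices into two chains; short vertical end edges are
  trimmed so they are not counted as bone interface; the lower-mean-y
  chain becomes the superior border.

## Known limitations

* No automatic segmentation of raw echo data and no echo-intensity
  outcome; inputs are segmentation-level.
* The intercondylar window is defined on the x-extent, not on bone arc
  length (parametric fraction, see above).
* The Fisher/t wrappers inherit `stats`' conventions for ties and
  continuity (none beyond the classical definitions).
* Reliability assumes complete subject × session grids; missing sessions
  are errors, not imputations, by design.
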
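---
title: "Surrogate-based ASAT volumetry: models, phantoms and design choices"
author: "fovfat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-based ASAT volumetry: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovfat)
```

## The problem

Abdominal subcutaneous adipose tissue (ASAT) is quantified from axial MRI
or CT by segmenting the fat between the skin and the abdominal muscle
wall on every slice between the diaphragm and the pelvic floor and
summing area times effective slice spacing. In large subjects the
scanner's field of view (FOV) is often too small: ventrolateral
subcutaneous tissue is cut off, and the fully segmented reference volume
`V_ASAT` is simply not measurable. Surrogate measures that live in
regions the FOV reliably covers — dorsally anchored boxes and paramedian
bands — remain computable and can be converted to an estimate of
`V_ASAT` through a linear calibration

\[ V_\mathrm{ASAT} = S \cdot m_s + b_s \]

fitted by ordinary least squares on subjects where the full segmentation
exists. This package implements the six surrogates, the calibration, the
agreement statistics used to rank them, and a synthetic phantom cohort
with analytic ground truth on which the whole pipeline is validated.

## The six surrogates

All surrogates are computed from a labeled volume (`0` background, `1`
ASAT, `2` other tissue, `3` out-of-FOV) plus a landmark set: bilateral
femoral-head (FH) centres, bilateral anterior-superior-iliac-spine
(ASIS) points, and the diaphragm / pelvic-floor slice bounds (the slice
range is inclusive on both ends).

* **AWF** (abdominal wall fat, mm): on the ASIS slice, the maximum
  anterior contiguous ASAT run ending at the skin, over columns 2–30 mm
  lateral of the body midline (midline = centroid column of all
  non-background voxels). A paramedian rather than midline band avoids
  the linea alba.
* **HGF** (hip girdle fat, mm): on the ASIS slice, the maximum
  horizontal ASAT run between the lateral tangent of the inner
  (non-ASAT) tissue and the skin, over rows within ±30 mm of the ASIS
  row, both sides. The tangent is the vertical through the most lateral
  inner-tissue voxel — in patient data this is the iliac plate, which
  has no phantom analogue.
* **A_p-FH / A_p-ASIS** (cm²): ASAT area on the landmark pair's own
  slice inside a rectangular box whose lateral edges pass through the
  two landmark columns, whose anterior edge lies at the rounded mean of
  the two landmark rows and whose posterior edge is the grid boundary.
* **V_p-FH / V_p-ASIS** (L): the same box, reused unchanged on every
  slice of the inclusive diaphragm–pelvic-floor range; in-box area times
  effective slice spacing, summed.

The box construction is the one genuinely open design point: we anchor
the anterior edge on the landmark pair and extend dorsally, which keeps
the box inside the inter-landmark span and therefore maximally robust to
ventrolateral truncation; thickness runs follow grid axes (no oblique
calipers) so every measure is exactly reproducible. Single-slice areas
are evaluated at the landmark's own slice for both FH and ASIS.

Truncation semantics are strict and asymmetric by design: any
out-of-FOV voxel in the slice range makes the *reference* volume
undefined (`v_asat` missing — mirroring the exclusion of subjects with
visibly missing tissue), while a surrogate fails only if out-of-FOV
voxels intrude into its own box or band. `measurePanel()` therefore
returns rows with a missing reference but complete surrogates — exactly
the situation the calibration exists for.

## Calibration and agreement

For each surrogate and each group (female, male, pooled; 12
sex-specific plus 6 pooled equations) the conversion is fitted by OLS
and evaluated **in-sample**, matching the study design; no
cross-validation is implied. Agreement is summarised by:

* Pearson `r_p` and `R² = r_p²` (asserted equal to the ANOVA
  decomposition within 1e-9 in the tests);
* `s_d%`: the sample (n−1) standard deviation of percent differences
  `(Ṽ − V)/V × 100` — the primary metric, scale-free across the very
  different female and male volume ranges;
* Bland–Altman limits of agreement on absolute differences,
  `mean(d) ± 1.96 sd(d)` (L). Because OLS residuals have mean zero, the
  in-sample mean difference is 0 by construction.

The sample-SD divisor and the 1.96 multiplier are conventional choices;
neither is prescribed by the conversion model itself.

## The phantom cohort

No patient data ship with this package; the generator produces a
cohort with the *statistical structure* the analysis assumes, not
biofidelic anatomy. Each subject is a stack of 40–50 axial
concentric-ellipse rings (10.5 mm effective spacing, 2 mm in-plane by
default): an outer ellipse (skin) and an inner ellipse (abdominal wall)
whose centre is displaced posteriorly, making the ring ventrally
thicker. The ring area has the closed form `π(a_out·b_out − a_in·b_in)`,
independent of the offset, which provides the exact per-slice and
volume oracles used throughout the tests (voxel counting converges to
these within 2% at ≤2 mm in-plane spacing).

The default cohort follows the study population it emulates: 116 female
and 77 male subjects, BMI drawn from a Gaussian 32.1 ± 3.7 kg/m²
truncated by rejection sampling to [24.8, 41.2] (rejection rather than
clipping, to avoid probability atoms at the boundaries). BMI acts as a
latent size score only; no BMI–volume allometry is claimed.

Per subject, the geometry is driven by:

* a **frame** factor (outer semi-axes; weakly BMI-coupled, SD 0.07
  noise) — a caliper thickness cannot see the perimeter, areas and
  volumes can;
* an **adiposity** factor (all ring thicknesses; strongly BMI-coupled,
  `1 + 0.22 z + 0.12 ε`);
* azimuthal **sector multipliers** for the lateral, dorsal and ventral
  ring thickness (log-SDs 0.12/0.12/0.15) — the heterogeneity a
  single-location measure cannot average away;
* smooth axial **modulation** per sector (two low-order cosines with
  random phases, amplitude scaled by `profileHeterogeneity`, default
  0.35; strongest ventrally, weakest dorsally) — slow trends along the
  trunk that shift fat between slices;
* short-scale slice-to-slice **ripple** (iid, SD `0.5 ×
  profileHeterogeneity`) — local variability that integrated measures
  average away but single-slice measures sample at full strength;
* an axial **taper**, much stronger laterally (0.78–1.00) than in AP
  depth (0.92–1.00), placing the FH and ASIS levels caudal of — and
  laterally well inside — the widest abdominal slices, which is what
  makes ventrolateral truncation survivable for the landmark-anchored
  measures.

Males get the larger frame and thinner ring, females the reverse.
Landmarks are placed by a fixed deterministic rule (ASIS on the inner
boundary at 45° anterolateral; FH at ±0.6·a_in laterally, 0.15·b_in
posterior of the inner centre); patients' landmarks are anatomical, but
anatomy has no phantom analogue, so the rule is simply documented and
frozen.

This construction makes partial volumes better predictors than
single-slice measures (integration cancels the axial terms), makes the
FH-anchored box the best of the six (its anterior edge sits posterior of
the inner centre, so its captured share is nearly immune to the noisy
ventral wall, while the ASIS box's anterior edge cuts through the
ventral fat at a subject-dependent level), and leaves the thickness
calipers in between — the qualitative ordering reported for real
cohorts, reproduced here at the default seed and checked empirically in
the acceptance tests. With `profileHeterogeneity = 0` every subject is a
clean scaled ring and all surrogates become nearly exact.

What the phantoms do **not** model: actual body contours, bone,
visceral fat, segmentation errors, intensity or acquisition effects
(labels are taken as given), or any particular BMI–fat allometry.
Passing tests therefore validate the *operators* and the *statistical
machinery*, not anatomical accuracy; numeric values of fitted slopes on
phantoms are not comparable to patient-data coefficients.

## FOV truncation

`applyFovTruncation()` relabels tissue voxels (never background) outside
an elliptical FOV to label 3. The ellipse is centred in the dorsal
quarter of the grid with lateral semi-axis `fovWidth/2`, so
ventrolateral corners are clipped first — where truncation occurs in
practice. The operator only relabels (the voxel grid is untouched), is
idempotent, and leaves the volume unchanged whenever the FOV encloses
the body. Reference, boxes and bands each check for label-3 intrusions
independently, which yields the study's three regimes: untouched
subjects, subjects with surrogates but no reference (the common case),
and subjects excluded because the truncation reached their measurement
regions.

## Numerical choices and degenerate inputs

* Inclusive slice ranges on both boundary slices (the counting
  convention behind "typically 40–50 slices").
* Indices are 1-based `(col, row, slice)`; landmarks are stored in voxel
  indices, not mm, so files are unambiguous without header affines.
* A voxel belongs to an ellipse if its *centre* does (boundary `≤`);
  zero-thickness rings are valid and give exactly zero ASAT, thickness
  measures return 0 mm with a warning rather than erroring.
* The reference volume and the partial volumes share one code path
  (an in-box area accumulator), so the whole-grid box reproduces the
  reference *bit for bit*, not merely within tolerance.
* Fits require n ≥ 3 and a non-constant predictor; agreement statistics
  require n ≥ 2 (sample SD) and strictly positive references; groups
  below the minimum are skipped with a warning, never silently.
* All generation is a pure function of `(CohortSpec, seed)`; the global
  RNG state is saved and restored, and reruns are byte-identical.

## Problem sizes

The validation suite uses 20 random constant-profile phantoms at 1 mm
in-plane spacing for the volume oracle, a 0.25 mm dense grid for the
partial-area oracle, 50 truncation-invariance phantoms, 200 Monte-Carlo
replicates at n = 193 for regression recovery, and one full default
cohort (193 subjects at 2 mm in-plane spacing) for the ranking check —
sizes at which every oracle is still exact enough to discriminate real
defects while the whole suite runs in a few minutes.

## Known limitations

* The ellipse-ring family cannot represent concave body contours or a
  separate iliac plate; the HGF tangent rule is a phantom-specific
  approximation.
* The qualitative surrogate ranking is a property of the generator's
  default parameters at cohort size n = 193; it is stable at the default
  seed and typical alternatives, but individual reseeded cohorts can
  reorder closely ranked surrogates (notably V_p-FH vs V_p-ASIS, which
  differ by a few hundredths of R² — as they do in real data).
* In-sample agreement flatters all surrogates equally; out-of-sample
  error will be somewhat larger.
* Phantom-fitted conversion coefficients apply to phantoms only and
  must never be used on patient data.
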
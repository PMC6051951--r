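---
title: "Methods: harmonized dual-scanner ¹²⁴I quantification and two-point TIAC uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized dual-scanner quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(petharm)
```

## The problem

Lesion dosimetry for radioiodine therapy of differentiated thyroid cancer
rests on quantitative ¹²⁴I PET: the activity concentration (AC, kBq/mL)
measured in a lesion at two time points determines the projected ¹³¹I
time-integrated activity, and from it the absorbed dose. When two scanner
systems contribute measurements to the same dosimetric protocol — for
instance a PET/CT with CT-based attenuation correction as reference and a
PET/MR with MR-based attenuation correction under evaluation — their images
differ in ways that have nothing to do with the patient: reconstructed
spatial resolution, voxel grid, and the scanner-dependent bias from
¹²⁴I prompt-gamma coincidences (PGCs). Comparing per-lesion ACs without
removing these differences conflates attenuation-correction performance
with reconstruction-parameter mismatch.

`petharm` implements the comparison pipeline: a synthetic dual-scanner
phantom for validation, post-reconstruction image harmonization, seeded
spherical-VOI lesion quantification, agreement statistics with an explicit
acceptance rule, and a Monte-Carlo engine that translates AC imprecision
into dosimetric imprecision.

## Forward model of the virtual scanners

The phantom generator works on a ground-truth AC map: spheres of constant
AC on a uniform background, painted by voxel-center-in-sphere membership.
No partial-volume weighting enters the truth; finite resolution is
exclusively the scanner model's job, which keeps every truth-level quantity
checkable by exhaustive enumeration. A `scanner_model()` then observes the
truth through four effects, in order:

1. isotropic Gaussian blur at the scanner's reconstructed resolution
   (FWHM, mm), applied on the fine truth grid;
2. trilinear resampling onto the scanner's reconstructed voxel grid;
3. multiplication by the PGC recovery factor (0.8 for the older PET/CT
   generation, 0.9 for the newer PET/CT and the PET/MR — i.e. the imaged AC
   underestimates the true AC by 20% or 10%);
4. additive zero-mean Gaussian noise with per-voxel SD
   `noise_coeff * sqrt(AC)`, the Poisson-like signal dependence of
   reconstructed PET. Negative noisy voxels are kept (and counted in
   provenance), as in real reconstructions.

Each simulated volume takes one integer seed and is bit-reproducible.

## Harmonization

`harmonize_volume()` brings a native volume to the common comparison space
in three stages:

* **Resolution matching.** Point-spread functions are assumed Gaussian and
  to compose in quadrature, so the matched filter has
  `FWHM = sqrt(target² − native²)` (`matched_filter_fwhm()`). The default
  target is 7.0 mm, the coarsest clinical reconstruction among the systems
  modeled; matched filtering can only add blur, so the target must dominate
  every native resolution.
* **Grid matching.** Trilinear interpolation onto a common grid, default
  spacing 2.1 × 2.1 × 2.4 mm³.
* **PGC rescaling.** Division by the scanner's PGC factor. Since the imaged
  AC is `factor × true`, correction must divide; the operation is linear
  and commutes with the two spatial stages (a tested invariant), so its
  position in the chain is a matter of convention, not of result.

Smoothing is applied on the native grid, before regridding, because the
native grid carries the most information; whether a clinical analysis
smooths before or after regridding is generally not stated in protocols,
and for the smooth fields involved the difference is far below the
acceptance tolerances used here.

### Numerical choice: the discrete Gaussian

`gaussian_smooth()` convolves each axis with the discrete Gaussian kernel
`exp(−t) I_n(t)` with `t = σ²` in voxel units, rather than with a sampled
continuous Gaussian or an FFT transfer function. Three properties drove
the choice:

* the discrete semigroup is exact — smoothing by f₁ then f₂ equals one
  smoothing by `sqrt(f₁² + f₂²)` up to kernel-truncation error (~1e−12) —
  which is precisely the assumption the matched filter relies on;
* the kernel's second moment is exactly `σ²` at any σ, including the
  sub-voxel sigmas that arise when a 6.8-mm image is matched to 7.0 mm on a
  ~2-mm grid (a sampled kernel underblurs there);
* all weights are positive, so sharp edges cannot ring.

The field is treated as zero outside the grid (zero-padding); values within
a few σ of the border are attenuated, which is why lesions are required to
lie interior to the grid. Kernels are truncated where their mass falls
below 1e−15 of the peak and renormalized.

Trilinear resampling clamps out-of-range target centers to the source edge
(constant extrapolation); the pipeline constructs the common grid on the
intersection of the two native extents so clamping never actually engages.

## Lesion quantification

Two ACs are extracted per lesion and volume, mirroring clinical practice:

* **max-AC** — the hottest voxel within a seeded search sphere
  (`locate_max()`, default radius 10 mm around the manifest lesion center).
  The search is seeded because lesions are identified by position; an
  unconstrained argmax would jump between lesions. Ties are broken by
  distance to the seed, then lexicographic voxel index, making the result
  deterministic on flat fields.
* **avg-AC** — the unweighted mean over a 7-mm-diameter sphere
  (`sphere_mean()`, matching the harmonized resolution) centered on *each
  volume's own* max-AC voxel, not a shared center.

Membership is voxel-center-in-sphere with ≤ comparisons throughout —
unweighted and brute-force verifiable. Percentage differences are
`100 (test − ref)/ref`. Lesions are classed by trachea-surface distance
(adjacent ≤ 5 mm, inclusive) because MR attenuation maps are most fragile
where soft tissue meets air. Lesions whose reference avg-AC is at or below
1 kBq/mL are flagged (never deleted): at such count densities the
percentage difference is noise-dominated. The clinical exclusion criterion
is quoted only as "approximately 1 kBq/mL" without naming the AC type; this
package keys it to the reference avg-AC, the most stable of the four
candidates, and reports summaries both with and without the flag.

## Agreement statistics

`summarize_agreement()` reports, per AC type:

* descriptive statistics in the form mean (median) ± SD (min to max), SD
  with the n−1 denominator;
* Lin's concordance correlation, `ρ_c = 2 s_xy / (s_x² + s_y² + (x̄−ȳ)²)`
  with n-denominator moments (Lin's original estimator — mixing the two
  denominator conventions changes third-decimal results, so both choices
  are pinned and tested against a direct moment-formula oracle). The 95% CI
  uses the Fisher z transform with Lin's asymptotic variance; the strength
  class follows McBride's bands, with the sub-0.95 bands (moderate, poor)
  filled in from the criteria's standard form;
* the Mann-Whitney U comparison of adjacent vs distant lesions, per AC
  type. The implementation delegates to `stats::wilcox.test` (exact
  enumeration for small untied samples, otherwise the normal approximation
  with midrank-tie and continuity corrections); the test suite checks the
  exact branch against full permutation enumeration;
* the acceptance verdict: mean within ±10 percentage points (accuracy) and
  SD at most 25 points (precision), boundaries inclusive — an interior
  passing result is unaffected by the boundary convention, which is fixed
  here for determinism.

## The comparison study

`run_comparison_study()` evaluates four correction modes — none, PGC
scaling only, harmonization only, and PGC + harmonization — from a single
pair of simulated scans, so all modes share one noise realization and are
directly comparable. On mismatched scanners the modes are ordered: each
correction reduces the absolute mean bias, the uncorrected mode violates
the ±10% accuracy bound, and the fully corrected mode passes both bounds
(tested on noise-free phantoms, and holding under the default noisy
conditions).

### Default study conditions

Chosen once, as a plausible clinical scenario, and not tuned thereafter:

* truth grid 1.0 mm isotropic, 150 × 150 × 120 mm (finer than every
  scanner grid, so resampling is well posed);
* reference scanner: 1.73 × 1.73 × 2.43 mm³ voxels, 6.7 mm FWHM, PGC
  factor 0.8, noise coefficient 0.4;
* test scanner: 2.09 × 2.09 × 2.03 mm³ voxels, 6.3 mm FWHM, PGC factor
  0.9, noise coefficient 0.6 (shorter emission time per bed, hence noisier);
* 40 lesions, diameters uniform 5–20 mm (no published size distribution
  exists for this setting; this range brackets thyroid remnants and nodal
  metastases), ACs log-uniform 0.2–800 kBq/mL (the span reported
  clinically), trachea distances uniform 0–30 mm so roughly one lesion in
  six is "adjacent";
* background 0.05 kBq/mL.

### What the generator emulates — and what it does not

The phantom reproduces the effects the pipeline corrects (resolution,
grid, PGC bias) and one it cannot (noise). It does **not** model OSEM
reconstruction and its non-Gaussian, object-dependent PSF; attenuation- or
scatter-correction errors (including the MR-segmentation failures near air
that motivate the trachea subgroup — trachea distance is a label here, not
a physical effect); patient motion or misregistration; or magnetic-field
positron-range effects. Passing end-to-end tests therefore demonstrates
that the pipeline's *algorithms* are correct and self-consistent, not that
any particular clinical scanner pair meets the acceptance rule; on real
data the residual differences would include the physics the phantom omits.

## TIAC uncertainty simulation

The dosimetric stake of AC precision is quantified by
`simulate_tiac_uncertainty()`. The two-point protocol measures ¹²⁴I ACs at
24 h and 120 h; a mono-exponential through the two points gives the
effective decay constant `λ_eff = ln(a24/a120)/96 h`. Projection to the
therapy nuclide keeps the biological clearance and swaps the physical
decay: `λ131 = λ_eff − λ_phys,124 + λ_phys,131` with physical half-lives
100.22 h (¹²⁴I) and 192.6 h (¹³¹I, standard nuclear data). The ¹³¹I TIAC
contribution between the scans is the area under the projected curve,
`B(24) (1 − e^{−λ131·96})/λ131`, with the analytic limit `B(24)·96` used
when `|λ131·96| < 1e−12` (continuity across the switch is tested). The
amplitude convention — re-projecting the 24-h AC by the physical-decay
ratio — affects only the absolute TIAC, never a relative SD, which is
verified by the scale-invariance test.

Each Monte-Carlo draw perturbs the two ACs independently with Gaussian
noise of equal relative SD (the first-order assumption for identically
acquired scans); draws producing a nonpositive AC are redrawn (truncated
normal) and counted, because the log of a nonpositive ratio is undefined —
at the noise levels of interest the rejection count is essentially zero.
The primary uncertainty figure is the RMS percentage difference from the
*reference* TIAC (the deviation that matters for a dose estimate anchored
to the true curve); the SD about the sample mean is reported alongside and
differs only through the small nonlinearity bias.

The effective-half-life sweep defaults to 24, 48, 72 and 96 h, bracketing
thyroid-remnant and metastasis kinetics; the uncertainty is maximal at the
short end, where the late-point measurement leverages the fit most. Under
these defaults the simulation reproduces the known behaviour of the
protocol: 15% AC noise yields ≈ 11–12% TIAC uncertainty and 25% AC noise
stays below the 20% level that is conventionally regarded as acceptable
for absorbed-dose precision (the acceptance suite and
`scripts/acceptance.R` recompute both figures from scratch; with 10⁵ draws
per cell the Monte-Carlo SE is ≈ 0.05 percentage points).

First-order error propagation explains the numbers: writing the TIAC's
log-derivatives with respect to the two measured ACs, the two sensitivity
exponents sum to one, so the ratio of TIAC to AC relative SD lies in
[1/√2, 1] in the small-noise limit — about 0.75 at a 24-h effective
half-life. This delta-method bound is enforced as a test at 2% AC noise.

## Problem sizes

The test suite runs phantoms of 60³–110³ voxels at 1 mm (a few seconds per
end-to-end case) and Monte-Carlo cells of 10³–2×10⁵ draws; the acceptance
sweeps use 10⁵ draws per cell, where the Monte-Carlo SE of the reported SD
is ~0.05 percentage points, i.e. well below all decision tolerances. These
sizes were chosen so the whole suite exercises every contract at
full numerical fidelity while remaining quick enough to run habitually.

## Known limitations

* The harmonization assumes Gaussian, spatially invariant PSFs; iterative
  reconstructions violate both assumptions mildly, and the residual error
  appears in the end-to-end tolerance (< 2% on resolvable lesions) rather
  than being modeled.
* Emission-time (noise-level) differences between scanners are *not*
  harmonized, matching clinical reality; they show up as precision (SD),
  not accuracy (mean), in the agreement summaries.
* The exclusion threshold, acceptance bounds, and McBride bands are
  conventions, exposed as arguments rather than hard-coded policy.
* The TIAC simulation propagates AC uncertainty only; it does not add
  lesion-mass or S-value uncertainty, and it models the two-point protocol,
  not multi-point curve fitting.
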
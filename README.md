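# petharm

Quantitative comparison of ¹²⁴I PET activity concentrations (ACs) between
two scanner systems — e.g. a CT-attenuation-corrected PET/CT as reference
and an MR-attenuation-corrected PET/MR under evaluation — plus the
dosimetric consequence of the residual AC uncertainty for two-point
radioiodine lesion dosimetry.

It is written for physicists and dosimetrists who need to (i) decide
whether two scanners can feed the same dosimetric protocol and (ii) know
how much AC imprecision their projected ¹³¹I time-integrated activity
(TIAC) can absorb. Since clinical paired scans are rarely shareable, the
package ships a synthetic dual-scanner phantom generator so the entire
pipeline is testable end to end.

## What it computes

**Harmonization.** Two reconstructions are made comparable by (1) matched
Gaussian filtering to a common resolution under the PSF-quadrature rule
`FWHM_filter = sqrt(FWHM_target² − FWHM_native²)` (default target 7.0 mm),
(2) trilinear regridding to a common voxel grid (default
2.1 × 2.1 × 2.4 mm³), and (3) prompt-gamma-coincidence (PGC) rescaling:
the imaged ¹²⁴I AC is `factor × true` (factor 0.8 or 0.9 depending on the
system generation), so correction divides by the factor.

**Quantification.** Per lesion and volume: the max-AC (hottest voxel
within a seeded 10-mm search sphere) and the avg-AC (unweighted mean over
a 7-mm-diameter sphere centered on that volume's own max voxel), then the
percentage difference `100 (test − ref)/ref`, a trachea-proximity class
(adjacent ≤ 5 mm), and a low-AC exclusion flag (reference avg-AC
≤ 1 kBq/mL).

**Agreement.** Mean (median) ± SD (min to max) of the percentage
differences; Lin's concordance correlation
`ρ_c = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` with 95% CI and McBride class;
Mann-Whitney U for adjacent vs distant lesions; and the acceptance rule
|mean| ≤ 10% (accuracy) and SD ≤ 25% (precision).

**TIAC uncertainty.** Monte-Carlo propagation of AC noise through the
two-point mono-exponential model: `λ_eff = ln(a24/a120)/96 h`, projected to
¹³¹I via `λ131 = λ_eff − λ_phys,124 + λ_phys,131` (physical half-lives
100.22 h and 192.6 h), TIAC = area under the projected curve over
24–120 h. Both ACs receive independent Gaussian noise of equal relative
SD; the relative SD of the resulting TIAC distribution is the dosimetric
uncertainty.

## Worked example

```r
library(petharm)

study <- run_comparison_study(study_config())
study
#> Dual-scanner comparison study
#>   40 lesions (7 excluded at low AC)
#>   none                avg:   15.2% +/-  16.6% [FAIL]   max:   18.0% +/-  14.1% [FAIL]
#>   pgc                 avg:    1.6% +/-  14.7% [pass]   max:    5.3% +/-  12.3% [pass]
#>   harmonization       avg:   13.8% +/-   5.5% [FAIL]   max:   13.2% +/-  10.5% [FAIL]
#>   pgc+harmonization   avg:    1.2% +/-   4.9% [pass]   max:    0.6% +/-   9.2% [pass]
#>   TIAC sweep: 20 cells, max rel SD 19.2% at AC rel SD 25%
```

Reading the mode table: with no corrections the test scanner's avg-AC is
biased +15.2% against the reference — outside the ±10% accuracy bound —
because the two systems differ in PGC recovery (0.8 vs 0.9) and
resolution (6.7 vs 6.3 mm FWHM). PGC scaling alone removes the scale
mismatch, harmonization alone removes the resolution/grid mismatch, and
applying both leaves a +1.2% ± 4.9% residual that passes both acceptance
bounds. Seven of the forty synthetic lesions fall at or below 1 kBq/mL
reference avg-AC and are flagged out of these summaries (they remain in
the records and in the `exclusions = "all"` rows of `tidy(study)`).

```r
tidy(study)                                  # mode table as a tibble
glance(study$summaries[["pgc+harmonization"]])
autoplot(study$summaries[["pgc+harmonization"]], ac_type = "avg")  # difference plot
autoplot(study$tiac)                         # TIAC uncertainty curves

# TIAC uncertainty on its own: 15% AC noise, 48-h effective half-life
tidy(simulate_tiac_uncertainty(tiacsim_config(rel_sd_ac = 0.15, t_eff_124 = 48)))
#> # A tibble: 1 × 8
#>   t_eff_h rel_sd_ac rel_sd_tiac_pct sd_about_mean_pct mean_pct_diff tiac_ref n_draws n_resampled
#>     <dbl>     <dbl>           <dbl>             <dbl>         <dbl>    <dbl>   <int>       <int>
#> 1      48      0.15            10.8              10.8        -0.393    6389.  100000           0
```

A 15% relative SD on both AC measurements propagates to ≈ 11% relative SD
on the projected ¹³¹I TIAC contribution — dosimetric precision degrades
*less* than imaging precision, because the two-point fit splits the error
between amplitude and slope.

Study configurations can also be read from YAML
(`read_study_config(system.file("extdata", "example_study.yaml", package = "petharm"))`),
and phantom bundles round-trip through NIfTI + CSV + JSON with
`write_phantom_bundle()` / `read_phantom_bundle()`.

## Layout

- `R/` — phantom generator, harmonization, quantification, agreement
  statistics, TIAC Monte-Carlo, study pipeline, plotting and tidiers.
- `tests/testthat/` — unit, property and oracle tests (trilinear vs
  8-corner sums, sphere membership vs enumeration, CCC vs moment formula,
  Mann-Whitney vs permutation enumeration, Gaussian quadrature semigroup),
  plus the end-to-end acceptance suite.
- `vignettes/petharm-methods.Rmd` — the model, its assumptions, parameter
  choices, and what the synthetic phantom does and does not emulate.
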
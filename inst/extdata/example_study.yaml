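# Example dual-scanner comparison study configuration.
# Any key left out falls back to the study_config() defaults.
grid:
  shape: [150, 150, 120]
  spacing_mm: 1.0
background_ac: 0.05
n_lesions: 40
lesion_seed: 101
ref_scanner:
  name: ref_petct
  spacing_mm: [1.73, 1.73, 2.43]
  resolution_fwhm_mm: 6.7
  pgc_factor: 0.8
  noise_coeff: 0.4
  emission_time_min: 3.5
test_scanner:
  name: test_petmr
  spacing_mm: [2.09, 2.09, 2.03]
  resolution_fwhm_mm: 6.3
  pgc_factor: 0.9
  noise_coeff: 0.6
  emission_time_min: 3
scan_seeds:
  ref: 211
  test: 212
target:
  fwhm_mm: 7.0
  spacing_mm: [2.1, 2.1, 2.4]
exclusion_threshold: 1.0
mean_limit: 10
sd_limit: 25
tiac:
  rel_sd_levels: [0.05, 0.10, 0.15, 0.20, 0.25]
  t_eff_list: [24, 48, 72, 96]
  n_draws: 100000
  seed: 7
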
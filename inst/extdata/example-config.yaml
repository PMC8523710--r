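# Desk-scale pipeline configuration. Units: seconds (tr, hp_cutoff),
# millimetres (fwhm_mm, voxel sizes), voxels (grid, radius).
seed: 7
cohort:
  n_per_group: 2
  grid_shape: [10, 10, 10]
  n_items_old: 6
  n_encoding_runs: 2
  n_recognition_runs: 2
  roi_size: 3
analysis:
  fwhm_mm: 6
  hp_cutoff: 128
  ar1: global
  radius: 3
  n_perm: 150
  variant: trial_specific
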
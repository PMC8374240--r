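# Example study configuration for run_study(study_config_from_yaml(...)).
# Desk-scale smoke settings; raise grid_shape / subject counts /
# n_iterations for a full-size study.
global_seed: 7
split_fraction: 0.8
cohort:
  n_hcs: 8
  n_msp: 8
  channels: [T1w, PD, MT, R1, "R2*"]
  grid_shape: [32, 32, 32]
  voxel_size_mm: [2.5, 2.5, 2.5]
  n_scanners: 2
  lesion_count_range: [1, 2]
  lesion_radius_range_mm: [4, 5]
  effect:
    null_effect: false
    mean_shift:
      "MT:NAWM": -0.10
      "MT:GM": -0.06
      "R1:NAWM": -0.05
validation_cohort:
  n_hcs: 10
  n_msp: 3
  channels: [T1w]
  grid_shape: [32, 32, 32]
  n_scanners: 3
  lesion_count_range: [1, 2]
  lesion_radius_range_mm: [4, 5]
selection:
  n_iterations: 5
  cohort_size: 40
model:
  n_boot: 100
  cohort_size: 100
output_dir: study_out
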
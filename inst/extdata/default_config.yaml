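# Default two-scanner texture-phantom study configuration.
# Scanner A exposes 6 reconstruction-filter levels and 3 tube voltages
# (21 one-factor-at-a-time settings incl. baseline); scanner B exposes
# 2 filter levels and 2 tube voltages (16 settings).
master_seed: 1
phantom:
  cylinder_diameter: 150      # mm
  cylinder_length: 40         # mm
  fill_fractions: [0.10, 0.20, 0.40]
  background_hu: 40           # urethane-like soft tissue
  insert_hu: -40              # ABS-like insert, -80 HU relative contrast
  lattice_period: 2           # mm
  supersample_factor: 2       # truth voxel = lattice_period / factor
scanners:
  matrix_size: 512            # in-plane reconstruction matrix
  A:
    hu_offset: 0
    noise_sigma_ref: 12       # HU at reference_ma
    reference_ma: 100
    filter_levels: [1, 2, 3, 4, 5, 6]
    filter_range_sigma: 20    # HU per filter level
    kvp: [80, 100, 140]
    slice_thickness: [1, 2, 3, 4, 5]
    fov: [125, 500]
    ma: [40, 60, 80, 100]
    baseline: {slice_thickness: 3, fov: 500, kvp: 100, ma: 100, filter: 0}
  B:
    hu_offset: 4
    noise_sigma_ref: 18
    reference_ma: 100
    filter_levels: [2, 5]     # "Mild" and "Strong"
    filter_range_sigma: 20
    kvp: [100, 135]
    slice_thickness: [1, 2, 3, 4, 5]
    fov: [125, 500]
    ma: [40, 60, 80, 100]
    baseline: {slice_thickness: 3, fov: 500, kvp: 100, ma: 100, filter: 0}
rois:
  radius: 16                  # mm, spheres at the pattern-region centers
analysis:
  n_bins: 20
  tally_cutoff: 0.15
  reliable_band: 0.05
  clip_max: 0.20
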
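# Mid region preset: approximately midway between the Golgi and the
# plasma membrane, 3-6 um from the PM.  The published per-region table
# reports only the interior and peripheral endpoint statistics, so this
# preset interpolates between them; ten peripheral tomograms.
name: region2
landmark: PM
distance_um: 4.5
n_tomograms: 10
generator:
  grid_shape: [512, 512, 110]
  voxel_size_nm: 2
  target_density_per_um3: 33
  diameter_mean_nm: 230
  diameter_sd_nm: 47
  mature_fraction: 0.22
  membrane_thickness_nm: 7
  core_to_lumen_ratio: 0.5
  cluster_prevalence: 0.10
  noise_sd: 0.15
  wedge_half_angle_deg: 30
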
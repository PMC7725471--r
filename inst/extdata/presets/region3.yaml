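# Peripheral region preset: adjacent to the plasma membrane, within 2 um
# of the PM.  Generator calibrated to the published region-3 statistics:
# lumen diameter 266 +/- 52 nm, 32% mature, 51 vesicles per um^3 (a
# packing near the jamming limit of non-overlapping spheres in a
# 220-nm slab; the achieved count is reported by the sampler); ten
# peripheral tomograms.
name: region3
landmark: PM
distance_um: 1.0
n_tomograms: 10
generator:
  grid_shape: [512, 512, 110]
  voxel_size_nm: 2
  target_density_per_um3: 51
  diameter_mean_nm: 266
  diameter_sd_nm: 52
  mature_fraction: 0.32
  membrane_thickness_nm: 7
  core_to_lumen_ratio: 0.5
  cluster_prevalence: 0.10
  noise_sd: 0.15
  wedge_half_angle_deg: 30
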
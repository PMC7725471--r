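# Interior region preset: just distal from the Golgi, 3-8 um from the
# nuclear membrane.  Generator calibrated to the published region-1
# vesicle statistics: lumen diameter 196 +/- 42 nm, 12% mature,
# 16 vesicles per um^3; five tomograms of cryo-FIB lamellae.
name: region1
landmark: NM
distance_um: 5.5
n_tomograms: 5
generator:
  grid_shape: [512, 512, 110]
  voxel_size_nm: 2
  target_density_per_um3: 16
  diameter_mean_nm: 196
  diameter_sd_nm: 42
  mature_fraction: 0.12
  membrane_thickness_nm: 7
  core_to_lumen_ratio: 0.5
  cluster_prevalence: 0.10
  noise_sd: 0.15
  wedge_half_angle_deg: 30
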
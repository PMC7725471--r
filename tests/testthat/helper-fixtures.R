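# Shared fixtures, built once per session and cached.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# analytically rasterized solid sphere: voxel centers inside the radius.
# The center is displaced from the lattice by a fixed sub-voxel offset so
# results do not depend on accidental lattice alignment.
raster_sphere <- function(d_nm, vs, off_nm = c(0.83, 1.37, 0.59),
                          pad_nm = 8) {
  r <- d_nm / 2
  n <- ceiling((d_nm + 2 * pad_nm) / vs)
  ctr <- n / 2 * vs + off_nm
  ax <- lapply(1:3, function(a) ((1:n) - 0.5) * vs - ctr[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  d2 <= r^2
}

# 20-vesicle noiseless field used across detection/morphometry tests
field20_config <- function(seed = 20) {
  generator_config(grid_shape = c(420, 420, 110), n_vesicles = 20,
                   diameter_mean_nm = 150, diameter_sd_nm = 20,
                   mature_fraction = 0.4, cluster_prevalence = 0,
                   noise_sd = 0, wedge_half_angle_deg = 30, seed = seed)
}

tomo20_clean <- function() fixture("tomo20_clean", function() {
  generate_tomogram(field20_config(), use_wedge = FALSE, use_noise = FALSE)
})

tomo20_wedge <- function() fixture("tomo20_wedge", function() {
  clean <- tomo20_clean()
  vol <- apply_missing_wedge(clean$clean, 30)
  list(field = clean$field, volume = vol, labels = clean$labels)
})

# truth outer diameters joined to measured records via IoU matching
match_measured_to_truth <- function(labels, truth_labels, records, field) {
  m <- match_to_truth(labels, truth_labels)
  dd <- merge(m$pairs, records, by.x = "pred_id", by.y = "id")
  merge(dd, field$vesicles[, c("id", "outer_diameter_nm", "mature",
                               "n_clusters")],
        by.x = "truth_id", by.y = "id", suffixes = c("", "_true"))
}
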
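test_that("empty request gives an empty field and a flat rendering", {
  cfg <- generator_config(grid_shape = c(32, 32, 16), n_vesicles = 0)
  f <- sample_vesicle_field(cfg)
  expect_identical(nrow(f$vesicles), 0L)
  r <- render_field(f, cfg)
  expect_true(all(r$volume$data == cfg$intensity$background))
  expect_true(all(r$labels$labels == 0L))
})

test_that("the same config and seed reproduce the field and volume exactly", {
  cfg <- generator_config(grid_shape = c(96, 96, 48), n_vesicles = 2,
                          diameter_mean_nm = 60, diameter_sd_nm = 6,
                          cluster_prevalence = 1, seed = 11)
  f1 <- sample_vesicle_field(cfg)
  f2 <- sample_vesicle_field(cfg)
  expect_identical(f1$vesicles, f2$vesicles)
  expect_identical(f1$clusters, f2$clusters)
  r1 <- render_field(f1, cfg)
  r2 <- render_field(f2, cfg)
  expect_identical(r1$volume$data, r2$volume$data)
  expect_identical(r1$labels$labels, r2$labels$labels)
})

test_that("sampled diameters follow the truncated normal calibration", {
  # wide virtual slab: sampling does not allocate the grid
  cfg <- generator_config(grid_shape = c(7000, 7000, 110), voxel_size_nm = 2,
                          n_vesicles = 1000, diameter_mean_nm = 266,
                          diameter_sd_nm = 52, seed = 5)
  f <- sample_vesicle_field(cfg)
  expect_gte(nrow(f$vesicles), 990)  # plenty of room at this density
  # CLT bound: mean within 3 * 52 / sqrt(n) of 266
  expect_lt(abs(mean(f$vesicles$lumen_diameter_nm) - 266),
            3 * 52 / sqrt(nrow(f$vesicles)))
  expect_true(all(f$vesicles$lumen_diameter_nm >
                    2 * cfg$membrane_thickness_nm))
})

test_that("fields respect non-overlap, gaps, and slab margins", {
  cfg <- generator_config(grid_shape = c(800, 800, 110), n_vesicles = 12,
                          diameter_mean_nm = 180, diameter_sd_nm = 30,
                          seed = 9)
  f <- sample_vesicle_field(cfg)
  v <- f$vesicles
  expect_gte(nrow(v), 10)
  ctr <- as.matrix(v[, c("cx_nm", "cy_nm", "cz_nm")])
  r <- v$outer_diameter_nm / 2
  dmat <- as.matrix(dist(ctr))
  need <- outer(r, r, `+`) + cfg$min_gap_nm
  diag(dmat) <- Inf
  expect_true(all(dmat >= need - 1e-9 | !is.finite(dmat)))
  # lateral containment: one radius plus detector margin from x/y faces
  expect_true(all(v$cx_nm - r > 0 & v$cx_nm + r < 1600))
  expect_true(all(v$cy_nm - r > 0 & v$cy_nm + r < 1600))
  # z margins: centers inside the slab, cores never cut
  expect_true(all(v$cz_nm >= cfg$min_z_margin_nm &
                    v$cz_nm <= 220 - cfg$min_z_margin_nm))
  # maturity flag and core diameter are consistent
  expect_identical(v$mature, v$core_diameter_nm > 0)
  expect_equal(v$core_diameter_nm[v$mature],
               0.5 * v$lumen_diameter_nm[v$mature])
})

test_that("clusters lie inside the lumen, adjacent to the core when mature", {
  cfg <- generator_config(grid_shape = c(900, 900, 110), n_vesicles = 14,
                          diameter_mean_nm = 220, diameter_sd_nm = 20,
                          mature_fraction = 0.5, cluster_prevalence = 1,
                          seed = 21)
  f <- sample_vesicle_field(cfg)
  cl <- f$clusters
  expect_gt(nrow(cl), 0)
  v <- f$vesicles
  for (i in seq_len(nrow(cl))) {
    ves <- v[v$id == cl$vesicle_id[i], ]
    gap <- sqrt(sum((c(cl$cx_nm[i], cl$cy_nm[i], cl$cz_nm[i]) -
                       c(ves$cx_nm, ves$cy_nm, ves$cz_nm))^2))
    # strictly inside the lumen
    expect_lte(gap + cl$diameter_nm[i] / 2, ves$lumen_diameter_nm / 2)
    if (ves$mature) # attached to the core surface
      expect_equal(gap, ves$core_diameter_nm / 2 + cl$diameter_nm[i] / 2,
                   tolerance = 1e-6)
  }
  # one or two clusters per affected vesicle
  expect_true(all(v$n_clusters %in% 0:2))
})

test_that("an impossible packing request is refused; jamming is reported", {
  cfg <- generator_config(grid_shape = c(100, 100, 110), n_vesicles = 50,
                          diameter_mean_nm = 180, diameter_sd_nm = 10,
                          seed = 2)
  expect_error(sample_vesicle_field(cfg), "infeasible packing")
  cfg2 <- generator_config(grid_shape = c(260, 260, 110), n_vesicles = 6,
                           diameter_mean_nm = 200, diameter_sd_nm = 5,
                           seed = 2)
  expect_warning(f <- sample_vesicle_field(cfg2), "packing jammed")
  expect_lt(f$achieved, f$requested)
  expect_identical(nrow(f$vesicles), f$achieved)
})

test_that("rendered vesicles have the right voxel volume and core contrast", {
  cfg <- generator_config(grid_shape = c(140, 140, 140), n_vesicles = 1,
                          diameter_mean_nm = 186, diameter_sd_nm = 1e-9,
                          mature_fraction = 1, cluster_prevalence = 0,
                          allow_truncation = FALSE, seed = 3)
  f <- sample_vesicle_field(cfg)
  r <- render_field(f, cfg)
  d_out <- f$vesicles$outer_diameter_nm
  n_vox <- sum(r$labels$labels == 1L)
  expect_equal(n_vox * cfg$voxel_size_nm^3, pi / 6 * d_out^3,
               tolerance = 0.02)
  # mean intensity in the core sphere exceeds the lumen shell around it
  vs <- cfg$voxel_size_nm
  ctr <- unlist(f$vesicles[1, c("cx_nm", "cy_nm", "cz_nm")])
  ax <- lapply(1:3, function(a) ((1:140) - 0.5) * vs - ctr[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r_core <- f$vesicles$core_diameter_nm / 2
  r_lum <- f$vesicles$lumen_diameter_nm / 2
  expect_gt(mean(r$volume$data[d2 <= r_core^2]),
            mean(r$volume$data[d2 > r_core^2 & d2 <= r_lum^2]))
})

test_that("a vesicle outside the grid is an error when truncation is off", {
  cfg <- generator_config(grid_shape = c(140, 140, 140), n_vesicles = 1,
                          diameter_mean_nm = 150, diameter_sd_nm = 1e-9,
                          allow_truncation = FALSE, seed = 3)
  f <- sample_vesicle_field(cfg)
  f$vesicles$cz_nm <- 270  # push it through the top face
  expect_error(render_field(f, cfg), "outside the grid")
})

test_that("noise is seeded, additive, and has the requested scale", {
  v <- voxel_volume(array(0, c(64, 64, 64)), 2)
  expect_identical(add_noise(v, 0, seed = 1)$data, v$data)
  n1 <- add_noise(v, 0.2, seed = 7)
  n2 <- add_noise(v, 0.2, seed = 7)
  expect_identical(n1$data, n2$data)
  n3 <- add_noise(v, 0.2, seed = 8)
  expect_false(identical(n1$data, n3$data))
  # chi-square concentration: sample SD within 5% of 0.2 at 64^3
  expect_equal(sd(n1$data), 0.2, tolerance = 0.05)
})
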
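# convenience: minimal records table with given diameters/flags
fake_records <- function(d, mature = rep(FALSE, length(d)),
                         clusters = rep(0L, length(d))) {
  n <- length(d)
  if (n == 0L) return(vesiclehood:::.empty_table("vesicles"))
  df <- data.frame(id = seq_len(n), tomogram_id = "t1",
                   region_label = "region1",
                   cx_nm = 0, cy_nm = 0, cz_nm = 0,
                   cross_section_area_nm2 = pi * (d / 2)^2,
                   diameter_nm = d,
                   volume_nm3 = volume_from_diameter(d),
                   in_volume_nm3 = volume_from_diameter(d),
                   n_voxels = 1L, voxel_volume_nm3 = volume_from_diameter(d),
                   mature = mature, contrast_statistic = 0,
                   cluster_count = clusters,
                   truncated = FALSE, edge_xy = FALSE, edge_z = FALSE)
  vesiclehood:::.as_table(df, "vesicles")
}

test_that("distances map to the published three-region scheme", {
  expect_identical(assign_region(1.5, "PM"), "region3")
  expect_identical(assign_region(5, "NM"), "region1")
  expect_identical(assign_region(4.5, "PM"), "region2")
  # closed interval ends
  expect_identical(assign_region(2, "PM"), "region3")
  expect_identical(assign_region(3, "NM"), "region1")
  expect_identical(assign_region(8, "NM"), "region1")
  # the gap between region 3 and region 2 is unassigned, as is far NM
  expect_identical(assign_region(2.5, "PM"), NA_character_)
  expect_identical(assign_region(10, "NM"), NA_character_)
  # overlapping bands for one landmark are rejected
  bad <- list(region_spec("a", "PM", 0, 3), region_spec("b", "PM", 2, 5))
  expect_error(assign_region(1, "PM", bad), "overlapping")
})

test_that("region summaries match hand arithmetic", {
  rec <- fake_records(c(100, 200, 300), mature = c(TRUE, FALSE, FALSE))
  s <- summarize_region(rec, 1, "region1", 1L)
  expect_identical(s$n_vesicles, 3L)
  expect_equal(s$count_density_per_um3, 3)
  expect_equal(s$mean_diameter_nm, 200)
  expect_equal(s$median_diameter_nm, 200)
  expect_equal(s$mature_fraction, 1 / 3)
  # V = pi d^3/6: (0.5236 + 4.1888 + 14.137)e6 / 1e9
  expect_equal(s$volume_fraction, 0.0188496, tolerance = 1e-4)
  # count density x volume = n, exactly
  expect_identical(s$count_density_per_um3 * s$tomogram_volume_um3,
                   as.numeric(s$n_vesicles))
  # all mature
  s2 <- summarize_region(fake_records(c(150, 150), mature = c(TRUE, TRUE)),
                         0.5, "r", 1L)
  expect_equal(s2$mature_fraction, 1)
  # empty set
  s0 <- summarize_region(vesiclehood:::.empty_table("vesicles"), 2, "r", 2L)
  expect_identical(s0$n_vesicles, 0L)
  expect_equal(s0$count_density_per_um3, 0)
  expect_true(is.na(s0$mean_diameter_nm))
  expect_error(summarize_region(rec, 0), "positive")
  # a physically impossible volume fraction is an error, not a number
  big <- fake_records(rep(400, 40))
  expect_error(summarize_region(big, 0.5, "r", 1L), "exceeds 1")
})

test_that("quantiles use the linear-interpolation convention", {
  rec <- fake_records(c(100, 150, 200, 250))
  s <- summarize_region(rec, 1, "r", 1L)
  expect_equal(s$q25_diameter_nm, quantile(c(100, 150, 200, 250), 0.25,
                                           type = 7, names = FALSE))
  expect_equal(s$q25_diameter_nm, 137.5)
  expect_equal(s$q75_diameter_nm, 212.5)
})

test_that("region comparisons behave on degenerate and shifted groups", {
  a <- fake_records(seq(150, 250, length.out = 20))
  # identical groups: t = 0, Mann-Whitney p near 1
  cmp <- compare_regions(a, a, "diameter")
  expect_equal(cmp$welch_t, 0)
  expect_gte(cmp$mann_whitney_p, 0.99)
  expect_false(cmp$significant)
  expect_identical(cmp$direction, "equal")
  # constant shift: direction b > a
  b <- fake_records(seq(150, 250, length.out = 20) + 100)
  cmp2 <- compare_regions(a, b, "diameter")
  expect_identical(cmp2$direction, "b > a")
  expect_lt(cmp2$welch_p, 1e-4)
  # volume variable works and errors are informative
  expect_s3_class(compare_regions(a, b, "volume"), "region_comparison")
  expect_error(compare_regions(a, fake_records(numeric(0))), "non-empty")
  expect_error(compare_regions(a, fake_records(180)), "at least 2")
})

test_that("the published group sizes give overwhelming diameter power", {
  # R1: N(196, 42^2), n = 25; R3: N(266, 52^2), n = 130
  hits_w <- 0L; hits_u <- 0L
  set.seed(4242)
  for (i in 1:100) {
    a <- rnorm(25, 196, 42)
    b <- rnorm(130, 266, 52)
    cmp <- compare_regions(a, b)
    hits_w <- hits_w + (cmp$welch_p < 1e-4)
    hits_u <- hits_u + (cmp$mann_whitney_p < 1e-4)
  }
  expect_gte(hits_w, 99L)
  expect_gte(hits_u, 99L)
})

test_that("cluster prevalence summaries count affected vesicles", {
  rec <- fake_records(rep(200, 10), clusters = c(2L, 1L, rep(0L, 8)))
  cs <- count_clusters(rec)
  expect_equal(cs$prevalence, 0.2)
  expect_equal(cs$mean_clusters_per_affected, 1.5)
  expect_identical(cs$n, 10L)
  cs0 <- count_clusters(fake_records(rep(200, 4)))
  expect_equal(cs0$prevalence, 0)
  expect_true(is.na(cs0$mean_clusters_per_affected))
})

test_that("truth summaries pool correctly across tomograms", {
  cfgs <- lapply(c(61, 62), function(s)
    generator_config(grid_shape = c(600, 600, 110), n_vesicles = 6,
                     diameter_mean_nm = 180, diameter_sd_nm = 20,
                     mature_fraction = 0.5, seed = s))
  fields <- lapply(cfgs, sample_vesicle_field)
  pooled <- summarize_truth_pooled(fields, "r")
  singles <- lapply(fields, summarize_truth)
  expect_identical(pooled$n_vesicles,
                   sum(vapply(singles, function(s) s$n_vesicles, 0L)))
  expect_equal(pooled$tomogram_volume_um3,
               sum(vapply(singles, function(s) s$tomogram_volume_um3, 0)))
  d_all <- unlist(lapply(fields, function(f) f$vesicles$outer_diameter_nm))
  expect_equal(pooled$mean_diameter_nm, mean(d_all))
  # densities pool by total volume, not by averaging
  expect_equal(pooled$count_density_per_um3,
               pooled$n_vesicles / pooled$tomogram_volume_um3)
})

test_that("per-vesicle assignment measures distance from a landmark plane", {
  rec <- fake_records(c(150, 150, 150))
  rec$cx_nm <- c(500, 2500, 5000)   # 0.5, 2.5, 5 um from a plane at x = 0
  out <- assign_regions_per_vesicle(rec, "PM", plane_nm = 0, axis = "x")
  expect_identical(out$region_label, c("region3", NA, "region2"))
  out2 <- assign_regions_per_vesicle(rec, "NM", plane_nm = 0, axis = "x")
  expect_identical(out2$region_label, c(NA, NA, "region1"))
})
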
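test_that("diameter and volume formulas are exact identities", {
  expect_equal(diameter_from_area(pi), 2)
  expect_equal(diameter_from_area(pi * 98^2), 196)    # circle of radius 98
  expect_equal(diameter_from_area(pi * 133^2), 266)   # circle of radius 133
  expect_equal(diameter_from_area(30171.86), 196, tolerance = 1e-5)
  expect_equal(diameter_from_area(55572.7), 266, tolerance = 1e-5)
  expect_equal(volume_from_diameter(0), 0)
  expect_equal(volume_from_diameter(1), pi / 6)
  expect_equal(volume_from_diameter(266), 9.8547e6, tolerance = 1e-4)
  expect_error(diameter_from_area(0), "> 0")
  expect_error(diameter_from_area(-3), "> 0")
  expect_error(volume_from_diameter(-1), ">= 0")
})

test_that("scale equivariance and doubling identities hold on random inputs", {
  set.seed(42)
  for (i in 1:1000) {
    A <- runif(1, 1, 1e5)
    s <- runif(1, 0.1, 10)
    d <- diameter_from_area(A)
    expect_equal(diameter_from_area(A * s^2), d * s, tolerance = 1e-12)
    expect_equal(volume_from_diameter(d * s), volume_from_diameter(d) * s^3,
                 tolerance = 1e-12)
    expect_equal(volume_from_diameter(2 * d), 8 * volume_from_diameter(d),
                 tolerance = 1e-12)
    # round trip: area of the circle with diameter d is A again
    expect_equal(pi * (d / 2)^2, A, tolerance = 1e-9)
  }
})

test_that("central slice recovers sphere diameters, converging with voxel size", {
  errs <- sapply(c(4, 2, 1), function(vs) {
    mean(sapply(c(100, 200, 300), function(d) {
      m <- raster_sphere(d, vs)
      a <- central_cross_section_area(m, vs)
      abs(diameter_from_area(a$area_nm2) - d) / d
    }))
  })
  expect_true(all(diff(errs) < 0))      # strictly decreasing mean error
  expect_lt(errs[3], 0.01)              # within 1% at 1 nm voxels
  expect_lt(errs[2], 0.015)             # and already within 1.5% at 2 nm
})

test_that("slice selection follows the centroid with ties toward larger area", {
  # a single voxel is its own central cross section
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  cs <- central_cross_section_area(m, 2)
  expect_equal(cs$area_nm2, 4)
  expect_identical(cs$slice_index, 3L)
  expect_error(central_cross_section_area(array(FALSE, c(3, 3, 3)), 2),
               "empty")
  # slice areas (3, 1, 10): centroid lands exactly between slices 2 and 3;
  # the tie goes to the larger-area slice
  m2 <- array(FALSE, c(7, 7, 3))
  m2[2:4, 3, 1] <- TRUE
  m2[3, 3, 2] <- TRUE
  m2[2:6, 3:4, 3][] <- TRUE
  stopifnot(sum(m2[, , 1]) == 3, sum(m2[, , 3]) == 10)
  cs2 <- central_cross_section_area(m2, 1)
  expect_identical(cs2$slice_index, 3L)
  expect_equal(cs2$area_nm2, 10)
  # hole-filled before measuring: a ring counts as its disk
  ring <- raster_sphere(60, 2) & !raster_sphere(48, 2, pad_nm = 14)
  cs3 <- central_cross_section_area(ring, 2)
  full <- central_cross_section_area(raster_sphere(60, 2), 2)
  expect_equal(cs3$area_nm2, full$area_nm2)
})

test_that("a hemisphere at the volume edge is measured from its equator", {
  sph <- raster_sphere(100, 2)
  half <- sph[, , 1:(dim(sph)[3] %/% 2)]  # truncated at the z face
  labs <- label_volume(array(as.integer(half), dim(half)), 2)
  rec <- measure_vesicles(labs)
  expect_identical(nrow(rec), 1L)
  expect_true(rec$edge_z)
  expect_false(rec$truncated)  # z-cut objects still carry a diameter
  expect_equal(rec$diameter_nm, 100, tolerance = 0.02)
  # in-slab volume is about half the sphere
  expect_equal(rec$in_volume_nm3, volume_from_diameter(100) / 2,
               tolerance = 0.06)
})

test_that("laterally truncated objects carry no diameter under 'flag'", {
  sph <- raster_sphere(60, 2)
  cut <- sph[1:(dim(sph)[1] %/% 2), , ]   # cut by an x face
  labs <- label_volume(array(as.integer(cut), dim(cut)), 2)
  rec <- measure_vesicles(labs)
  expect_true(rec$truncated)
  expect_true(is.na(rec$diameter_nm))
  expect_equal(rec$voxel_volume_nm3, sum(cut) * 8)
  rec2 <- measure_vesicles(labs, boundary_policy = "exclude")
  expect_identical(nrow(rec2), 0L)
})

test_that("measured diameters track generator truth within 2% (no wedge)", {
  tomo <- tomo20_clean()
  labs <- segment_vesicles(tomo$volume)
  recs <- measure_vesicles(labs)
  dd <- match_measured_to_truth(labs, tomo$labels, recs, tomo$field)
  ok <- !is.na(dd$diameter_nm)
  expect_gte(sum(ok), 15)
  rel <- abs(dd$diameter_nm - dd$outer_diameter_nm)[ok] /
    dd$outer_diameter_nm[ok]
  expect_lte(mean(rel), 0.02)
})

test_that("measured diameters stay within 5% under the missing wedge", {
  tomo <- tomo20_wedge()
  labs <- segment_vesicles(tomo$volume)
  recs <- measure_vesicles(labs)
  dd <- match_measured_to_truth(labs, tomo$labels, recs, tomo$field)
  ok <- !is.na(dd$diameter_nm)
  rel <- abs(dd$diameter_nm - dd$outer_diameter_nm)[ok] /
    dd$outer_diameter_nm[ok]
  expect_lte(mean(rel), 0.05)
})

test_that("empty label volume measures to an empty record table", {
  labs <- label_volume(array(0L, c(8, 8, 8)), 2)
  expect_identical(nrow(measure_vesicles(labs)), 0L)
})
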
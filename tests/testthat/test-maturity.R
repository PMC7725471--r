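# maturity fixtures: larger vesicles than the detection fixture, so the
# eroded interior always retains a core-free lumen shell (the classifier's
# documented operating range)
maturity_config_field <- function(mature_fraction, seed, n = 10,
                                  noise_sd = 0, cluster_prevalence = 0) {
  generator_config(grid_shape = c(430, 430, 110), n_vesicles = n,
                   diameter_mean_nm = 200, diameter_sd_nm = 25,
                   mature_fraction = mature_fraction,
                   cluster_prevalence = cluster_prevalence,
                   noise_sd = noise_sd, wedge_half_angle_deg = 0, seed = seed)
}

classified_against_truth <- function(cfg, use_noise = cfg$noise_sd > 0) {
  tomo <- generate_tomogram(cfg, use_wedge = FALSE, use_noise = use_noise)
  labs <- suppressWarnings(segment_vesicles(tomo$volume))
  recs <- measure_vesicles(labs)
  recs <- classify_vesicles(recs, tomo$volume, labs)
  match_measured_to_truth(labs, tomo$labels, recs, tomo$field)
}

test_that("a uniform interior scores zero contrast", {
  m <- raster_sphere(160, 2)
  dat <- array(0.15, dim(m))
  cc <- core_contrast(m, dat, 2)
  expect_equal(cc$statistic, 0)
  expect_equal(cc$core_diameter_nm, 0)
  expect_error(core_contrast(array(FALSE, c(4, 4, 4)), array(0, c(4, 4, 4)), 2),
               "empty")
})

test_that("a noiseless dense core saturates the statistic", {
  m <- raster_sphere(200, 2)
  dat <- array(0.15, dim(m))
  core <- raster_sphere(100, 2, pad_nm = 58)
  stopifnot(identical(dim(core), dim(m)))
  dat[core] <- 0.6
  cc <- core_contrast(m, dat, 2)
  cfg <- maturity_config()
  expect_equal(cc$statistic, cfg$cap)   # zero-spread limit is capped
  expect_gt(cc$core_diameter_nm, 30)
  # classified mature at any finite threshold
  expect_true(cc$statistic >= maturity_config(contrast_threshold = 100)$contrast_threshold)
})

test_that("noiseless classification reproduces ground truth exactly", {
  # all immature, all mature, and the mixed peripheral-region fraction
  for (mf in c(0, 1)) {
    dd <- classified_against_truth(maturity_config_field(mf, seed = 31 + mf))
    expect_identical(mean(dd$mature), mf)
  }
  # mature_fraction 0.32 over n = 130 noiseless vesicles, in batches
  n_tot <- 0; n_mat_true <- 0; n_mat_call <- 0; exact <- TRUE
  b <- 0
  while (n_tot < 130) {
    b <- b + 1
    dd <- classified_against_truth(maturity_config_field(0.32, seed = 700 + b,
                                                         n = 12))
    n_tot <- n_tot + nrow(dd)
    n_mat_true <- n_mat_true + sum(dd$mature_true)
    n_mat_call <- n_mat_call + sum(dd$mature)
    exact <- exact && all(dd$mature == dd$mature_true)
  }
  expect_true(exact)
  expect_identical(n_mat_call, n_mat_true)
})

test_that("classification stays accurate when noise is half the core contrast", {
  # core - lumen contrast is 0.45 by default; noise_sd 0.225
  acc <- c()
  b <- 0
  while (length(acc) < 60) {
    b <- b + 1
    dd <- classified_against_truth(
      maturity_config_field(0.5, seed = 900 + b, noise_sd = 0.225))
    acc <- c(acc, dd$mature == dd$mature_true)
  }
  expect_gte(mean(acc), 0.95)
})

test_that("raising the contrast threshold never adds mature calls", {
  cfg <- maturity_config_field(0.5, seed = 55, noise_sd = 0.225)
  tomo <- generate_tomogram(cfg, use_wedge = FALSE, use_noise = TRUE)
  labs <- suppressWarnings(segment_vesicles(tomo$volume))
  recs <- measure_vesicles(labs)
  calls <- vapply(c(0.5, 1, 3, 10, 1e7), function(thr) {
    r <- classify_vesicles(recs, tomo$volume, labs,
                           maturity_config(contrast_threshold = thr))
    sum(r$mature)
  }, 0)
  expect_true(all(diff(calls) <= 0))
})

test_that("metal clusters are detected at the right prevalence, not as cores", {
  # clusters in every vesicle; none may be mistaken for a dense core
  cfg <- maturity_config_field(0, seed = 77, cluster_prevalence = 1)
  tomo <- generate_tomogram(cfg, use_wedge = FALSE, use_noise = FALSE)
  labs <- suppressWarnings(segment_vesicles(tomo$volume))
  recs <- measure_vesicles(labs)
  recs <- classify_vesicles(recs, tomo$volume, labs)
  expect_identical(sum(recs$mature), 0L)
  recs <- detect_clusters(recs, tomo$volume, labs)
  dd <- match_measured_to_truth(labs, tomo$labels, recs, tomo$field)
  # no false positives; near-complete recall (a deposit at the 30 nm gate
  # hugging the membrane can fall below the extent gate)
  expect_true(all(dd$n_clusters[dd$cluster_count > 0] > 0))
  expect_gte(mean(dd$cluster_count[dd$n_clusters > 0] > 0), 0.9)

  # mature vesicles: clusters sit against the core
  cfg2 <- maturity_config_field(1, seed = 78, cluster_prevalence = 1)
  tomo2 <- generate_tomogram(cfg2, use_wedge = FALSE, use_noise = FALSE)
  labs2 <- suppressWarnings(segment_vesicles(tomo2$volume))
  recs2 <- measure_vesicles(labs2)
  recs2 <- classify_vesicles(recs2, tomo2$volume, labs2)
  expect_identical(mean(recs2$mature), 1)
  recs2 <- detect_clusters(recs2, tomo2$volume, labs2)
  adj <- attr(recs2, "core_adjacency")
  expect_gt(length(adj), 0)
  expect_identical(mean(adj, na.rm = TRUE), 1)
})

test_that("detected cluster prevalence sits in the planted binomial band", {
  # noiseless fields planted at 10% prevalence; the detected prevalence
  # must fall inside the exact binomial 99% interval for the sample size
  n <- 0L; hits <- 0L; b <- 0L
  while (n < 120L) {
    b <- b + 1L
    cfg <- maturity_config_field(0.3, seed = 1200 + b, n = 15,
                                 cluster_prevalence = 0.10)
    tomo <- suppressWarnings(
      generate_tomogram(cfg, use_wedge = FALSE, use_noise = FALSE))
    labs <- suppressWarnings(segment_vesicles(tomo$volume))
    recs <- measure_vesicles(labs)
    recs <- classify_vesicles(recs, tomo$volume, labs)
    recs <- detect_clusters(recs, tomo$volume, labs)
    cs <- count_clusters(recs)
    n <- n + cs$n
    hits <- hits + as.integer(round(cs$prevalence * cs$n))
  }
  lo <- qbinom(0.005, n, 0.1)
  hi <- qbinom(0.995, n, 0.1)
  expect_gte(hits, lo)
  expect_lte(hits, hi)
})

test_that("zero-prevalence fields yield zero cluster calls", {
  cfg <- maturity_config_field(0.5, seed = 79, cluster_prevalence = 0)
  tomo <- generate_tomogram(cfg, use_wedge = FALSE, use_noise = FALSE)
  labs <- suppressWarnings(segment_vesicles(tomo$volume))
  recs <- detect_clusters(measure_vesicles(labs), tomo$volume, labs)
  expect_identical(sum(recs$cluster_count), 0L)
  cs <- count_clusters(recs)
  expect_equal(cs$prevalence, 0)
})
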
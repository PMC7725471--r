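# Subcellular region assignment and per-region neighborhood statistics.
#
# Tomograms are binned into distance bands from one of two membrane
# landmarks: the nuclear membrane (NM) for interior lamellae, where the
# plasma membrane is not visible, and the plasma membrane (PM) for
# peripheral tomograms.  The default bands follow the three-region scheme
# of the beta-cell study this package models: region 1 at 3-8 um from the
# NM (just distal from the Golgi), region 2 at 3-6 um from the PM, and
# region 3 within 2 um of the PM.

#' Region specification
#'
#' A named closed distance interval relative to a landmark membrane.
#'
#' @param name region name.
#' @param landmark `"NM"` (nuclear membrane) or `"PM"` (plasma membrane).
#' @param min_distance_um,max_distance_um closed interval bounds in um,
#'   `0 <= min <= max`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, landmark = c("NM", "PM"),
                        min_distance_um, max_distance_um) {
  landmark <- match.arg(landmark)
  stopifnot(min_distance_um >= 0, min_distance_um <= max_distance_um)
  structure(list(name = name, landmark = landmark,
                 min_distance_um = min_distance_um,
                 max_distance_um = max_distance_um),
            class = "region_spec")
}

#' Default three-region scheme
#'
#' Region 1: 3-8 um from the NM; region 2: 3-6 um from the PM;
#' region 3: within 2 um of the PM.
#'
#' @return list of three [region_spec()] objects.
#' @export
default_region_specs <- function() {
  list(region_spec("region1", "NM", 3, 8),
       region_spec("region2", "PM", 3, 6),
       region_spec("region3", "PM", 0, 2))
}

#' Assign a landmark distance to a region
#'
#' Returns the unique region whose landmark matches and whose closed
#' interval contains the distance, or `NA` (unassigned) when no region
#' matches. Region specs that overlap for the same landmark are an error.
#'
#' @param distance_um distance from the landmark, in um (>= 0).
#' @param landmark `"NM"` or `"PM"`.
#' @param specs list of [region_spec()]s (default the three-region scheme).
#' @return region name, or `NA_character_`.
#' @export
assign_region <- function(distance_um, landmark,
                          specs = default_region_specs()) {
  stopifnot(is.finite(distance_um), distance_um >= 0)
  landmark <- match.arg(landmark, c("NM", "PM"))
  same <- Filter(function(s) s$landmark == landmark, specs)
  if (length(same) > 1) {
    for (i in seq_len(length(same) - 1))
      for (j in (i + 1):length(same))
        if (same[[i]]$min_distance_um <= same[[j]]$max_distance_um &&
            same[[j]]$min_distance_um <= same[[i]]$max_distance_um)
          stop("overlapping region specs for landmark ", landmark, ": ",
               same[[i]]$name, " and ", same[[j]]$name)
  }
  for (s in same)
    if (distance_um >= s$min_distance_um && distance_um <= s$max_distance_um)
      return(s$name)
  NA_character_
}

#' Per-region neighborhood summary
#'
#' Aggregates vesicle records from one region: counts, mature fraction,
#' diameter statistics (mean, SD, median, 25-75% quantiles with the
#' linear-interpolation quantile definition, computed over non-truncated
#' records), count density (n per um^3 of tomogram volume) and volume
#' fraction. The volume fraction sums each record's `in_volume_nm3` (the
#' sphere volume clipped to the tomogram slab, or the labelled voxel
#' volume for laterally truncated records), so only in-tomogram material
#' is counted; the denominator is the total reconstructed tomogram volume
#' (1 um^3 = 1e9 nm^3).
#'
#' @param records `vesicles`-schema data.frame (one region's records).
#' @param tomogram_volume_um3 per-tomogram volumes in um^3 (vector; summed).
#' @param region region name for the summary row.
#' @param n_tomograms number of tomograms the records came from.
#' @return one-row data.frame in the `summaries` schema.
#' @export
summarize_region <- function(records, tomogram_volume_um3, region = "region",
                             n_tomograms = length(tomogram_volume_um3)) {
  vol <- sum(tomogram_volume_um3)
  if (!is.finite(vol) || vol <= 0) stop("tomogram volume must be positive")
  n <- nrow(records)
  d <- records$diameter_nm[!is.na(records$diameter_nm)]
  if (n == 0L) {
    out <- data.frame(region = region, n_tomograms = n_tomograms,
                      n_vesicles = 0L, n_mature = 0L, mature_fraction = NA_real_,
                      mean_diameter_nm = NA_real_, sd_diameter_nm = NA_real_,
                      median_diameter_nm = NA_real_, q25_diameter_nm = NA_real_,
                      q75_diameter_nm = NA_real_,
                      count_density_per_um3 = 0, volume_fraction = 0,
                      tomogram_volume_um3 = vol)
    return(.as_table(out, "summaries"))
  }
  n_mat <- sum(records$mature, na.rm = TRUE)
  vf_contrib <- ifelse(is.na(records$in_volume_nm3),
                       records$voxel_volume_nm3, records$in_volume_nm3)
  vf <- sum(vf_contrib) / (vol * 1e9)
  if (vf > 1)
    stop("volume fraction ", sprintf("%.3f", vf),
         " exceeds 1: non-overlapping vesicles cannot fill more than the ",
         "tomogram volume; inputs are inconsistent")
  q <- if (length(d)) quantile(d, c(0.25, 0.5, 0.75), type = 7,
                               names = FALSE) else rep(NA_real_, 3)
  out <- data.frame(
    region = region, n_tomograms = n_tomograms, n_vesicles = n,
    n_mature = n_mat, mature_fraction = n_mat / n,
    mean_diameter_nm = if (length(d)) mean(d) else NA_real_,
    sd_diameter_nm = if (length(d) > 1) sd(d) else NA_real_,
    median_diameter_nm = q[2], q25_diameter_nm = q[1], q75_diameter_nm = q[3],
    count_density_per_um3 = n / vol,
    volume_fraction = vf,
    tomogram_volume_um3 = vol)
  .as_table(out, "summaries")
}

#' Ground-truth summary of a planted vesicle field
#'
#' The generator-truth counterpart of [summarize_region()], for validating
#' the pipeline: diameters are outer diameters (lumen + 2 x membrane),
#' matching what the filled-profile estimator measures; the volume
#' fraction is the analytic in-slab sphere volume (spherical caps cut by
#' the lamella surfaces removed) over the slab volume.
#'
#' @param field a `vesicle_field`.
#' @param region region name for the summary row.
#' @return one-row data.frame in the `summaries` schema.
#' @export
summarize_truth <- function(field, region = "truth") {
  stopifnot(inherits(field, "vesicle_field"))
  cfg <- field$config
  ves <- field$vesicles
  vol <- slab_volume_um3(cfg)
  zext <- cfg$grid_shape[3] * cfg$voxel_size_nm
  if (nrow(ves) == 0L)
    return(summarize_region(.empty_table("vesicles"), vol, region, 1L))
  d <- ves$outer_diameter_nm
  in_slab <- vapply(seq_len(nrow(ves)), function(i)
    .sphere_slab_volume(d[i] / 2, ves$cz_nm[i], 0, zext), 0)
  q <- quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- data.frame(
    region = region, n_tomograms = 1L, n_vesicles = nrow(ves),
    n_mature = sum(ves$mature), mature_fraction = mean(ves$mature),
    mean_diameter_nm = mean(d),
    sd_diameter_nm = if (nrow(ves) > 1) sd(d) else NA_real_,
    median_diameter_nm = q[2], q25_diameter_nm = q[1], q75_diameter_nm = q[3],
    count_density_per_um3 = nrow(ves) / vol,
    volume_fraction = sum(in_slab) / (vol * 1e9),
    tomogram_volume_um3 = vol)
  .as_table(out, "summaries")
}

#' Combine truth summaries from several tomograms of one region
#'
#' Pools the per-tomogram truth rows into one region-level row: counts and
#' volumes add; diameter statistics are recomputed over the pooled outer
#' diameters.
#'
#' @param fields list of `vesicle_field`s.
#' @param region region name.
#' @return one-row data.frame in the `summaries` schema.
#' @export
summarize_truth_pooled <- function(fields, region = "truth") {
  ves <- do.call(rbind, lapply(fields, function(f) f$vesicles))
  rows <- lapply(fields, summarize_truth)
  vol <- sum(vapply(rows, function(r) r$tomogram_volume_um3, 0))
  vfnum <- sum(vapply(rows, function(r)
    r$volume_fraction * r$tomogram_volume_um3, 0))
  n <- nrow(ves)
  if (n == 0L) {
    out <- summarize_region(.empty_table("vesicles"), vol, region,
                            length(fields))
    return(out)
  }
  d <- ves$outer_diameter_nm
  q <- quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- data.frame(
    region = region, n_tomograms = length(fields), n_vesicles = n,
    n_mature = sum(ves$mature), mature_fraction = mean(ves$mature),
    mean_diameter_nm = mean(d),
    sd_diameter_nm = if (n > 1) sd(d) else NA_real_,
    median_diameter_nm = q[2], q25_diameter_nm = q[1], q75_diameter_nm = q[3],
    count_density_per_um3 = n / vol,
    volume_fraction = vfnum / vol,
    tomogram_volume_um3 = vol)
  .as_table(out, "summaries")
}

#' Compare a variable between two regions
#'
#' Welch's two-sample t test (unequal variances) and the Mann-Whitney U
#' test (normal approximation with continuity and tie correction), both
#' two-sided, on per-vesicle diameters or volumes. Significance is flagged
#' at p < 1e-4, the starred level of the study this package models. A
#' pooled-variance t test is available by flag.
#'
#' @param records_a,records_b `vesicles`-schema data.frames (or numeric
#'   vectors of the variable itself).
#' @param variable `"diameter"` or `"volume"`.
#' @param pooled use the pooled-variance t test instead of Welch.
#' @param alpha significance level for the flag (default 1e-4).
#' @return An object of class `region_comparison`: list with `welch_t`,
#'   `welch_p`, `mann_whitney_U`, `mann_whitney_p`, `significant`,
#'   `direction`, group sizes and means.
#' @export
compare_regions <- function(records_a, records_b,
                            variable = c("diameter", "volume"),
                            pooled = FALSE, alpha = 1e-4) {
  variable <- match.arg(variable)
  pull <- function(x) {
    if (is.numeric(x)) return(x[is.finite(x)])
    col <- if (variable == "diameter") "diameter_nm" else "volume_nm3"
    v <- x[[col]]
    v[is.finite(v)]
  }
  a <- pull(records_a); b <- pull(records_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations for the t test")
  tt <- t.test(a, b, var.equal = pooled)
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  structure(list(
    variable = variable,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    median_a = median(a), median_b = median(b),
    welch_t = unname(tt$statistic), welch_p = tt$p.value,
    mann_whitney_U = unname(wt$statistic), mann_whitney_p = wt$p.value,
    significant = tt$p.value < alpha && wt$p.value < alpha,
    direction = if (mean(b) > mean(a)) "b > a"
    else if (mean(b) < mean(a)) "b < a" else "equal",
    alpha = alpha, pooled = pooled),
    class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("<region_comparison> %s: n = %d vs %d, mean %.1f vs %.1f (%s)\n",
              x$variable, x$n_a, x$n_b, x$mean_a, x$mean_b, x$direction))
  cat(sprintf("  %s t = %.3f, p = %.3g; Mann-Whitney U = %.1f, p = %.3g%s\n",
              if (x$pooled) "pooled" else "Welch",
              x$welch_t, x$welch_p, x$mann_whitney_U, x$mann_whitney_p,
              if (x$significant) sprintf("  [p < %g]", x$alpha) else " [ns]"))
  invisible(x)
}

#' Metal-cluster prevalence of a record set
#'
#' @param records `vesicles`-schema data.frame with `cluster_count` filled
#'   by [detect_clusters()].
#' @return list with `prevalence` (fraction of vesicles with >= 1
#'   cluster), `mean_clusters_per_affected`, and `n`.
#' @export
count_clusters <- function(records) {
  cc <- records$cluster_count
  cc <- cc[!is.na(cc)]
  n <- length(cc)
  aff <- cc[cc >= 1L]
  list(prevalence = if (n) length(aff) / n else NA_real_,
       mean_clusters_per_affected = if (length(aff)) mean(aff) else NA_real_,
       n = n)
}

#' Per-vesicle region assignment from a landmark plane
#'
#' The default sampling design assigns whole tomograms to regions (each
#' tomogram carries one landmark distance). When a tomogram's coordinate
#' frame contains the landmark membrane itself, regions can instead be
#' assigned per vesicle from the distance between each vesicle center and
#' a landmark plane orthogonal to one axis. Off by default in the
#' pipeline; provided for sensitivity analysis.
#'
#' @param records `vesicles`-schema data.frame with centroid columns.
#' @param landmark `"NM"` or `"PM"`.
#' @param plane_nm coordinate of the landmark plane along `axis`, in nm.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param specs list of [region_spec()]s.
#' @return `records` with `region_label` filled per vesicle (`NA` where no
#'   region matches).
#' @export
assign_regions_per_vesicle <- function(records, landmark, plane_nm,
                                       axis = c("x", "y", "z"),
                                       specs = default_region_specs()) {
  axis <- match.arg(axis)
  col <- paste0("c", axis, "_nm")
  d_um <- abs(records[[col]] - plane_nm) / 1000
  records$region_label <- vapply(d_um, function(d)
    assign_region(d, landmark, specs), character(1))
  records
}
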
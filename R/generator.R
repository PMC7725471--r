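# Synthetic tomogram generator: vesicle fields in a lamella-thickness slab,
# rendered as membrane shells with lumens, dense cores and metal clusters,
# then corrupted by the missing wedge and Gaussian noise.

#' Generator configuration
#'
#' Defines one synthetic tomogram: the voxel grid, the lamella slab, the
#' vesicle population (size distribution, maturity mix, metal-cluster
#' prevalence) and the imaging corruption (missing wedge, noise).
#'
#' Conventions: the slab spans the full z extent of the grid (the grid *is*
#' the lamella); the "diameter" of a ground-truth vesicle is its lumen
#' (inner-membrane) diameter, and its outer diameter is
#' `lumen + 2 * membrane_thickness_nm`. Objects are rendered bright
#' (positive density over a zero background); set `invert_contrast = TRUE`
#' for the conventional dark-on-light display sign.
#'
#' @param grid_shape voxel counts `c(nx, ny, nz)`; z is the beam axis.
#' @param voxel_size_nm isotropic voxel size (nm).
#' @param lamella_thickness_nm slab thickness; must equal the grid z extent.
#' @param n_vesicles number of vesicles to place, or `NULL` to derive the
#'   count from `target_density_per_um3`.
#' @param target_density_per_um3 desired vesicle count density (per um^3 of
#'   slab); ignored when `n_vesicles` is given.
#' @param diameter_mean_nm,diameter_sd_nm mean and SD of the lumen diameter
#'   distribution (normal, truncated below at `2 * membrane_thickness_nm`).
#' @param mature_fraction probability that a vesicle carries a dense core.
#' @param membrane_thickness_nm lipid bilayer shell thickness (nm).
#' @param core_to_lumen_ratio dense-core diameter as a fraction of the
#'   lumen diameter, in (0, 1).
#' @param cluster_prevalence probability that a vesicle contains metal
#'   clusters (default 0.10); affected vesicles carry 1 or 2 clusters with
#'   equal probability.
#' @param cluster_diameter_range_nm min/max metal-cluster diameter
#'   (default 30-90 nm).
#' @param cluster_particle_range_nm min/max diameter of the individual
#'   particles a cluster is built from (default 3-8 nm).
#' @param intensity named list of density levels: `background`, `lumen`,
#'   `membrane`, `core`, `cluster`.
#' @param noise_sd SD of additive Gaussian noise (0 disables).
#' @param wedge_half_angle_deg missing-wedge half angle about the beam
#'   axis; 30 degrees corresponds to a -60..+60 degree tilt range.
#' @param allow_truncation if `TRUE` (default) vesicle spheres may be cut
#'   by the top/bottom lamella surfaces, as happens physically when vesicle
#'   diameters are comparable to the lamella thickness; centers always stay
#'   inside the slab by at least `min_z_margin_nm` (and by the core radius
#'   plus membrane, so cores and equators are never cut). If `FALSE`,
#'   centers keep one outer radius from every face and the diameter
#'   distribution is additionally truncated so spheres fit.
#' @param min_z_margin_nm minimum distance of vesicle centers from the
#'   lamella surfaces when truncation is allowed.
#' @param min_gap_nm minimum surface-to-surface gap between vesicles
#'   (default 20 nm): vesicle membranes carry coats and tethers and do not
#'   touch, and a gap wider than twice the closing radius (plus the extent
#'   the smoothed threshold crossing reaches past the membrane) keeps
#'   distinct vesicles separable by threshold segmentation.
#' @param invert_contrast render objects dark instead of bright.
#' @param seed integer seed; together with the config it fully determines
#'   the field, the rendered volume and the labels.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(grid_shape = c(256, 256, 110),
                             voxel_size_nm = 2,
                             lamella_thickness_nm = NULL,
                             n_vesicles = NULL,
                             target_density_per_um3 = NULL,
                             diameter_mean_nm = 230,
                             diameter_sd_nm = 50,
                             mature_fraction = 0.25,
                             membrane_thickness_nm = 7,
                             core_to_lumen_ratio = 0.5,
                             cluster_prevalence = 0.10,
                             cluster_diameter_range_nm = c(30, 90),
                             cluster_particle_range_nm = c(3, 8),
                             intensity = list(background = 0, lumen = 0.15,
                                              membrane = 1, core = 0.6,
                                              cluster = 1.5),
                             noise_sd = 0.15,
                             wedge_half_angle_deg = 30,
                             allow_truncation = TRUE,
                             min_z_margin_nm = 40,
                             min_gap_nm = 20,
                             invert_contrast = FALSE,
                             seed = 1L) {
  if (is.null(lamella_thickness_nm))
    lamella_thickness_nm <- grid_shape[3] * voxel_size_nm
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_nm = voxel_size_nm,
              lamella_thickness_nm = lamella_thickness_nm,
              n_vesicles = n_vesicles,
              target_density_per_um3 = target_density_per_um3,
              diameter_mean_nm = diameter_mean_nm,
              diameter_sd_nm = diameter_sd_nm,
              mature_fraction = mature_fraction,
              membrane_thickness_nm = membrane_thickness_nm,
              core_to_lumen_ratio = core_to_lumen_ratio,
              cluster_prevalence = cluster_prevalence,
              cluster_diameter_range_nm = cluster_diameter_range_nm,
              cluster_particle_range_nm = cluster_particle_range_nm,
              intensity = intensity,
              noise_sd = noise_sd,
              wedge_half_angle_deg = wedge_half_angle_deg,
              allow_truncation = isTRUE(allow_truncation),
              min_z_margin_nm = min_z_margin_nm,
              min_gap_nm = min_gap_nm,
              invert_contrast = isTRUE(invert_contrast),
              seed = as.integer(seed))
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 1L),
            cfg$voxel_size_nm > 0,
            cfg$diameter_mean_nm > 0, cfg$diameter_sd_nm >= 0,
            cfg$membrane_thickness_nm > 0,
            cfg$core_to_lumen_ratio > 0, cfg$core_to_lumen_ratio < 1,
            cfg$mature_fraction >= 0, cfg$mature_fraction <= 1,
            cfg$cluster_prevalence >= 0, cfg$cluster_prevalence <= 1,
            length(cfg$cluster_diameter_range_nm) == 2L,
            diff(cfg$cluster_diameter_range_nm) >= 0,
            length(cfg$cluster_particle_range_nm) == 2L,
            cfg$noise_sd >= 0,
            cfg$wedge_half_angle_deg >= 0, cfg$wedge_half_angle_deg < 90,
            cfg$min_z_margin_nm >= 0, cfg$min_gap_nm >= 0)
  z_extent <- cfg$grid_shape[3] * cfg$voxel_size_nm
  if (abs(cfg$lamella_thickness_nm - z_extent) > 1e-6)
    stop("lamella_thickness_nm must equal the grid z extent (",
         z_extent, " nm); resize grid_shape[3] instead")
  if (is.null(cfg$n_vesicles) && is.null(cfg$target_density_per_um3))
    stop("give either n_vesicles or target_density_per_um3")
  need <- c("background", "lumen", "membrane", "core", "cluster")
  if (!all(need %in% names(cfg$intensity)))
    stop("intensity must name: ", paste(need, collapse = ", "))
  structure(cfg, class = "generator_config")
}

#' Slab volume of a generator config, in um^3
#' @param config a [generator_config()].
#' @return scalar, grid extent in um^3.
#' @export
slab_volume_um3 <- function(config) {
  prod(config$grid_shape) * config$voxel_size_nm^3 / 1e9
}

# number of vesicles a config asks for
.requested_count <- function(config) {
  if (!is.null(config$n_vesicles)) return(as.integer(config$n_vesicles))
  as.integer(round(config$target_density_per_um3 * slab_volume_um3(config)))
}

# truncated-normal lumen diameters; lower bound 2 * membrane thickness,
# optional upper bound (used when spheres must fit inside the slab).
.sample_diameters <- function(n, mean, s, lower, upper = Inf) {
  if (lower >= upper) stop("diameter truncation bounds are empty")
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    guard <- guard + 1
    if (guard > 1000) stop("diameter sampling failed: bounds reject ",
                           "essentially all of the distribution")
    x <- rnorm(max(n, 10L), mean, s)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Sample a ground-truth vesicle field
#'
#' Places non-overlapping spheres in the lamella slab by random sequential
#' placement (up to 1e5 attempts per vesicle, largest vesicles placed
#' first). Lumen diameters are i.i.d. truncated normal, maturity is i.i.d.
#' Bernoulli(`mature_fraction`), and metal clusters occur with probability
#' `cluster_prevalence` (1 or 2 clusters, equiprobable). In mature vesicles
#' clusters sit adjacent to the dense-core surface; in immature vesicles
#' they are uniform in the lumen.
#'
#' If the packing jams before the requested count is reached the achieved
#' field is returned with a warning; the request and the achieved count are
#' stored in attributes `requested` / `achieved` so under-delivery is never
#' silent. A request whose expected in-slab vesicle volume exceeds 90% of
#' a random-close-packing bound (0.64 of the slab) is refused outright.
#'
#' @param config a [generator_config()].
#' @return An object of class `vesicle_field`: list with data.frames
#'   `vesicles` (truth schema) and `clusters`, plus the config.
#' @export
sample_vesicle_field <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_req <- .requested_count(config)
  vs <- config$voxel_size_nm
  ext <- config$grid_shape * vs
  memb <- config$membrane_thickness_nm

  if (n_req == 0L)
    return(structure(list(vesicles = .empty_table("truth"),
                          clusters = .empty_table("clusters"),
                          config = config),
                     class = "vesicle_field"))

  upper <- Inf
  if (!config$allow_truncation) {
    # sphere plus margin must fit between the slab surfaces
    upper <- ext[3] - 2 * memb
    if (upper <= 2 * memb)
      stop("slab too thin to hold any untruncated vesicle")
  }
  d_lumen <- .sample_diameters(n_req, config$diameter_mean_nm,
                               config$diameter_sd_nm, 2 * memb, upper)
  d_outer <- d_lumen + 2 * memb
  mature <- runif(n_req) < config$mature_fraction
  d_core <- ifelse(mature, config$core_to_lumen_ratio * d_lumen, 0)

  # feasibility: expected in-slab occupied volume vs packing bound
  r_out <- d_outer / 2
  zmar <- pmax(config$min_z_margin_nm, d_core / 2 + memb + vs)
  in_slab <- vapply(seq_len(n_req), function(i) {
    .sphere_slab_volume(r_out[i], ext[3] / 2, 0, ext[3])
  }, numeric(1))
  if (sum(in_slab) > 0.9 * prod(ext))
    stop("infeasible packing request: expected in-slab vesicle volume ",
         sprintf("%.2g", sum(in_slab) / 1e9), " um^3 exceeds 90% of the ",
         "slab volume; no sphere packing can realize this")

  ord <- order(d_outer, decreasing = TRUE)  # big first packs better
  placed <- matrix(NA_real_, n_req, 3)
  ok <- logical(n_req)
  max_attempts <- 1e5
  for (i in ord) {
    r <- r_out[i]
    if (config$allow_truncation) {
      zlo <- max(zmar[i], 0); zhi <- ext[3] - max(zmar[i], 0)
    } else {
      zlo <- r; zhi <- ext[3] - r
    }
    xybuf <- r + 10  # lateral margin: sphere plus room for detector dilation
    if (ext[1] < 2 * xybuf || ext[2] < 2 * xybuf || zhi <= zlo) next
    prev <- placed[ok, , drop = FALSE]
    rprev <- r_out[ok]
    for (a in seq_len(max_attempts)) {
      cand <- c(runif(1, xybuf, ext[1] - xybuf),
                runif(1, xybuf, ext[2] - xybuf),
                runif(1, zlo, zhi))
      if (nrow(prev) == 0L) { placed[i, ] <- cand; ok[i] <- TRUE; break }
      dd <- sqrt(colSums((t(prev) - cand)^2))
      if (all(dd >= rprev + r + config$min_gap_nm)) {
        placed[i, ] <- cand; ok[i] <- TRUE; break
      }
    }
  }
  if (!all(ok))
    warning(sprintf(paste0("packing jammed: placed %d of %d requested ",
                           "vesicles"), sum(ok), n_req))

  keep <- which(ok)
  ves <- data.frame(id = seq_along(keep),
                    cx_nm = placed[keep, 1], cy_nm = placed[keep, 2],
                    cz_nm = placed[keep, 3],
                    lumen_diameter_nm = d_lumen[keep],
                    outer_diameter_nm = d_outer[keep],
                    mature = mature[keep],
                    core_diameter_nm = d_core[keep],
                    n_clusters = 0L,
                    region_label = NA_character_)

  # metal clusters
  cl <- list()
  if (nrow(ves) > 0 && config$cluster_prevalence > 0) {
    has <- runif(nrow(ves)) < config$cluster_prevalence
    for (i in which(has)) {
      k <- sample(1:2, 1)
      lum_r <- ves$lumen_diameter_nm[i] / 2
      core_r <- ves$core_diameter_nm[i] / 2
      for (j in seq_len(k)) {
        # cluster must lie strictly inside the lumen (and outside the core)
        max_cr <- if (ves$mature[i]) (lum_r - core_r) / 2 else lum_r / 2
        lo <- config$cluster_diameter_range_nm[1]
        hi <- min(config$cluster_diameter_range_nm[2], 2 * max_cr * 0.98)
        if (hi < lo) next  # vesicle too small for a cluster
        dcl <- runif(1, lo, hi)
        rcl <- dcl / 2
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        if (ves$mature[i]) {
          # attached to the core surface
          rad <- core_r + rcl
        } else {
          # uniform in the sphere of feasible centers
          rad <- (lum_r - rcl) * runif(1)^(1 / 3)
        }
        cl[[length(cl) + 1L]] <- data.frame(
          vesicle_id = ves$id[i],
          cx_nm = ves$cx_nm[i] + rad * u[1],
          cy_nm = ves$cy_nm[i] + rad * u[2],
          cz_nm = ves$cz_nm[i] + rad * u[3],
          diameter_nm = dcl)
        ves$n_clusters[i] <- ves$n_clusters[i] + 1L
      }
    }
  }
  clusters <- if (length(cl)) do.call(rbind, cl) else .empty_table("clusters")
  attr(clusters, "table_type") <- "clusters"
  attr(ves, "table_type") <- "truth"
  structure(list(vesicles = ves, clusters = clusters, config = config,
                 requested = n_req, achieved = nrow(ves)),
            class = "vesicle_field")
}

#' @export
print.vesicle_field <- function(x, ...) {
  cat(sprintf("<vesicle_field> %d vesicle(s) (%d requested), %d mature, %d cluster(s)\n",
              nrow(x$vesicles), x$requested %||% nrow(x$vesicles),
              sum(x$vesicles$mature), nrow(x$clusters)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# analytic volume of a sphere of radius r centred at z = cz, clipped to the
# slab [z0, z1] (spherical-cap subtraction)
.sphere_slab_volume <- function(r, cz, z0, z1) {
  cap <- function(h) if (h <= 0) 0 else pi * h^2 * (r - h / 3)
  v <- 4 / 3 * pi * r^3
  v - cap(r - (z1 - cz)) - cap(r - (cz - z0))
}

#' Render a vesicle field into a density volume and label volume
#'
#' Each vesicle is drawn as a membrane shell around a lumen; mature
#' vesicles get a concentric dense-core sphere, and metal clusters are
#' drawn as granular blobs built from particle-scale sub-spheres. The
#' label volume marks each vesicle's full extent (membrane + interior)
#' with its id. A voxel belongs to a sphere when its physical center is
#' inside the sphere's radius.
#'
#' @param field a `vesicle_field` from [sample_vesicle_field()].
#' @param config the [generator_config()] used to build the field.
#' @return list with elements `volume` ([voxel_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
render_field <- function(field, config = field$config) {
  stopifnot(inherits(field, "vesicle_field"),
            inherits(config, "generator_config"))
  set.seed(config$seed + 7919L)  # particle substream, decoupled from packing
  dims <- config$grid_shape
  vs <- config$voxel_size_nm
  ints <- config$intensity
  vol <- array(ints$background, dim = dims)
  lab <- array(0L, dim = dims)
  ves <- field$vesicles

  stamp_idx <- function(center, radius) {
    # returns in-grid voxel ranges and squared distances for a sphere
    lo <- pmax(1L, as.integer(floor((center - radius) / vs + 0.5)))
    hi <- pmin(dims, as.integer(ceiling((center + radius) / vs + 0.5)))
    if (any(lo > hi)) return(NULL)
    ax <- lapply(1:3, function(a) ((lo[a]:hi[a]) - 0.5) * vs - center[a])
    d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
    list(lo = lo, hi = hi, d2 = d2)
  }

  for (i in seq_len(nrow(ves))) {
    ctr <- c(ves$cx_nm[i], ves$cy_nm[i], ves$cz_nm[i])
    r_out <- ves$outer_diameter_nm[i] / 2
    r_lum <- ves$lumen_diameter_nm[i] / 2
    if (!config$allow_truncation &&
        (any(ctr - r_out < 0) || any(ctr + r_out > dims * vs)))
      stop("vesicle ", ves$id[i], " extends outside the grid and ",
           "truncation is disabled")
    s <- stamp_idx(ctr, r_out)
    if (is.null(s)) next
    sl <- list(s$lo[1]:s$hi[1], s$lo[2]:s$hi[2], s$lo[3]:s$hi[3])
    inside <- s$d2 <= r_out^2
    lumen <- s$d2 <= r_lum^2
    vb <- vol[sl[[1]], sl[[2]], sl[[3]]]
    lb <- lab[sl[[1]], sl[[2]], sl[[3]]]
    vb[lumen] <- ints$lumen
    vb[inside & !lumen] <- ints$membrane
    if (ves$mature[i] && ves$core_diameter_nm[i] > 0) {
      core <- s$d2 <= (ves$core_diameter_nm[i] / 2)^2
      vb[core] <- ints$core
    }
    lb[inside] <- ves$id[i]
    vol[sl[[1]], sl[[2]], sl[[3]]] <- vb
    lab[sl[[1]], sl[[2]], sl[[3]]] <- lb
  }

  # metal clusters: granular fill of particle-scale sub-spheres
  if (nrow(field$clusters) > 0) {
    pr <- config$cluster_particle_range_nm
    for (i in seq_len(nrow(field$clusters))) {
      ccl <- c(field$clusters$cx_nm[i], field$clusters$cy_nm[i],
               field$clusters$cz_nm[i])
      rcl <- field$clusters$diameter_nm[i] / 2
      mean_pr <- mean(pr) / 2
      n_part <- max(1L, as.integer(round(
        0.35 * rcl^3 / mean_pr^3)))  # ~35% granular fill
      for (p in seq_len(n_part)) {
        rp <- runif(1, pr[1], pr[2]) / 2
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        pc <- ccl + u * (max(rcl - rp, 0) * runif(1)^(1 / 3))
        s <- stamp_idx(pc, max(rp, vs / 2 * 1.01))
        if (is.null(s)) next
        sl <- list(s$lo[1]:s$hi[1], s$lo[2]:s$hi[2], s$lo[3]:s$hi[3])
        vb <- vol[sl[[1]], sl[[2]], sl[[3]]]
        vb[s$d2 <= max(rp, vs / 2 * 1.01)^2] <- ints$cluster
        vol[sl[[1]], sl[[2]], sl[[3]]] <- vb
      }
    }
  }

  if (config$invert_contrast) vol <- -vol
  list(volume = voxel_volume(vol, vs),
       labels = label_volume(lab, vs))
}

#' Apply the missing-wedge Fourier mask
#'
#' Emulates the limited tilt range of single-axis tomography: Fourier
#' coefficients whose direction lies within `half_angle_deg` of the beam
#' (z) axis, measured in the plane perpendicular to the tilt axis, are
#' zeroed. With the default y tilt axis the mask removes all frequencies
#' with `|k_x| < |k_z| * tan(half_angle)`, except the `k_z = 0` plane which
#' is always measured. The mask is symmetric under k -> -k, so the output
#' is real; masking is idempotent and never increases Fourier energy.
#'
#' @param volume a [voxel_volume()].
#' @param half_angle_deg wedge half angle in `[0, 90)`; a -60..+60 degree
#'   tilt series leaves a 30 degree half-angle wedge.
#' @param tilt_axis `"y"` (default) or `"x"`.
#' @return a [voxel_volume()] with the wedge removed.
#' @export
apply_missing_wedge <- function(volume, half_angle_deg = 30,
                                tilt_axis = c("y", "x")) {
  stopifnot(inherits(volume, "voxel_volume"))
  tilt_axis <- match.arg(tilt_axis)
  if (!is.finite(half_angle_deg) || half_angle_deg < 0 || half_angle_deg >= 90)
    stop("half_angle_deg must lie in [0, 90)")
  if (half_angle_deg == 0) return(volume)
  dims <- dim(volume$data)
  t <- tan(half_angle_deg * pi / 180)
  freqs <- function(n) {
    neg <- ceiling(n / 2) - 1
    k <- c(0:(n %/% 2), if (neg >= 1) -(neg:1))
    k / n
  }
  # the in-plane axis paired with z is x for a y tilt axis, y for an x one
  ia <- if (tilt_axis == "y") 1L else 2L
  fa <- abs(freqs(dims[ia]))
  fz <- abs(freqs(dims[3]))
  m2 <- outer(fa, fz, function(a, z) a < z * t & z > 0)
  # the mask has no k-component along the tilt axis, so masking commutes
  # with the transform along it: apply 2D FFTs slab by slab
  out <- volume$data
  n2 <- length(m2)
  if (ia == 1L) {
    for (y in seq_len(dims[2])) {
      F <- fft(volume$data[, y, ])
      F[m2] <- 0
      out[, y, ] <- Re(fft(F, inverse = TRUE)) / n2
    }
  } else {
    for (x in seq_len(dims[1])) {
      F <- fft(volume$data[x, , ])
      F[m2] <- 0
      out[x, , ] <- Re(fft(F, inverse = TRUE)) / n2
    }
  }
  voxel_volume(out, volume$voxel_size_nm, volume$origin_nm)
}

#' Add seeded Gaussian noise
#'
#' @param volume a [voxel_volume()].
#' @param noise_sd standard deviation of i.i.d. additive Gaussian noise;
#'   0 returns the input unchanged.
#' @param seed integer seed, so the corruption is reproducible.
#' @return a [voxel_volume()].
#' @export
add_noise <- function(volume, noise_sd, seed = 1L) {
  stopifnot(inherits(volume, "voxel_volume"), noise_sd >= 0)
  if (noise_sd == 0) return(volume)
  set.seed(as.integer(seed))
  d <- dim(volume$data)
  noisy <- volume$data + array(rnorm(prod(d), 0, noise_sd), dim = d)
  voxel_volume(noisy, volume$voxel_size_nm, volume$origin_nm)
}

#' Generate one synthetic tomogram end to end
#'
#' Convenience wrapper: sample the field, render it, apply the missing
#' wedge and add noise, as configured.
#'
#' @param config a [generator_config()].
#' @param use_wedge,use_noise logical switches to disable the wedge or the
#'   noise without touching the config (used for noiseless control runs).
#' @return list with `field`, `volume` (corrupted), `clean` (pre-corruption
#'   volume) and `labels`.
#' @export
generate_tomogram <- function(config, use_wedge = TRUE, use_noise = TRUE) {
  field <- sample_vesicle_field(config)
  r <- render_field(field, config)
  vol <- r$volume
  if (use_wedge && config$wedge_half_angle_deg > 0)
    vol <- apply_missing_wedge(vol, config$wedge_half_angle_deg)
  if (use_noise && config$noise_sd > 0)
    vol <- add_noise(vol, config$noise_sd, seed = config$seed + 104729L)
  list(field = field, volume = vol, clean = r$volume, labels = r$labels)
}
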
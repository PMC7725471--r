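# Per-vesicle size estimation from the central cross section.
#
# Because the missing wedge hides the membrane at the vesicle poles,
# direct 3D integration of a segmented vesicle underestimates its volume.
# For (near-)spherical vesicles the central cross section is unaffected:
# its area A gives the diameter d = 2*sqrt(A/pi) and volume V = pi*d^3/6.

#' Diameter from cross-section area
#'
#' `d = 2 * sqrt(A / pi)`: the diameter of the circle with area `A`.
#'
#' @param A cross-section area(s) in nm^2, strictly positive.
#' @return diameter(s) in nm.
#' @examples
#' diameter_from_area(pi)          # 2
#' diameter_from_area(pi * 98^2)   # 196
#' @export
diameter_from_area <- function(A) {
  if (any(!is.finite(A) | A <= 0)) stop("cross-section area must be > 0")
  2 * sqrt(A / pi)
}

#' Volume from diameter
#'
#' `V = pi * d^3 / 6`: the volume of the sphere with diameter `d`.
#'
#' @param d diameter(s) in nm, non-negative.
#' @return volume(s) in nm^3.
#' @examples
#' volume_from_diameter(1)  # pi/6
#' @export
volume_from_diameter <- function(d) {
  if (any(!is.finite(d) | d < 0)) stop("diameter must be >= 0")
  pi * d^3 / 6
}

#' Central cross-section area of one vesicle mask
#'
#' Among the z-slices intersecting the (hole-filled) mask, takes the slice
#' through the filled-mask centroid, rounded to the nearest slice with
#' ties broken toward the larger in-slice area; the area is the filled
#' in-slice voxel count times `voxel_size_nm^2`. With `slice = "max"` the
#' largest-area slice is used instead (exact for z-truncated spheres whose
#' centroid is displaced from the equator).
#'
#' @param mask 3D logical array containing one connected object.
#' @param voxel_size_nm voxel size in nm.
#' @param slice `"centroid"` (default) or `"max"`.
#' @return list with `area_nm2`, `slice_index`, and `n_slice_voxels`.
#' @export
central_cross_section_area <- function(mask, voxel_size_nm,
                                       slice = c("centroid", "max")) {
  slice <- match.arg(slice)
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty vesicle mask")
  dims <- dim(mask)
  filled <- .fill3d(.fill_slices(mask))
  # per-slice filled areas
  areas <- apply(filled, 3, sum)
  kz <- which(areas > 0)
  if (slice == "max") {
    k <- kz[which.max(areas[kz])]
  } else {
    zc <- sum(seq_len(dims[3]) * areas) / sum(areas)
    lo <- floor(zc); hi <- ceiling(zc)
    k <- if (lo == hi) lo
    else if (abs(zc - lo) < abs(hi - zc)) lo
    else if (abs(zc - lo) > abs(hi - zc)) hi
    else if (areas[hi] >= areas[lo]) hi else lo   # tie: larger area
    k <- min(max(k, min(kz)), max(kz))
  }
  list(area_nm2 = areas[k] * voxel_size_nm^2,
       slice_index = as.integer(k), n_slice_voxels = areas[k])
}

#' Measure all labelled vesicles
#'
#' Applies the central-cross-section estimator to every object of a label
#' volume, producing one `vesicles`-schema record per label, ordered by
#' id. Objects touching the lateral (x/y) grid boundary are flagged
#' `truncated`: their in-plane profile is cut, so they carry no area,
#' diameter or volume (their labelled voxel volume is still recorded for
#' volume-fraction accounting). Objects cut only by the lamella surfaces
#' (z faces) are the expected geometry of slab-shaped tomograms; they are
#' measured with the largest-area slice, which coincides with the
#' equatorial slice of a sphere whose center lies inside the slab.
#'
#' @param labels a [label_volume()].
#' @param boundary_policy `"flag"` (default) or `"exclude"`; with
#'   `"exclude"`, laterally truncated objects are dropped entirely.
#' @param slice slice rule for fully interior objects (`"centroid"` or
#'   `"max"`).
#' Each record also carries `in_volume_nm3`, the estimated vesicle volume
#' *inside* the tomogram: the full sphere volume for interior objects, the
#' analytic sphere-minus-caps volume (from the measured diameter and the
#' equatorial slice position) for lamella-cut objects, and the labelled
#' voxel volume for laterally truncated ones. Volume-fraction accounting
#' uses this column, so out-of-slab caps are never counted.
#'
#' @return data.frame in the `vesicles` schema (maturity and cluster
#'   columns are NA; see [classify_vesicles()] and [detect_clusters()]).
#' @export
measure_vesicles <- function(labels, boundary_policy = c("flag", "exclude"),
                             slice = c("centroid", "max")) {
  boundary_policy <- match.arg(boundary_policy)
  slice <- match.arg(slice)
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  vs <- labels$voxel_size_nm
  dims <- dim(lab)
  K <- max(lab)
  if (K == 0L) return(.empty_table("vesicles"))
  idx <- which(lab > 0L)
  ids <- lab[idx]
  co <- arrayInd(idx, dims)
  by_id <- split(seq_along(ids), ids)
  rows <- vector("list", K)
  for (nm in names(by_id)) {
    k <- as.integer(nm)
    sel <- by_id[[nm]]
    ck <- co[sel, , drop = FALSE]
    lo <- apply(ck, 2, min); hi <- apply(ck, 2, max)
    edge_xy <- lo[1] == 1L || hi[1] == dims[1] ||
      lo[2] == 1L || hi[2] == dims[2]
    edge_z <- lo[3] == 1L || hi[3] == dims[3]
    if (edge_xy && boundary_policy == "exclude") next
    sub <- array(FALSE, hi - lo + 1L)
    sub[cbind(ck[, 1] - lo[1] + 1L, ck[, 2] - lo[2] + 1L,
              ck[, 3] - lo[3] + 1L)] <- TRUE
    n_vox <- length(sel)
    centroid <- (colMeans(ck) - 0.5) * vs
    if (edge_xy) {
      A <- NA_real_; d <- NA_real_; V <- NA_real_
      v_in <- n_vox * vs^3
    } else {
      cs <- central_cross_section_area(sub, vs,
                                       slice = if (edge_z) "max" else slice)
      A <- cs$area_nm2
      d <- diameter_from_area(A)
      V <- volume_from_diameter(d)
      # in-tomogram volume: subtract the caps the lamella surfaces cut
      # off; the measurement slice sits at the equator, so its z locates
      # the sphere center better than the truncated-mask centroid
      cz_eq <- (lo[3] + cs$slice_index - 1L - 0.5) * vs
      v_in <- .sphere_slab_volume(d / 2, cz_eq, 0, dims[3] * vs)
    }
    rows[[k]] <- data.frame(
      id = k, tomogram_id = NA_character_, region_label = NA_character_,
      cx_nm = centroid[1], cy_nm = centroid[2], cz_nm = centroid[3],
      cross_section_area_nm2 = A, diameter_nm = d, volume_nm3 = V,
      in_volume_nm3 = v_in, n_voxels = n_vox,
      voxel_volume_nm3 = n_vox * vs^3,
      mature = NA, contrast_statistic = NA_real_,
      cluster_count = NA_integer_,
      truncated = edge_xy, edge_xy = edge_xy, edge_z = edge_z)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) return(.empty_table("vesicles"))
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  .as_table(out, "vesicles")
}
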
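# Volume container, MRC-2014 input/output, and tabular result schemas.
#
# Spatial conventions used throughout the package:
#   * volumes are 3D arrays indexed [x, y, z]; because R arrays are
#     column-major this stores x fastest, which is also the MRC on-disk
#     layout, and z (the third index) is the electron-beam / lamella
#     thinning axis;
#   * voxel indices are 1-based in R; the physical center of data[i, j, k]
#     is origin_nm + (c(i, j, k) - 0.5) * voxel_size_nm;
#   * all physical positions and lengths are in nm; region distances from
#     a membrane landmark are in micrometres and converted exactly once,
#     in the neighborhood summaries (1 um^3 = 1e9 nm^3).

#' Voxel volume container
#'
#' Wraps a 3D numeric array with its isotropic voxel size. The third array
#' index is the beam (lamella thickness) axis, conventionally called z.
#'
#' @param data 3D numeric array, indexed `[x, y, z]`, all values finite.
#' @param voxel_size_nm positive isotropic voxel edge length in nm.
#' @param origin_nm physical offset of the corner of voxel `[1, 1, 1]`,
#'   length-3 numeric (nm).
#' @return An object of class `voxel_volume`: a list with elements `data`,
#'   `voxel_size_nm`, `origin_nm`.
#' @examples
#' v <- voxel_volume(array(0, c(8, 8, 4)), voxel_size_nm = 2)
#' dim(v$data)
#' extent_nm(v)
#' @export
voxel_volume <- function(data, voxel_size_nm, origin_nm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("`voxel_size_nm` must be a single positive number")
  if (anyNA(data) || !all(is.finite(data)))
    stop("volume data must be finite")
  if (length(origin_nm) != 3L) stop("`origin_nm` must have length 3")
  structure(
    list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
         origin_nm = as.numeric(origin_nm)),
    class = "voxel_volume")
}

#' Label volume container
#'
#' Integer instance labels congruent with a parent [voxel_volume()]:
#' 0 is background, k > 0 identifies one object. After relabelling the ids
#' form the contiguous set 1..K.
#'
#' @param labels 3D integer array (same shape as the parent volume).
#' @param voxel_size_nm voxel size in nm (same as the parent volume).
#' @param origin_nm origin of voxel `[1, 1, 1]` in nm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size_nm, origin_nm = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers")
  structure(
    list(labels = labels, voxel_size_nm = as.numeric(voxel_size_nm),
         origin_nm = as.numeric(origin_nm)),
    class = "label_volume")
}

#' Physical extent of a volume
#'
#' @param x a `voxel_volume` or `label_volume`.
#' @return Length-3 numeric, grid shape times voxel size, in nm.
#' @export
extent_nm <- function(x) {
  d <- if (inherits(x, "label_volume")) dim(x$labels) else dim(x$data)
  d * x$voxel_size_nm
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %g nm (%g x %g x %g nm)\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              d[1] * x$voxel_size_nm, d[2] * x$voxel_size_nm,
              d[3] * x$voxel_size_nm))
  cat(sprintf("  range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %g nm, %d object(s)\n",
              d[1], d[2], d[3], x$voxel_size_nm, max(x$labels)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# MRC-2014 I/O (mode 2, 32-bit float, little-endian).  The header voxel size
# is stored in Angstrom as cell length / sampling; 10 A = 1 nm.

.mrc_modes <- list(
  `0` = list(what = "integer", size = 1L, signed = TRUE),
  `1` = list(what = "integer", size = 2L, signed = TRUE),
  `2` = list(what = "numeric", size = 4L, signed = TRUE),
  `6` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Read an MRC-2014 volume
#'
#' Reads a single-volume MRC file (modes 0, 1, 2 and 6; standard axis order
#' mapc/mapr/maps = 1/2/3). The voxel size is taken from the header cell
#' dimensions (Angstrom) and converted to nm; an absent or non-positive
#' voxel size is a calibration error, not something to guess around.
#'
#' @param path path to an existing MRC file.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little")  # cellb
  mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little")  # dmin/max/mean
  ispg <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  # origin lives at byte 196 in MRC-2014
  seek(con, 196L)
  origin_a <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")

  if (nx <= 0 || ny <= 0 || nz <= 0)
    stop("invalid MRC header: non-positive dimensions")
  m <- .mrc_modes[[as.character(mode)]]
  if (is.null(m)) stop("unsupported MRC mode: ", mode)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order (mapc/mapr/maps must be 1/2/3)")
  if (mx <= 0 || my <= 0 || mz <= 0 || any(!is.finite(cella)) || cella[1] <= 0)
    stop("unusable voxel size calibration in MRC header")
  vs_a <- cella / c(mx, my, mz)
  if (any(vs_a <= 0) || diff(range(vs_a)) > 1e-4 * vs_a[1])
    stop("unusable voxel size calibration in MRC header (anisotropic or <= 0)")

  seek(con, 1024L + max(0L, nsymbt))
  n <- as.double(nx) * ny * nz
  vals <- readBin(con, m$what, n = n, size = m$size,
                  signed = m$signed, endian = "little")
  if (length(vals) != n) stop("truncated MRC data block")
  arr <- array(as.numeric(vals), dim = c(nx, ny, nz))
  voxel_volume(arr, voxel_size_nm = vs_a[1] / 10,
               origin_nm = origin_a / 10)
}

#' Write a volume as MRC-2014 (mode 2)
#'
#' 32-bit float output; the voxel size is recorded in the header in
#' Angstrom (voxel_size_nm * 10). Lossless round trip for data already
#' representable in 32-bit floats.
#'
#' @param volume a [voxel_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$data)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  vs_a <- volume$voxel_size_nm * 10
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(c(d * vs_a, 90, 90, 90)), con, size = 4L,
           endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4L, endian = "little")
  rng <- range(volume$data)
  writeBin(as.numeric(c(rng[1], rng[2], mean(volume$data))), con, size = 4L,
           endian = "little")
  writeBin(c(0L, 0L), con, size = 4L, endian = "little")     # ispg, nsymbt
  writeBin(integer(25), con, size = 4L, endian = "little")   # extra (100 B)
  writeBin(as.numeric(volume$origin_nm * 10), con, size = 4L,
           endian = "little")                                 # origin @196
  writeChar("MAP ", con, nchars = 4L, eos = NULL)             # @208
  writeBin(c(0x44L, 0x44L, 0x00L, 0x00L), con, size = 1L)     # machine stamp
  writeBin(as.numeric(sd(as.numeric(volume$data))), con, size = 4L,
           endian = "little")                                 # rms
  writeBin(0L, con, size = 4L, endian = "little")             # nlabl
  writeBin(integer(200), con, size = 4L, endian = "little")   # labels
  writeBin(as.numeric(volume$data), con, size = 4L, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tabular results.  Each record type has a fixed, documented column schema;
# read_table() refuses files whose columns do not match it exactly.

.table_schemas <- list(
  truth = c("id", "cx_nm", "cy_nm", "cz_nm", "lumen_diameter_nm",
            "outer_diameter_nm", "mature", "core_diameter_nm",
            "n_clusters", "region_label"),
  clusters = c("vesicle_id", "cx_nm", "cy_nm", "cz_nm", "diameter_nm"),
  vesicles = c("id", "tomogram_id", "region_label", "cx_nm", "cy_nm", "cz_nm",
               "cross_section_area_nm2", "diameter_nm", "volume_nm3",
               "in_volume_nm3", "n_voxels", "voxel_volume_nm3", "mature",
               "contrast_statistic", "cluster_count", "truncated",
               "edge_xy", "edge_z"),
  summaries = c("region", "n_tomograms", "n_vesicles", "n_mature",
                "mature_fraction", "mean_diameter_nm", "sd_diameter_nm",
                "median_diameter_nm", "q25_diameter_nm", "q75_diameter_nm",
                "count_density_per_um3", "volume_fraction",
                "tomogram_volume_um3"),
  manifest = c("tomogram_id", "region_label", "landmark", "distance_um",
               "volume_um3")
)

#' Write a result table as CSV
#'
#' @param records data.frame following one of the package's fixed schemas
#'   (`truth`, `clusters`, `vesicles`, `summaries`, `manifest`).
#' @param path output CSV path.
#' @param type schema name; defaults to the data.frame's `table_type`
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path,
                        type = attr(records, "table_type")) {
  type <- match.arg(type, names(.table_schemas))
  schema <- .table_schemas[[type]]
  if (!identical(names(records), schema))
    stop("records do not follow the '", type, "' schema")
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path CSV path.
#' @param type schema name (`truth`, `clusters`, `vesicles`, `summaries`,
#'   `manifest`).
#' @return data.frame with a `table_type` attribute.
#' @export
read_table <- function(path, type) {
  type <- match.arg(type, names(.table_schemas))
  schema <- .table_schemas[[type]]
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), schema))
    stop("CSV columns do not match the '", type, "' schema: ",
         paste(setdiff(union(names(df), schema),
                       intersect(names(df), schema)), collapse = ", "))
  for (cl in intersect(c("mature", "truncated", "edge_xy", "edge_z"),
                       names(df)))
    df[[cl]] <- as.logical(df[[cl]])
  attr(df, "table_type") <- type
  df
}

.as_table <- function(df, type) {
  df <- df[, .table_schemas[[type]], drop = FALSE]
  attr(df, "table_type") <- type
  df
}

.empty_table <- function(type) {
  cols <- .table_schemas[[type]]
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  attr(df, "table_type") <- type
  df
}
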
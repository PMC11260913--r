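#' Scan metadata
#'
#' Light-weight provenance attached to every volume: which cheese wheel it
#' is, which production batch it came from, its age at scanning (days), and
#' where the voxel data came from (a file path, or `"phantom"` for synthetic
#' volumes).
#'
#' @param cheese_id Character identifier of the wheel.
#' @param batch_id Character identifier of the production batch.
#' @param age_days Non-negative integer age at scanning, in days.
#' @param source Character, origin of the data.
#' @param ... Further named fields kept verbatim (e.g. rescale slope and
#'   intercept found in scanner headers; these are recorded, never applied).
#' @return A `scan_meta` object (named list).
#' @export
scan_meta <- function(cheese_id = "", batch_id = "", age_days = 0L,
                      source = "", ...) {
  age_days <- as.integer(age_days)
  if (is.na(age_days) || age_days < 0L)
    stop("age_days must be a nonnegative integer", call. = FALSE)
  structure(list(cheese_id = as.character(cheese_id),
                 batch_id = as.character(batch_id),
                 age_days = age_days,
                 source = as.character(source), ...),
            class = "scan_meta")
}

#' CT scan volume
#'
#' Container for a reconstructed CT volume: a 3D array of stored integer CT
#' numbers, the voxel spacing, and scan metadata. Axis order is
#' `(x, y, slice)` with the slice axis last, so `spacing[3]` is the slice
#' thickness used for 2D-to-3D volume extrapolation. Physical position of a
#' voxel is its 0-based index times the spacing.
#'
#' @param ctn 3D integer (or numeric) array of stored CT numbers.
#' @param spacing Numeric length-3, voxel spacing in mm `(dx, dy, dz)`;
#'   all entries must be positive.
#' @param meta A [scan_meta()] object.
#' @return A `scan_volume` object.
#' @examples
#' v <- scan_volume(array(2174L, c(4, 4, 2)), spacing = c(1, 1, 1.25))
#' dim(v$ctn)
#' @export
scan_volume <- function(ctn, spacing = c(1, 1, 1.25), meta = scan_meta()) {
  if (length(dim(ctn)) != 3L)
    stop("ctn must be a 3D array", call. = FALSE)
  if (any(dim(ctn) < 1L))
    stop("ctn must have at least one voxel in each dimension", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)", call. = FALSE)
  if (!inherits(meta, "scan_meta"))
    stop("meta must be a scan_meta object", call. = FALSE)
  structure(list(ctn = ctn, spacing = spacing, meta = meta),
            class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$ctn)
  cat(sprintf("<scan_volume> %d x %d x %d voxels, spacing %g x %g x %g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  cheese_id='%s' batch='%s' age=%d d, source='%s'\n",
              x$meta$cheese_id, x$meta$batch_id, x$meta$age_days,
              x$meta$source))
  invisible(x)
}

#' Hounsfield CT number from linear attenuation coefficients
#'
#' Normalized attenuation scale: `CTN = 1000 * (mu - mu_w) / (mu_w - mu_a)`,
#' so that water maps to 0 and air to -1000. Requires `mu_w > mu_a`; a
#' calibration with water no more attenuating than air is rejected.
#'
#' @param mu Linear attenuation coefficient of the material (1/m), >= 0.
#' @param mu_w,mu_a Attenuation coefficients of water and air.
#' @return CT number on the Hounsfield scale (vectorized over `mu`).
#' @examples
#' attenuation_to_ctn(0.2, mu_w = 0.2, mu_a = 0.0002)  # water -> 0
#' @export
attenuation_to_ctn <- function(mu, mu_w, mu_a) {
  if (!is.finite(mu_w) || !is.finite(mu_a) || mu_w <= mu_a)
    stop("invalid calibration: mu_w must exceed mu_a", call. = FALSE)
  if (any(mu < 0) || mu_a < 0)
    stop("attenuation coefficients must be nonnegative", call. = FALSE)
  1000 * (mu - mu_w) / (mu_w - mu_a)
}

#' Convert stored CT numbers to density
#'
#' The scanner stores CT numbers with a fixed offset; density in kg/m3 is
#' recovered as `ctn - offset`. With the default offset of 1024 the stored
#' value 1024 maps to density 0 and the segmentation threshold of
#' 850 kg/m3 corresponds to a stored value of 1874. This is a total
#' function; [density_to_ctn()] is its exact inverse.
#'
#' @param ctn Stored CT number(s) (integer or real).
#' @param offset Positive offset of the stored scale, default 1024.
#' @return Density in kg/m3, same shape as `ctn`.
#' @examples
#' ctn_to_density(c(1024, 1874, 2174))  # 0, 850, 1150
#' @export
ctn_to_density <- function(ctn, offset = 1024) {
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
    stop("offset must be a single positive number", call. = FALSE)
  ctn - offset
}

#' Convert density to a stored CT number
#'
#' Exact inverse of [ctn_to_density()]; values are kept real and only
#' rounded to integers at serialization time (e.g. in the phantom forward
#' model).
#'
#' @param rho Density in kg/m3.
#' @inheritParams ctn_to_density
#' @return Stored CT number(s).
#' @export
density_to_ctn <- function(rho, offset = 1024) {
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
    stop("offset must be a single positive number", call. = FALSE)
  rho + offset
}

#' Density volume from a CT scan
#'
#' Applies the stored-CT-number-to-density conversion voxelwise, preserving
#' shape and spacing.
#'
#' @param scan A [scan_volume()].
#' @param offset Stored-scale offset passed to [ctn_to_density()].
#' @return A `density_volume` object with fields `rho` (3D array, kg/m3)
#'   and `spacing` (mm).
#' @export
density_volume <- function(scan, offset = 1024) {
  stopifnot(inherits(scan, "scan_volume"))
  structure(list(rho = ctn_to_density(scan$ctn, offset),
                 spacing = scan$spacing, meta = scan$meta,
                 offset = offset),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$rho)
  cat(sprintf(
    "<density_volume> %d x %d x %d voxels, range %.1f..%.1f kg/m3\n",
    d[1], d[2], d[3], min(x$rho), max(x$rho)))
  invisible(x)
}

# ---- raster series I/O -----------------------------------------------------
# One little-endian int32 .raw file per slice plus a JSON sidecar
# (volume.json) holding shape, spacing, dtype and metadata. Mirrors the
# one-file-per-slice layout of a scanner DICOM export while staying a
# simple documented raster format.

.sidecar_name <- "volume.json"

#' Write a CT volume to disk
#'
#' Supported formats: `"raster-series"` (one little-endian int32 `.raw`
#' file per slice plus a `volume.json` sidecar, mirroring a one-file-per-
#' slice scanner export) and `"raster"` (a single `.raw` file plus the
#' sidecar). Stored CT numbers are rounded to integers at this point;
#' round-tripping integer-valued volumes is lossless.
#'
#' @param vol A [scan_volume()].
#' @param path Directory to create/write into.
#' @param format `"raster-series"` or `"raster"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("raster-series", "raster")) {
  stopifnot(inherits(vol, "scan_volume"))
  format <- match.arg(format)
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", path, call. = FALSE)
  d <- dim(vol$ctn)
  ctn <- as.integer(round(vol$ctn))

  side <- list(format = format, shape = d, spacing_mm = vol$spacing,
               dtype = "int32", byte_order = "little",
               meta = unclass(vol$meta))
  if (format == "raster-series") {
    files <- sprintf("slice_%04d.raw", seq_len(d[3]) - 1L)
    side$slices <- data.frame(index = seq_len(d[3]) - 1L, file = files,
                              z_mm = (seq_len(d[3]) - 1L) * vol$spacing[3])
    for (k in seq_len(d[3])) {
      con <- file(file.path(path, files[k]), "wb")
      writeBin(ctn[seq_len(d[1] * d[2]) + (k - 1L) * d[1] * d[2]],
               con, size = 4L, endian = "little")
      close(con)
    }
  } else {
    side$file <- "volume.raw"
    con <- file(file.path(path, "volume.raw"), "wb")
    writeBin(ctn, con, size = 4L, endian = "little")
    close(con)
  }
  jsonlite::write_json(side, file.path(path, .sidecar_name),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a CT volume from disk
#'
#' Reads a volume written by [write_volume()]. For `raster-series` input the
#' slices are sorted by their index/position from the sidecar; a gap in the
#' slice indices, a missing slice file, or inconsistent slice spacing is a
#' structured ingest error naming the offending slices. Any rescale
#' slope/intercept present in the sidecar metadata is recorded in `meta`
#' but never applied.
#'
#' @param path Directory containing a `volume.json` sidecar.
#' @param format `"auto"` (read from sidecar), `"raster-series"` or
#'   `"raster"`.
#' @return A [scan_volume()].
#' @export
read_volume <- function(path, format = "auto") {
  sc <- file.path(path, .sidecar_name)
  if (!file.exists(sc))
    stop("no volume sidecar found at: ", path, call. = FALSE)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (format != "auto" && !identical(side$format, format))
    stop(sprintf("requested format '%s' but sidecar says '%s'",
                 format, side$format), call. = FALSE)
  d <- as.integer(side$shape)
  spacing <- as.numeric(side$spacing_mm)
  m <- side$meta
  meta <- do.call(scan_meta, c(
    list(cheese_id = m$cheese_id %||% "", batch_id = m$batch_id %||% "",
         age_days = m$age_days %||% 0L, source = path),
    m[setdiff(names(m), c("cheese_id", "batch_id", "age_days", "source"))]))

  if (identical(side$format, "raster-series")) {
    sl <- side$slices
    sl <- sl[order(sl$index), , drop = FALSE]
    expected <- seq_len(d[3]) - 1L
    missing_idx <- setdiff(expected, sl$index)
    if (length(missing_idx) > 0L)
      stop("ingest error: missing slice index(es): ",
           paste(missing_idx, collapse = ", "), call. = FALSE)
    gone <- sl$file[!file.exists(file.path(path, sl$file))]
    if (length(gone) > 0L)
      stop("ingest error: missing slice file(s): ",
           paste(gone, collapse = ", "), call. = FALSE)
    if (!is.null(sl$z_mm) && d[3] > 1L) {
      dzs <- diff(sl$z_mm)
      if (max(dzs) - min(dzs) > 1e-6 ||
          abs(dzs[1] - spacing[3]) > 1e-6)
        stop("ingest error: inconsistent slice spacing (z positions: ",
             paste(signif(sl$z_mm, 6), collapse = ", "), ")", call. = FALSE)
    }
    ctn <- integer(prod(d))
    np <- d[1] * d[2]
    for (k in seq_len(d[3])) {
      con <- file(file.path(path, sl$file[k]), "rb")
      ctn[seq_len(np) + (k - 1L) * np] <-
        readBin(con, "integer", n = np, size = 4L, endian = "little")
      close(con)
    }
  } else {
    f <- file.path(path, side$file)
    if (!file.exists(f))
      stop("ingest error: missing raster file: ", side$file, call. = FALSE)
    con <- file(f, "rb")
    ctn <- readBin(con, "integer", n = prod(d), size = 4L, endian = "little")
    close(con)
  }
  dim(ctn) <- d
  scan_volume(ctn, spacing, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
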
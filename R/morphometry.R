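#' Cavity volume from per-slice areas
#'
#' Extrapolates per-slice cavity cross-section areas to a 3D volume: each
#' slice area (mm2) is multiplied by the slice thickness (mm) and the sum
#' is converted to cm3. On voxel data this is algebraically identical to
#' voxel count times voxel volume.
#'
#' @param slice_areas Numeric vector of per-slice areas in mm2 (>= 0).
#' @param dz Slice thickness in mm (> 0).
#' @return Volume in cm3.
#' @examples
#' cavity_volume(c(12, 20, 12), dz = 1.25)  # 0.055 cm3
#' @export
cavity_volume <- function(slice_areas, dz) {
  if (!is.numeric(dz) || length(dz) != 1L || dz <= 0)
    stop("dz must be a single positive slice thickness (mm)", call. = FALSE)
  if (any(slice_areas < 0))
    stop("slice areas must be nonnegative", call. = FALSE)
  sum(slice_areas) * dz / 1000
}

#' Surface area of a voxelized region
#'
#' Normal-weighted exposed-face surface estimator: every voxel face
#' separating the region from its complement contributes its physical face
#' area weighted by the corresponding component of the local unit surface
#' normal, estimated from the gradient of a Gaussian-smoothed copy of the
#' mask (`sigma_mm`, default 1.25 mm, the coarsest voxel dimension). The estimator is asymptotically exact
#' for planar interfaces of any orientation, so it handles both round eyes
#' and thin planar cracks; on very small regions discretization can push
#' the derived sphericity above 1.
#'
#' @param mask 3D logical array, TRUE inside the region.
#' @param spacing Voxel spacing in mm.
#' @param sigma_mm Smoothing scale for normal estimation, in mm.
#' @return Surface area in mm2 (deterministic for fixed input).
#' @export
surface_area_mask <- function(mask, spacing, sigma_mm = 1.25) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  cpp_surface_area(as.logical(mask), dim(mask), as.numeric(spacing),
                   sigma_mm)
}

#' Surface area of one labeled cavity
#'
#' Extracts the cavity's bounding box (padded so the smoothing kernel sees
#' the full boundary) and applies [surface_area_mask()].
#'
#' @param labels A `label_map` from [label_cavities()], or a 3D integer
#'   array of labels.
#' @param label Cavity label to measure.
#' @param spacing Voxel spacing in mm (taken from the label map if omitted).
#' @param sigma_mm Smoothing scale passed on to [surface_area_mask()].
#' @return Surface area in mm2.
#' @export
cavity_surface_area <- function(labels, label, spacing = NULL, sigma_mm = 1.25) {
  if (inherits(labels, "label_map")) {
    spacing <- spacing %||% labels$spacing
    labels <- labels$labels
  }
  if (is.null(spacing)) stop("spacing required", call. = FALSE)
  idx <- which(labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("label ", label, " not present", call. = FALSE)
  d <- dim(labels)
  pad <- 4L
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == label
  surface_area_mask(sub, spacing, sigma_mm)
}

#' Sphericity (roundness) of a cavity
#'
#' Isoperimetric shape score `psi = pi^(1/3) * (6 V)^(2/3) / A` with the
#' volume and surface in consistent mm units. A perfect sphere scores
#' exactly 1; flat or elongated voids (cracks, splits) score well below 1;
#' discrete surface estimation on very small cavities can push the score
#' above 1.
#'
#' @param volume_cm3 Cavity volume in cm3 (> 0).
#' @param surface_area_mm2 Cavity surface area in mm2 (> 0).
#' @return Dimensionless roundness score >= 0.
#' @examples
#' r <- 10
#' roundness(4 / 3 * pi * r^3 / 1000, 4 * pi * r^2)  # exactly 1
#' @export
roundness <- function(volume_cm3, surface_area_mm2) {
  if (any(volume_cm3 <= 0))
    stop("volume must be positive", call. = FALSE)
  if (any(surface_area_mm2 <= 0))
    stop("undefined roundness: surface area must be positive", call. = FALSE)
  v_mm3 <- volume_cm3 * 1000
  pi^(1 / 3) * (6 * v_mm3)^(2 / 3) / surface_area_mm2
}

#' Measure every cavity in a label map
#'
#' Builds the per-cavity catalog: voxel count, per-slice areas, volume (by
#' the exact voxel-count identity), surface area, roundness, centroid (mm),
#' bounding box and a crack flag (initialized FALSE; see [flag_cracks()]).
#'
#' @param labels A `label_map` from [label_cavities()].
#' @param sigma_mm Surface-normal smoothing scale, passed to
#'   [cavity_surface_area()].
#' @return A data frame with one row per cavity, ordered by label;
#'   per-slice areas are kept in the `slice_areas` list column as
#'   `(slice, area_mm2)` matrices.
#' @export
measure_cavities <- function(labels, sigma_mm = 1.25) {
  stopifnot(inherits(labels, "label_map"))
  sp <- labels$spacing
  voxel_cm3 <- prod(sp) / 1000
  K <- labels$n_cavities
  if (K == 0L) {
    out <- data.frame(label = integer(0), voxel_count = numeric(0),
                      volume_cm3 = numeric(0), surface_area_mm2 = numeric(0),
                      roundness = numeric(0), centroid_x_mm = numeric(0),
                      centroid_y_mm = numeric(0), centroid_z_mm = numeric(0),
                      crack_flag = logical(0))
    out$slice_areas <- list()
    attr(out, "spacing") <- sp
    return(out)
  }
  pr <- cpp_region_props(labels$labels, dim(labels$labels), K)
  area_px <- sp[1] * sp[2]
  d <- dim(labels$labels)

  slice_areas <- vector("list", K)
  for (z in seq_len(d[3])) {
    page <- labels$labels[, , z]
    tab <- tabulate(page[page > 0L], nbins = K)
    hit <- which(tab > 0L)
    for (k in hit)
      slice_areas[[k]] <- rbind(slice_areas[[k]],
                                c(slice = z - 1L, area_mm2 = tab[k] * area_px))
  }

  surf <- vapply(seq_len(K), function(k)
    cavity_surface_area(labels, k, sigma_mm = sigma_mm), numeric(1))
  # same association as the slice-area path so the two volume readings
  # agree bit for bit: (count * dx * dy) * dz / 1000
  vol <- pr$count * sp[1] * sp[2] * sp[3] / 1000

  out <- data.frame(
    label = seq_len(K),
    voxel_count = pr$count,
    volume_cm3 = vol,
    surface_area_mm2 = surf,
    roundness = roundness(vol, surf),
    centroid_x_mm = pr$sx / pr$count * sp[1],
    centroid_y_mm = pr$sy / pr$count * sp[2],
    centroid_z_mm = pr$sz / pr$count * sp[3],
    bbox_x0 = pr$x0, bbox_x1 = pr$x1,
    bbox_y0 = pr$y0, bbox_y1 = pr$y1,
    bbox_z0 = pr$z0, bbox_z1 = pr$z1,
    crack_flag = FALSE)
  out$slice_areas <- slice_areas
  attr(out, "spacing") <- sp
  out
}

#' Flag crack/split candidates in a cavity catalog
#'
#' A cavity is flagged as a crack when it is both irregular (roundness
#' below `roundness_cutoff`) and large (volume above `volume_cutoff_cm3`):
#' large flat voids are the morphological signature of splits, while small
#' low-roundness components are usually discretization artifacts. Flagged
#' cavities stay in the catalog; whether downstream summaries include them
#' is controlled by [summarize_wheel()].
#'
#' @param catalog Data frame from [measure_cavities()].
#' @param roundness_cutoff Roundness below which a cavity may be a crack;
#'   default 0.4.
#' @param volume_cutoff_cm3 Volume above which a low-roundness cavity is
#'   flagged; default 1 cm3.
#' @return The catalog with `crack_flag` set.
#' @export
flag_cracks <- function(catalog, roundness_cutoff = 0.4,
                        volume_cutoff_cm3 = 1) {
  if (nrow(catalog) == 0L) return(catalog)
  catalog$crack_flag <- catalog$roundness < roundness_cutoff &
    catalog$volume_cm3 > volume_cutoff_cm3
  catalog
}

#' Percentile by linear interpolation
#'
#' Linear interpolation between order statistics (the classical
#' `(n-1)q + 1` rule); a single value is returned unchanged for any `q`.
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in `[0, 100]`.
#' @return The interpolated percentile.
#' @examples
#' percentile(1:5, 50)          # 3
#' percentile(seq(0.1, 1, 0.1), 10)  # 0.19
#' @export
percentile <- function(values, q) {
  if (length(values) == 0L)
    stop("percentile of an empty vector is undefined", call. = FALSE)
  if (q < 0 || q > 100) stop("q must lie in [0, 100]", call. = FALSE)
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

#' Per-wheel summary metrics
#'
#' Aggregates a cavity catalog into the standard per-wheel report: eye
#' count, mean and 10th/90th-percentile eye volume, total eye volume, wheel
#' volume (cheese matrix only, excluding the cavities), the eye-to-wheel
#' volume ratio, the eye percentage
#' `eye_percent = 100 * ratio / (1 + ratio)` (equivalently
#' `100 * eye volume / (wheel volume + eye volume)`), and roundness
#' statistics. A wheel with no cavities reports zero count, ratio and eye
#' percentage and `NA` (absent, not zero) volume and roundness statistics
#' so that empty wheels do not bias group means.
#'
#' @param catalog Data frame from [measure_cavities()] (optionally after
#'   [flag_cracks()]).
#' @param wheel_voxel_count Number of cheese-matrix voxels (from
#'   [extract_wheel()] / [label_cavities()] accounting).
#' @param spacing Voxel spacing in mm.
#' @param meta A [scan_meta()] for the id columns.
#' @param include_cracks If `FALSE`, crack-flagged cavities are excluded
#'   from all eye statistics; default `TRUE` (all cavities count, matching
#'   all-cavity reporting).
#' @return One-row data frame of class `wheel_summary`.
#' @export
summarize_wheel <- function(catalog, wheel_voxel_count, spacing,
                            meta = scan_meta(), include_cracks = TRUE) {
  voxel_cm3 <- prod(spacing) / 1000
  wheel_volume <- wheel_voxel_count * voxel_cm3
  if (!include_cracks && nrow(catalog) > 0L)
    catalog <- catalog[!catalog$crack_flag, , drop = FALSE]

  n <- nrow(catalog)
  if (n == 0L) {
    vols <- numeric(0)
    total <- 0
    ratio <- 0
    eyep <- 0
  } else {
    vols <- catalog$volume_cm3
    total <- sum(vols)
    ratio <- total / wheel_volume
    eyep <- 100 * ratio / (1 + ratio)
  }
  out <- data.frame(
    cheese_id = meta$cheese_id,
    batch_id = meta$batch_id,
    age_days = meta$age_days,
    n_eyes = n,
    mean_eye_volume_cm3 = if (n) mean(vols) else NA_real_,
    eye_volume_p10_cm3 = if (n) percentile(vols, 10) else NA_real_,
    eye_volume_p90_cm3 = if (n) percentile(vols, 90) else NA_real_,
    total_eye_volume_cm3 = total,
    wheel_volume_cm3 = wheel_volume,
    ratio = ratio,
    eye_percent = eyep,
    mean_roundness = if (n) mean(catalog$roundness) else NA_real_,
    roundness_p10 = if (n) percentile(catalog$roundness, 10) else NA_real_,
    roundness_p90 = if (n) percentile(catalog$roundness, 90) else NA_real_,
    n_cracks = sum(catalog$crack_flag),
    stringsAsFactors = FALSE)
  class(out) <- c("wheel_summary", class(out))
  out
}
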
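#' Density thresholding of a CT volume
#'
#' Classifies every voxel as cheese matrix or not-cheese by comparing its
#' density against a fixed threshold. The comparison is inclusive: a voxel
#' with density exactly at the threshold counts as cheese, keeping the
#' threshold value itself on the cheese side. The default of 850 kg/m3 sits
#' well below the typical cheese density range of roughly 1100-1200 kg/m3
#' and well above air, so it separates the cheese body from both the
#' external background and the gas-filled cavities.
#'
#' @param rho A [density_volume()].
#' @param threshold Density threshold in kg/m3 (> 0), default 850.
#' @return A `binary_mask` object: `mask` (TRUE = cheese matrix),
#'   `spacing`, `threshold_used`.
#' @export
threshold_volume <- function(rho, threshold = 850) {
  stopifnot(inherits(rho, "density_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive density (kg/m3)", call. = FALSE)
  structure(list(mask = rho$rho >= threshold,
                 spacing = rho$spacing,
                 threshold_used = threshold,
                 meta = rho$meta),
            class = "binary_mask")
}

#' Construct a binary mask directly
#'
#' Mostly used in tests and by the labeling oracle; `TRUE` is cheese matrix,
#' `FALSE` is not-cheese (cavities and background air).
#'
#' @param mask 3D logical array.
#' @param spacing Voxel spacing in mm.
#' @param threshold_used Threshold recorded for provenance.
#' @param meta Optional [scan_meta()].
#' @export
binary_mask <- function(mask, spacing = c(1, 1, 1.25), threshold_used = 850,
                        meta = scan_meta()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 threshold_used = threshold_used, meta = meta),
            class = "binary_mask")
}

#' Isolate the cheese wheel from a thresholded volume
#'
#' Keeps the largest 26-connected component of the cheese phase (the wheel)
#' and drops every other above-threshold voxel (isolated debris or noise
#' specks). If two components tie for largest, the one containing the
#' smallest linear voxel index wins and a warning is issued.
#'
#' @param mask A `binary_mask` from [threshold_volume()].
#' @param connectivity Connectivity for the cheese phase (6, 18 or 26).
#' @return A `binary_mask` containing only the wheel; attribute
#'   `wheel_voxel_count` holds its size and `dropped_voxels` the number of
#'   above-threshold voxels discarded.
#' @export
extract_wheel <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$mask))
    stop("no wheel found: mask contains no cheese voxels", call. = FALSE)
  comp <- cpp_label_components(as.logical(mask$mask), dim(mask$mask),
                               as.integer(connectivity))
  counts <- comp$counts
  best <- max(counts)
  cand <- which(counts == best)
  if (length(cand) > 1L) {
    cand <- cand[order(comp$min_index[cand])]
    warning(sprintf(
      "%d equal-size largest components; keeping the one at smallest linear index",
      length(cand)), call. = FALSE)
  }
  keep <- cand[1L]
  wheel <- array(comp$labels == keep, dim = dim(mask$mask))
  out <- binary_mask(wheel, mask$spacing, mask$threshold_used, mask$meta)
  attr(out, "wheel_voxel_count") <- counts[keep]
  attr(out, "dropped_voxels") <- sum(counts) - counts[keep]
  out
}

.face_touch <- function(mask) {
  d <- dim(mask)
  c(any(mask[1, , ]), any(mask[d[1], , ]),
    any(mask[, 1, ]), any(mask[, d[2], ]),
    any(mask[, , 1]), any(mask[, , d[3]]))
}

#' Identify cavities as labeled connected components
#'
#' Partitions the below-threshold (not-cheese) phase: components reachable
#' from the volume boundary by flood fill are external air; the remaining
#' components lying inside the wheel's filled interior are cavities (eyes,
#' cracks, splits). Components smaller than `min_volume_cm3` are discarded
#' as noise speckle and counted in the returned attributes. Labels are
#' assigned in decreasing volume order (ties broken by smallest linear
#' index). Cavities open to the rind are connected to the boundary and
#' therefore merge into external air by construction; they are not counted.
#'
#' Default connectivities are complementary: 26 for the cheese phase and 6
#' for the cavity/air phase, which avoids topological paradoxes between the
#' two phases. With `mode = "2d-stacked"` the same 3D-classified cavity
#' voxels are relabeled slice by slice with the in-plane connectivity, so
#' the two modes agree exactly on total cavity volume and differ only in
#' how coalesced features are counted.
#'
#' @param mask A `binary_mask` from [threshold_volume()].
#' @param wheel The wheel mask from [extract_wheel()]; its TRUE set must be
#'   a subset of `mask`'s.
#' @param connectivity Connectivity for the cavity/air phase: 6 (default),
#'   18 or 26.
#' @param min_volume_cm3 Minimum cavity volume kept, in cm3; default 0.01
#'   (8 voxels at 1 x 1 x 1.25 mm).
#' @param mode `"3d"` (default) or `"2d-stacked"`.
#' @return A `label_map`: `labels` (3D integer array, 0 = cheese or
#'   external air, 1..K = cavities), `n_cavities`, `connectivity_used`,
#'   plus accounting attributes `cavity_voxels`, `external_air_voxels`,
#'   `discarded_voxels`, `discarded_components`, `wheel_voxels`.
#' @export
label_cavities <- function(mask, wheel, connectivity = 6,
                           min_volume_cm3 = 0.01, mode = c("3d", "2d-stacked")) {
  stopifnot(inherits(mask, "binary_mask"), inherits(wheel, "binary_mask"))
  mode <- match.arg(mode)
  if (any(wheel$mask & !mask$mask))
    stop("wheel mask is not a subset of the cheese mask", call. = FALSE)
  d <- dim(mask$mask)
  voxel_cm3 <- prod(mask$spacing) / 1000

  wt <- .face_touch(wheel$mask)
  if (all(wt))
    warning("wheel touches all six volume faces; field of view may clip the wheel",
            call. = FALSE)

  # filled interior of the wheel: complement of the boundary-connected
  # part of the wheel's complement
  wcomp <- cpp_label_components(!wheel$mask, d, as.integer(connectivity))
  ext_ids <- which(wcomp$touches_boundary == 1L)
  # wheel voxels carry label 0, so they stay inside the filled region
  filled <- array(!(wcomp$labels %in% ext_ids), d)

  comp <- cpp_label_components(!mask$mask, d, as.integer(connectivity))
  K0 <- comp$n
  labarr <- array(comp$labels, d)
  air_ids <- which(comp$touches_boundary == 1L)

  # which components intersect the filled interior
  inside <- labarr[filled]
  inside_counts <- tabulate(inside[inside > 0L], nbins = K0)

  is_air <- seq_len(K0) %in% air_ids
  is_cand <- !is_air & inside_counts > 0L
  big_enough <- comp$counts * voxel_cm3 >= min_volume_cm3
  keep <- which(is_cand & big_enough)
  n_speck <- sum(is_cand & !big_enough)

  # decreasing volume order, ties by smallest linear index
  keep <- keep[order(-comp$counts[keep], comp$min_index[keep])]
  relab <- integer(K0 + 1L)
  relab[keep + 1L] <- seq_along(keep)
  labels_out <- array(relab[comp$labels + 1L], d)

  if (mode == "2d-stacked") {
    cav <- labels_out > 0L
    conn2d <- if (connectivity == 6) 6L else 26L  # in-plane 4- or 8-conn
    lab2 <- array(0L, d)
    off <- 0L
    for (k in seq_len(d[3])) {
      sl <- cpp_label_components(as.logical(cav[, , k]),
                                 c(d[1], d[2], 1L), conn2d)
      if (sl$n > 0L) {
        page <- array(sl$labels, c(d[1], d[2]))
        page[page > 0L] <- page[page > 0L] + off
        lab2[, , k] <- page
        off <- off + sl$n
      }
    }
    labels_out <- lab2
    keep_counts <- as.numeric(tabulate(labels_out[labels_out > 0L],
                                       nbins = off))
    n_cav <- off
  } else {
    keep_counts <- comp$counts[keep]
    n_cav <- length(keep)
  }

  air_vox <- sum(comp$counts[air_ids])
  cav_vox <- sum(keep_counts)
  wheel_vox <- sum(wheel$mask)
  total <- prod(d)

  structure(list(labels = labels_out,
                 n_cavities = as.integer(n_cav),
                 connectivity_used = as.integer(connectivity),
                 spacing = mask$spacing,
                 mode = mode,
                 meta = mask$meta),
            class = "label_map",
            cavity_voxels = keep_counts,
            external_air_voxels = air_vox,
            wheel_voxels = wheel_vox,
            discarded_voxels = total - air_vox - cav_vox - wheel_vox,
            discarded_components = n_speck)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s, %d cavities, connectivity %d (%s mode)\n",
              paste(dim(x$labels), collapse = " x "), x$n_cavities,
              x$connectivity_used, x$mode))
  invisible(x)
}

# ---- brute-force oracle ----------------------------------------------------

.oracle_offsets <- function(connectivity, in_plane_only = FALSE) {
  g <- expand.grid(ox = -1:1, oy = -1:1, oz = if (in_plane_only) 0L else -1:1)
  m <- abs(g$ox) + abs(g$oy) + abs(g$oz)
  keep <- m > 0 & switch(as.character(connectivity),
                         "6" = m <= 1, "18" = m <= 2, "26" = m <= 3)
  as.matrix(g[keep, , drop = FALSE])
}

.oracle_flood <- function(mask, connectivity) {
  # plain breadth-first flood fill over TRUE voxels, written independently
  # of the compiled labeling path
  d <- dim(mask)
  offs <- .oracle_offsets(connectivity)
  lab <- array(0L, d)
  K <- 0L
  counts <- integer(0)
  touches <- logical(0)
  minidx <- integer(0)
  idx_true <- which(mask)
  for (s in idx_true) {
    if (lab[s] != 0L) next
    K <- K + 1L
    lab[s] <- K
    q <- integer(256L)
    q[1L] <- s
    qh <- 1L
    qt <- 1L
    cnt <- 0L
    touch <- FALSE
    while (qh <= qt) {
      v <- q[qh]
      qh <- qh + 1L
      cnt <- cnt + 1L
      z <- (v - 1L) %/% (d[1] * d[2])
      r <- (v - 1L) %% (d[1] * d[2])
      y <- r %/% d[1]
      x <- r %% d[1]
      if (x == 0L || y == 0L || z == 0L ||
          x == d[1] - 1L || y == d[2] - 1L || z == d[3] - 1L) touch <- TRUE
      for (j in seq_len(nrow(offs))) {
        xx <- x + offs[j, 1]; yy <- y + offs[j, 2]; zz <- z + offs[j, 3]
        if (xx < 0 || yy < 0 || zz < 0 ||
            xx >= d[1] || yy >= d[2] || zz >= d[3]) next
        w <- zz * d[1] * d[2] + yy * d[1] + xx + 1L
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- K
          qt <- qt + 1L
          if (qt > length(q)) q <- c(q, integer(length(q)))
          q[qt] <- w
        }
      }
    }
    counts <- c(counts, cnt)
    touches <- c(touches, touch)
    minidx <- c(minidx, s)
  }
  list(labels = lab, n = K, counts = counts, touches_boundary = touches,
       min_index = minidx)
}

#' Brute-force cavity labeling oracle
#'
#' Reference implementation of [label_cavities()] using a plain R
#' breadth-first flood fill, restricted to volumes of at most 32^3 voxels.
#' Used in tests to verify that the compiled labeling path produces an
#' identical cavity partition (up to label renumbering).
#'
#' @inheritParams label_cavities
#' @param wheel Optional wheel mask; if `NULL` the oracle derives it as the
#'   largest cheese-phase component by its own flood fill.
#' @return A `label_map` with the same semantics as [label_cavities()].
#' @export
labeling_oracle <- function(mask, wheel = NULL, connectivity = 6,
                            min_volume_cm3 = 0.01) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$mask)
  if (any(d > 32L))
    stop("labeling_oracle refuses volumes larger than 32^3 voxels",
         call. = FALSE)
  voxel_cm3 <- prod(mask$spacing) / 1000

  if (is.null(wheel)) {
    ch <- .oracle_flood(mask$mask, 26)
    if (ch$n == 0L)
      stop("no wheel found: mask contains no cheese voxels", call. = FALSE)
    best <- which(ch$counts == max(ch$counts))
    best <- best[which.min(ch$min_index[best])]
    wheel_mask <- ch$labels == best
  } else {
    wheel_mask <- wheel$mask
  }

  wfl <- .oracle_flood(!wheel_mask, connectivity)
  filled <- array(TRUE, d)
  for (k in which(wfl$touches_boundary)) filled[wfl$labels == k] <- FALSE

  fl <- .oracle_flood(!mask$mask, connectivity)
  keep <- integer(0)
  for (k in seq_len(fl$n)) {
    if (fl$touches_boundary[k]) next
    vox <- fl$labels == k
    if (!any(vox & filled)) next
    if (fl$counts[k] * voxel_cm3 < min_volume_cm3) next
    keep <- c(keep, k)
  }
  keep <- keep[order(-fl$counts[keep], fl$min_index[keep])]
  out <- array(0L, d)
  for (i in seq_along(keep)) out[fl$labels == keep[i]] <- i

  structure(list(labels = out, n_cavities = length(keep),
                 connectivity_used = as.integer(connectivity),
                 spacing = mask$spacing, mode = "3d", meta = mask$meta),
            class = "label_map",
            cavity_voxels = fl$counts[keep],
            external_air_voxels = sum(fl$counts[fl$touches_boundary]),
            wheel_voxels = sum(wheel_mask),
            discarded_voxels = prod(d) - sum(fl$counts[fl$touches_boundary]) -
              sum(fl$counts[keep]) - sum(wheel_mask),
            discarded_components = NA_integer_)
}
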
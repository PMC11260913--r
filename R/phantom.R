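#' Specification of a synthetic cheese-wheel phantom
#'
#' Describes a cylindrical wheel of uniform cheese density surrounded by
#' air, optionally wrapped in a thin wax shell, containing air-filled
#' spherical eyes (optionally coalescing) and thin planar crack voids. The
#' phantom is rasterized by a voxel-center membership test, forward-modeled
#' to stored CT numbers via [density_to_ctn()], and optionally degraded
#' with additive white Gaussian density noise, so that every stage of the
#' analysis pipeline can be validated against analytic ground truth.
#'
#' Defaults: wheel density 1150 kg/m3 (mid typical cheese range), air
#' background 1.2 kg/m3, voxel spacing 1 x 1 x 1.25 mm, wheel radius
#' 165 mm and height 120 mm (configurable; realistic for a semi-hard
#' wheel), no wax, no noise.
#'
#' @param wheel_radius_mm,wheel_height_mm Wheel cylinder dimensions (mm).
#' @param wheel_density,background_density Densities in kg/m3 (>= 0).
#' @param spacing Voxel spacing in mm.
#' @param n_eyes Number of spherical eyes to place.
#' @param eye_radius Radius model: `list(dist = "uniform", min, max)` or
#'   `list(dist = "lognormal", meanlog, sdlog)` (mm).
#' @param allow_overlap If `FALSE` (default) eyes are placed with rejection
#'   sampling so that no two overlap.
#' @param eye_centers,eye_radii Optional explicit placement (matrix of mm
#'   coordinates / vector of mm radii) overriding random placement.
#' @param n_cracks Number of planar crack voids.
#' @param crack_extent_mm Length-2 in-plane extents of each crack (mm).
#' @param crack_thickness_mm Crack thickness (mm, > 0).
#' @param wax_thickness_mm,wax_density Optional wax shell (mm, kg/m3).
#' @param noise_sd Additive white Gaussian density noise sigma (kg/m3).
#' @param offset Stored-CT-number offset for the forward model.
#' @param air_margin_vox Air margin around the wheel, in voxels (>= 2).
#' @param cheese_id,batch_id,age_days Metadata stamped on the volume.
#' @param seed Optional RNG seed; a fixed seed makes the phantom
#'   bit-reproducible.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(wheel_radius_mm = 165, wheel_height_mm = 120,
                         wheel_density = 1150, background_density = 1.2,
                         spacing = c(1, 1, 1.25),
                         n_eyes = 50,
                         eye_radius = list(dist = "uniform", min = 2, max = 12),
                         allow_overlap = FALSE,
                         eye_centers = NULL, eye_radii = NULL,
                         n_cracks = 0, crack_extent_mm = c(40, 30),
                         crack_thickness_mm = 1.25,
                         wax_thickness_mm = 0, wax_density = 930,
                         noise_sd = 0, offset = 1024,
                         air_margin_vox = 3,
                         cheese_id = "phantom", batch_id = "P1",
                         age_days = 0L, seed = NULL) {
  if (wheel_radius_mm <= 0 || wheel_height_mm <= 0)
    stop("wheel dimensions must be positive", call. = FALSE)
  if (wheel_density < 0 || background_density < 0 || wax_density < 0)
    stop("densities must be nonnegative", call. = FALSE)
  if (air_margin_vox < 2)
    stop("air margin must be at least 2 voxels", call. = FALSE)
  if (n_cracks > 0 && crack_thickness_mm <= 0)
    stop("crack thickness must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(
    wheel_radius_mm = wheel_radius_mm, wheel_height_mm = wheel_height_mm,
    wheel_density = wheel_density, background_density = background_density,
    spacing = as.numeric(spacing), n_eyes = as.integer(n_eyes),
    eye_radius = eye_radius, allow_overlap = isTRUE(allow_overlap),
    eye_centers = eye_centers, eye_radii = eye_radii,
    n_cracks = as.integer(n_cracks), crack_extent_mm = crack_extent_mm,
    crack_thickness_mm = crack_thickness_mm,
    wax_thickness_mm = wax_thickness_mm, wax_density = wax_density,
    noise_sd = noise_sd, offset = offset,
    air_margin_vox = as.integer(air_margin_vox),
    cheese_id = cheese_id, batch_id = batch_id,
    age_days = as.integer(age_days), seed = seed),
    class = "phantom_spec")
}

.phantom_grid <- function(spec) {
  sp <- spec$spacing
  rt <- spec$wheel_radius_mm + spec$wax_thickness_mm
  nx <- as.integer(ceiling(2 * rt / sp[1])) + 2L * spec$air_margin_vox + 1L
  ny <- as.integer(ceiling(2 * rt / sp[2])) + 2L * spec$air_margin_vox + 1L
  nz <- as.integer(ceiling((spec$wheel_height_mm + 2 * spec$wax_thickness_mm) /
                             sp[3])) + 2L * spec$air_margin_vox + 1L
  cx <- (nx - 1) * sp[1] / 2
  cy <- (ny - 1) * sp[2] / 2
  zlo <- (nz - 1) * sp[3] / 2 - spec$wheel_height_mm / 2
  list(dim = c(nx, ny, nz), cx = cx, cy = cy,
       zlo = zlo, zhi = zlo + spec$wheel_height_mm)
}

.draw_radii <- function(spec, n) {
  er <- spec$eye_radius
  r <- switch(er$dist,
              uniform = stats::runif(n, er$min, er$max),
              lognormal = stats::rlnorm(n, er$meanlog, er$sdlog),
              stop("unknown eye radius distribution: ", er$dist,
                   call. = FALSE))
  if (any(r >= spec$wheel_radius_mm))
    stop("eye radii must be smaller than the wheel radius", call. = FALSE)
  r
}

#' Place spherical eyes inside the wheel
#'
#' Samples eye centers uniformly in the wheel interior with full
#' containment (center at least one voxel plus the eye radius away from
#' the wheel surface). When overlap is disallowed, rejection sampling
#' enforces pairwise non-overlap with a one-voxel guard band (so that
#' rasterized spheres remain disconnected) and a budget of `10 * n_eyes` attempts
#' per eye; exhausting the budget is a placement error suggesting fewer or
#' smaller eyes. Uses the current RNG stream.
#'
#' @param spec A [phantom_spec()].
#' @return Data frame with columns `cx_mm, cy_mm, cz_mm, r_mm`.
#' @export
place_eyes <- function(spec) {
  g <- .phantom_grid(spec)
  marg <- max(spec$spacing)
  n <- spec$n_eyes
  if (!is.null(spec$eye_centers)) {
    cent <- as.matrix(spec$eye_centers)
    r <- spec$eye_radii
    stopifnot(nrow(cent) == length(r))
    return(data.frame(cx_mm = cent[, 1], cy_mm = cent[, 2],
                      cz_mm = cent[, 3], r_mm = r))
  }
  if (n == 0L)
    return(data.frame(cx_mm = numeric(0), cy_mm = numeric(0),
                      cz_mm = numeric(0), r_mm = numeric(0)))
  r <- if (!is.null(spec$eye_radii)) spec$eye_radii else .draw_radii(spec, n)
  r <- sort(r, decreasing = TRUE)  # place large eyes first
  cent <- matrix(NA_real_, n, 3)
  budget <- 10L * n
  for (i in seq_len(n)) {
    rmax <- spec$wheel_radius_mm - r[i] - marg
    z0 <- g$zlo + r[i] + marg
    z1 <- g$zhi - r[i] - marg
    if (rmax <= 0 || z1 <= z0)
      stop("placement error: eye of radius ", signif(r[i], 3),
           " mm cannot fit inside the wheel; use smaller radii",
           call. = FALSE)
    ok <- FALSE
    for (a in seq_len(budget)) {
      rad <- rmax * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      p <- c(g$cx + rad * cos(th), g$cy + rad * sin(th),
             stats::runif(1, z0, z1))
      if (!spec$allow_overlap && i > 1L) {
        # one-voxel guard band: analytically disjoint spheres must also
        # stay disconnected after rasterization
        dd <- sqrt(colSums((t(cent[seq_len(i - 1L), , drop = FALSE]) - p)^2))
        if (any(dd <= r[seq_len(i - 1L)] + r[i] + marg)) next
      }
      cent[i, ] <- p
      ok <- TRUE
      break
    }
    if (!ok)
      stop("placement error: could not fit ", n,
           " non-overlapping eyes in ", budget,
           " attempts per eye; use fewer or smaller eyes", call. = FALSE)
  }
  data.frame(cx_mm = cent[, 1], cy_mm = cent[, 2], cz_mm = cent[, 3],
             r_mm = r)
}

#' Insert a planar crack void
#'
#' Samples a thin rectangular slab with random orientation through the
#' wheel interior (all eight slab corners inside the wheel with a one-voxel
#' margin). Returns the slab center, half-extents and orientation matrix.
#' Uses the current RNG stream.
#'
#' @param spec A [phantom_spec()].
#' @return List with `center` (mm), `half` (half-extents mm, length 3) and
#'   `rot` (3x3 orientation matrix, columns = slab axes).
#' @export
insert_crack <- function(spec) {
  if (spec$crack_thickness_mm <= 0)
    stop("crack thickness must be positive", call. = FALSE)
  g <- .phantom_grid(spec)
  marg <- max(spec$spacing)
  half <- c(spec$crack_extent_mm / 2, spec$crack_thickness_mm / 2)
  for (a in seq_len(200L)) {
    # random orientation: normal on the sphere + in-plane angle
    nvec <- stats::rnorm(3)
    nvec <- nvec / sqrt(sum(nvec^2))
    ref <- if (abs(nvec[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * nvec) * nvec
    u <- u / sqrt(sum(u^2))
    v <- c(nvec[2] * u[3] - nvec[3] * u[2],
           nvec[3] * u[1] - nvec[1] * u[3],
           nvec[1] * u[2] - nvec[2] * u[1])
    phi <- stats::runif(1, 0, 2 * pi)
    e1 <- cos(phi) * u + sin(phi) * v
    e2 <- -sin(phi) * u + cos(phi) * v
    rot <- cbind(e1, e2, nvec)
    rad <- (spec$wheel_radius_mm / 2) * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    ctr <- c(g$cx + rad * cos(th), g$cy + rad * sin(th),
             stats::runif(1, g$zlo + spec$wheel_height_mm / 4,
                          g$zhi - spec$wheel_height_mm / 4))
    corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) *
      rep(half, each = 8)
    pts <- t(rot %*% t(corners)) + rep(ctr, each = 8)
    rad_ok <- all(sqrt((pts[, 1] - g$cx)^2 + (pts[, 2] - g$cy)^2) <=
                    spec$wheel_radius_mm - marg)
    z_ok <- all(pts[, 3] >= g$zlo + marg & pts[, 3] <= g$zhi - marg)
    if (rad_ok && z_ok)
      return(list(center = ctr, half = half, rot = rot))
  }
  stop("placement error: crack of extents ",
       paste(signif(2 * half, 3), collapse = " x "),
       " mm does not fit inside the wheel", call. = FALSE)
}

# oriented-box / oriented-box intersection by the separating axis theorem
.obb_intersect <- function(c1, h1, r1, c2, h2, r2) {
  axes <- cbind(r1, r2)
  for (i in 1:3) for (j in 1:3) {
    a <- r1[, i]; b <- r2[, j]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    axes <- cbind(axes, cr)
  }
  d <- c2 - c1
  for (k in seq_len(ncol(axes))) {
    L <- axes[, k]
    nl <- sqrt(sum(L^2))
    if (nl < 1e-9) next
    L <- L / nl
    ra <- sum(h1 * abs(as.numeric(t(r1) %*% L)))
    rb <- sum(h2 * abs(as.numeric(t(r2) %*% L)))
    if (abs(sum(d * L)) > ra + rb) return(FALSE)
  }
  TRUE
}

# distance from a point to an oriented box surface (0 if inside)
.point_obb_dist <- function(p, ctr, half, rot) {
  u <- as.numeric(t(rot) %*% (p - ctr))
  dv <- pmax(abs(u) - half, 0)
  sqrt(sum(dv^2))
}

.merge_groups <- function(features, crack_frames) {
  n <- nrow(features)
  if (n == 0L) return(list(groups = integer(0), n_components = 0L))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  overlap <- function(i, j) {
    ci <- features$class[i]; cj <- features$class[j]
    pi_ <- c(features$cx_mm[i], features$cy_mm[i], features$cz_mm[i])
    pj <- c(features$cx_mm[j], features$cy_mm[j], features$cz_mm[j])
    if (ci == "sphere" && cj == "sphere") {
      sqrt(sum((pi_ - pj)^2)) < features$r_mm[i] + features$r_mm[j]
    } else if (ci == "sphere" && cj == "crack") {
      fr <- crack_frames[[features$frame[j]]]
      .point_obb_dist(pi_, fr$center, fr$half, fr$rot) < features$r_mm[i]
    } else if (ci == "crack" && cj == "sphere") {
      overlap(j, i)
    } else {
      fi <- crack_frames[[features$frame[i]]]
      fj <- crack_frames[[features$frame[j]]]
      .obb_intersect(fi$center, fi$half, fi$rot, fj$center, fj$half, fj$rot)
    }
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (overlap(i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  groups <- match(roots, unique(roots))
  list(groups = groups, n_components = length(unique(groups)))
}

#' Generate a synthetic cheese-wheel CT volume with ground truth
#'
#' Rasterizes the wheel, wax shell, eyes and cracks described by a
#' [phantom_spec()] (voxel membership by center-point test), converts the
#' density field to stored CT numbers, adds Gaussian density noise if
#' requested, and quantizes to integers. The returned ground truth records
#' every inserted feature with its analytic volume and the expected number
#' of connected cavity components after merging overlapping features
#' (computed by sphere/box overlap analysis). Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [scan_volume()]) and `truth` (list:
#'   `features` data frame, `crack_frames`, `merge_groups`,
#'   `expected_components`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
    set.seed(spec$seed)
  }
  g <- .phantom_grid(spec)
  sp <- spec$spacing
  d <- g$dim

  eyes <- place_eyes(spec)
  crack_frames <- list()
  if (spec$n_cracks > 0L)
    crack_frames <- lapply(seq_len(spec$n_cracks),
                           function(i) insert_crack(spec))

  features <- data.frame(
    id = seq_len(nrow(eyes) + length(crack_frames)),
    class = c(rep("sphere", nrow(eyes)), rep("crack", length(crack_frames))),
    cx_mm = c(eyes$cx_mm, vapply(crack_frames, function(f) f$center[1], 1)),
    cy_mm = c(eyes$cy_mm, vapply(crack_frames, function(f) f$center[2], 1)),
    cz_mm = c(eyes$cz_mm, vapply(crack_frames, function(f) f$center[3], 1)),
    r_mm = c(eyes$r_mm, rep(NA_real_, length(crack_frames))),
    frame = c(rep(NA_integer_, nrow(eyes)), seq_along(crack_frames)),
    volume_cm3 = c(4 / 3 * pi * eyes$r_mm^3 / 1000,
                   vapply(crack_frames,
                          function(f) prod(2 * f$half) / 1000, 1)),
    roundness_class = c(rep("~1", nrow(eyes)),
                        rep("<0.6", length(crack_frames))),
    stringsAsFactors = FALSE)

  mg <- .merge_groups(features, crack_frames)

  # rasterize
  x <- (seq_len(d[1]) - 1L) * sp[1]
  y <- (seq_len(d[2]) - 1L) * sp[2]
  z <- (seq_len(d[3]) - 1L) * sp[3]
  r2 <- outer((x - g$cx)^2, (y - g$cy)^2, "+")
  in_wheel <- r2 <= spec$wheel_radius_mm^2
  wax <- spec$wax_thickness_mm
  in_wax <- r2 <= (spec$wheel_radius_mm + wax)^2
  eps <- 1e-9

  rho <- array(spec$background_density, d)
  bgsl <- matrix(spec$background_density, d[1], d[2])
  for (k in seq_len(d[3])) {
    sl <- bgsl
    if (wax > 0 && z[k] >= g$zlo - wax - eps && z[k] <= g$zhi + wax + eps)
      sl[in_wax] <- spec$wax_density
    if (z[k] >= g$zlo - eps && z[k] <= g$zhi + eps)
      sl[in_wheel] <- spec$wheel_density
    rho[, , k] <- sl
  }

  for (i in seq_len(nrow(eyes))) {
    ix <- which(abs(x - eyes$cx_mm[i]) <= eyes$r_mm[i])
    iy <- which(abs(y - eyes$cy_mm[i]) <= eyes$r_mm[i])
    iz <- which(abs(z - eyes$cz_mm[i]) <= eyes$r_mm[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (x[ix] - eyes$cx_mm[i])^2
    dy2 <- (y[iy] - eyes$cy_mm[i])^2
    dz2 <- (z[iz] - eyes$cz_mm[i])^2
    dist2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sub <- rho[ix, iy, iz, drop = FALSE]
    sub[dist2 <= eyes$r_mm[i]^2] <- spec$background_density
    rho[ix, iy, iz] <- sub
  }

  for (f in crack_frames) {
    ext <- sqrt(sum(f$half^2))
    ix <- which(abs(x - f$center[1]) <= ext + sp[1])
    iy <- which(abs(y - f$center[2]) <= ext + sp[2])
    iz <- which(abs(z - f$center[3]) <= ext + sp[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    grid <- as.matrix(expand.grid(x[ix], y[iy], z[iz]))
    u <- (grid - rep(f$center, each = nrow(grid))) %*% f$rot
    inside <- abs(u[, 1]) <= f$half[1] & abs(u[, 2]) <= f$half[2] &
      abs(u[, 3]) <= f$half[3]
    if (any(inside)) {
      sub <- rho[ix, iy, iz, drop = FALSE]
      sub[inside] <- spec$background_density
      rho[ix, iy, iz] <- sub
    }
  }

  if (spec$noise_sd > 0)
    rho <- rho + stats::rnorm(length(rho), 0, spec$noise_sd)

  ctn <- array(as.integer(round(density_to_ctn(rho, spec$offset))), d)
  vol <- scan_volume(ctn, sp,
                     scan_meta(cheese_id = spec$cheese_id,
                               batch_id = spec$batch_id,
                               age_days = spec$age_days,
                               source = "phantom"))
  list(volume = vol,
       truth = list(features = features, crack_frames = crack_frames,
                    merge_groups = mg$groups,
                    expected_components = mg$n_components,
                    grid = g))
}

#' Generate young and mature phantom cohorts
#'
#' Two cohorts of wheel phantoms whose eye-size distributions differ: the
#' young cohort emulates an early ripening stage with small eyes, the
#' mature cohort a late stage with larger eyes (eye volume grows with the
#' cube of the radius). The per-wheel eye count is drawn from a Poisson
#' distribution with the same mean in both cohorts, so eye counts carry
#' sampling variation but no group effect. Used for end-to-end ANOVA
#' power and null checks.
#'
#' @param n_per_group Number of wheels per cohort (>= 2).
#' @param young,mature Named lists of [phantom_spec()] overrides for each
#'   cohort; defaults give eye radii U(2, 5) mm (young, 44 days) and
#'   U(4, 10) mm (mature, 170 days).
#' @param base Baseline [phantom_spec()] overrides shared by both cohorts;
#'   the default uses a reduced wheel (radius 60 mm, height 60 mm, mean 20
#'   eyes) to keep simulation volumes manageable.
#' @param seed RNG seed for the whole pair of cohorts.
#' @return List with elements `young` and `mature`, each a list of
#'   [generate_phantom()] results.
#' @export
young_mature_cohorts <- function(n_per_group = 10,
                                 young = list(eye_radius = list(
                                   dist = "uniform", min = 2, max = 5),
                                   age_days = 44L),
                                 mature = list(eye_radius = list(
                                   dist = "uniform", min = 4, max = 10),
                                   age_days = 170L),
                                 base = list(wheel_radius_mm = 60,
                                             wheel_height_mm = 60,
                                             n_eyes = 20),
                                 seed = 1) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  set.seed(seed)
  make <- function(params, stage, i) {
    args <- utils::modifyList(base, params)
    args$cheese_id <- sprintf("%s-%02d", stage, i)
    args$batch_id <- sprintf("B%d", (i - 1L) %% 3L + 1L)
    args$n_eyes <- max(1L, stats::rpois(1, args$n_eyes %||% 20))
    args$seed <- sample.int(.Machine$integer.max, 1)
    generate_phantom(do.call(phantom_spec, args))
  }
  list(young = lapply(seq_len(n_per_group), function(i)
         make(young, "young", i)),
       mature = lapply(seq_len(n_per_group), function(i)
         make(mature, "mature", i)))
}
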
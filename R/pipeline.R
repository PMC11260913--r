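#' Pipeline configuration
#'
#' Bundles every tunable analysis parameter with its default: density
#' threshold 850 kg/m3, stored-CT-number offset 1024, cavity-phase
#' connectivity 6, minimum cavity volume 0.01 cm3, 3D labeling mode,
#' sphericity roundness with 1.25 mm normal smoothing, crack cutoffs
#' (roundness < 0.4 and volume > 1 cm3), and alpha 0.05. The resolved
#' configuration is serialized into every report for provenance.
#'
#' @param threshold Density threshold in kg/m3.
#' @param offset Stored-CT-number offset.
#' @param connectivity Cavity/air-phase connectivity (6, 18 or 26).
#' @param min_volume_cm3 Minimum cavity volume kept.
#' @param mode Labeling mode, `"3d"` or `"2d-stacked"`.
#' @param sigma_mm Surface-normal smoothing scale (mm).
#' @param crack_roundness_cutoff,crack_volume_cutoff_cm3 Crack flag rule.
#' @param include_cracks Include crack-flagged cavities in eye summaries.
#' @param alpha Significance threshold for group comparisons.
#' @param seed Seed recorded for provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = 850, offset = 1024,
                            connectivity = 6, min_volume_cm3 = 0.01,
                            mode = c("3d", "2d-stacked"), sigma_mm = 1.25,
                            crack_roundness_cutoff = 0.4,
                            crack_volume_cutoff_cm3 = 1,
                            include_cracks = TRUE, alpha = 0.05,
                            seed = NULL) {
  mode <- match.arg(mode)
  structure(list(threshold = threshold, offset = offset,
                 connectivity = connectivity,
                 min_volume_cm3 = min_volume_cm3, mode = mode,
                 sigma_mm = sigma_mm,
                 crack_roundness_cutoff = crack_roundness_cutoff,
                 crack_volume_cutoff_cm3 = crack_volume_cutoff_cm3,
                 include_cracks = include_cracks, alpha = alpha,
                 seed = seed),
            class = "pipeline_config")
}

#' Analyze one CT scan of a cheese wheel
#'
#' Runs the full per-wheel pipeline: CT-number-to-density conversion,
#' density thresholding, wheel extraction, cavity labeling, per-cavity
#' morphometry, crack flagging, and the wheel summary. If `out_dir` is
#' given, writes `cavities.csv`, `summary.json` (embedding the resolved
#' configuration and package version) and two PNG montages: axial slices
#' with cavities outlined, and a quarter-section view (half-depth axial
#' cut beside a mid-plane vertical cut). Numeric outputs never depend on
#' the plotting step, and re-running on identical input and configuration
#' reproduces the CSV/JSON outputs byte for byte.
#'
#' @param x A [scan_volume()] or a path readable by [read_volume()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with `density`, `mask`, `wheel`, `labels`, `catalog` and
#'   `summary`.
#' @export
analyze_scan <- function(x, config = pipeline_config(), out_dir = NULL) {
  vol <- if (inherits(x, "scan_volume")) x else read_volume(x)
  dens <- density_volume(vol, offset = config$offset)
  mask <- threshold_volume(dens, threshold = config$threshold)
  wheel <- extract_wheel(mask)
  labels <- label_cavities(mask, wheel, connectivity = config$connectivity,
                           min_volume_cm3 = config$min_volume_cm3,
                           mode = config$mode)
  catalog <- measure_cavities(labels, sigma_mm = config$sigma_mm)
  catalog <- flag_cracks(catalog,
                         roundness_cutoff = config$crack_roundness_cutoff,
                         volume_cutoff_cm3 = config$crack_volume_cutoff_cm3)
  summary <- summarize_wheel(catalog,
                             wheel_voxel_count = attr(labels, "wheel_voxels"),
                             spacing = vol$spacing, meta = vol$meta,
                             include_cracks = config$include_cracks)
  res <- list(density = dens, mask = mask, wheel = wheel, labels = labels,
              catalog = catalog, summary = summary, config = config)
  if (!is.null(out_dir)) write_wheel_report(res, out_dir)
  res
}

#' Write per-wheel report files
#'
#' @param res Result of [analyze_scan()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_wheel_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- res$catalog[, setdiff(names(res$catalog), "slice_areas")]
  names(flat)[names(flat) == "volume_cm3"] <- "volume_cm3"
  utils::write.csv(flat, file.path(out_dir, "cavities.csv"),
                   row.names = FALSE)
  payload <- list(summary = as.list(res$summary),
                  accounting = list(
                    wheel_voxels = attr(res$labels, "wheel_voxels"),
                    external_air_voxels = attr(res$labels,
                                               "external_air_voxels"),
                    discarded_voxels = attr(res$labels, "discarded_voxels"),
                    discarded_components = attr(res$labels,
                                                "discarded_components")),
                  config = unclass(res$config),
                  package_version =
                    as.character(utils::packageVersion("cheeseCT")))
  jsonlite::write_json(payload, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  try({
    montage_png(res, file.path(out_dir, "montage.png"))
    quarter_png(res, file.path(out_dir, "quarter.png"))
  }, silent = TRUE)
  invisible(out_dir)
}

#' Axial slice montage with cavity outlines
#'
#' Renders a grid of equally spaced axial density slices with the labeled
#' cavities outlined, for visual QC of the segmentation.
#'
#' @param res Result of [analyze_scan()].
#' @param file PNG path.
#' @param n_slices Number of slices shown.
#' @export
montage_png <- function(res, file, n_slices = 6) {
  d <- dim(res$density$rho)
  ks <- unique(round(seq(1, d[3], length.out = n_slices)))
  grDevices::png(file, width = 220 * length(ks), height = 240)
  op <- graphics::par(mfrow = c(1, length(ks)), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  for (k in ks) {
    graphics::image(res$density$rho[, , k], col = grDevices::gray.colors(64),
                    axes = FALSE, main = sprintf("slice %d", k - 1L))
    lab <- res$labels$labels[, , k]
    if (any(lab > 0L))
      graphics::contour(seq(0, 1, length.out = d[1]),
                        seq(0, 1, length.out = d[2]),
                        (lab > 0L) * 1, levels = 0.5, add = TRUE,
                        drawlabels = FALSE, col = "red")
  }
  invisible(file)
}

#' Quarter-section montage
#'
#' Two cuts rendered side by side: a half-depth axial cut and a mid-plane
#' vertical cut, emulating a virtual quarter-sectioned wheel.
#'
#' @inheritParams montage_png
#' @export
quarter_png <- function(res, file) {
  d <- dim(res$density$rho)
  grDevices::png(file, width = 700, height = 360)
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(res$density$rho[, , max(1L, d[3] %/% 2L)],
                  col = grDevices::gray.colors(64), axes = FALSE,
                  main = "half-depth axial cut")
  graphics::image(res$density$rho[, max(1L, d[2] %/% 2L), ],
                  col = grDevices::gray.colors(64), axes = FALSE,
                  main = "mid-plane vertical cut")
  invisible(file)
}

#' Analyze a batch of scans
#'
#' Runs [analyze_scan()] on each input path, isolating per-file failures:
#' a corrupt or unreadable input is logged and the run continues. Reports
#' are written to one subdirectory of `out_dir` per input.
#'
#' @param paths Character vector of volume paths.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A data frame with columns `path`, `ok`, `error`; the wheel
#'   summaries of the successful runs are in attribute `summaries`.
#' @export
analyze_scans <- function(paths, config = pipeline_config(),
                          out_dir = NULL) {
  status <- data.frame(path = paths, ok = FALSE, error = NA_character_,
                       stringsAsFactors = FALSE)
  summaries <- list()
  for (i in seq_along(paths)) {
    res <- tryCatch({
      sub <- if (is.null(out_dir)) NULL else
        file.path(out_dir, sprintf("wheel_%03d", i))
      analyze_scan(paths[i], config, out_dir = sub)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status$error[i] <- conditionMessage(res)
      message("analysis failed for ", paths[i], ": ",
              conditionMessage(res))
    } else {
      status$ok[i] <- TRUE
      summaries[[length(summaries) + 1L]] <- res$summary
    }
  }
  attr(status, "summaries") <- if (length(summaries))
    do.call(rbind, summaries) else NULL
  status
}
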
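# Interchange formats: TIFF frames with a JSON sidecar, CSV marker /
# outcome / profile tables.

#' Write an experiment bundle to disk
#'
#' Frames go to single-page float TIFF (counts), markers to CSV, and
#' timestamps/exposure/dose plus the generator truth to a JSON sidecar.
#' Requires the `tiff` package.
#'
#' @param bundle An `experiment_bundle` built with `keep_frames = TRUE`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(bundle, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for frame I/O")
  }
  if (is.null(bundle$frames)) stop("bundle holds no frames (keep_frames = FALSE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(bundle$frames)) {
    fr <- bundle$frames[[i]]
    tiff::writeTIFF(fr$counts / max(1, max(fr$counts)),
                    file.path(dir, sprintf("frame_%04d.tif", i)),
                    bits.per.sample = 32L)
    # scale factor recorded in the sidecar so counts round-trip
  }
  scales <- vapply(bundle$frames, function(fr) max(1, max(fr$counts)),
                   numeric(1L))
  utils::write.csv(bundle$ccd_markers, file.path(dir, "markers.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$sample_meta, file.path(dir, "sample_meta.csv"),
                   row.names = FALSE)
  sidecar <- list(
    phase = bundle$phase,
    time_s = bundle$schedule$time_s,
    tissue_strain_truth = bundle$schedule$tissue_strain,
    exposure_s = bundle$truth$exposure,
    dose_per_exposure_kgy = bundle$truth$dose_per_exposure,
    frame_scale = scales,
    truth = unclass(bundle$truth),
    geometry = unclass(bundle$geometry))
  jsonlite::write_json(sidecar, file.path(dir, "experiment.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an experiment bundle written by [write_experiment()]
#'
#' @param dir Directory containing `frame_*.tif`, `markers.csv`,
#'   `sample_meta.csv` and `experiment.json`.
#' @return An `experiment_bundle`.
#' @export
read_experiment <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for frame I/O")
  }
  sidecar <- jsonlite::read_json(file.path(dir, "experiment.json"),
                                 simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  truth <- do.call(tensile_truth, sidecar$truth[names(sidecar$truth) %in%
    names(formals(tensile_truth))])
  geometry <- do.call(xray_geometry, sidecar$geometry)
  frames <- lapply(seq_along(files), function(i) {
    counts <- tiff::readTIFF(files[i]) * sidecar$frame_scale[i]
    detector_frame(round(counts), time_s = sidecar$time_s[i],
                   exposure_s = sidecar$exposure_s,
                   dose_kgy = sidecar$dose_per_exposure_kgy)
  })
  markers <- utils::read.csv(file.path(dir, "markers.csv"))
  meta <- utils::read.csv(file.path(dir, "sample_meta.csv"))
  sched <- list(n = length(frames), time_s = sidecar$time_s,
                tissue_strain = sidecar$tissue_strain_truth)
  structure(list(frames = frames, ccd_markers = markers, sample_meta = meta,
                 truth = truth, geometry = geometry, phase = sidecar$phase,
                 schedule = sched),
            class = "experiment_bundle")
}

#' Write a paired strain series to CSV
#'
#' Columns: `sample_id`, `time_s`, `tissue_strain`, `material_strain`,
#' `phase`.
#' @param paired A `paired_strain_series`.
#' @param path Output CSV path.
#' @export
write_paired_csv <- function(paired, path) {
  utils::write.csv(as.data.frame(paired), path, row.names = FALSE)
  invisible(path)
}

#' Write a Table-2-style slope table to CSV
#'
#' One row per (group, phase) slope fit: labels, slope, SE, point and
#' sample counts, R^2.
#' @param fits List of `slope_fit` objects.
#' @param path Output CSV path.
#' @export
write_slope_table <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    g <- f$group
    data.frame(age = if (is.null(g)) NA else g[["age"]],
               sex = if (is.null(g)) NA else g[["sex"]],
               genotype = if (is.null(g)) NA else g[["genotype"]],
               phase = if (is.null(f$phase)) NA else f$phase,
               slope = f$slope, se = f$se,
               n_points = f$n_points, n_samples = f$n_samples,
               r2 = f$r2)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
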
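# End-to-end pipeline: calibrant -> geometry -> per-frame reduction ->
# strain series -> tissue-strain pairing -> pooled group regression.

#' Default SAXS camera geometry (collagen regime)
#'
#' Long camera (4 m) placing the collagen 67 nm first-order reflection at a
#' usable radius on a Pilatus-class detector at 10 keV.
#' @param ... Overrides passed to [xray_geometry()].
#' @export
saxs_geometry <- function(...) {
  xray_geometry(sample_detector_distance_mm = 4000, ...)
}

#' Default WAXD camera geometry (mineral regime)
#'
#' Short camera (250 mm) placing the apatite (002) reflection (3.44 A) on
#' the detector at 10 keV.
#' @param ... Overrides passed to [xray_geometry()].
#' @export
waxd_geometry <- function(...) {
  xray_geometry(sample_detector_distance_mm = 250, ...)
}

#' Calibrate geometry from a calibrant frame
#'
#' Beam-center search followed by distance calibration against a known
#' d-spacing (silver behenate 001 by default).
#'
#' @param cal_frame Calibrant [detector_frame()].
#' @param wavelength_A Wavelength, Angstrom.
#' @param known_d Calibrant d-spacing, Angstrom.
#' @param initial_center Starting guess for the center; default frame
#'   midpoint.
#' @param pixel_size_um Pixel pitch, um.
#' @param expected_distance_mm Optional prior camera length for the annulus
#'   search.
#' @return A calibrated [xray_geometry()].
#' @export
calibrate_geometry <- function(cal_frame, wavelength_A, known_d = 58.380,
                               initial_center = NULL, pixel_size_um = 172,
                               expected_distance_mm = NULL) {
  center <- find_beam_center(cal_frame, initial_guess = initial_center)
  calibrate_distance(cal_frame, center, wavelength_A, known_d = known_d,
                     pixel_size_um = pixel_size_um,
                     expected_distance_mm = expected_distance_mm)
}

# default fit window for a phase: wide enough to hold the moving peak
phase_fit_window <- function(d0, sigma_q, max_strain = 0.02) {
  q0 <- q_from_d(d0)
  half <- q0 * max_strain + 6 * sigma_q
  c(q0 - half, q0 + half)
}

#' Reduce one tensile experiment to a paired strain series
#'
#' Runs the per-frame analysis for a single specimen: radial integration in
#' a sector about the tensile axis, Bragg-peak fitting, conversion to a
#' material strain series against the pre-load reference, tissue strain
#' from the CCD marker table, and time matching.  Frames can come from a
#' stored bundle or be generated on the fly (memory-light streaming) when
#' the bundle was built with `keep_frames = FALSE`.
#'
#' @param bundle An `experiment_bundle`.
#' @param geometry Calibrated [xray_geometry()]; defaults to the bundle's
#'   generating geometry.
#' @param chi_halfwidth Integration sector half-width about the tensile
#'   axis, degrees.
#' @param n_bins Radial bin count (default 800 for collagen SAXS, 1200 for
#'   mineral WAXD).
#' @param window Peak fit window; default derived from the phase's d0.
#' @return A `paired_strain_series` (see [time_match()]); attributes carry
#'   the per-frame `peaks` and the `strain_series`.
#' @export
reduce_experiment <- function(bundle, geometry = NULL, chi_halfwidth = 20,
                              n_bins = NULL, window = NULL) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  truth <- bundle$truth
  if (is.null(geometry)) geometry <- bundle$geometry
  phase <- bundle$phase
  d0 <- if (phase == "collagen") truth$d0_collagen else truth$d0_mineral
  sig <- if (phase == "collagen") truth$ring_width_collagen else
    truth$ring_width_mineral
  if (is.null(n_bins)) n_bins <- if (phase == "collagen") 800L else 1200L
  if (is.null(window)) window <- phase_fit_window(d0, sig)
  sched <- bundle$schedule
  peaks <- vector("list", sched$n)
  for (i in seq_len(sched$n)) {
    fr <- if (!is.null(bundle$frames)) {
      bundle$frames[[i]]
    } else {
      simulate_tensile_frame(truth, bundle$geometry, phase, i, sched)
    }
    prof <- integrate_radial(fr, geometry,
                             chi_range = c(-chi_halfwidth, chi_halfwidth),
                             mirror = TRUE, n_bins = n_bins,
                             q_range = c(max(0, window[1L] - 2 * sig),
                                         window[2L] + 2 * sig))
    peaks[[i]] <- fit_peak(prof, window = window)
  }
  mat <- strain_series(peaks, sched$time_s, phase = phase,
                       reference = first_n_preload(truth$n_preload))
  tis <- tissue_strain_from_markers(
    bundle$ccd_markers,
    reference_time_max = (truth$n_preload - 1) * truth$frame_interval)
  paired <- time_match(mat, tis, sample_id = bundle$sample_meta$sample_id)
  attr(paired, "peaks") <- peaks
  attr(paired, "strain_series") <- mat
  paired
}

#' Simulate and analyse a whole group, recovering its strain slope
#'
#' Full synthetic pipeline for one group and phase: for each specimen a
#' tensile experiment is generated with the programmed ground-truth slope,
#' the detector geometry is re-derived from a simulated silver behenate
#' calibrant (beam-center search + distance fit), every frame is reduced
#' and peak-fitted, material strains are time-matched to the CCD tissue
#' strain, and the pooled scatter is fitted by OLS.
#'
#' @param truth A [tensile_truth()]; its `seed` field seeds sample 1 and
#'   successive samples increment it.
#' @param geometry True camera geometry used to generate frames; defaults
#'   to [saxs_geometry()] / [waxd_geometry()] by phase.
#' @param phase `"collagen"` or `"mineral"`.
#' @param n_samples Specimens per group.
#' @param group Group labels.
#' @param calibrate Re-derive the geometry from a synthetic calibrant
#'   (`TRUE`, the full pipeline) or reuse the generating geometry.
#' @return List with `fit` (a [fit_group_slope()] result), `points` (the
#'   pooled `paired_strain_series`), `geometry_used`, `truth`.
#' @export
recover_group_slope <- function(truth, geometry = NULL,
                                phase = c("collagen", "mineral"),
                                n_samples = 3L,
                                group = c(age = "4mo", sex = "M",
                                          genotype = "Ctrl"),
                                calibrate = TRUE) {
  phase <- match.arg(phase)
  if (is.null(geometry)) {
    geometry <- if (phase == "collagen") saxs_geometry() else waxd_geometry()
  }
  geom_used <- geometry
  if (calibrate) {
    cal <- simulate_calibrant_frame(geometry, seed = truth$seed + 900001L)
    guess <- geometry$beam_center_xy + c(3, -2)  # deliberately off
    geom_used <- calibrate_geometry(
      cal, wavelength_A = geometry$wavelength_A,
      initial_center = guess,
      pixel_size_um = geometry$pixel_size_um,
      # nominal camera length is always known to the experimenter; it keeps
      # the ring search away from calibrant harmonics
      expected_distance_mm = geometry$sample_detector_distance_mm)
  }
  pooled <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    tr <- truth
    tr$seed <- truth$seed + (s - 1L) * 10000L
    bundle <- simulate_tensile_experiment(tr, geometry, phase = phase,
                                          sample_id = sprintf("S%d", s),
                                          group = group,
                                          keep_frames = FALSE)
    pooled[[s]] <- reduce_experiment(bundle, geometry = geom_used)
  }
  points <- do.call(rbind, lapply(pooled, as.data.frame))
  class(points) <- c("paired_strain_series", "data.frame")
  fit <- fit_group_slope(points, group = group, phase = phase)
  list(fit = fit, points = points, geometry_used = geom_used, truth = truth)
}
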
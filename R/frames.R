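# Detector frames and the synthetic scattering-frame generator.
#
# The generator emulates the in situ tensile protocol: 0.5 s exposures every
# 5 s at 10 keV, frame count capped by a 30 kGy cumulative dose budget.
# Rings are Gaussian in q with Poisson counting noise; azimuthal anisotropy
# follows I(chi) ~ exp(kappa * cos 2*chi), with kappa solved so the ring's
# intensity-weighted second Legendre coefficient hits the requested P2.

#' Detector frame container
#'
#' A single exposure: a photon-count matrix plus acquisition metadata.
#'
#' @param counts Numeric matrix of photon counts (non-negative).
#' @param time_s Acquisition timestamp (s, start of exposure).
#' @param exposure_s Exposure time (s).
#' @param dose_kgy Dose delivered by this exposure (kGy).
#' @param meta Optional list of extra metadata (e.g. generator truth).
#' @return Object of class `detector_frame`.
#' @export
detector_frame <- function(counts, time_s = 0, exposure_s = 0.5,
                           dose_kgy = 0, meta = list()) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  structure(list(counts = counts, time_s = time_s, exposure_s = exposure_s,
                 dose_kgy = dose_kgy, meta = meta),
            class = "detector_frame")
}

#' @export
print.detector_frame <- function(x, ...) {
  cat(sprintf("<detector_frame> %d x %d px, t = %.1f s, %.2g total counts\n",
              nrow(x$counts), ncol(x$counts), x$time_s, sum(x$counts)))
  invisible(x)
}

# P2 of the azimuthal model I(chi) ~ exp(kappa cos 2 chi), by the same
# sin-weighted (fiber symmetry) quadrature that p2_orientation applies
p2_of_kappa <- function(kappa) {
  chi <- seq(-pi, pi, length.out = 4001L)[-1L]
  w <- exp(kappa * cos(2 * chi)) * abs(sin(chi))
  sum(w * (3 * cos(chi)^2 - 1) / 2) / sum(w)
}

# solve kappa so that the ring azimuthal profile has the requested P2
kappa_for_p2 <- function(p2) {
  if (p2 <= -0.5 || p2 >= 1) stop("target P2 must lie in (-0.5, 1)")
  if (abs(p2) < 1e-12) return(0)
  lim <- 60
  lo <- p2_of_kappa(-lim)
  hi <- p2_of_kappa(lim)
  if (p2 <= lo || p2 >= hi) {
    stop("requested P2 too extreme for the exp(kappa cos 2 chi) model")
  }
  stats::uniroot(function(k) p2_of_kappa(k) - p2,
                 lower = -lim, upper = lim, tol = 1e-10)$root
}

# Expected (noise-free) intensity for a set of rings on geometry `g`.
# rings: data.frame(d_A, amplitude, sigma_q, kappa); background: counts/px.
expected_ring_frame <- function(geometry, rings, background) {
  maps <- pixel_maps(geometry)
  mu <- matrix(background, nrow = geometry$detector_shape[1L],
               ncol = geometry$detector_shape[2L])
  if (nrow(rings) == 0L) return(mu)
  qmax <- max(maps$q)
  for (i in seq_len(nrow(rings))) {
    q0 <- q_of_d(rings$d_A[i])
    if (q0 > qmax) {
      stop(sprintf("ring for d = %.4g A falls beyond the detector (q = %.4g)",
                   rings$d_A[i], q0))
    }
    sig <- rings$sigma_q[i]
    sel <- which(abs(maps$q - q0) < 5 * sig)
    if (length(sel) == 0L) next
    radial <- rings$amplitude[i] * exp(-(maps$q[sel] - q0)^2 / (2 * sig^2))
    k <- rings$kappa[i]
    if (is.finite(k) && abs(k) > 0) {
      # normalise so the azimuthal mean modulation is 1
      az <- exp(k * cos(2 * maps$chi[sel] * pi / 180)) /
        besselI(abs(k), 0, expon.scaled = FALSE)
      radial <- radial * az
    }
    mu[sel] <- mu[sel] + radial
  }
  mu
}

# silver behenate 001 harmonics that land on the detector
agbe_rings_on_detector <- function(geometry, d001 = 58.380, max_order = 10L) {
  d <- d001 / seq_len(max_order)
  qmax <- q_max_on_detector(geometry)
  d[q_of_d(d) < 0.95 * qmax]
}

#' Simulate a calibrant (silver behenate) frame
#'
#' Generates azimuthally uniform Gaussian-in-q rings at the requested
#' d-spacings with Poisson counting noise, for exercising beam-center search
#' and distance calibration.  With `ring_d = NULL`, the silver behenate 001
#' reflection (58.380 A) and whichever harmonics land on the detector are
#' used.
#'
#' @param geometry An [xray_geometry()].
#' @param ring_d d-spacings (Angstrom) of the rings, or `NULL` for silver
#'   behenate defaults.  An explicitly requested ring that falls beyond the
#'   detector is an error; an empty vector yields a pure-background frame.
#' @param seed Integer RNG seed; identical seeds give identical frames.
#' @param amplitude Peak ring intensity, counts/pixel.
#' @param background Flat background, counts/pixel.
#' @param width_frac Gaussian ring sigma as a fraction of the ring q.
#' @return A [detector_frame()] whose `meta` records the generating truth.
#' @export
simulate_calibrant_frame <- function(geometry, ring_d = NULL, seed = 1L,
                                     amplitude = 500, background = 5,
                                     width_frac = 0.01) {
  if (is.null(ring_d)) ring_d <- agbe_rings_on_detector(geometry)
  if (length(ring_d) > 0 && any(ring_d <= 0)) stop("ring_d must be positive")
  rings <- if (length(ring_d) > 0) {
    data.frame(d_A = as.numeric(ring_d),
               amplitude = amplitude,
               sigma_q = width_frac * q_of_d(as.numeric(ring_d)),
               kappa = 0)
  } else {
    data.frame(d_A = numeric(0), amplitude = numeric(0),
               sigma_q = numeric(0), kappa = numeric(0))
  }
  mu <- expected_ring_frame(geometry, rings, background)
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
  detector_frame(counts, time_s = 0, exposure_s = 0.5, dose_kgy = 0,
                 meta = list(kind = "calibrant", ring_d = ring_d,
                             geometry = geometry, seed = seed))
}

#' Ground-truth parameters for a synthetic tensile experiment
#'
#' Describes the tensile protocol and the material response used by
#' [simulate_tensile_experiment()]: exposure cadence (0.5 s every 5 s),
#' per-exposure dose against the 30 kGy budget, linear material-to-tissue
#' strain coupling for the collagen (67 nm first order) and mineral
#' (apatite (002), 3.44 A) reflections, and a linear P2 orientation ramp.
#'
#' @param slope_collagen,slope_mineral Material-vs-tissue strain coupling
#'   slopes (dimensionless, in `[0, 1.5]`).
#' @param tissue_strain_rate Bulk strain rate, 1/s.
#' @param d0_collagen,d0_mineral Unloaded d-spacings, Angstrom.
#' @param p2_initial Initial orientation parameter, in `(-0.5, 1)`.
#' @param p2_rate Change in P2 per unit tissue strain.
#' @param frame_interval,exposure Frame cadence and exposure time, s
#'   (exposure must be shorter than the interval).
#' @param dose_per_exposure Dose per exposure, kGy (> 0).
#' @param dose_cap Total dose budget, kGy.
#' @param noise_level Flat detector background, expected counts/pixel.
#' @param amplitude Peak ring intensity, counts/pixel.
#' @param ring_width_collagen,ring_width_mineral Gaussian ring sigma in q
#'   (1/Angstrom) for each phase.
#' @param strain_noise_sd Per-frame multiplicative d-spacing jitter
#'   (sample heterogeneity / beam pointing), as strain s.d.
#' @param d0_sd_frac Inter-specimen fractional scatter of the unloaded
#'   d-spacing (biological variability); drawn once per sample.
#' @param failure_strain Tissue strain at specimen failure.
#' @param n_preload Number of unloaded frames recorded before the ramp.
#' @param ccd_hz Sampling rate of the CCD marker camera, Hz.
#' @param seed Integer RNG seed.
#' @return Object of class `tensile_truth`.
#' @export
tensile_truth <- function(slope_collagen = 0.7482,
                          slope_mineral = 0.3561,
                          tissue_strain_rate = 2.8e-5,
                          d0_collagen = 670,
                          d0_mineral = 3.44,
                          p2_initial = 0.35,
                          p2_rate = 2,
                          frame_interval = 5,
                          exposure = 0.5,
                          dose_per_exposure = 0.5,
                          dose_cap = 30,
                          noise_level = 5,
                          amplitude = 100,
                          ring_width_collagen = 6e-4,
                          ring_width_mineral = 1.2e-2,
                          strain_noise_sd = 2e-4,
                          d0_sd_frac = 0.003,
                          failure_strain = 0.008,
                          n_preload = 3L,
                          ccd_hz = 1,
                          seed = 1L) {
  if (slope_collagen < 0 || slope_collagen > 1.5 ||
      slope_mineral < 0 || slope_mineral > 1.5) {
    stop("strain slopes must lie in [0, 1.5]")
  }
  if (p2_initial <= -0.5 || p2_initial >= 1) {
    stop("p2_initial must lie in (-0.5, 1)")
  }
  if (exposure >= frame_interval) stop("exposure must be < frame_interval")
  if (dose_per_exposure <= 0) stop("dose_per_exposure must be > 0")
  if (tissue_strain_rate <= 0) stop("tissue_strain_rate must be > 0")
  if (failure_strain <= 0) stop("failure_strain must be > 0")
  structure(
    list(slope_collagen = slope_collagen, slope_mineral = slope_mineral,
         tissue_strain_rate = tissue_strain_rate,
         d0_collagen = d0_collagen, d0_mineral = d0_mineral,
         p2_initial = p2_initial, p2_rate = p2_rate,
         frame_interval = frame_interval, exposure = exposure,
         dose_per_exposure = dose_per_exposure, dose_cap = dose_cap,
         noise_level = noise_level, amplitude = amplitude,
         ring_width_collagen = ring_width_collagen,
         ring_width_mineral = ring_width_mineral,
         strain_noise_sd = strain_noise_sd,
         d0_sd_frac = d0_sd_frac,
         failure_strain = failure_strain,
         n_preload = as.integer(n_preload), ccd_hz = ccd_hz,
         seed = as.integer(seed)),
    class = "tensile_truth"
  )
}

# frame timetable for a truth: times, tissue strain, frame count after the
# dose cap.  Loading starts right after the n_preload-th frame.
tensile_schedule <- function(truth) {
  ramp_frames <- ceiling(truth$failure_strain /
                           (truth$tissue_strain_rate * truth$frame_interval))
  n_total <- truth$n_preload + ramp_frames
  n_cap <- floor(truth$dose_cap / truth$dose_per_exposure)
  n <- as.integer(min(n_total, n_cap))
  t <- (seq_len(n) - 1) * truth$frame_interval
  t_start <- (truth$n_preload - 1) * truth$frame_interval
  eps <- truth$tissue_strain_rate * pmax(0, t - t_start)
  list(n = n, time_s = t, tissue_strain = eps, t_start = t_start)
}

# per-sample unloaded d-spacing factor (biological variability), seeded
sample_d0_factor <- function(truth) {
  if (truth$d0_sd_frac <= 0) return(1)
  set.seed(truth$seed + 424243L)
  1 + stats::rnorm(1L, 0, truth$d0_sd_frac)
}

# ring placed at frame i for one phase, with seeded heterogeneity jitter
frame_ring_truth <- function(truth, phase, eps, jitter, d0_factor = 1) {
  if (phase == "collagen") {
    d0 <- truth$d0_collagen; slope <- truth$slope_collagen
    sig <- truth$ring_width_collagen
  } else {
    d0 <- truth$d0_mineral; slope <- truth$slope_mineral
    sig <- truth$ring_width_mineral
  }
  d <- d0 * d0_factor * (1 + slope * eps) * (1 + jitter)
  list(d = d, sigma_q = sig)
}

# simulate the i-th frame of a tensile run (deterministic in truth$seed + i)
simulate_tensile_frame <- function(truth, geometry, phase, i,
                                   schedule = tensile_schedule(truth)) {
  d0f <- sample_d0_factor(truth)
  set.seed(truth$seed + i)
  eps <- schedule$tissue_strain[i]
  jitter <- stats::rnorm(1L, 0, truth$strain_noise_sd)
  ring <- frame_ring_truth(truth, phase, eps, jitter, d0f)
  p2_t <- min(0.999, max(-0.499, truth$p2_initial + truth$p2_rate * eps))
  kappa <- kappa_for_p2(p2_t)
  rings <- data.frame(d_A = ring$d, amplitude = truth$amplitude,
                      sigma_q = ring$sigma_q, kappa = kappa)
  mu <- expected_ring_frame(geometry, rings, truth$noise_level)
  counts <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
  detector_frame(counts, time_s = schedule$time_s[i],
                 exposure_s = truth$exposure,
                 dose_kgy = truth$dose_per_exposure,
                 meta = list(kind = "tensile", phase = phase,
                             tissue_strain = eps, d_true = ring$d,
                             p2_true = p2_t, frame_index = i))
}

# CCD marker table encoding the tissue strain ramp exactly: two markers on
# the tensile axis whose separation is gauge_px * (1 + eps(t))
tensile_marker_table <- function(truth, t_end, gauge_px = 400,
                                 center_xy = c(500, 300)) {
  t <- seq(0, t_end, by = 1 / truth$ccd_hz)
  t_start <- (truth$n_preload - 1) * truth$frame_interval
  eps <- truth$tissue_strain_rate * pmax(0, t - t_start)
  half <- gauge_px / 2 * (1 + eps)
  data.frame(
    time_s = rep(t, 2L),
    marker_id = rep(c(1L, 2L), each = length(t)),
    x_px = c(center_xy[1L] - half, center_xy[1L] + half),
    y_px = rep(center_xy[2L], 2L * length(t))
  )
}

#' Simulate a complete in situ tensile scattering experiment
#'
#' Produces everything the analysis pipeline consumes for one specimen and
#' one material phase: a sequence of detector frames (one ring whose
#' d-spacing tracks the programmed material strain and whose azimuthal
#' anisotropy tracks the programmed P2 ramp), a CCD marker table encoding
#' the tissue-strain ramp exactly, and sample metadata.  The frame count is
#' capped by the dose budget (`floor(dose_cap / dose_per_exposure)`).
#'
#' @param truth A [tensile_truth()].
#' @param geometry An [xray_geometry()] appropriate for the phase (long
#'   camera for collagen SAXS, short for mineral WAXD).
#' @param phase `"collagen"` or `"mineral"`.
#' @param sample_id Sample label.
#' @param group Named character vector of group labels (age, sex, genotype).
#' @param keep_frames If `FALSE`, frames are not retained in the bundle
#'   (use [simulate_tensile_frame()]-driven streaming analysis instead).
#' @return Object of class `experiment_bundle` with fields `frames`,
#'   `ccd_markers`, `sample_meta`, `truth`, `geometry`, `phase`,
#'   `schedule`.
#' @export
simulate_tensile_experiment <- function(truth, geometry,
                                        phase = c("collagen", "mineral"),
                                        sample_id = "S1",
                                        group = c(age = "4mo", sex = "M",
                                                  genotype = "Ctrl"),
                                        keep_frames = TRUE) {
  phase <- match.arg(phase)
  stopifnot(inherits(truth, "tensile_truth"), inherits(geometry, "xray_geometry"))
  sched <- tensile_schedule(truth)
  frames <- NULL
  if (keep_frames) {
    frames <- lapply(seq_len(sched$n), function(i) {
      simulate_tensile_frame(truth, geometry, phase, i, sched)
    })
  }
  markers <- tensile_marker_table(truth, t_end = max(sched$time_s))
  meta <- data.frame(sample_id = sample_id,
                     age = group[["age"]], sex = group[["sex"]],
                     genotype = group[["genotype"]],
                     slipped = FALSE, depotted = FALSE,
                     fracture_site = "diaphyseal",
                     cumulative_dose_kgy = sched$n * truth$dose_per_exposure,
                     stringsAsFactors = FALSE)
  structure(list(frames = frames, ccd_markers = markers, sample_meta = meta,
                 truth = truth, geometry = geometry, phase = phase,
                 schedule = sched),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> %s, phase %s: %d frames, %.0f s, %.1f kGy\n",
              x$sample_meta$sample_id, x$phase, x$schedule$n,
              max(x$schedule$time_s),
              x$schedule$n * x$truth$dose_per_exposure))
  invisible(x)
}
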
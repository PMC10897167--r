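# Detector geometry and pixel -> (q, chi) mapping.
#
# Conventions: frames are count matrices indexed [row, col] with the origin at
# the top-left pixel; beam_center_xy is 0-based (x = column, y = row).
# Azimuth chi is measured in degrees from the detector +x axis (the tensile
# axis unless reconfigured), range [-180, 180).  Exact 2-theta geometry is
# used throughout -- no small-angle approximation -- so the same code serves
# the SAXS (collagen, ~67 nm) and WAXD (apatite (002), ~3.44 A) regimes.

#' X-ray photon energy to wavelength
#'
#' Converts photon energy to wavelength via `lambda = 12.39842 / E`
#' (hc = 12.39842 keV A).
#'
#' @param energy_kev Photon energy in keV; must be positive.
#' @return Wavelength in Angstrom.
#' @examples
#' energy_to_wavelength(10)       # 1.239842 A
#' energy_to_wavelength(12.39842) # 1 A
#' @export
energy_to_wavelength <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(!is.finite(energy_kev)) ||
      any(energy_kev <= 0)) {
    stop("'energy_kev' must be a positive finite number")
  }
  12.39842 / energy_kev
}

#' Detector geometry descriptor
#'
#' Bundles the constants needed to map detector pixels to scattering vectors:
#' beam center, sample-detector distance, wavelength, pixel pitch and frame
#' shape.  Defaults describe a Pilatus-class hybrid photon counting detector
#' (1475 x 1679 pixels of 172 um).
#'
#' @param beam_center_xy Beam center as `c(x, y)` in 0-based pixel
#'   coordinates (x = column, y = row).  Default: frame midpoint.
#' @param sample_detector_distance_mm Sample-to-detector distance in mm.
#' @param wavelength_A Wavelength in Angstrom.
#' @param pixel_size_um Square pixel pitch in micrometres.
#' @param detector_shape Frame dimensions `c(nrow, ncol)` in pixels.
#' @return An object of class `xray_geometry`.
#' @examples
#' g <- xray_geometry(sample_detector_distance_mm = 4000,
#'                    wavelength_A = energy_to_wavelength(10))
#' @export
xray_geometry <- function(beam_center_xy = NULL,
                          sample_detector_distance_mm = 4000,
                          wavelength_A = energy_to_wavelength(10),
                          pixel_size_um = 172,
                          detector_shape = c(1679L, 1475L)) {
  detector_shape <- as.integer(detector_shape)
  if (length(detector_shape) != 2L || any(detector_shape < 2L)) {
    stop("'detector_shape' must be c(nrow, ncol) with both >= 2")
  }
  if (is.null(beam_center_xy)) {
    beam_center_xy <- c((detector_shape[2L] - 1) / 2,
                        (detector_shape[1L] - 1) / 2)
  }
  if (sample_detector_distance_mm <= 0) stop("distance must be > 0")
  if (wavelength_A <= 0) stop("wavelength must be > 0")
  if (pixel_size_um <= 0) stop("pixel size must be > 0")
  # allow the center slightly off-frame (common for offset SAXS setups)
  margin <- 0.5 * max(detector_shape)
  if (beam_center_xy[1L] < -margin ||
      beam_center_xy[1L] > detector_shape[2L] - 1 + margin ||
      beam_center_xy[2L] < -margin ||
      beam_center_xy[2L] > detector_shape[1L] - 1 + margin) {
    stop("beam center is far outside the detector frame")
  }
  structure(
    list(beam_center_xy = as.numeric(beam_center_xy),
         sample_detector_distance_mm = as.numeric(sample_detector_distance_mm),
         wavelength_A = as.numeric(wavelength_A),
         pixel_size_um = as.numeric(pixel_size_um),
         detector_shape = detector_shape),
    class = "xray_geometry"
  )
}

#' @export
print.xray_geometry <- function(x, ...) {
  cat("<xray_geometry>\n",
      sprintf("  detector: %d x %d px, %.0f um pitch\n",
              x$detector_shape[1L], x$detector_shape[2L], x$pixel_size_um),
      sprintf("  beam center (x, y): (%.2f, %.2f) px\n",
              x$beam_center_xy[1L], x$beam_center_xy[2L]),
      sprintf("  distance: %.1f mm, wavelength: %.5f A\n",
              x$sample_detector_distance_mm, x$wavelength_A), sep = "")
  invisible(x)
}

# q (A^-1) for a radial distance r in mm at geometry g; exact 2-theta.
q_of_r_mm <- function(r_mm, geometry) {
  two_theta <- atan2(r_mm, geometry$sample_detector_distance_mm)
  (4 * pi / geometry$wavelength_A) * sin(two_theta / 2)
}

# inverse: radius in mm at which scattering vector q lands on the detector
r_mm_of_q <- function(q, geometry) {
  s <- q * geometry$wavelength_A / (4 * pi)
  if (any(s >= 1)) stop("q outside the accessible range for this wavelength")
  geometry$sample_detector_distance_mm * tan(2 * asin(s))
}

# Bragg: scattering vector of a d-spacing ring
q_of_d <- function(d_A) 2 * pi / d_A

# --- cached per-geometry pixel maps -----------------------------------------

.matstrain_cache <- new.env(parent = emptyenv())

geometry_key <- function(geometry) {
  paste(format(c(geometry$beam_center_xy,
                 geometry$sample_detector_distance_mm,
                 geometry$wavelength_A, geometry$pixel_size_um,
                 geometry$detector_shape), digits = 12), collapse = "|")
}

# per-pixel q (A^-1), chi (deg, [-180, 180)) and r (mm) maps, memoised
pixel_maps <- function(geometry) {
  key <- geometry_key(geometry)
  hit <- .matstrain_cache[[key]]
  if (!is.null(hit)) return(hit)
  nr <- geometry$detector_shape[1L]
  nc <- geometry$detector_shape[2L]
  px_mm <- geometry$pixel_size_um / 1000
  # pixel centers, 0-based coordinates
  dy <- (seq_len(nr) - 1) - geometry$beam_center_xy[2L]
  dx <- (seq_len(nc) - 1) - geometry$beam_center_xy[1L]
  dxm <- matrix(dx, nrow = nr, ncol = nc, byrow = TRUE)
  dym <- matrix(dy, nrow = nr, ncol = nc)
  r_mm <- sqrt(dxm^2 + dym^2) * px_mm
  chi <- atan2(dym, dxm) * 180 / pi
  chi[chi >= 180] <- chi[chi >= 180] - 360
  maps <- list(q = q_of_r_mm(r_mm, geometry), chi = chi, r_mm = r_mm)
  # keep the cache small: maps for a full 2M-pixel detector are ~60 MB
  if (length(ls(.matstrain_cache)) > 6L) {
    rm(list = ls(.matstrain_cache), envir = .matstrain_cache)
  }
  .matstrain_cache[[key]] <- maps
  maps
}

# largest q fully inside the detector along at least one direction
q_max_on_detector <- function(geometry) {
  m <- pixel_maps(geometry)
  max(m$q)
}
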
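# Calibration and 2-D -> 1-D reduction (cake integration).

#' Locate the beam center from ring scattering
#'
#' Finds the sub-pixel beam center that maximises ring sharpness: bright
#' pixels are radially histogrammed around a candidate center and the
#' concentration of the histogram (sum of squared bin mass) is maximised by
#' Nelder-Mead.  A misplaced center smears every ring over radius, so the
#' optimum is the circular center.
#'
#' @param frame A [detector_frame()] containing at least one ring.
#' @param initial_guess Starting center `c(x, y)` in 0-based pixels.
#' @param bright_quantile Quantile above which pixels count as ring signal.
#' @return Numeric `c(x, y)`, 0-based pixels.
#' @export
find_beam_center <- function(frame, initial_guess = NULL,
                             bright_quantile = 0.995) {
  counts <- frame$counts
  if (is.null(initial_guess)) {
    initial_guess <- c((ncol(counts) - 1) / 2, (nrow(counts) - 1) / 2)
  }
  # bright pixels: above the quantile AND clear of the Poisson background
  # tail (thin rings can cover far less than 1 - bright_quantile of pixels)
  m <- mean(counts)
  thr <- max(stats::quantile(counts, bright_quantile),
             m + 5 * sqrt(max(m, 1)))
  sel <- which(counts > thr)
  if (length(sel) < 20L) {
    stop("no ring detected: frame has no bright feature above background")
  }
  w <- as.numeric(counts[sel]) - thr
  row <- (sel - 1L) %% nrow(counts)        # 0-based y
  col <- (sel - 1L) %/% nrow(counts)       # 0-based x
  sharpness <- function(cxy) {
    r <- sqrt((col - cxy[1L])^2 + (row - cxy[2L])^2)
    b <- floor(r)                           # 1-px radial bins
    mass <- rowsum(w, b)
    -sum(mass^2)
  }
  fit <- stats::optim(initial_guess, sharpness, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  # polish with a finer objective (0.25-px bins) around the optimum
  sharp_fine <- function(cxy) {
    r <- sqrt((col - cxy[1L])^2 + (row - cxy[2L])^2)
    mass <- rowsum(w, floor(r * 4))
    -sum(mass^2)
  }
  fit2 <- stats::optim(fit$par, sharp_fine, method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 500))
  as.numeric(fit2$par)
}

# radial pixel profile (1-px bins) around a center; intensity mean per bin,
# abscissa = mean pixel radius per bin (unbiased for lumpy pixel sets)
radial_pixel_profile <- function(counts, center_xy, bin_px = 1) {
  nr <- nrow(counts); nc <- ncol(counts)
  dx <- (seq_len(nc) - 1) - center_xy[1L]
  dy <- (seq_len(nr) - 1) - center_xy[2L]
  r <- sqrt(outer(dy^2, dx^2, `+`))
  b <- as.vector(floor(r / bin_px))
  tot <- rowsum(as.numeric(counts), b)
  npx <- rowsum(rep(1, length(b)), b)
  rbar <- rowsum(as.vector(r), b) / npx
  data.frame(r_px = as.numeric(rbar), intensity = tot / npx,
             n_pixels = as.numeric(npx))
}

# Gaussian + linear background fit of the strongest peak in a (x, y) profile;
# returns the sub-bin center.  Used by distance calibration.
fit_profile_peak_center <- function(x, y, halfwidth = 12) {
  i0 <- which.max(y)
  sel <- which(x > x[i0] - halfwidth & x < x[i0] + halfwidth)
  if (length(sel) < 6L) stop("peak too close to the profile edge")
  xs <- x[sel]; ys <- y[sel]
  bg <- min(ys)
  start <- list(A = max(ys) - bg, mu = x[i0],
                sig = halfwidth / 4, b0 = bg)
  fit <- minpack.lm::nlsLM(
    ys ~ A * exp(-(xs - mu)^2 / (2 * sig^2)) + b0,
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  as.numeric(stats::coef(fit)[["mu"]])
}

#' Calibrate the sample-detector distance from a known ring
#'
#' Radially profiles the frame about the given center, fits the strongest
#' ring with a Gaussian, and solves `L = r / tan(2 theta)` with
#' `sin(theta) = lambda / (2 d)` for the known calibrant d-spacing
#' (silver behenate 001 = 58.380 A by convention).
#'
#' @param frame Calibrant [detector_frame()].
#' @param center Beam center `c(x, y)`, 0-based pixels.
#' @param wavelength_A Wavelength in Angstrom.
#' @param known_d Calibrant d-spacing in Angstrom.
#' @param pixel_size_um Pixel pitch (um).
#' @param expected_distance_mm Optional prior distance; when given, the ring
#'   is searched in an annulus around the predicted radius instead of taking
#'   the global maximum.
#' @return An [xray_geometry()] with the fitted distance.
#' @export
calibrate_distance <- function(frame, center, wavelength_A, known_d = 58.380,
                               pixel_size_um = 172,
                               expected_distance_mm = NULL) {
  if (known_d <= 0) stop("known_d must be positive")
  prof <- radial_pixel_profile(frame$counts, center)
  # drop the beamstop region and the far corners (incomplete rings)
  r_edge <- min(center[1L], ncol(frame$counts) - 1 - center[1L],
                center[2L], nrow(frame$counts) - 1 - center[2L])
  keep <- prof$r_px > 5 & prof$r_px <= r_edge
  prof <- prof[keep, , drop = FALSE]
  if (nrow(prof) < 10L) stop("profile too short to calibrate")
  s <- wavelength_A / (2 * known_d)
  if (s >= 1) stop("known_d is not accessible at this wavelength")
  two_theta <- 2 * asin(s)
  if (!is.null(expected_distance_mm)) {
    r_pred <- expected_distance_mm * tan(two_theta) / (pixel_size_um / 1000)
    ann <- prof$r_px > 0.8 * r_pred & prof$r_px < 1.2 * r_pred
    if (!any(ann)) stop("ring not found in the expected annulus")
    prof <- prof[ann, , drop = FALSE]
  }
  bg <- stats::median(prof$intensity)
  if (max(prof$intensity) < bg + 5 * sqrt(max(bg, 1))) {
    stop("ring not found: no clear peak in the radial profile")
  }
  r_px <- fit_profile_peak_center(prof$r_px, prof$intensity)
  r_mm <- r_px * pixel_size_um / 1000
  L <- r_mm / tan(two_theta)
  xray_geometry(beam_center_xy = center,
                sample_detector_distance_mm = L,
                wavelength_A = wavelength_A,
                pixel_size_um = pixel_size_um,
                detector_shape = dim(frame$counts))
}

# normalise a chi sector spec into [-180, 180) interval membership test
chi_in_sector <- function(chi, chi_range, mirror) {
  lo <- chi_range[1L]; hi <- chi_range[2L]
  inside <- chi >= lo & chi <= hi
  if (mirror) {
    op <- chi + 180
    op[op >= 180] <- op[op >= 180] - 360
    inside <- inside | (op >= lo & op <= hi)
  }
  inside
}

# memoised integration plan: pixel selection + q-bin assignment for a
# (geometry, chi sector, q grid) combination
radial_plan <- function(geometry, chi_range, mirror, n_bins, q_range) {
  key <- paste("radial", geometry_key(geometry),
               paste(format(c(chi_range, mirror, n_bins, q_range),
                            digits = 12), collapse = "|"))
  hit <- .matstrain_cache[[key]]
  if (!is.null(hit)) return(hit)
  maps <- pixel_maps(geometry)
  edges <- seq(q_range[1L], q_range[2L], length.out = n_bins + 1L)
  sel <- which(chi_in_sector(maps$chi, chi_range, mirror) &
                 maps$q >= q_range[1L] & maps$q < q_range[2L])
  bin <- findInterval(maps$q[sel], edges, rightmost.closed = TRUE)
  npx <- tabulate(bin, nbins = n_bins)
  # abscissa: mean pixel q per populated bin (bin midpoint where empty).
  # With bins comparable to or finer than a pixel, the bin midpoint is a
  # biased abscissa for the lumpy pixel set it holds; the pixel mean removes
  # that bias, which otherwise drifts systematically as a ring moves.
  q_mid <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  qbar <- q_mid
  agg <- rowsum(maps$q[sel], bin)
  pop <- as.integer(rownames(agg))
  qbar[pop] <- agg[, 1L] / npx[pop]
  plan <- list(sel = sel, bin = bin, n_pixels = npx, q_mid = qbar)
  .matstrain_cache[[key]] <- plan
  plan
}

#' Radial (cake) integration of a detector frame
#'
#' Maps every pixel to (q, chi) under the exact 2-theta geometry, selects the
#' azimuthal sector of interest (optionally with its mirror at chi + 180
#' degrees) and averages counts per linear q bin.  Bins without pixels carry
#' `NA` intensity and `n_pixels = 0`; total counts are conserved:
#' `sum(intensity * n_pixels)` equals the summed counts of the selected
#' pixels.
#'
#' @param frame A [detector_frame()].
#' @param geometry Calibrated [xray_geometry()].
#' @param chi_range Azimuth sector `c(lo, hi)` in degrees about the tensile
#'   axis (chi = 0).  Default +/- 20 degrees.
#' @param mirror Include the antipodal sector (chi + 180)?  Default `TRUE`.
#' @param n_bins Number of linear q bins (default 800, the SAXS convention;
#'   use ~1200 for WAXD windows).
#' @param q_range Bin range `c(q_lo, q_hi)` in 1/Angstrom; default spans the
#'   detector coverage.
#' @return Object of class `radial_profile`: data.frame with `q`,
#'   `intensity`, `n_pixels` and a `chi_range` attribute.
#' @export
integrate_radial <- function(frame, geometry, chi_range = c(-20, 20),
                             mirror = TRUE, n_bins = 800L, q_range = NULL) {
  if (length(chi_range) != 2L || chi_range[2L] <= chi_range[1L]) {
    stop("'chi_range' must be c(lo, hi) with lo < hi")
  }
  if (is.null(q_range)) q_range <- c(0, q_max_on_detector(geometry))
  if (q_range[2L] <= q_range[1L]) stop("'q_range' must be increasing")
  plan <- radial_plan(geometry, chi_range, mirror, as.integer(n_bins), q_range)
  vals <- as.numeric(frame$counts)[plan$sel]
  tot <- numeric(length(plan$q_mid))
  agg <- rowsum(vals, plan$bin)
  tot[as.integer(rownames(agg))] <- agg[, 1L]
  intensity <- ifelse(plan$n_pixels > 0, tot / pmax(plan$n_pixels, 1L), NA_real_)
  out <- data.frame(q = plan$q_mid, intensity = intensity,
                    n_pixels = plan$n_pixels)
  attr(out, "chi_range") <- chi_range
  attr(out, "mirror") <- mirror
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Azimuthal integration of a detector frame
#'
#' Averages counts per azimuth bin for pixels whose q falls inside a band,
#' producing the I(chi) profile that feeds the P2 orientation parameter.
#'
#' @param frame A [detector_frame()].
#' @param geometry Calibrated [xray_geometry()].
#' @param q_band `c(q_lo, q_hi)` in 1/Angstrom, strictly increasing and
#'   within detector coverage.
#' @param chi_bins Number of azimuth bins over `[-180, 180)`.
#' @return Object of class `azimuthal_profile`: data.frame with `chi`,
#'   `intensity`, `n_pixels` and a `q_band` attribute.
#' @export
integrate_azimuthal <- function(frame, geometry, q_band, chi_bins = 72L) {
  if (length(q_band) != 2L || q_band[2L] <= q_band[1L]) {
    stop("'q_band' must be c(q_lo, q_hi) with q_lo < q_hi")
  }
  maps <- pixel_maps(geometry)
  sel <- which(maps$q >= q_band[1L] & maps$q < q_band[2L])
  if (length(sel) == 0L) stop("q_band outside detector coverage")
  edges <- seq(-180, 180, length.out = chi_bins + 1L)
  bin <- findInterval(maps$chi[sel], edges, rightmost.closed = TRUE)
  vals <- as.numeric(frame$counts)[sel]
  npx <- tabulate(bin, nbins = chi_bins)
  tot <- numeric(chi_bins)
  agg <- rowsum(vals, bin)
  tot[as.integer(rownames(agg))] <- agg[, 1L]
  out <- data.frame(chi = (edges[-1L] + edges[-(chi_bins + 1L)]) / 2,
                    intensity = ifelse(npx > 0, tot / pmax(npx, 1L), NA_real_),
                    n_pixels = npx)
  attr(out, "q_band") <- q_band
  class(out) <- c("azimuthal_profile", "data.frame")
  out
}
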
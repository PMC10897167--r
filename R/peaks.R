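# Bragg peak fitting, d-spacing strain series and the P2 orientation
# parameter.

#' Fit a Bragg peak in a radial profile
#'
#' Nonlinear least-squares fit of a Gaussian or Lorentzian peak plus linear
#' background inside a q window.  A failed or implausible fit is reported
#' with `converged = FALSE` rather than an error, so a strain series can
#' carry missing frames explicitly.
#'
#' @param profile A `radial_profile` from [integrate_radial()].
#' @param window Fit window `c(q_lo, q_hi)` in 1/Angstrom; must intersect
#'   the profile and contain at least 8 populated bins.
#' @param model `"gaussian"` (default) or `"lorentzian"`.
#' @return Object of class `peak_fit`: list with `q_center`, `se`, `width`
#'   (Gaussian sigma or Lorentzian HWHM), `amplitude`, `background`
#'   (intercept, slope), `r2`, `converged`.
#' @export
fit_peak <- function(profile, window, model = c("gaussian", "lorentzian")) {
  model <- match.arg(model)
  if (length(window) != 2L || window[2L] <= window[1L]) {
    stop("'window' must be c(q_lo, q_hi) with q_lo < q_hi")
  }
  if (window[1L] > max(profile$q) || window[2L] < min(profile$q)) {
    stop("fit window lies outside the profile")
  }
  sel <- profile$q >= window[1L] & profile$q <= window[2L] &
    profile$n_pixels > 0 & is.finite(profile$intensity)
  if (sum(sel) < 8L) stop("fewer than 8 populated bins in the fit window")
  x <- profile$q[sel]
  y <- profile$intensity[sel]

  failed <- function() {
    structure(list(q_center = NA_real_, se = NA_real_, width = NA_real_,
                   amplitude = NA_real_, background = c(NA_real_, NA_real_),
                   r2 = NA_real_, converged = FALSE, model = model,
                   window = window),
              class = "peak_fit")
  }

  # fit in standardised abscissa coordinates: q windows are narrow relative
  # to their offset, which leaves the raw nls gradient ill-conditioned
  x0 <- mean(x)
  xs <- stats::sd(x)
  z <- (x - x0) / xs

  # initial values: background from the window edges, peak from the residual
  n_edge <- max(2L, floor(length(z) * 0.15))
  edge <- c(seq_len(n_edge), seq(length(z) - n_edge + 1L, length(z)))
  bgfit <- stats::lm(y[edge] ~ z[edge])
  b0 <- stats::coef(bgfit)[[1L]]; b1 <- stats::coef(bgfit)[[2L]]
  # zap numerically-zero starts: numericDeriv's relative step underflows on
  # coefficients of order 1e-15 and reports a spurious singular gradient
  tiny <- 1e-9 * max(stats::sd(y), 1e-12)
  if (abs(b0) < tiny) b0 <- 0
  if (abs(b1) < tiny) b1 <- 0
  resid0 <- y - (b0 + b1 * z)
  i0 <- which.max(resid0)
  amp0 <- resid0[i0]
  if (!is.finite(amp0) || amp0 <= 0) return(failed())
  # crude width from the half-maximum crossing of the residual
  above <- resid0 > amp0 / 2
  w0 <- max(diff(range(z[above])), diff(z)[1L] * 2) / 2.355
  start <- list(A = amp0, mu = z[i0], sig = w0, b0 = b0, b1 = b1)

  form <- if (model == "gaussian") {
    y ~ A * exp(-(z - mu)^2 / (2 * sig^2)) + b0 + b1 * z
  } else {
    y ~ A * sig^2 / ((z - mu)^2 + sig^2) + b0 + b1 * z
  }
  # unconstrained LM; implausible optima are rejected by the checks below
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  se_z <- tryCatch(sqrt(diag(stats::vcov(fit)))[["mu"]],
                   error = function(e) NA_real_)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  q_center <- x0 + xs * cf[["mu"]]
  ok <- is.finite(q_center) && q_center > window[1L] &&
    q_center < window[2L] && cf[["sig"]] > 0 && cf[["A"]] > 0 &&
    is.finite(se_z) && se_z > 0 &&
    # reject "peaks" indistinguishable from background noise
    cf[["A"]] > 3 * stats::sd(stats::resid(fit))
  if (!ok) return(failed())
  structure(list(q_center = q_center, se = xs * se_z,
                 width = xs * abs(cf[["sig"]]),
                 amplitude = cf[["A"]],
                 background = c(intercept = cf[["b0"]] -
                                  cf[["b1"]] * x0 / xs,
                                slope = cf[["b1"]] / xs),
                 r2 = r2, converged = TRUE, model = model, window = window),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<peak_fit> q = %.6g +/- %.2g 1/A (sigma %.3g, R2 %.4f)\n",
                x$q_center, x$se, x$width, x$r2))
  } else {
    cat("<peak_fit> not converged\n")
  }
  invisible(x)
}

#' Bragg d-spacing from a scattering vector
#'
#' `d = 2 pi / q`.
#'
#' @param q Scattering vector modulus, 1/Angstrom; must be positive.
#' @return d-spacing in Angstrom.
#' @export
d_from_q <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("'q' must be positive")
  2 * pi / q
}

#' Scattering vector of a d-spacing
#'
#' Inverse of [d_from_q()].
#' @param d d-spacing in Angstrom; positive.
#' @return q in 1/Angstrom.
#' @export
q_from_d <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("'d' must be positive")
  2 * pi / d
}

#' Reference policy: average the first n (pre-load) frames
#'
#' @param n Number of leading unloaded frames defining d0.
#' @return A reference-policy descriptor for [strain_series()].
#' @export
first_n_preload <- function(n = 3L) {
  if (n < 1L) stop("need at least one pre-load frame")
  structure(list(policy = "first_n_preload", n = as.integer(n)),
            class = "reference_policy")
}

#' Material strain series from per-frame peak fits
#'
#' Converts per-frame peak positions to d-spacings (`d = 2 pi / q`), sets the
#' unloaded reference `d0` as the mean d over the pre-load frames, and
#' reports the material strain `(d - d0) / d0` per frame.  Frames whose fit
#' did not converge carry `NA` -- they are never silently interpolated.
#'
#' @param peaks List of [fit_peak()] results, one per frame.
#' @param time_s Frame timestamps (s), same length.
#' @param phase `"collagen"` or `"mineral"`.
#' @param reference A [first_n_preload()] policy.
#' @return Object of class `strain_series`: data.frame with `time_s`,
#'   `material_strain`, `d_A`, plus attributes `d0`, `phase`,
#'   `reference_policy`.
#' @export
strain_series <- function(peaks, time_s, phase = c("collagen", "mineral"),
                          reference = first_n_preload(3L)) {
  phase <- match.arg(phase)
  if (length(peaks) != length(time_s)) {
    stop("'peaks' and 'time_s' lengths differ")
  }
  if (!inherits(reference, "reference_policy")) {
    stop("'reference' must come from first_n_preload()")
  }
  conv <- vapply(peaks, function(p) isTRUE(p$converged), logical(1L))
  d <- rep(NA_real_, length(peaks))
  d[conv] <- d_from_q(vapply(peaks[conv], `[[`, numeric(1L), "q_center"))
  n_ref <- min(reference$n, length(peaks))
  ref_idx <- seq_len(n_ref)
  ref_d <- d[ref_idx]
  if (all(is.na(ref_d))) stop("no converged pre-load frames to define d0")
  d0 <- mean(ref_d, na.rm = TRUE)
  out <- data.frame(time_s = time_s, material_strain = (d - d0) / d0,
                    d_A = d)
  attr(out, "d0") <- d0
  attr(out, "phase") <- phase
  attr(out, "reference_policy") <- reference
  class(out) <- c("strain_series", "data.frame")
  out
}

#' Second Legendre orientation parameter P2
#'
#' Intensity-weighted mean of the second Legendre polynomial of cos(chi)
#' over an azimuthal profile, with the fiber-symmetry solid-angle weight:
#' `P2 = sum(I |sin chi| (3 cos^2 chi - 1) / 2) / sum(I |sin chi|)`,
#' chi measured from the tensile axis (the Herman orientation average;
#' midpoint quadrature on the chi grid).  P2 = 1 for perfect axial
#' alignment, 0 for an isotropic distribution, -0.5 for transverse
#' alignment.
#'
#' @param profile An `azimuthal_profile` from [integrate_azimuthal()], or any
#'   data.frame with `chi` (degrees) and `intensity`.
#' @param axis_deg Tensile axis azimuth (degrees); chi is measured from it.
#' @return P2, a number in `[-0.5, 1]`.
#' @export
p2_orientation <- function(profile, axis_deg = 0) {
  ok <- is.finite(profile$intensity)
  chi <- profile$chi[ok]
  I <- profile$intensity[ok]
  if (length(chi) == 0L) stop("profile has no populated bins")
  if (diff(range(chi)) < 179) stop("profile must cover at least 180 degrees")
  if (any(I < 0)) stop("intensity must be non-negative")
  if (sum(I) <= 0) stop("all-zero intensity profile")
  rel <- (chi - axis_deg) * pi / 180
  if (length(rel) > 1L) {
    # treat I as piecewise constant per bin and integrate both
    # |sin chi| and P2(cos chi) |sin chi| in closed form over each bin, so
    # the quadrature is exact up to the binning of I itself
    mids <- (rel[-1L] + rel[-length(rel)]) / 2
    lo <- c(rel[1L] - (mids[1L] - rel[1L]), mids)
    hi <- c(mids, rel[length(rel)] +
              (rel[length(rel)] - mids[length(mids)]))
    G <- function(x) {           # antiderivative of |sin|, G(0) = 0, odd
      k <- floor(abs(x) / pi)
      sign(x) * (2 * k + 1 - cos(abs(x) - k * pi))
    }
    H <- function(x) {           # antiderivative of P2(cos)|sin|, odd;
      v <- abs(x) %% pi          # the integrand is pi-periodic, net 0/period
      sign(x) * (cos(v) - cos(v)^3) / 2
    }
    w <- I * (G(hi) - G(lo))
    num <- I * (H(hi) - H(lo))
    sw <- sum(w)
    if (sw <= 0) return(1)       # all intensity exactly on the axis
    sum(num) / sw
  } else {
    (3 * cos(rel)^2 - 1) / 2
  }
}

#' Slope of P2 against tissue strain
#'
#' Ordinary least-squares slope of the orientation parameter on tissue
#' strain, quantifying the (in)ability of collagen to realign under load.
#'
#' @param p2 Per-frame P2 values.
#' @param tissue_strain Matching tissue strains (same length, >= 3 finite
#'   pairs).
#' @return List with `slope`, `se`, `n`.
#' @export
delta_p2 <- function(p2, tissue_strain) {
  ok <- is.finite(p2) & is.finite(tissue_strain)
  if (sum(ok) < 3L) stop("need at least 3 paired points")
  f <- ols_line(tissue_strain[ok], p2[ok])
  list(slope = f$slope, se = f$slope_se, n = sum(ok))
}
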
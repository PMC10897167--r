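# Three-point-bend structural metrics and elliptical-section material
# properties.

#' Structural metrics of a three-point-bend load-displacement curve
#'
#' Extracts stiffness (steepest sliding-window linear fit below 50% of the
#' ultimate load), yield (0.2% span-offset method by default, or 10% secant
#' stiffness loss), ultimate force (peak load), the fracture point
#' (terminal load drop), postyield displacement and work to fracture
#' (trapezoidal area).
#'
#' The yield criterion is a package convention, selected because standard
#' offset practice transfers directly to span-normalized bending strain;
#' switch `yield_method = "secant"` for the 10% secant-stiffness-loss
#' alternative.
#'
#' @param curve Data frame with `displacement_mm` (nondecreasing) and
#'   `load_N`.
#' @param yield_method `"offset"` (default) or `"secant"`.
#' @param span_mm Support span (mm); scales the offset criterion.
#' @param offset_strain Offset as span-normalized strain (default 0.002).
#' @param window_frac Sliding-window width for the stiffness fit, as a
#'   fraction of the pre-yield points.
#' @return Object of class `bend_summary`: `stiffness_N_mm`, `yield_point`
#'   (`c(mm, N)`), `ultimate_force_N`, `fracture_point`,
#'   `postyield_disp_mm`, `work_to_fracture_Nmm`.
#' @export
bend_metrics <- function(curve, yield_method = c("offset", "secant"),
                         span_mm = 8, offset_strain = 0.002,
                         window_frac = 0.2) {
  yield_method <- match.arg(yield_method)
  d <- curve$displacement_mm
  f <- curve$load_N
  if (length(d) < 5L) stop("curve too short")
  if (any(diff(d) < -1e-9)) stop("displacement must be nondecreasing")
  ult_idx <- which.max(f)
  ult <- f[ult_idx]
  if (ult <= 0) stop("curve has no positive load")
  if (f[length(f)] >= 0.5 * ult) {
    stop("no fracture detected: curve ends without a terminal load drop")
  }

  # stiffness: steepest sliding-window OLS below 50% ultimate, pre-peak
  pre <- which(f <= 0.5 * ult & seq_along(f) <= ult_idx)
  pre <- pre[pre <= max(pre)]  # contiguous low-load region
  if (length(pre) < 3L) pre <- seq_len(max(3L, ult_idx - 1L))
  w <- max(3L, ceiling(window_frac * length(pre)))
  slopes <- vapply(seq_len(length(pre) - w + 1L), function(i) {
    idx <- pre[i:(i + w - 1L)]
    xs <- d[idx]; ys <- f[idx]
    sxx <- sum((xs - mean(xs))^2)
    if (sxx <= 0) return(NA_real_)
    sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
  }, numeric(1L))
  # smooth across neighbouring windows before taking the max: the maximum of
  # many noisy slope estimates is biased upward under load noise
  if (length(slopes) >= 15L) {
    sm <- stats::filter(slopes, rep(1 / 15, 15))
    if (any(is.finite(sm))) slopes <- sm
  }
  stiffness <- max(slopes, na.rm = TRUE)

  # fracture point: just before the load first collapses below 10% ultimate
  post <- seq(ult_idx, length(f))
  below <- post[f[post] < 0.1 * ult]
  frac_idx <- if (length(below)) max(ult_idx, below[1L] - 1L) else length(f)

  # yield point
  rising <- seq_len(frac_idx)
  if (yield_method == "offset") {
    off <- offset_strain * span_mm
    gap <- f[rising] - stiffness * (d[rising] - off)
    cross <- which(gap < 0 & d[rising] > off)
    if (length(cross)) {
      i <- cross[1L]
      if (i > 1L) {
        # linear interpolation of the crossing
        t <- gap[i - 1L] / (gap[i - 1L] - gap[i])
        d_y <- d[i - 1L] + t * (d[i] - d[i - 1L])
        f_y <- f[i - 1L] + t * (f[i] - f[i - 1L])
      } else {
        d_y <- d[i]; f_y <- f[i]
      }
    } else {
      # never crosses the offset line: brittle, yield at fracture
      d_y <- d[frac_idx]; f_y <- f[frac_idx]
    }
  } else {
    sec <- f[rising] / pmax(d[rising], .Machine$double.eps)
    soft <- which(sec < 0.9 * stiffness & d[rising] > 0.1 * d[frac_idx])
    if (length(soft)) {
      d_y <- d[soft[1L]]; f_y <- f[soft[1L]]
    } else {
      d_y <- d[frac_idx]; f_y <- f[frac_idx]
    }
  }

  work <- sum(diff(d[seq_len(frac_idx)]) *
                (f[seq_len(frac_idx - 1L)] + f[2:frac_idx]) / 2)
  structure(list(stiffness_N_mm = stiffness,
                 yield_point = c(displacement_mm = d_y, load_N = f_y),
                 ultimate_force_N = ult,
                 fracture_point = c(displacement_mm = d[frac_idx],
                                    load_N = f[frac_idx]),
                 postyield_disp_mm = max(0, d[frac_idx] - d_y),
                 work_to_fracture_Nmm = work,
                 yield_method = yield_method),
            class = "bend_summary")
}

#' @export
print.bend_summary <- function(x, ...) {
  cat(sprintf(paste0("<bend_summary> stiffness %.4g N/mm, ultimate %.4g N, ",
                     "postyield %.4g mm, work %.4g N.mm\n"),
              x$stiffness_N_mm, x$ultimate_force_N, x$postyield_disp_mm,
              x$work_to_fracture_Nmm))
  invisible(x)
}

#' Moment of inertia of a hollow elliptical cross-section
#'
#' `I = (pi / 64) (w_o h_o^3 - w_i h_i^3)` about the bending axis, with h
#' the diameter along the loading direction.  Inner diameters of zero give
#' the solid ellipse; inner equal to outer gives zero.
#'
#' @param outer_width,outer_height Periosteal diameters, mm.
#' @param inner_width,inner_height Endosteal diameters, mm (each `<=` its
#'   outer counterpart).
#' @return Moment of inertia in mm^4.
#' @examples
#' elliptical_moi(4, 3, 2, 1.5)  # 4.970
#' elliptical_moi(2, 2, 0, 0)    # solid circle: pi * 2^4 / 64
#' @export
elliptical_moi <- function(outer_width, outer_height,
                           inner_width = 0, inner_height = 0) {
  if (outer_width <= 0 || outer_height <= 0) stop("outer diameters must be > 0")
  if (inner_width < 0 || inner_height < 0) stop("inner diameters must be >= 0")
  if (inner_width > outer_width || inner_height > outer_height) {
    stop("endosteal (inner) diameters exceed periosteal (outer) diameters")
  }
  (pi / 64) * (outer_width * outer_height^3 - inner_width * inner_height^3)
}

#' Material properties from structural bend metrics
#'
#' Standard three-point-bend beam formulas: bending modulus
#' `E = k L^3 / (48 I)` and outer-fibre stress `sigma = F L c / (4 I)` with
#' `c = h_o / 2`, evaluated at the yield and ultimate loads.  With N, mm and
#' mm^4 inputs the results are in MPa.
#'
#' @param summary A [bend_metrics()] result.
#' @param moi Cross-section moment of inertia, mm^4 (> 0).
#' @param span_mm Support span L, mm (> 0).
#' @param c_mm Distance from the neutral axis to the outer fibre
#'   (half the outer height), mm.
#' @return List with `modulus_MPa`, `yield_stress_MPa`,
#'   `ultimate_stress_MPa`.
#' @export
material_properties <- function(summary, moi, span_mm, c_mm) {
  if (moi <= 0) stop("moment of inertia must be > 0")
  if (span_mm <= 0) stop("span must be > 0")
  if (c_mm <= 0) stop("c must be > 0")
  list(
    modulus_MPa = summary$stiffness_N_mm * span_mm^3 / (48 * moi),
    yield_stress_MPa = summary$yield_point[["load_N"]] * span_mm * c_mm /
      (4 * moi),
    ultimate_stress_MPa = summary$ultimate_force_N * span_mm * c_mm /
      (4 * moi)
  )
}
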
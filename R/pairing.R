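# Tissue strain from CCD markers, time matching to X-ray frames, radiation
# dose bookkeeping and sample exclusion rules.

#' Bulk tissue strain from CCD marker coordinates
#'
#' Projects per-time marker positions onto the tensile axis and reports the
#' engineering strain of the inter-marker gauge:
#' `eps(t) = (L(t) - L0) / L0`, with `L0` the mean gauge length over the
#' pre-load reference times.  Rigid-body motion of the marker set leaves the
#' gauge, hence the strain, unchanged.
#'
#' @param markers Data frame with `time_s`, `marker_id`, `x_px`, `y_px`.
#' @param axis_deg Tensile axis direction in degrees (0 = +x).
#' @param reference_time_max Times `<=` this value define the unloaded
#'   gauge `L0`; `NULL` uses the earliest time point only.
#' @return Data frame with `time_s` and `tissue_strain`.
#' @export
tissue_strain_from_markers <- function(markers, axis_deg = 0,
                                       reference_time_max = NULL) {
  need <- c("time_s", "marker_id", "x_px", "y_px")
  if (!all(need %in% names(markers))) {
    stop("markers must have columns time_s, marker_id, x_px, y_px")
  }
  u <- c(cos(axis_deg * pi / 180), sin(axis_deg * pi / 180))
  proj <- markers$x_px * u[1L] + markers$y_px * u[2L]
  times <- sort(unique(markers$time_s))
  gauge <- vapply(times, function(t) {
    p <- proj[markers$time_s == t]
    if (length(p) < 2L) return(NA_real_)
    diff(range(p))
  }, numeric(1L))
  if (all(!is.finite(gauge))) stop("need >= 2 markers per time point")
  ref <- if (is.null(reference_time_max)) {
    gauge[which.min(times)]
  } else {
    mean(gauge[times <= reference_time_max], na.rm = TRUE)
  }
  if (!is.finite(ref) || ref <= 0) {
    stop("markers are collinear across the axis: zero gauge length")
  }
  data.frame(time_s = times, tissue_strain = (gauge - ref) / ref)
}

#' Time-match a material strain series to tissue strain
#'
#' Linearly interpolates the (typically faster-sampled) CCD tissue strain to
#' each X-ray frame timestamp.  Material strain values pass through
#' unmodified.  Frames outside the CCD coverage take the nearest tissue
#' value only if within one CCD sampling interval; farther frames are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param material A [strain_series()] (columns `time_s`,
#'   `material_strain`).
#' @param tissue Output of [tissue_strain_from_markers()].
#' @param sample_id Sample label carried into the pairing.
#' @return Object of class `paired_strain_series`: data.frame with
#'   `sample_id`, `time_s`, `tissue_strain`, `material_strain`, `phase`.
#' @export
time_match <- function(material, tissue, sample_id = "S1") {
  t_frame <- material$time_s
  t_ccd <- tissue$time_s
  if (min(t_frame) > max(t_ccd) || max(t_frame) < min(t_ccd)) {
    stop("no temporal overlap between frames and CCD record")
  }
  dt <- if (length(t_ccd) > 1L) stats::median(diff(sort(t_ccd))) else Inf
  inside <- t_frame >= min(t_ccd) & t_frame <= max(t_ccd)
  near_lo <- !inside & t_frame < min(t_ccd) & (min(t_ccd) - t_frame) <= dt
  near_hi <- !inside & t_frame > max(t_ccd) & (t_frame - max(t_ccd)) <= dt
  keep <- inside | near_lo | near_hi
  ts <- rep(NA_real_, length(t_frame))
  ts[inside] <- stats::approx(t_ccd, tissue$tissue_strain,
                              xout = t_frame[inside], ties = "ordered")$y
  ts[near_lo] <- tissue$tissue_strain[which.min(t_ccd)]
  ts[near_hi] <- tissue$tissue_strain[which.max(t_ccd)]
  phase <- attr(material, "phase")
  out <- data.frame(sample_id = sample_id,
                    time_s = t_frame[keep],
                    tissue_strain = ts[keep],
                    material_strain = material$material_strain[keep],
                    phase = if (is.null(phase)) NA_character_ else phase,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("paired_strain_series", "data.frame")
  out
}

#' Cumulative radiation dose ledger with dose-cap truncation
#'
#' Running per-frame dose total; frames whose cumulative dose exceeds the
#' cap (30 kGy by protocol) are marked excluded from analysis.
#'
#' @param frames Number of exposures, a list of [detector_frame()]s, or an
#'   `experiment_bundle`.
#' @param dose_per_exposure Dose per exposure in kGy (> 0).
#' @param cap_kgy Dose budget (kGy).
#' @return List with `ledger` (data.frame: `frame`, `dose_kgy`,
#'   `cumulative_kgy`, `included`) and `truncation_index` (first excluded
#'   frame, or `NA` when the cap is never reached).
#' @export
dose_ledger <- function(frames, dose_per_exposure, cap_kgy = 30) {
  if (dose_per_exposure <= 0) stop("dose_per_exposure must be > 0")
  n <- if (inherits(frames, "experiment_bundle")) {
    frames$schedule$n
  } else if (is.list(frames)) {
    length(frames)
  } else {
    as.integer(frames)
  }
  if (n < 1L) stop("need at least one frame")
  cum <- cumsum(rep(dose_per_exposure, n))
  included <- cum <= cap_kgy
  ledger <- data.frame(frame = seq_len(n),
                       dose_kgy = dose_per_exposure,
                       cumulative_kgy = cum,
                       included = included)
  list(ledger = ledger,
       truncation_index = if (all(included)) NA_integer_ else
         which(!included)[1L])
}

#' Apply the tensile-test sample exclusion rules
#'
#' Removes samples that slipped from the clamps, detached from the potting
#' resin before fracture, or fractured outside the diaphysis, and reports
#' counts per reason (a sample can trip several).  Idempotent.
#'
#' @param samples Data frame of sample metadata with columns `sample_id`,
#'   `slipped`, `depotted`, `fracture_site`.
#' @return List with `retained` (data.frame) and `report` (data.frame of
#'   `reason`, `n`).
#' @export
apply_exclusions <- function(samples) {
  if (nrow(samples) == 0L) {
    return(list(retained = samples,
                report = data.frame(reason = character(), n = integer())))
  }
  slipped <- isTRUE_vec(samples$slipped)
  depotted <- isTRUE_vec(samples$depotted)
  nondiaph <- !is.na(samples$fracture_site) &
    samples$fracture_site != "diaphyseal"
  drop <- slipped | depotted | nondiaph
  report <- data.frame(
    reason = c("slipped", "depotted", "nondiaphyseal_fracture", "retained"),
    n = c(sum(slipped), sum(depotted), sum(nondiaph), sum(!drop))
  )
  if (all(drop)) warning("all samples excluded")
  list(retained = samples[!drop, , drop = FALSE], report = report)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
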
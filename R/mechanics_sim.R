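# Synthetic whole-bone mechanics and grouped-outcome generators.

#' Simulate a three-point-bend load-displacement curve
#'
#' Piecewise curve: linear ramp at the programmed stiffness to the yield
#' point, a smooth hardening plateau rising to the ultimate force over the
#' postyield displacement, then a terminal load drop at fracture.  Optional
#' additive Gaussian load noise is seeded.
#'
#' @param stiffness Elastic stiffness, N/mm (> 0).
#' @param yield_point `c(displacement_mm, load_N)` at yield; the load
#'   component should equal `stiffness * displacement` (checked loosely).
#' @param postyield_disp Displacement between yield and fracture, mm
#'   (>= 0; 0 gives a brittle triangle).
#' @param ultimate_force Peak load, N; default 10% above yield load.
#' @param fracture_drop Fraction of the ultimate load lost at the terminal
#'   drop (1 = drop to zero).
#' @param sampling_hz Sampling rate, Hz.
#' @param disp_rate_mm_s Crosshead displacement rate, mm/s.
#' @param noise_sd Additive load noise s.d., N.
#' @param seed Integer RNG seed.
#' @return Object of class `load_displacement_curve`: data.frame with
#'   `displacement_mm`, `load_N`, and a `truth` attribute recording the
#'   programmed metrics.
#' @export
simulate_load_displacement <- function(stiffness, yield_point,
                                       postyield_disp,
                                       ultimate_force = NULL,
                                       fracture_drop = 1,
                                       sampling_hz = 100,
                                       disp_rate_mm_s = 0.1,
                                       noise_sd = 0, seed = 1L) {
  if (stiffness <= 0) stop("stiffness must be > 0")
  if (postyield_disp < 0) stop("postyield_disp must be >= 0")
  d_y <- yield_point[1L]; f_y <- yield_point[2L]
  if (d_y <= 0 || f_y <= 0) stop("yield point must be positive")
  if (abs(f_y - stiffness * d_y) > 0.05 * f_y) {
    warning("yield load differs from stiffness * yield displacement by > 5%")
  }
  if (is.null(ultimate_force)) {
    ultimate_force <- if (postyield_disp > 0) 1.1 * f_y else f_y
  }
  if (ultimate_force < f_y) stop("ultimate force below yield load")
  d_f <- d_y + postyield_disp
  dd <- disp_rate_mm_s / sampling_hz
  d <- seq(0, d_f, by = dd)
  if (d[length(d)] < d_f) d <- c(d, d_f)
  load <- ifelse(d <= d_y, stiffness * d, {
    u <- (d - d_y) / max(d_f - d_y, .Machine$double.eps)
    f_y + (ultimate_force - f_y) * u * (2 - u)  # parabola, plateau at d_f
  })
  # terminal drop
  f_end <- max(load[length(load)] * (1 - fracture_drop), 0)
  d <- c(d, d_f + dd / 2)
  load <- c(load, f_end)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    load <- load + stats::rnorm(length(load), 0, noise_sd)
  }
  out <- data.frame(displacement_mm = d, load_N = load)
  attr(out, "truth") <- list(stiffness = stiffness,
                             yield_point = c(d_y, f_y),
                             ultimate_force = ultimate_force,
                             postyield_disp = postyield_disp,
                             fracture_disp = d_f)
  class(out) <- c("load_displacement_curve", "data.frame")
  out
}

#' Simulate a balanced factorial outcome table
#'
#' Long-format age-by-genotype outcome table with normally distributed cell
#' values, the fixture for the ANOVA / Fisher's LSD framework.
#'
#' @param levels_age,levels_genotype Factor level labels.
#' @param cell_means Matrix of cell means, rows = age levels, columns =
#'   genotype levels (dimnames optional but checked when present).
#' @param sd Scalar or matrix of per-cell s.d.
#' @param n_per_cell Observations per cell (>= 2).
#' @param sex Constant sex label for the table.
#' @param seed Integer RNG seed.
#' @return Data frame with `sample_id`, `age`, `genotype`, `sex`, `value`.
#' @export
simulate_group_outcomes <- function(levels_age, levels_genotype, cell_means,
                                    sd = 1, n_per_cell = 8L,
                                    sex = "M", seed = 1L) {
  a <- length(levels_age); g <- length(levels_genotype)
  cell_means <- as.matrix(cell_means)
  if (!identical(dim(cell_means), c(a, g))) {
    stop("cell_means must be a ", a, " x ", g,
         " matrix (age levels x genotype levels); missing cells not allowed")
  }
  if (any(!is.finite(cell_means))) stop("missing cell mean")
  if (n_per_cell < 2L) stop("n_per_cell must be >= 2")
  sdm <- if (length(sd) == 1L) matrix(sd, a, g) else as.matrix(sd)
  if (!identical(dim(sdm), c(a, g))) stop("sd must be scalar or a x g matrix")
  set.seed(as.integer(seed))
  rows <- expand.grid(rep = seq_len(n_per_cell),
                      age = seq_len(a), genotype = seq_len(g))
  value <- stats::rnorm(nrow(rows),
                        mean = cell_means[cbind(rows$age, rows$genotype)],
                        sd = sdm[cbind(rows$age, rows$genotype)])
  data.frame(sample_id = sprintf("S%03d", seq_len(nrow(rows))),
             age = factor(levels_age[rows$age], levels = levels_age),
             genotype = factor(levels_genotype[rows$genotype],
                               levels = levels_genotype),
             sex = sex,
             value = value,
             stringsAsFactors = FALSE)
}
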
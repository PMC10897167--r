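# Material-vs-tissue strain slope regression, slope comparison by extra
# sum-of-squares F test, and the slope-sum composite diagnostic.
#
# The group slope is the fraction of bulk tissue strain carried by a
# material phase (collagen or mineral).  When the collagen and mineral
# slopes of a group sum to ~1, the nanoscale phases account for all tissue
# deformation (a stable composite); a sum well below 1 indicates deformation
# lost to unresolved mechanisms such as fibril sliding.

# closed-form simple OLS with SEs; kept free of lm() so tests can use lm as
# the independent oracle
ols_line <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("degenerate regressor: zero variance in x")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  s2 <- sse / (n - 2L)
  syy <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(s2 / sxx),
       intercept_se = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
       sse = sse, r2 = if (syy > 0) 1 - sse / syy else NA_real_,
       n = n, sxx = sxx)
}

#' Fit the pooled material-vs-tissue strain slope of a group
#'
#' Ordinary least squares of material strain on tissue strain over the
#' pooled scatter of all samples in a group.  Strains are dimensionless
#' fractions.
#'
#' @param points A `paired_strain_series` (or data.frame with
#'   `tissue_strain`, `material_strain`, optionally `sample_id`), pooled
#'   across the group's samples.
#' @param group Optional named character vector of group labels.
#' @param phase Optional phase label (`"collagen"` or `"mineral"`).
#' @return Object of class `slope_fit`: slope and intercept with SEs, `r2`,
#'   `n_points`, `n_samples`, `group`, `phase`.
#' @export
fit_group_slope <- function(points, group = NULL, phase = NULL) {
  ok <- is.finite(points$tissue_strain) & is.finite(points$material_strain)
  x <- points$tissue_strain[ok]
  y <- points$material_strain[ok]
  if (length(x) < 3L) stop("need at least 3 finite paired points")
  f <- ols_line(x, y)
  n_samples <- if (!is.null(points$sample_id)) {
    length(unique(points$sample_id[ok]))
  } else NA_integer_
  if (is.null(phase) && !is.null(points$phase)) {
    phase <- as.character(points$phase[ok][1L])
  }
  structure(list(slope = f$slope, se = f$slope_se,
                 intercept = f$intercept, intercept_se = f$intercept_se,
                 r2 = f$r2, n_points = f$n, n_samples = n_samples,
                 sse = f$sse, group = group, phase = phase),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope = %.4f +/- %.4f (n = %d points", x$slope,
              x$se, x$n_points))
  if (!is.na(x$n_samples)) cat(sprintf(", %d samples", x$n_samples))
  cat(sprintf(", R2 = %.3f)\n", x$r2))
  invisible(x)
}

#' 95% confidence interval of a fitted slope
#'
#' t-based interval on the slope of a [fit_group_slope()] result.
#'
#' @param fit A `slope_fit`.
#' @param level Confidence level.
#' @return `c(lo, hi)`.
#' @export
slope_ci <- function(fit, level = 0.95) {
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n_points - 2L)
  fit$slope + c(-1, 1) * tq * fit$se
}

#' Compare two group slopes by the extra sum-of-squares F test
#'
#' Nested-model F test of a common slope against separate slopes.  Both
#' models keep separate intercepts per group, so the hypothesis concerns the
#' slopes only:
#' `F = ((SSE_common - SSE_separate) / 1) / (SSE_separate / (n - 4))`.
#'
#' @param points_a,points_b Paired-strain data for the two groups (as in
#'   [fit_group_slope()]).
#' @return Object of class `f_test_result`: `F`, `df_num`, `df_den`,
#'   `p_value`, `sse_common`, `sse_separate`, `slopes`.
#' @export
compare_slopes <- function(points_a, points_b) {
  grab <- function(p) {
    ok <- is.finite(p$tissue_strain) & is.finite(p$material_strain)
    list(x = p$tissue_strain[ok], y = p$material_strain[ok])
  }
  a <- grab(points_a); b <- grab(points_b)
  fa <- ols_line(a$x, a$y)   # errors if degenerate
  fb <- ols_line(b$x, b$y)
  sse_sep <- fa$sse + fb$sse
  # common slope with separate intercepts, closed form
  sxy <- function(x, y) sum((x - mean(x)) * (y - mean(y)))
  syy <- function(y) sum((y - mean(y))^2)
  b_common <- (sxy(a$x, a$y) + sxy(b$x, b$y)) / (fa$sxx + fb$sxx)
  sse_com <- (syy(a$y) - 2 * b_common * sxy(a$x, a$y) + b_common^2 * fa$sxx) +
    (syy(b$y) - 2 * b_common * sxy(b$x, b$y) + b_common^2 * fb$sxx)
  df_den <- fa$n + fb$n - 4L
  if (df_den < 1L) stop("too few points for the separate-slopes model")
  if (sse_sep <= 0) {
    # noiseless limit: distinct slopes are detected with certainty
    Fstat <- if (sse_com > sse_sep) Inf else 0
  } else {
    Fstat <- max(0, (sse_com - sse_sep) / 1) / (sse_sep / df_den)
  }
  p <- stats::pf(Fstat, 1, df_den, lower.tail = FALSE)
  structure(list(F = Fstat, df_num = 1L, df_den = df_den, p_value = p,
                 sse_common = sse_com, sse_separate = sse_sep,
                 slopes = c(a = fa$slope, b = fb$slope),
                 common_slope = b_common),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("<f_test_result> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$F, x$p_value))
  invisible(x)
}

#' Slope-sum composite diagnostic
#'
#' Sums a group's collagen and mineral strain slopes and propagates their
#' SEs (`sqrt(se_c^2 + se_m^2)`).  A sum of ~1 means the two nanoscale
#' phases carry all of the tissue strain; `deficient` (sum + 2 se < 1)
#' indicates deformation unaccounted for (e.g. fibril sliding);
#' `oversumming` (sum - 2 se > 1) the converse.  Because collagen and
#' mineral are typically measured on contralateral bones of the same
#' animal, the result carries a `contralateral_caveat` flag.
#'
#' @param collagen,mineral `slope_fit` objects for the two phases of the
#'   same group.
#' @return Object of class `composite_diagnostic`: `slope_sum`, `se_sum`,
#'   `classification`, `group`, `contralateral_caveat`.
#' @export
slope_sum <- function(collagen, mineral) {
  stopifnot(inherits(collagen, "slope_fit"), inherits(mineral, "slope_fit"))
  if (!is.null(collagen$group) && !is.null(mineral$group) &&
      !identical(collagen$group, mineral$group)) {
    stop("slope fits come from different groups")
  }
  if (!is.null(collagen$phase) && !is.null(mineral$phase) &&
      identical(collagen$phase, mineral$phase)) {
    stop("need one collagen and one mineral fit, got two of the same phase")
  }
  s <- collagen$slope + mineral$slope
  se <- sqrt(collagen$se^2 + mineral$se^2)
  classification <- if (s + 2 * se < 1) {
    "deficient"
  } else if (s - 2 * se > 1) {
    "oversumming"
  } else {
    "balanced"
  }
  structure(list(slope_sum = s, se_sum = se, classification = classification,
                 group = collagen$group, contralateral_caveat = TRUE),
            class = "composite_diagnostic")
}

#' @export
print.composite_diagnostic <- function(x, ...) {
  cat(sprintf("<composite_diagnostic> sum = %.4f +/- %.4f (%s)\n",
              x$slope_sum, x$se_sum, x$classification))
  if (isTRUE(x$contralateral_caveat)) {
    cat("  note: collagen and mineral slopes typically measured on",
        "contralateral limbs\n")
  }
  invisible(x)
}
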
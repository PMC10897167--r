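# Shared fixtures: small detectors keep unit tests fast; the acceptance
# tests use the full-size camera geometries.

small_geometry <- function(distance_mm = 300, shape = c(401L, 401L),
                           center = NULL) {
  xray_geometry(beam_center_xy = center,
                sample_detector_distance_mm = distance_mm,
                detector_shape = shape)
}

# noiseless Gaussian radial profile for peak-fit tests
gaussian_profile <- function(q0 = 0.0094, sigma = 6e-4, amplitude = 100,
                             b0 = 5, b1 = 0, n = 120,
                             span = c(0.7 * q0, 1.3 * q0)) {
  q <- seq(span[1L], span[2L], length.out = n)
  out <- data.frame(q = q,
                    intensity = amplitude * exp(-(q - q0)^2 / (2 * sigma^2)) +
                      b0 + b1 * q,
                    n_pixels = 50L)
  class(out) <- c("radial_profile", "data.frame")
  out
}

azimuthal_profile_df <- function(chi, intensity) {
  out <- data.frame(chi = chi, intensity = intensity,
                    n_pixels = rep(10L, length(chi)))
  class(out) <- c("azimuthal_profile", "data.frame")
  out
}

# two-group paired-strain scatter with programmed slopes, for regression tests
slope_points <- function(slope, n = 40, noise = 0.02, intercept = 0,
                         seed = 1) {
  set.seed(seed)
  x <- seq(0, 0.01, length.out = n)
  data.frame(tissue_strain = x,
             material_strain = intercept + slope * x +
               rnorm(n, 0, noise * 0.01))
}

# textbook two-way ANOVA decomposition (cell-mean formulas, balanced only);
# independent oracle for the aov/lm-backed implementation
textbook_two_way <- function(data, fa = "age", fb = "genotype",
                             response = "value") {
  y <- data[[response]]
  A <- factor(data[[fa]]); B <- factor(data[[fb]])
  n <- table(A, B)[1L, 1L]
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_a <- n * nlevels(B) * sum((mA - gm)^2)
  ss_b <- n * nlevels(A) * sum((mB - gm)^2)
  ss_cells <- n * sum((mAB - gm)^2)
  ss_int <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - gm)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_int = ss_int,
       ss_res = ss_tot - ss_cells, ss_tot = ss_tot)
}
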
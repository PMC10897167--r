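test_that("a noiseless Gaussian peak is located to 5 significant figures", {
  prof <- gaussian_profile(q0 = 0.0094, sigma = 6e-4)
  pk <- fit_peak(prof, window = c(0.007, 0.012))
  expect_true(pk$converged)
  expect_equal(pk$q_center, 0.0094, tolerance = 1e-5)
  # and with a sloped background
  prof2 <- gaussian_profile(q0 = 0.0094, sigma = 6e-4, b1 = 300)
  pk2 <- fit_peak(prof2, window = c(0.007, 0.012))
  expect_equal(pk2$q_center, 0.0094, tolerance = 1e-5)
})

test_that("a featureless profile reports converged = FALSE, not an error", {
  prof <- gaussian_profile(amplitude = 0, b0 = 20)
  set.seed(1)
  prof$intensity <- prof$intensity + rnorm(nrow(prof), 0, 0.3)
  pk <- fit_peak(prof, window = range(prof$q))
  expect_false(pk$converged)
  expect_true(is.na(pk$q_center))
})

test_that("fit windows are validated", {
  prof <- gaussian_profile()
  expect_error(fit_peak(prof, window = c(1, 2)), "outside")
  expect_error(fit_peak(prof, window = prof$q[1] + c(0, 1e-5)), "8")
})

test_that("the fitted center is invariant under intensity rescaling", {
  prof <- gaussian_profile(q0 = 0.0094)
  set.seed(2)
  prof$intensity <- prof$intensity + rnorm(nrow(prof), 0, 0.5)
  pk1 <- fit_peak(prof, window = c(0.007, 0.012))
  prof$intensity <- prof$intensity * 37.5
  pk2 <- fit_peak(prof, window = c(0.007, 0.012))
  expect_equal(pk1$q_center, pk2$q_center, tolerance = 1e-9)
})

test_that("Poisson-noisy peak centers fall within 3 SE in >= 95% of seeds", {
  q0 <- 0.0094
  hits <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    prof <- gaussian_profile(q0 = q0, sigma = 6e-4, amplitude = 1000,
                             b0 = 10)
    set.seed(s)
    # per-bin Poisson on the mean of n_pixels pixels
    prof$intensity <- rpois(nrow(prof), prof$intensity * prof$n_pixels) /
      prof$n_pixels
    pk <- fit_peak(prof, window = c(0.007, 0.012))
    if (pk$converged && abs(pk$q_center - q0) <= 3 * pk$se) hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * n_rep - 3 * sqrt(n_rep * 0.05 * 0.95))
})

test_that("lorentzian peak model converges on lorentzian data", {
  q <- seq(0.007, 0.012, length.out = 150)
  gam <- 5e-4
  prof <- data.frame(q = q,
                     intensity = 80 * gam^2 / ((q - 0.0095)^2 + gam^2) + 3,
                     n_pixels = 40L)
  class(prof) <- c("radial_profile", "data.frame")
  pk <- fit_peak(prof, window = c(0.007, 0.012), model = "lorentzian")
  expect_true(pk$converged)
  expect_equal(pk$q_center, 0.0095, tolerance = 1e-5)
})

test_that("strain series uses the pre-load mean as d0 and flags NA frames", {
  mk_peak <- function(q) structure(list(q_center = q, se = 1e-6,
                                        converged = TRUE),
                                   class = "peak_fit")
  d0 <- 670
  # constant d: all strains zero
  pk <- lapply(rep(2 * pi / d0, 6), mk_peak)
  ss <- strain_series(pk, time_s = 0:5 * 5, reference = first_n_preload(3))
  expect_equal(ss$material_strain, rep(0, 6), tolerance = 1e-12)
  # 0.5% longer d-spacing gives strain 0.005
  pk2 <- lapply(2 * pi / c(d0, d0, d0, d0 * 1.005), mk_peak)
  ss2 <- strain_series(pk2, time_s = 0:3, reference = first_n_preload(3))
  expect_equal(ss2$material_strain[4], 0.005, tolerance = 1e-12)
  # unconverged frames carry NA, never interpolated
  bad <- structure(list(q_center = NA_real_, converged = FALSE),
                   class = "peak_fit")
  ss3 <- strain_series(c(pk[1:3], list(bad), pk[5:6]), time_s = 0:5,
                       reference = first_n_preload(3))
  expect_true(is.na(ss3$material_strain[4]))
  expect_false(anyNA(ss3$material_strain[-4]))
  # no converged reference frames is an error
  expect_error(strain_series(list(bad, bad, mk_peak(0.01)), time_s = 0:2,
                             reference = first_n_preload(2)),
               "pre-load")
})

test_that("P2 hits its anchor values and bounds", {
  chi <- seq(-179.5, 179.5, by = 1)
  # uniform -> 0 (the grid is symmetric, quadrature error ~ 0)
  expect_equal(p2_orientation(azimuthal_profile_df(chi, rep(3, length(chi)))),
               0, tolerance = 1e-6)
  # delta on the tensile axis -> 1
  I_axial <- ifelse(abs(chi - 0.5) < 1, 100, 0)
  expect_equal(p2_orientation(azimuthal_profile_df(chi, I_axial)),
               1, tolerance = 1e-3)
  # transverse delta -> -0.5
  I_trans <- ifelse(abs(chi - 90.5) < 1, 100, 0)
  expect_equal(p2_orientation(azimuthal_profile_df(chi, I_trans)),
               -0.5, tolerance = 1e-3)
  # bounds hold for arbitrary non-negative profiles
  set.seed(3)
  for (i in 1:50) {
    I <- runif(length(chi))^2 * 10
    p2 <- p2_orientation(azimuthal_profile_df(chi, I))
    expect_gte(p2, -0.5)
    expect_lte(p2, 1)
  }
  expect_error(p2_orientation(azimuthal_profile_df(chi, rep(0, length(chi)))))
  expect_error(p2_orientation(azimuthal_profile_df(chi[1:90], rep(1, 90))),
               "180")
})

test_that("P2-vs-strain slope is recovered from its OLS fit", {
  eps <- seq(0, 0.008, length.out = 50)
  # constant P2 -> slope 0
  expect_equal(delta_p2(rep(0.3, 50), eps)$slope, 0, tolerance = 1e-12)
  # programmed ramp with mild noise recovered within 2 SE
  set.seed(6)
  p2 <- 0.3 + 0.05 * eps + rnorm(50, 0, 1e-5)
  d <- delta_p2(p2, eps)
  expect_lt(abs(d$slope - 0.05), 2 * d$se)
  expect_error(delta_p2(c(0.1, 0.2), c(0, 1)), "3")
})

test_that("generator anisotropy yields the programmed P2 after reduction", {
  g <- small_geometry(distance_mm = 1500, shape = c(301L, 301L))
  tr <- tensile_truth(d0_collagen = 300, p2_initial = 0.35, p2_rate = 0,
                      amplitude = 3000, noise_level = 0.2, seed = 12)
  sch <- matstrain:::tensile_schedule(tr)
  f <- simulate_tensile_frame(tr, g, "collagen", 1L, sch)
  q0 <- 2 * pi / f$meta$d_true
  az <- integrate_azimuthal(f, g, q_band = q0 * c(0.97, 1.03),
                            chi_bins = 72L)
  expect_equal(p2_orientation(az), 0.35, tolerance = 0.02)
})
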
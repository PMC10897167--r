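test_that("beam center is recovered to sub-pixel accuracy", {
  g <- small_geometry(center = c(207, 193))
  f <- simulate_calibrant_frame(g, ring_d = 58.38, seed = 4)
  ctr <- find_beam_center(f, initial_guess = c(200, 200))
  expect_lt(max(abs(ctr - c(207, 193))), 0.5)
})

test_that("a shifted center is tracked within 0.5 px", {
  g <- small_geometry(center = c(210, 200))
  f <- simulate_calibrant_frame(g, ring_d = 58.38, seed = 5)
  ctr <- find_beam_center(f, initial_guess = c(200, 200))
  expect_lt(max(abs(ctr - c(210, 200))), 0.5)
})

test_that("a constant frame has no detectable ring", {
  fr <- detector_frame(matrix(7, 101, 101))
  expect_error(find_beam_center(fr), "no ring")
})

test_that("camera length is calibrated within 0.2% from silver behenate", {
  g <- small_geometry(distance_mm = 300)
  f <- simulate_calibrant_frame(g, ring_d = 58.38, seed = 6)
  cal <- calibrate_distance(f, g$beam_center_xy, g$wavelength_A,
                            known_d = 58.38)
  expect_lt(abs(cal$sample_detector_distance_mm - 300) / 300, 0.002)
})

test_that("distance inversion is exact when the radius is exact", {
  g <- small_geometry(distance_mm = 1234)
  s <- g$wavelength_A / (2 * 58.38)
  r_exact <- 1234 * tan(2 * asin(s))
  expect_equal(r_exact / tan(2 * asin(s)), 1234, tolerance = 1e-12)
})

test_that("calibration fails gracefully without a ring in the annulus", {
  g <- small_geometry(distance_mm = 300)
  f <- simulate_calibrant_frame(g, ring_d = 58.38, seed = 6)
  expect_error(calibrate_distance(f, g$beam_center_xy, g$wavelength_A,
                                  known_d = 58.38,
                                  expected_distance_mm = 4000))
  flat <- detector_frame(matrix(rpois(301^2, 5), 301, 301))
  expect_error(calibrate_distance(flat, c(150, 150), 1.2398,
                                  known_d = 58.38),
               "ring not found")
})

test_that("radial integration conserves counts over the selected sector", {
  g <- small_geometry(shape = c(201L, 201L))
  f <- simulate_calibrant_frame(g, ring_d = 58.38, seed = 8)
  prof <- integrate_radial(f, g, chi_range = c(-30, 30), mirror = TRUE,
                           n_bins = 300L)
  maps <- matstrain:::pixel_maps(g)
  qr <- range(prof$q) # reconstruct selection: full q coverage used
  sel <- matstrain:::chi_in_sector(maps$chi, c(-30, 30), TRUE) &
    maps$q >= 0 & maps$q < max(maps$q)
  total_binned <- sum(prof$intensity * prof$n_pixels, na.rm = TRUE)
  expect_equal(total_binned, sum(f$counts[sel]), tolerance = 1e-9)
})

test_that("a zero frame integrates to an all-zero profile", {
  g <- small_geometry(shape = c(101L, 101L))
  f <- detector_frame(matrix(0, 101, 101))
  prof <- integrate_radial(f, g, n_bins = 100L)
  expect_true(all(prof$intensity[prof$n_pixels > 0] == 0))
  expect_true(all(is.na(prof$intensity[prof$n_pixels == 0])))
})

test_that("radial integration validates its sector and grid", {
  g <- small_geometry(shape = c(101L, 101L))
  f <- detector_frame(matrix(0, 101, 101))
  expect_error(integrate_radial(f, g, chi_range = c(20, 20)))
  expect_error(integrate_radial(f, g, q_range = c(0.2, 0.1)))
})

test_that("azimuthal profile of a uniform ring is flat", {
  g <- small_geometry()
  f <- simulate_calibrant_frame(g, ring_d = 58.38, seed = 9,
                                amplitude = 2000)
  q0 <- 2 * pi / 58.38
  az <- integrate_azimuthal(f, g, q_band = q0 * c(0.97, 1.03),
                            chi_bins = 36L)
  cv <- sd(az$intensity, na.rm = TRUE) / mean(az$intensity, na.rm = TRUE)
  expect_lt(cv, 0.1)
})

test_that("anisotropic rings peak along the tensile axis", {
  g <- small_geometry(distance_mm = 1500, shape = c(301L, 301L))
  tr <- tensile_truth(d0_collagen = 300, p2_initial = 0.5, p2_rate = 0,
                      amplitude = 1000, seed = 10)
  sch <- matstrain:::tensile_schedule(tr)
  f <- simulate_tensile_frame(tr, g, "collagen", 1L, sch)
  q0 <- 2 * pi / f$meta$d_true
  az <- integrate_azimuthal(f, g, q_band = q0 * c(0.97, 1.03),
                            chi_bins = 36L)
  imax <- which.max(az$intensity)
  expect_lt(min(abs(az$chi[imax]), abs(abs(az$chi[imax]) - 180)), 20)
})

test_that("azimuthal integration rejects empty or inverted q bands", {
  g <- small_geometry(shape = c(101L, 101L))
  f <- detector_frame(matrix(1, 101, 101))
  expect_error(integrate_azimuthal(f, g, q_band = c(0.5, 0.5)))
  expect_error(integrate_azimuthal(f, g, q_band = c(50, 60)))
})

test_that("programmed rings are recovered within one bin across geometries", {
  set.seed(42)
  for (i in 1:8) {
    L <- runif(1, 200, 1500)
    shape <- sample(151:301, 1)
    g <- small_geometry(distance_mm = L, shape = c(shape, shape),
                        center = (shape - 1) / 2 + runif(2, -4, 4))
    # pick a d whose ring sits at 30-45% of the half-width
    r_target <- shape / 2 * runif(1, 0.3, 0.45) * g$pixel_size_um / 1000
    q_target <- matstrain:::q_of_r_mm(r_target, g)
    d <- 2 * pi / q_target
    f <- simulate_calibrant_frame(g, ring_d = d, seed = i,
                                  amplitude = 1000)
    prof <- integrate_radial(f, g, chi_range = c(-180, 180),
                             mirror = FALSE, n_bins = 250L)
    q_hat <- prof$q[which.max(prof$intensity)]
    expect_lt(abs(q_hat - q_target), 2 * diff(range(prof$q)) / 250)
  }
})
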
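test_that("an exact line is fitted with slope 0.5 and vanishing SE", {
  pts <- data.frame(tissue_strain = seq(0, 0.01, length.out = 20),
                    material_strain = 0.5 * seq(0, 0.01, length.out = 20))
  f <- fit_group_slope(pts)
  expect_equal(f$slope, 0.5, tolerance = 1e-12)
  expect_lt(f$se, 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_group_slope(data.frame(tissue_strain = 1,
                                          material_strain = 1)))
  expect_error(fit_group_slope(data.frame(tissue_strain = rep(2, 5),
                                          material_strain = 1:5)),
               "degenerate|variance")
})

test_that("the closed-form OLS agrees with lm() to 1e-10", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- 0.3 + 0.7 * x + rnorm(n)
    pts <- data.frame(tissue_strain = x, material_strain = y)
    f <- fit_group_slope(pts)
    m <- lm(y ~ x)
    expect_equal(f$slope, unname(coef(m)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(m)[1]), tolerance = 1e-10)
    expect_equal(f$se, summary(m)$coefficients[2, 2], tolerance = 1e-10)
  }
})

test_that("comparing a group with itself gives F ~ 0, p ~ 1", {
  a <- slope_points(0.7, seed = 21)
  r <- compare_slopes(a, a)
  expect_lt(r$F, 1e-8)
  expect_gt(r$p_value, 1 - 1e-4)
})

test_that("noiseless distinct slopes drive p to the machine floor", {
  x <- seq(0, 0.01, length.out = 30)
  a <- data.frame(tissue_strain = x, material_strain = 0.5 * x)
  b <- data.frame(tissue_strain = x, material_strain = 0.6 * x)
  r <- compare_slopes(a, b)
  expect_true(is.infinite(r$F))
  expect_identical(r$p_value, 0)
})

test_that("the extra sum-of-squares F matches the nested lm comparison", {
  set.seed(31)
  for (i in 1:10) {
    a <- slope_points(0.7, n = 30, noise = 1, seed = i)
    b <- slope_points(0.75, n = 25, noise = 1, seed = i + 100)
    r <- compare_slopes(a, b)
    df <- rbind(cbind(a, g = "a"), cbind(b, g = "b"))
    fit_sep <- lm(material_strain ~ g + tissue_strain:g, data = df)
    fit_com <- lm(material_strain ~ g + tissue_strain, data = df)
    oracle <- anova(fit_com, fit_sep)
    expect_equal(r$F, oracle$F[2], tolerance = 1e-9)
    expect_equal(r$p_value, oracle$`Pr(>F)`[2], tolerance = 1e-9)
  }
})

test_that("with equal designs the F test is the squared slope t-test", {
  set.seed(41)
  x <- seq(0, 1, length.out = 30)
  a <- data.frame(tissue_strain = x,
                  material_strain = 0.5 * x + rnorm(30, 0, 0.05))
  b <- data.frame(tissue_strain = x,
                  material_strain = 0.6 * x + rnorm(30, 0, 0.05))
  r <- compare_slopes(a, b)
  fa <- matstrain:::ols_line(a$tissue_strain, a$material_strain)
  fb <- matstrain:::ols_line(b$tissue_strain, b$material_strain)
  s2 <- (fa$sse + fb$sse) / (30 + 30 - 4)          # pooled residual variance
  t2 <- (fa$slope - fb$slope)^2 / (s2 * (1 / fa$sxx + 1 / fb$sxx))
  expect_equal(r$F, t2, tolerance = 1e-9)
})

test_that("slope sums reproduce the composite arithmetic and classes", {
  mk <- function(slope, se, phase, group = c(age = "4mo", sex = "M",
                                             genotype = "Ctrl")) {
    structure(list(slope = slope, se = se, group = group, phase = phase,
                   n_points = 100L),
              class = "slope_fit")
  }
  # healthy young male: 0.7482 + 0.3561 = 1.1043
  s1 <- slope_sum(mk(0.7482, 0.0451, "collagen"), mk(0.3561, 0.0191,
                                                     "mineral"))
  expect_equal(s1$slope_sum, 1.1043, tolerance = 1e-12)
  expect_equal(s1$se_sum, sqrt(0.0451^2 + 0.0191^2), tolerance = 1e-12)
  # receptor-deficient young male: 0.4539 + 0.2352 = 0.6891, deficient
  s2 <- slope_sum(mk(0.4539, 0.0272, "collagen"), mk(0.2352, 0.0207,
                                                     "mineral"))
  expect_equal(s2$slope_sum, 0.6891, tolerance = 1e-12)
  expect_identical(s2$classification, "deficient")
  # tight SEs around 1.0 classify as balanced
  s3 <- slope_sum(mk(0.6, 1e-4, "collagen"), mk(0.4, 1e-4, "mineral"))
  expect_identical(s3$classification, "balanced")
  expect_true(s3$contralateral_caveat)
  # mismatched groups and duplicated phases are errors
  expect_error(slope_sum(mk(0.6, 0.01, "collagen"),
                         mk(0.4, 0.01, "mineral",
                            group = c(age = "15mo", sex = "M",
                                      genotype = "Ctrl"))),
               "group")
  expect_error(slope_sum(mk(0.6, 0.01, "collagen"),
                         mk(0.4, 0.01, "collagen")), "phase")
})
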
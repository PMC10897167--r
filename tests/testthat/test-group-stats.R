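test_that("balanced two-way ANOVA matches the textbook decomposition", {
  set.seed(51)
  d <- simulate_group_outcomes(c("4mo", "15mo"), c("Ctrl", "KO"),
                               matrix(c(10, 12, 11, 16), 2, 2),
                               sd = 2, n_per_cell = 6, seed = 51)
  an <- two_way_anova(d, c("age", "genotype"))
  oracle <- textbook_two_way(d)
  expect_equal(an$sum_sq[an$term == "age"], oracle$ss_a, tolerance = 1e-10)
  expect_equal(an$sum_sq[an$term == "genotype"], oracle$ss_b,
               tolerance = 1e-10)
  expect_equal(an$sum_sq[an$term == "age:genotype"], oracle$ss_int,
               tolerance = 1e-10)
  expect_equal(an$sum_sq[an$term == "Residuals"], oracle$ss_res,
               tolerance = 1e-10)
  # SS additivity on the balanced design
  expect_equal(sum(an$sum_sq), oracle$ss_tot, tolerance = 1e-10)
})

test_that("empty cells are reported by name", {
  d <- simulate_group_outcomes(c("4mo", "15mo"), c("Ctrl", "KO"),
                               matrix(10, 2, 2), n_per_cell = 3, seed = 1)
  d <- d[!(d$age == "15mo" & d$genotype == "KO"), ]
  expect_error(two_way_anova(d), "15mo.*KO|KO.*15mo")
})

test_that("unbalanced designs fall back to Type II sums of squares", {
  d <- simulate_group_outcomes(c("4mo", "15mo"), c("Ctrl", "KO"),
                               matrix(c(10, 12, 11, 16), 2, 2),
                               sd = 2, n_per_cell = 8, seed = 52)
  d <- d[-c(1, 2, 10), ]  # unbalance it
  an <- two_way_anova(d)
  expect_identical(attr(an, "type"), "II")
  fit <- lm(value ~ age * genotype, data = d)
  oracle <- car::Anova(fit, type = 2)
  expect_equal(an$sum_sq[an$term == "age"], oracle["age", "Sum Sq"],
               tolerance = 1e-10)
})

test_that("one-way ANOVA reduces to the squared pooled t for two groups", {
  set.seed(53)
  d <- data.frame(age = rep(c("a", "b"), each = 10),
                  value = c(rnorm(10, 5), rnorm(10, 6)))
  an <- one_way_anova(d, "age")
  tt <- t.test(value ~ age, data = d, var.equal = TRUE)
  expect_equal(an$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p[1], tt$p.value, tolerance = 1e-10)
  expect_error(one_way_anova(data.frame(age = "a", value = 1:5), "age"),
               "2 groups")
})

test_that("one-way SS agree with the direct decomposition to 1e-10", {
  set.seed(54)
  d <- data.frame(age = rep(c("a", "b", "c", "d"), each = 7),
                  value = rnorm(28, rep(c(1, 2, 3, 2.5), each = 7)))
  an <- one_way_anova(d, "age")
  gm <- mean(d$value)
  mg <- tapply(d$value, d$age, mean)
  ss_between <- sum(7 * (mg - gm)^2)
  expect_equal(an$sum_sq[1], ss_between, tolerance = 1e-10)
  expect_equal(sum(an$sum_sq), sum((d$value - gm)^2), tolerance = 1e-10)
})

test_that("Fisher's LSD reproduces the hand-worked example", {
  # means 10 vs 12, MSE 4, n = 5 each, df = 16
  an <- structure(data.frame(term = "Residuals", df = 16, sum_sq = 64,
                             mean_sq = 4, F = NA, p = NA),
                  class = c("anova_table", "data.frame"))
  d <- data.frame(age = rep(c("a", "b"), each = 5),
                  value = c(10 + scale(1:5, scale = FALSE),
                            12 + scale(1:5, scale = FALSE)))
  r <- fisher_lsd(an, d, c(age = "a"), c(age = "b"))
  expect_equal(abs(r$t), 2 / sqrt(4 * (1 / 5 + 1 / 5)), tolerance = 1e-10)
  expect_equal(abs(r$t), 1.5811, tolerance = 1e-4)
  expect_equal(r$p_value, 0.1334, tolerance = 2e-3)
  # identical cells: p = 1
  r0 <- fisher_lsd(an, d, c(age = "a"), c(age = "a"))
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  expect_error(fisher_lsd(an, d, c(age = "zz"), c(age = "b")), "cell")
})

test_that("LSD on a two-group one-way design equals the pooled t-test", {
  set.seed(55)
  d <- data.frame(age = rep(c("a", "b"), each = 8),
                  value = c(rnorm(8, 3), rnorm(8, 4)))
  an <- one_way_anova(d, "age")
  r <- fisher_lsd(an, d, c(age = "a"), c(age = "b"))
  tt <- t.test(value ~ age, data = d, var.equal = TRUE)
  expect_equal(abs(r$t), abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("Bonferroni alphas follow the printed conventions", {
  expect_identical(bonferroni_alpha(4)$alpha, 0.0125)
  expect_identical(bonferroni_alpha(1)$alpha, 0.05)
  b7 <- bonferroni_alpha(7)
  expect_equal(b7$alpha, 0.05 / 7, tolerance = 1e-12)
  expect_identical(b7$printed, 0.007)
  expect_identical(bonferroni_alpha(6)$printed, 0.008)
  # exact family identity
  for (m in 1:12) expect_equal(bonferroni_alpha(m)$alpha * m, 0.05,
                               tolerance = 1e-15)
  expect_error(bonferroni_alpha(0))
})

test_that("an additive 2x2 design keeps the interaction near its null", {
  n_rep <- 300L
  rej <- 0L
  for (s in seq_len(n_rep)) {
    d <- simulate_group_outcomes(c("a", "b"), c("c", "d"),
                                 matrix(c(10, 12, 11, 13), 2, 2), # additive
                                 sd = 1.5, n_per_cell = 6, seed = s)
    an <- two_way_anova(d)
    if (an$p[an$term == "age:genotype"] < 0.05) rej <- rej + 1L
  }
  # 95% binomial band around the nominal 5% type-I rate
  expect_lt(abs(rej / n_rep - 0.05), 2 * sqrt(0.05 * 0.95 / n_rep) + 1e-9)
})

test_that("a crossed effect is detected in most seeds at its effect size", {
  hits <- 0L
  for (s in 1:60) {
    d <- simulate_group_outcomes(c("a", "b"), c("c", "d"),
                                 matrix(c(10, 12, 11, 16), 2, 2), # 3-unit cross
                                 sd = 1, n_per_cell = 8, seed = 1000 + s)
    an <- two_way_anova(d)
    if (an$p[an$term == "age:genotype"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.8)
})
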
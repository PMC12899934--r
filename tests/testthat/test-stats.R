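test_that("adequacy prevalence implements the cut-point definition", {
  expect_equal(adequacy_prevalence(c(8, 9, 10, 11), 10), 50)
  expect_equal(adequacy_prevalence(c(12, 15), 10), 100)
  expect_error(adequacy_prevalence(numeric(0), 10), "empty")
  expect_error(adequacy_prevalence(1:3, 0), "positive")
  # order invariance and monotonicity in the threshold
  set.seed(3)
  x <- rgamma(200, 4, 0.5)
  expect_equal(adequacy_prevalence(x, 7), adequacy_prevalence(rev(x), 7))
  thresholds <- seq(1, 20, by = 0.5)
  prev <- vapply(thresholds, function(t) adequacy_prevalence(x, t),
                 numeric(1))
  expect_true(all(diff(prev) <= 0))
  # per-person thresholds: sex-specific cut-points
  sex <- rep(c("male", "female"), 100)
  thr <- ifelse(sex == "male", 8, 18)
  expect_equal(adequacy_prevalence(x, thr),
               100 * mean(x >= thr))
})

test_that("chi-square matches hand values and the reference implementation", {
  even <- chi_square_independence(matrix(50, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  t2 <- chi_square_independence(matrix(c(30, 10, 10, 30), 2))
  expect_equal(t2$statistic, 20)
  expect_equal(t2$df, 1)

  expect_equal(chi_square_independence(matrix(c(5, 10, 15, 10, 20, 40),
                                              3))$df, 2)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2)),
               "marginal")

  set.seed(4)
  for (i in 1:100) {
    r <- sample(2:5, 1); c <- sample(2:4, 1)
    tab <- matrix(rpois(r * c, 20) + 1, r, c)
    own <- chi_square_independence(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(own$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(own$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(own$df, unname(ref$parameter))
  }
})

test_that("one-way ANOVA matches hand values and aov", {
  flat <- one_way_anova(list(c(1, 3), c(1, 3), c(1, 3)))
  expect_equal(flat$statistic, 0)

  f <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(f$statistic, 13.5)
  expect_equal(f$df, c(1, 4))

  k4 <- one_way_anova(list(rnorm(5), rnorm(5), rnorm(5), rnorm(5)))
  expect_equal(k4$df[1], 3)

  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "zero within")

  set.seed(5)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:12, 1), j / 2))
    own <- one_way_anova(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_len(k), lengths(groups))))
    ref <- summary(aov(y ~ g, df))[[1]]
    expect_equal(own$statistic, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(own$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("bootstrap SE converges to the closed-form SE of the mean", {
  x <- with_seed(6, rnorm(1500, 100, 15))
  bs <- bootstrap_summary(x, B = 1000, seed = 8)
  expect_lt(abs(bs$se - 15 / sqrt(1500)) / (15 / sqrt(1500)), 0.10)
  expect_lte(bs$ci_low, bs$point_mean)
  expect_gte(bs$ci_high, bs$point_mean)
  expect_equal(bs$cv_pct, 100 * bs$se / abs(bs$point_mean))

  expect_identical(bootstrap_summary(x, B = 500, seed = 8),
                   bootstrap_summary(x, B = 500, seed = 8))

  const <- bootstrap_summary(rep(5, 50), B = 200, seed = 1)
  expect_equal(const$se, 0)
  expect_equal(const$ci_low, 5)
  expect_equal(const$ci_high, 5)

  expect_warning(bootstrap_summary(x[1:10], B = 50, seed = 1), "B < 100")
  expect_error(bootstrap_summary(x, B = 0), "positive")
  expect_error(bootstrap_summary(1), "at least 2")
})

test_that("trade-off regression and elasticity follow their definitions", {
  t1 <- tradeoff_regression(1:10, 2 * (1:10))
  expect_equal(t1$slope, 2, tolerance = 1e-12)
  expect_equal(t1$elasticity, 1, tolerance = 1e-12)

  t0 <- tradeoff_regression(1:10, rep(3, 10))
  expect_equal(t0$elasticity, 0, tolerance = 1e-12)

  # elasticity at stated sample means: 0.5 x 3.88 / 11.34
  set.seed(7)
  x <- rnorm(400, 3.88, 0.5)
  x <- x - mean(x) + 3.88
  y <- 11.34 - 0.5 * 3.88 + 0.5 * x
  t2 <- tradeoff_regression(x, y)
  expect_equal(t2$elasticity, 0.5 * 3.88 / 11.34, tolerance = 1e-9)

  expect_error(tradeoff_regression(rep(1, 5), 1:5), "constant")
  expect_error(tradeoff_regression(1:2, 1:2), ">= 3")
})

test_that("Bonferroni correction uses all pairwise comparisons", {
  b4 <- bonferroni_alpha(0.05, 4)
  expect_equal(b4$m, 6)
  expect_equal(b4$adjusted_alpha, 0.05 / 6)
  expect_equal(bonferroni_alpha(0.05, 2)$adjusted_alpha, 0.05)
  expect_equal(bonferroni_alpha(0.01, 3)$adjusted_alpha, 0.01 / 3)
  expect_error(bonferroni_alpha(0.05, 1), "2 groups")
  expect_error(bonferroni_alpha(1.2, 3), "alpha")
})

test_that("post hoc pairwise tests run under both corrections", {
  pop <- small_pop()
  bonf <- pairwise_pattern_tests(pop$bmi_kg_m2, pop$pattern)
  expect_equal(nrow(bonf), 6)
  expect_equal(attr(bonf, "adjusted_alpha"), 0.05 / 6)
  tuk <- pairwise_pattern_tests(pop$bmi_kg_m2, pop$pattern,
                                method = "tukey")
  expect_equal(nrow(tuk), 6)
  expect_true(all(tuk$p_value >= 0 & tuk$p_value <= 1))
})
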
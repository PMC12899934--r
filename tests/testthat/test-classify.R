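brute_force_metrics <- function(true, pred, labels) {
  per <- lapply(labels, function(l) {
    tp <- sum(true == l & pred == l)
    fp <- sum(true != l & pred == l)
    fn <- sum(true == l & pred != l)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    list(p = p, r = r,
         f1 = if (p + r == 0) 0 else 2 * p * r / (p + r),
         support = sum(true == l))
  })
  list(accuracy = mean(true == pred),
       precision = vapply(per, `[[`, 0, "p"),
       recall = vapply(per, `[[`, 0, "r"),
       f1 = vapply(per, `[[`, 0, "f1"),
       support = vapply(per, `[[`, 0, "support"))
}

test_that("confusion metrics agree with a brute-force tally oracle", {
  set.seed(10)
  labels <- c("A", "B", "C", "D")
  for (case in 1:100) {
    n <- sample(20:80, 1)
    true <- sample(labels, n, replace = TRUE)
    pred <- sample(labels, n, replace = TRUE)
    m <- suppressMessages(confusion_metrics(true, pred, labels = labels))
    o <- brute_force_metrics(true, pred, labels)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$per_class$precision, unname(o$precision))
    expect_equal(m$per_class$recall, unname(o$recall))
    expect_equal(m$per_class$f1, unname(o$f1))
    expect_equal(m$per_class$support, unname(o$support))
    expect_equal(m$macro_f1, mean(o$f1))
    expect_equal(m$weighted_f1,
                 sum(o$f1 * o$support) / sum(o$support))
    # row sums of the confusion matrix are the supports
    expect_equal(unname(rowSums(m$confusion)), unname(o$support))
  }
})

test_that("perfect and degenerate predictions give the expected metrics", {
  m <- confusion_metrics(c("a", "b", "a", "b"), c("a", "b", "a", "b"))
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$f1, c(1, 1))
  expect_error(confusion_metrics(character(0), character(0)), "empty")
  expect_error(confusion_metrics(c("a", "b"), "a"), "equal length")
})

test_that("published class-level metrics are arithmetically consistent", {
  ref <- read.csv(dietsim_file("reference_class_metrics.csv"))
  labs <- reference_confusion_labels()
  m <- confusion_metrics(labs$true, labs$pred,
                         labels = ref$class)
  expect_equal(round(m$per_class$f1, 3)[1], 0.185)
  expect_equal(round(m$macro_f1, 3), 0.288)
  expect_equal(round(sum(ref$recall * ref$support) / sum(ref$support), 3),
               0.391)
  expect_equal(unname(rowSums(labs$counts)), ref$support)
})

test_that("the forest separates well-separated clusters and not shuffled labels", {
  sep <- separable_pop()
  clf <- train_pattern_classifier(sep, seed = 5, importance_batches = 5)
  expect_gte(clf$metrics$accuracy, 0.95)
  expect_true(all(clf$importances$mean >= 0))
  expect_equal(sum(clf$importances$mean), 1, tolerance = 1e-9)
  expect_true(all(clf$importances$se >= 0))

  shuffled <- sep
  set.seed(11)
  shuffled$pattern <- sample(shuffled$pattern)
  clf0 <- train_pattern_classifier(shuffled, seed = 5,
                                   importance_batches = 5)
  n_test <- clf0$metrics$n
  se <- sqrt(0.25 * 0.75 / n_test)
  expect_lt(abs(clf0$metrics$accuracy - 0.25), 3 * se)

  single <- sep[sep$pattern == "P1", ]
  expect_error(train_pattern_classifier(single), "two patterns")
  expect_error(train_pattern_classifier(sep, features = c("age_years",
                                                          "nope")),
               "unknown feature")
})

test_that("regression error metrics match hand-computed values", {
  exact <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(exact$r2, 1)
  expect_equal(exact$rmse, 0)
  expect_equal(exact$mape_pct, 0)

  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(m$mape_pct, 100 / 9, tolerance = 1e-12)  # 11.11%

  # predicting the mean gives R2 = 0 by definition
  y <- c(4, 7, 1, 9)
  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2, 0)

  expect_message(z <- regression_metrics(c(0, 1, 2), c(0, 1, 2)),
                 "excluded from MAPE")
})

test_that("adequacy regression fits, validates, and flags collinearity", {
  pop <- small_pop()
  rep <- fit_adequacy_regression(pop, seed = 3)
  expect_lte(rep$r2, 1)
  expect_gte(rep$rmse, 0)
  expect_length(rep$per_pattern_r2, 4)

  # a response that is an exact linear function of predictors fits perfectly
  df <- as.data.frame(pop)
  df$lin <- 2 + 0.5 * df$energy_kcal - 1.5 * df$ghg_kgco2e
  perfect <- fit_adequacy_regression(df, response = "lin",
                                     predictors = c("energy_kcal",
                                                    "ghg_kgco2e"), seed = 3)
  expect_equal(perfect$r2, 1, tolerance = 1e-9)
  expect_equal(perfect$rmse, 0, tolerance = 1e-6)

  df$dup <- df$energy_kcal
  expect_error(
    fit_adequacy_regression(df, predictors = c("energy_kcal", "dup"),
                            seed = 3),
    "collinear")
  df$const <- 1
  expect_error(fit_adequacy_regression(df, response = "const"), "constant")
})
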
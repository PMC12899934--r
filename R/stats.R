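# Inference toolkit: EAR cut-point adequacy prevalence, chi-square
# independence, percentile bootstrap, cost-emissions trade-off regression
# with elasticity, one-way ANOVA, and Bonferroni-corrected post hoc tests.
# Chi-square and ANOVA are computed from their defining formulas (and
# cross-checked against stats::chisq.test / aov in the test suite).

#' Adequacy prevalence by the EAR cut-point method
#'
#' 100 x the fraction of individuals whose intake/threshold ratio is >= 1.
#' Thresholds may be a scalar or a per-person vector (e.g. sex-specific
#' EARs via [requirement_threshold()]).
#'
#' @param intakes Numeric intake values.
#' @param thresholds Positive scalar or vector of per-person cut-points.
#' @return Prevalence percentage in \[0, 100\].
#' @export
#' @examples
#' adequacy_prevalence(c(8, 9, 10, 11), 10)  # 50
adequacy_prevalence <- function(intakes, thresholds) {
  if (length(intakes) == 0) stop("empty intake input", call. = FALSE)
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  100 * mean(intakes / thresholds >= 1)
}

#' Chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table: X2 = sum (O - E)^2 / E
#' with E = row total x column total / grand total, df = (r-1)(c-1), no
#' continuity correction.
#'
#' @param counts Matrix of nonnegative counts with positive marginals.
#' @return A `stat_test` list: `statistic`, `df`, `p_value`, `expected`,
#'   `test_name`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(30, 10, 10, 30), 2))$statistic  # 20
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal total", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = expected,
                 test_name = "chi-square test of independence"),
            class = "stat_test")
}

#' Percentile bootstrap of the mean
#'
#' B resamples with replacement of size n; the bootstrap SE is the SD of
#' the replicate means (Bessel-corrected); the 95% CI uses the literal
#' 0.025 x B and 0.975 x B order statistics of the bootstrap distribution
#' (no interpolation). Deterministic given `seed`.
#'
#' @param values Numeric vector (>= 2 values).
#' @param B Number of bootstrap replicates (default 1000; < 100 warns).
#' @param seed Integer seed.
#' @param statistic Statistic to bootstrap (default [mean()]).
#' @return A `bootstrap_summary` list: `point_mean`, `se`, `ci_low`,
#'   `ci_high`, `cv_pct`, `B`, `seed`.
#' @export
#' @examples
#' bootstrap_summary(rnorm(100), B = 200, seed = 1)$se
bootstrap_summary <- function(values, B = 1000, seed = 42,
                              statistic = mean) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (B <= 0) stop("B must be positive", call. = FALSE)
  if (B < 100) warning("B < 100 gives unstable bootstrap quantiles",
                       call. = FALSE)
  n <- length(values)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      statistic(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  sorted <- sort(boot)
  lo_i <- max(1L, round(0.025 * B))
  hi_i <- min(B, round(0.975 * B))
  point <- statistic(values)
  se <- stats::sd(boot)
  structure(list(point_mean = point, se = se,
                 ci_low = sorted[lo_i], ci_high = sorted[hi_i],
                 cv_pct = 100 * se / abs(point), B = as.integer(B),
                 seed = as.integer(seed)),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap (B = %d): mean %.4g, SE %.4g, 95%% CI [%.4g, %.4g], CV %.2f%%\n",
              x$B, x$point_mean, x$se, x$ci_low, x$ci_high, x$cv_pct))
  invisible(x)
}

#' Cost-emissions trade-off regression with elasticity
#'
#' OLS of y on x (e.g. daily cost on daily GHG emissions); the elasticity is
#' slope x mean(x)/mean(y), the percent change in y per percent change in x
#' at sample means.
#'
#' @param x Predictor values (var(x) > 0, >= 3 pairs).
#' @param y Response values.
#' @return A `tradeoff_result` list: `intercept`, `slope`, `elasticity`,
#'   `r2`.
#' @export
#' @examples
#' tradeoff_regression(1:10, 2 * (1:10))$elasticity  # 1
tradeoff_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need >= 3 (x, y) pairs", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  beta <- unname(stats::coef(fit)[2])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::resid(fit)^2) / sst
  structure(list(intercept = unname(stats::coef(fit)[1]), slope = beta,
                 elasticity = beta * mean(x) / mean(y),
                 r2 = r2),
            class = "tradeoff_result")
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with df (K - 1, N - K), computed from the
#' defining sums of squares.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values,
#'   positive pooled within-group variance).
#' @return A `stat_test` list: `statistic` (F), `df` (length-2), `p_value`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))$statistic  # 13.5
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values",
                                     call. = FALSE)
  all_vals <- unlist(groups)
  grand <- mean(all_vals)
  k <- length(groups)
  n <- length(all_vals)
  ss_between <- sum(lengths(groups) *
                      (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  if (ss_within == 0) stop("zero within-group variance", call. = FALSE)
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (n - k)
  f <- ms_between / ms_within
  structure(list(statistic = f, df = c(k - 1, n - k),
                 p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
                 test_name = "one-way ANOVA"),
            class = "stat_test")
}

#' Bonferroni-adjusted significance threshold
#'
#' For K groups there are m = K(K-1)/2 pairwise comparisons; the adjusted
#' threshold is alpha/m.
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param k_groups Number of groups (>= 2).
#' @return List with `m` and `adjusted_alpha`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 4)  # m = 6, adjusted ~0.0083
bonferroni_alpha <- function(alpha, k_groups) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (k_groups < 2) stop("need at least 2 groups", call. = FALSE)
  m <- k_groups * (k_groups - 1) / 2
  list(m = m, adjusted_alpha = alpha / m)
}

#' Pairwise post hoc comparisons across patterns
#'
#' Default: pairwise Welch t-tests at the Bonferroni-adjusted threshold;
#' `method = "tukey"` instead runs Tukey's HSD on a one-way `aov` fit.
#'
#' @param values Numeric response.
#' @param groups Group labels (same length).
#' @param alpha Family-wise level (default 0.05).
#' @param method `"bonferroni"` (pairwise Welch t-tests) or `"tukey"`.
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `estimate` (mean difference), `p_value`, `significant`.
#' @export
pairwise_pattern_tests <- function(values, groups, alpha = 0.05,
                                   method = c("bonferroni", "tukey")) {
  method <- match.arg(method)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  pairs <- utils::combn(lv, 2)
  if (method == "bonferroni") {
    adj <- bonferroni_alpha(alpha, length(lv))$adjusted_alpha
    rows <- apply(pairs, 2, function(pr) {
      tt <- stats::t.test(values[groups == pr[1]], values[groups == pr[2]])
      data.frame(group1 = pr[1], group2 = pr[2],
                 estimate = unname(diff(rev(tt$estimate))),
                 p_value = tt$p.value, significant = tt$p.value < adj)
    })
    out <- do.call(rbind, rows)
    attr(out, "adjusted_alpha") <- adj
  } else {
    fit <- stats::aov(values ~ factor(groups))
    th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)[[1]]
    out <- data.frame(
      group1 = sub("-.*", "", rownames(th)),
      group2 = sub(".*-", "", rownames(th)),
      estimate = th[, "diff"], p_value = th[, "p adj"],
      significant = th[, "p adj"] < alpha, row.names = NULL)
  }
  out
}
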
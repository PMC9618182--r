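test_that("regression validation matches the closed-form least-squares fit", {
  pairs <- simulate_validation_panel(6, slope = 1, noise_sd = 0.1,
                                     seed = 7)
  res <- regression_validation(pairs)
  x <- pairs$proteomics_ratio
  y <- pairs$orthogonal_ratio
  # closed-form oracle
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(res$slope, b, tolerance = 1e-12)
  expect_equal(res$intercept, a, tolerance = 1e-12)
  expect_equal(res$r_squared, r2, tolerance = 1e-12)
  expect_equal(res$r_squared, cor(x, y)^2, tolerance = 1e-12)

  collinear <- data.frame(proteomics_ratio = c(0.5, 1, 2),
                          orthogonal_ratio = c(1, 2, 4))
  expect_equal(suppressWarnings(regression_validation(collinear))$r_squared,
               1.0)
  expect_error(regression_validation(
    data.frame(proteomics_ratio = 1:2, orthogonal_ratio = 1:2)),
    "at least 3")
  expect_error(regression_validation(
    data.frame(proteomics_ratio = c(1, 1, 1),
               orthogonal_ratio = c(1, 2, 3))), "zero variance")
})

test_that("R^2 is invariant to affine rescaling of either axis", {
  pairs <- simulate_validation_panel(8, slope = 0.9, noise_sd = 0.2,
                                     seed = 12)
  r2 <- regression_validation(pairs)$r_squared
  scaled <- data.frame(proteomics_ratio = 3 * pairs$proteomics_ratio - 1,
                       orthogonal_ratio = -2 * pairs$orthogonal_ratio + 5)
  expect_equal(regression_validation(scaled)$r_squared, r2,
               tolerance = 1e-12)
})

test_that("summary t-test equals a raw-data t-test fed its own summaries", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(3:15, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:15, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    sx <- summary_stats(mean(x), sd(x), length(x))
    sy <- summary_stats(mean(y), sd(y), length(y))

    student <- summary_ttest(sx, sy, welch = FALSE)
    ref_s <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(student$t, unname(ref_s$statistic), tolerance = 1e-10)
    expect_equal(student$p_value, ref_s$p.value, tolerance = 1e-10)

    welch <- summary_ttest(sx, sy, welch = TRUE)
    ref_w <- stats::t.test(x, y)
    expect_equal(welch$t, unname(ref_w$statistic), tolerance = 1e-10)
    expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-10)
    expect_equal(welch$p_value, ref_w$p.value, tolerance = 1e-10)
  }
})

test_that("cognitive-score group contrast from printed summaries is significant", {
  # ECAS-style summaries: 117 +/- 5 (n=9) vs 99 +/- 11 (n=9)
  res <- summary_ttest(summary_stats(117, 5, 9), summary_stats(99, 11, 9))
  expect_equal(res$t, 4.469072, tolerance = 1e-6)
  expect_equal(res$df, 16)
  expect_equal(res$p_value, 0.000387566, tolerance = 1e-4)
  # consistent with a printed two-tailed p of 0.0005 given rounded inputs
  expect_lt(res$p_value, 0.001)
})

test_that("summary t-test degenerate and monotonicity behaviour", {
  same <- summary_ttest(summary_stats(5, 0, 4), summary_stats(5, 0, 4))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  idn <- summary_ttest(summary_stats(10, 2, 5), summary_stats(10, 2, 5))
  expect_equal(idn$t, 0)
  expect_equal(idn$p_value, 1)

  p1 <- summary_ttest(summary_stats(10, 3, 6), summary_stats(12, 3, 6))
  p2 <- summary_ttest(summary_stats(10, 3, 12), summary_stats(12, 3, 12))
  expect_lt(p2$p_value, p1$p_value)

  expect_error(summary_stats(1, -1, 5), "sd")
  expect_error(summary_stats(1, 1, 1), "n must be")
})
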
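test_that("ICC matches the hand-computed ANOVA oracle", {
  # rows (8,9), (4,5), (2,3): MS_R = 18.667, MS_C = 1.5, MS_E = 0
  # ICC(A,k) = 18.667 / (18.667 + 1.5/3) = 0.974
  tab <- matrix(c(8, 9, 4, 5, 2, 3), 3, 2, byrow = TRUE)
  icc <- icc_agreement(tab)
  expect_equal(icc$estimate, 0.974, tolerance = 5e-4)
  expect_equal(icc$estimate, (56 / 3) / (56 / 3 + 1 / 2), tolerance = 1e-12)
})

test_that("ICC agrees with a brute-force aov variance decomposition", {
  withr::with_seed(42, {
    for (r in 1:10) {
      tab <- matrix(stats::rnorm(15, 10, 2), 5, 3)
      icc <- icc_agreement(tab)$estimate
      df <- data.frame(v = as.numeric(tab),
                       s = factor(rep(1:5, 3)),
                       k = factor(rep(1:3, each = 5)))
      a <- stats::anova(stats::aov(v ~ s + k, data = df))
      MSR <- a["s", "Mean Sq"]; MSC <- a["k", "Mean Sq"]
      MSE <- a["Residuals", "Mean Sq"]
      oracle <- (MSR - MSE) / (MSR + (MSC - MSE) / 5)
      expect_equal(icc, oracle, tolerance = 1e-10)
    }
  })
})

test_that("ICC limiting cases and invariances hold", {
  # identical columns with row variance: perfect agreement
  tab <- matrix(rep(c(10, 20, 30), 3), 3, 3)
  expect_equal(icc_agreement(tab)$estimate, 1)
  # permuting subjects changes nothing
  t2 <- matrix(stats::rnorm(21, 50, 5), 7, 3)
  expect_equal(icc_agreement(t2)$estimate,
               icc_agreement(t2[sample(7), ])$estimate, tolerance = 1e-12)
  expect_error(icc_agreement(matrix(5, 4, 3)), "zero total variance")
  expect_error(icc_agreement(matrix(1:4, 2, 2)), "3 subjects")
  tm <- matrix(stats::rnorm(9), 3, 3); tm[1, 1] <- NA
  expect_error(icc_agreement(tm), "complete")
})

test_that("ICC point estimate lies inside its confidence interval", {
  withr::with_seed(11, {
    tab <- 100 * matrix(exp(stats::rnorm(21, 0, 0.1)), 7, 3) *
      (1 + stats::rnorm(21, 0, 0.02))
    icc <- icc_agreement(tab)
    expect_lte(icc$ci_low, icc$estimate)
    expect_gte(icc$ci_high, icc$estimate)
    expect_gte(icc$ci_low, -1)
    expect_lte(icc$ci_high, 1)
  })
})

test_that("ICC decreases as within-session noise grows", {
  med_icc <- function(wcv) {
    vals <- vapply(1:120, function(r) {
      tab <- generate_repeat_sessions(100, k = 3, within_cv = wcv,
                                      n_subjects = 10, between_cv = 0.08,
                                      seed = 7000 + r)
      icc_agreement(tab)$estimate
    }, numeric(1))
    stats::median(vals)
  }
  m <- vapply(c(0.01, 0.05, 0.15), med_icc, numeric(1))
  expect_true(all(diff(m) < 0))
  expect_gt(m[1], 0.95)
})

test_that("Lin's concordance matches its closed form", {
  expect_equal(lin_ccc(1:10, 1:10)$estimate, 1)
  # hand evaluation: s_xy = 4/3, s_x2 = 2/3, s_y2 = 8/3, (dx)^2 = 4
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 4, 6))$estimate, 8 / 22)
  x <- c(-2, 0, 2, -1, 1)
  expect_equal(lin_ccc(x, -x)$estimate, -1)
  expect_error(lin_ccc(rep(1, 5), rep(2, 5)), "constant")
})

test_that("LCC never exceeds Pearson correlation in magnitude", {
  withr::with_seed(3, {
    for (r in 1:20) {
      x <- stats::rnorm(30, 10, 2)
      y <- 0.8 * x + stats::rnorm(30, sample(0:5, 1), 1)
      l <- lin_ccc(x, y)$estimate
      expect_lte(abs(l), abs(stats::cor(x, y)) + 1e-12)
    }
    # equality when location and scale match exactly
    x <- stats::rnorm(50)
    expect_equal(lin_ccc(x, x)$estimate, 1)
  })
})

test_that("LCC interval behaves like a confidence interval", {
  withr::with_seed(8, {
    x <- stats::rnorm(100, 50, 10)
    y <- x * (1 + stats::rnorm(100, 0, 0.05))
    l <- lin_ccc(x, y)
    expect_lt(l$ci_low, l$estimate)
    expect_gt(l$ci_high, l$estimate)
    expect_lt(l$ci_high, 1)
  })
})

test_that("normalized SD is scale-free and exact in limiting cases", {
  tab <- matrix(rep(c(10, 20, 30), 3), 3, 3)
  expect_equal(normalized_sd(tab), 0)
  t2 <- generate_repeat_sessions(50, k = 3, within_cv = 0.05,
                                 n_subjects = 20, between_cv = 0.1, seed = 4)
  expect_equal(normalized_sd(t2), normalized_sd(t2 * 10), tolerance = 1e-12)
  expect_error(normalized_sd(matrix(c(0, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE)),
               "zero subject mean")
})

test_that("reliability labels follow the interpretation thresholds", {
  tabs <- list(
    excellent = generate_repeat_sessions(100, 3, 0.005, 10, 0.2, seed = 1))
  expect_equal(icc_agreement(tabs$excellent)$label, "excellent")
  expect_equal(aomosaic:::reliability_label(0.3), "poor")
  expect_equal(aomosaic:::reliability_label(0.6), "moderate")
  expect_equal(aomosaic:::reliability_label(0.8), "good")
})
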
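test_that("each model family recovers noiseless coefficients exactly", {
  E <- 0:12
  fl <- fit_topography(E, 6913 - 123 * E, "linear")
  expect_equal(unname(fl$coefficients), c(6913, -123), tolerance = 1e-10)
  expect_equal(fl$r2_pearson, 1)

  E1 <- 1:12
  fp <- fit_topography(E1, 53329 * E1^-0.731, "power")
  expect_equal(fp$coefficients[["a"]], 53329, tolerance = 1e-4)
  expect_equal(fp$coefficients[["b"]], -0.731, tolerance = 1e-4)
  expect_equal(fp$r2_pearson, 1, tolerance = 1e-10)

  md <- default_topography_models()$osl
  fq <- fit_topography(E1, eval_topography_model("osl", E1), "poly2")
  expect_equal(unname(fq$coefficients), unname(md), tolerance = 1e-8)
})

test_that("power-law exponent is invariant to scaling of the response", {
  E <- 1:10
  y <- 200 * E^-0.6 * exp(stats::rnorm(10, 0, 0.02))
  f1 <- fit_topography(E, y, "power")
  f2 <- fit_topography(E, 7 * y, "power")
  expect_equal(f1$coefficients[["b"]], f2$coefficients[["b"]],
               tolerance = 1e-6)
  expect_equal(f2$coefficients[["a"]] / f1$coefficients[["a"]], 7,
               tolerance = 1e-6)
})

test_that("degenerate and invalid fits are handled explicitly", {
  fc <- fit_topography(1:6, rep(5, 6), "linear")
  expect_true(fc$degenerate)
  expect_equal(fc$coefficients[["slope"]], 0)
  expect_true(is.na(fc$r2_pearson))
  expect_error(fit_topography(1:2, c(1, 2), "linear"), "at least")
  expect_error(fit_topography(1:3, c(1, 2, 3), "poly2"), "at least")
  expect_error(fit_topography(0:4, c(1, 2, 3, 4, 5), "power"), "positive")
  expect_error(fit_topography(rep(2, 5), 1:5, "linear"), "rank")
})

test_that("predictions invert the fitted models", {
  E <- 1:12
  f <- fit_topography(E, 50 * E^-0.7, "power")
  expect_equal(predict(f, E), 50 * E^-0.7, tolerance = 1e-6)
})

test_that("PR/RPE ratio arithmetic matches the printed values", {
  expect_equal(round(pr_rpe_ratio(53329, 7335), 1), 7.3)
  expect_equal(round(pr_rpe_ratio(8669, 5547), 2), 1.56)
  expect_equal(pr_rpe_ratio(5000, 5000), 1)
  expect_error(pr_rpe_ratio(100, 0), "positive")
})

test_that("topography tables summarize and fit the cohort means", {
  md <- default_topography_models()
  sp <- cohort_spec(n_subjects = 5, eccentricities_deg = 0:12,
                    between_subject_cv = c(cone = 0, rpe = 0, osl = 0))
  tr <- generate_cohort(sp)$truth
  roi <- data.frame(subject = tr$subject, eccentricity_deg = tr$eccentricity_deg,
                    pr_density = tr$cone_density, rpe_density = tr$rpe_density,
                    osl_mean = tr$osl_um)
  topo <- build_topography_table(roi)
  # zero-noise cohort: fits reproduce the generator models exactly
  expect_equal(topo$fits$rpe_density$coefficients[["slope"]], -123,
               tolerance = 1e-8)
  expect_equal(topo$fits$pr_density$coefficients[["b"]], md$cone[["b"]],
               tolerance = 1e-4)
  expect_equal(unname(topo$fits$osl$coefficients), unname(md$osl),
               tolerance = 1e-6)
  # mean-of-ratios and ratio-of-means agree when between-subject CV is 0
  mor <- topo$table[topo$table$metric == "pr_rpe_ratio", ]
  rom <- topo$ratio_of_means
  expect_equal(mor$mean[mor$eccentricity_deg >= 1], rom$ratio_of_means,
               tolerance = 1e-10)
  # subject order is irrelevant
  topo2 <- build_topography_table(roi[sample(nrow(roi)), ])
  expect_equal(topo2$fits$rpe_density$coefficients,
               topo$fits$rpe_density$coefficients)
  expect_equal(topo2$table, topo$table)
})

test_that("topography table validates its inputs", {
  roi <- data.frame(subject = 1, eccentricity_deg = 0:12,
                    rpe_density = 6913 - 123 * (0:12))
  expect_error(build_topography_table(roi), "2 subjects")
  roi2 <- data.frame(subject = rep(1:2, 2), eccentricity_deg = rep(1:2, 2),
                     rpe_density = 1:4)
  expect_error(build_topography_table(roi2), "4 eccentricities")
})
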
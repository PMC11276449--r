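test_that("default models hit the printed normative endpoints", {
  md <- default_topography_models()
  expect_equal(eval_topography_model("cone", 1, md), 53329)
  expect_equal(eval_topography_model("cone", 12, md), 8669, tolerance = 0.001)
  expect_equal(eval_topography_model("rpe", 0, md), 6913)
  expect_equal(eval_topography_model("rpe", 12, md), 6913 - 123 * 12)
  expect_equal(eval_topography_model("osl", 1, md), 33.3)
  expect_equal(eval_topography_model("osl", 12, md), 18.0)
  # monotone decrease of OSL over the quantified range
  osl <- eval_topography_model("osl", seq(1, 12, 0.25), md)
  expect_true(all(diff(osl) < 0))
})

test_that("cohort generation honors the spec and is reproducible", {
  sp <- cohort_spec(n_subjects = 4, eccentricities_deg = c(0, 1, 6, 12),
                    seed = 5)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$truth, c2$truth)
  expect_equal(nrow(c1$truth), 16)
  # cones and OSL undefined at the fovea, RPE defined everywhere
  expect_true(all(is.na(c1$truth$cone_density[c1$truth$eccentricity_deg == 0])))
  expect_true(all(is.finite(c1$truth$rpe_density)))
})

test_that("zero between-subject CV collapses subjects onto the model", {
  sp <- cohort_spec(n_subjects = 3, eccentricities_deg = 1:4,
                    between_subject_cv = c(cone = 0, rpe = 0, osl = 0))
  tr <- generate_cohort(sp)$truth
  md <- default_topography_models()
  expect_equal(tr$cone_density,
               eval_topography_model("cone", tr$eccentricity_deg, md))
  expect_equal(tr$rpe_density,
               eval_topography_model("rpe", tr$eccentricity_deg, md))
  # printed 12-degree endpoints under the default models
  sp12 <- cohort_spec(n_subjects = 2, eccentricities_deg = c(1, 12),
                      between_subject_cv = c(cone = 0, rpe = 0, osl = 0))
  tr12 <- generate_cohort(sp12)$truth
  expect_equal(unique(tr12$rpe_density[tr12$eccentricity_deg == 12]), 5437)
  expect_equal(unique(tr12$cone_density[tr12$eccentricity_deg == 12]), 8669,
               tolerance = 0.001)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(cone_model = c(a = 100, b = 0.5)), "negative")
  expect_error(cohort_spec(rpe_model = c(intercept = 100, slope = 1)),
               "negative")
  expect_error(cohort_spec(n_subjects = 0))
  expect_error(cohort_spec(eccentricities_deg = numeric(0)))
})

test_that("subject effects are lognormal with the requested spread", {
  sp <- cohort_spec(n_subjects = 2000, eccentricities_deg = 1,
                    between_subject_cv = c(cone = 0.10, rpe = 0.08, osl = 0.07),
                    seed = 9)
  ef <- generate_cohort(sp)$subject_effects
  expect_equal(mean(ef$cone), 1, tolerance = 0.01)
  expect_equal(stats::sd(ef$cone), 0.10, tolerance = 0.1)
  expect_equal(stats::sd(ef$osl), 0.07, tolerance = 0.1)
})

test_that("repeat-session tables have the generated noise structure", {
  t1 <- generate_repeat_sessions(100, k = 3, within_cv = 0, n_subjects = 5,
                                 between_cv = 0.1, seed = 2)
  # zero within-session CV: identical sessions per subject
  expect_equal(t1[, 1], t1[, 2])
  expect_equal(t1[, 1], t1[, 3])
  expect_identical(t1, generate_repeat_sessions(100, k = 3, within_cv = 0,
                                                n_subjects = 5,
                                                between_cv = 0.1, seed = 2))
  # normalized SD recovers the generating within-session CV at large n
  t2 <- generate_repeat_sessions(100, k = 25, within_cv = 0.016,
                                 n_subjects = 400, between_cv = 0.1, seed = 3)
  expect_equal(normalized_sd(t2), 0.016, tolerance = 0.0625)  # +-0.001
  expect_error(generate_repeat_sessions(100, k = 1, within_cv = 0.1))
})

test_that("ground truth round-trips losslessly through disk", {
  sp <- cohort_spec(n_subjects = 3, eccentricities_deg = c(0, 1, 6, 12),
                    seed = 11)
  co <- generate_cohort(sp)
  dir <- file.path(tempdir(), "gt-roundtrip")
  write_ground_truth(co, dir)
  back <- read_ground_truth(dir)
  expect_equal(back$truth, co$truth)
  expect_equal(back$spec$cone_model, sp$cone_model)
  expect_equal(back$spec$seed, sp$seed)
})
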
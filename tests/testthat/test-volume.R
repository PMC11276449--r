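test_that("volume averaging reduces speckle as 1/sqrt(N)", {
  m <- generate_mosaic(20000, 64, seed = 5)
  clean <- render_volume(m, osl_um = 25, noise_cv = 0)
  noisy <- lapply(1:25, function(i) {
    render_volume(m, osl_um = 25, noise_cv = 0.3, seed = 100 + i)
  })
  expect_identical(average_volumes(noisy[1])$intensity, noisy[[1]]$intensity)
  expect_identical(average_volumes(list(clean, clean))$intensity,
                   clean$intensity)
  r5 <- stats::sd(average_volumes(noisy[1:5])$intensity - clean$intensity)
  r25 <- stats::sd(average_volumes(noisy)$intensity - clean$intensity)
  expect_equal(r5 / r25, sqrt(5), tolerance = 0.1)
  short <- noisy[[1]]
  short$intensity <- short$intensity[, 1:10, ]
  expect_error(average_volumes(list(noisy[[1]], short)), "match")
})

test_that("flattening recovers a known tilt and inverts cleanly", {
  m <- generate_mosaic(20000, 80, seed = 5)
  vol <- render_volume(m, osl_um = 25, noise_cv = 0.1, seed = 6,
                       tilt_um = function(y, x) 10 * x / 80)
  fl <- flatten_volume(vol)
  expect_equal(sum(fl$flagged), 0)
  nx <- dim(vol$intensity)[3]
  xs <- (seq_len(nx) - 0.5) * 80 / nx
  true_tilt <- 10 * xs / 80
  rec <- -as.numeric(fl$shift_px[40, ])
  err <- rec - (true_tilt - stats::median(true_tilt))
  expect_lt(max(abs(err)), 1.5)  # integer shifts quantize to +-0.5 px

  # flatten then unflatten is the identity away from the z boundary
  unf <- apply_axial_shifts(fl$volume, -fl$shift_px)
  nz <- dim(vol$intensity)[1]
  expect_equal(unf$intensity[15:(nz - 15), , ],
               vol$intensity[15:(nz - 15), , ])

  # an already-flat volume needs (almost) no shifting
  fl0 <- flatten_volume(render_volume(m, osl_um = 25, noise_cv = 0, seed = 6))
  expect_lte(max(abs(fl0$shift_px)), 1)
})

test_that("layer segmentation finds ISOS < COST < RPE", {
  m <- generate_mosaic(20000, 80, seed = 5)
  vol <- render_volume(m, osl_um = 25, isos_depth_um = 40, noise_cv = 0,
                       seed = 6)
  seg <- segment_layers(vol)
  expect_lt(seg$isos, seg$cost)
  expect_lt(seg$cost, seg$rpe)
  expect_equal(seg$isos, 40, tolerance = 2)
  expect_equal(seg$cost, 65, tolerance = 2)
  expect_equal(seg$rpe, 80, tolerance = 2)
})

test_that("slab extraction projects the intended layer", {
  m <- generate_mosaic(20000, 80, seed = 5)
  vol <- render_volume(m, osl_um = 25, noise_cv = 0, seed = 6)
  seg <- segment_layers(vol)
  # single-slice extraction equals the raw slice
  s0 <- extract_enface(vol, seg, "RPE", slab_px = 0)
  raw <- vol$intensity[seg$rpe, , ]
  expect_equal(s0$intensity, raw / max(raw))
  # RPE slab of a texture-free band is laterally uniform away from cones
  expect_lt(stats::sd(s0$intensity), 0.2)
  # cone slab round-trips through the detector
  img <- extract_enface(vol, seg, "ISOS+COST", slab_px = 1)
  mp <- match_points(detect_cells(img, hex_spacing_um(20000)), m$points,
                     tol_um = 2)
  expect_gte(mp$recall, 0.98)
  # slab clipped at the volume boundary is flagged
  segc <- list(isos = 2, cost = seg$cost, rpe = seg$rpe)
  expect_true(attr(extract_enface(vol, segc, "ISOS", slab_px = 5), "clipped"))
})

test_that("OSL equals the separation of two constructed peaks", {
  z <- (1:100) - 0.5
  a <- exp(-(z - 40)^2 / (2 * 1.5^2)) + exp(-(z - 50)^2 / (2 * 1.5^2))
  vol <- ao_volume(array(rep(a, 9), dim = c(100, 3, 3)), 1, 1)
  rec <- measure_osl(vol, data.frame(x_um = 1.5, y_um = 1.5),
                     search_window_px = c(1, 70))
  expect_true(rec$valid)
  expect_equal(rec$osl_um, 10, tolerance = 1e-3)
  # translation invariance: same profile shifted 7 px deeper
  a7 <- c(rep(0, 7), a[1:93])
  vol7 <- ao_volume(array(rep(a7, 9), dim = c(100, 3, 3)), 1, 1)
  rec7 <- measure_osl(vol7, data.frame(x_um = 1.5, y_um = 1.5),
                      search_window_px = c(1, 77))
  expect_equal(rec7$osl_um, rec$osl_um, tolerance = 1e-6)
})

test_that("single-peak columns are flagged invalid, not dropped", {
  z <- (1:80) - 0.5
  a <- exp(-(z - 40)^2 / (2 * 2^2))
  vol <- ao_volume(array(rep(a, 9), dim = c(80, 3, 3)), 1, 1)
  rec <- measure_osl(vol, data.frame(x_um = 1.5, y_um = 1.5),
                     search_window_px = c(1, 80))
  expect_equal(nrow(rec), 1)
  expect_false(rec$valid)
})

test_that("OSL recovery is unbiased within 0.2 um on rendered volumes", {
  m <- generate_mosaic(20000, 100, seed = 9)
  vol <- render_volume(m, osl_um = 28, osl_sd_um = 2, axial_pixel_um = 1,
                       noise_cv = 0.15, seed = 10)
  gt <- attr(vol, "ground_truth")$cones
  rec <- measure_osl(vol, m$points)
  ok <- rec$valid
  expect_gte(mean(ok), 0.95)
  expect_lt(abs(mean(rec$osl_um[ok] - gt$osl_um[ok])), 0.2)
  # per-cone records agree with their own truth, not just on average
  expect_lt(stats::median(abs(rec$osl_um[ok] - gt$osl_um[ok])), 1.5)
})

test_that("parabolic refinement beats integer argmax on subpixel peaks", {
  offsets <- seq(-0.4, 0.4, 0.1)
  z <- (1:60) - 0.5
  err_ref <- err_int <- numeric(length(offsets))
  for (i in seq_along(offsets)) {
    true_sep <- 20 + offsets[i]
    a <- exp(-(z - 20)^2 / (2 * 2^2)) + exp(-(z - 20 - true_sep)^2 / (2 * 2^2))
    vol <- ao_volume(array(rep(a, 9), dim = c(60, 3, 3)), 1, 1)
    rec <- measure_osl(vol, data.frame(x_um = 1.5, y_um = 1.5),
                       search_window_px = c(1, 60))
    err_ref[i] <- rec$osl_um - true_sep
    pk <- sort(order(a, decreasing = TRUE)[1:2])
    err_int[i] <- abs(diff(z[pk])) - true_sep
  }
  expect_lt(sqrt(mean(err_ref^2)), sqrt(mean(err_int^2)))
  expect_lt(sqrt(mean(err_ref^2)), 0.1)
})

test_that("volume geometry violating the layer order is rejected", {
  m <- generate_mosaic(20000, 64, seed = 5)
  expect_error(render_volume(m, osl_um = 30, isos_depth_um = 40,
                             rpe_depth_um = 60), "layer order")
})

test_that("OSL summaries flag bimodal distributions", {
  uni <- data.frame(osl_um = stats::rnorm(300, 30, 1.5), valid = TRUE)
  bi <- data.frame(osl_um = c(stats::rnorm(150, 24, 1), stats::rnorm(150, 34, 1)),
                   valid = TRUE)
  expect_false(osl_summary(uni)$bimodal)
  expect_true(osl_summary(bi)$bimodal)
  expect_equal(osl_summary(uni)$n_invalid, 0)
})
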
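test_that("lattice spacing matches the hexagonal density relation", {
  # D = 2 / (sqrt(3) a^2): spacing 10 um <-> 11547 cells/mm^2
  expect_equal(hex_spacing_um(11547), 10, tolerance = 1e-4)
  m <- generate_mosaic(11547, 200, jitter_frac = 0, seed = 1)
  nn <- aomosaic:::nn_distances(m$points$x_um, m$points$y_um)
  expect_equal(mean(nn), 10, tolerance = 1e-6)
})

test_that("mosaic generation is a pure function of parameters and seed", {
  m1 <- generate_mosaic(20000, 150, seed = 42)
  m2 <- generate_mosaic(20000, 150, seed = 42)
  expect_identical(m1$points, m2$points)
  m3 <- generate_mosaic(20000, 150, seed = 43)
  expect_false(identical(m1$points, m3$points))
  # generator must not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_mosaic(20000, 150, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("realized density and count track the request", {
  m <- generate_mosaic(53329, 250, seed = 3)
  expect_equal(nrow(m$points), 53329 * 0.0625, tolerance = 0.03)
  # interior density within 3% on a 0.25 x 0.25 mm window
  vm <- voronoi_metrics(m)
  expect_equal(vm$density_cells_mm2, 53329, tolerance = 0.03)
  expect_error(generate_mosaic(100, 100), "window too small")
})

test_that("jittered mosaics keep near-lattice neighbor structure", {
  # the mean Voronoi-adjacent spacing stays at the lattice constant; the
  # nearest-neighbor mean sits below it by the order statistics of the
  # jitter but never under the hard-core separation
  for (jf in c(0.05, 0.10, 0.15)) {
    m <- generate_mosaic(15000, 300, jitter_frac = jf, seed = round(100 * jf))
    nn <- aomosaic:::nn_distances(m$points$x_um, m$points$y_um)
    expect_gte(min(nn), 0.5 * m$spacing_um - 1e-9)
    expect_gt(mean(nn), 0.7 * m$spacing_um)
    expect_lt(mean(nn), m$spacing_um)
    vm <- voronoi_metrics(m)
    expect_equal(vm$mean_spacing_um, m$spacing_um, tolerance = 0.05)
  }
})

test_that("vessel masks have the requested geometry", {
  m0 <- generate_vessel_mask(200, 0, 10, seed = 1)
  expect_false(any(m0))
  expect_equal(attr(m0, "excluded_fraction"), 0)
  # one straight band of width w across a square window of side L
  # excludes approximately w/L of the area
  m1 <- generate_vessel_mask(250, 1, 12, seed = 5, curvature_sd = 0)
  expect_equal(attr(m1, "excluded_fraction"), 12 / 250, tolerance = 0.15)
  expect_identical(m1, generate_vessel_mask(250, 1, 12, seed = 5,
                                            curvature_sd = 0))
  expect_error(generate_vessel_mask(100, 1, 150, seed = 1))
})

test_that("rendered spots peak at their generating cells", {
  one <- structure(
    list(points = data.frame(id = 1, x_um = 25.5, y_um = 40.5),
         cell_class = "cone", window = c(0, 64, 0, 64), pixel_size_um = 1,
         vessel_mask = NULL, eccentricity_deg = 0, spacing_um = 10),
    class = "cell_mosaic")
  img <- render_enface(one, spot_fwhm_um = 4)
  pk <- which(img$intensity == max(img$intensity), arr.ind = TRUE)
  # pixel (r, c) has center ((c - 0.5), (r - 0.5)) um
  expect_true(abs(pk[1, "col"] - 0.5 - 25.5) <= 1)
  expect_true(abs(pk[1, "row"] - 0.5 - 40.5) <= 1)

  m <- generate_mosaic(15000, 128, seed = 2)
  img <- render_enface(m)
  expect_true(all(img$intensity >= 0 & img$intensity <= 1))
  # every spot's local peak within 1 px of its point (noiseless render)
  px <- img$pixel_size_um
  ok <- vapply(seq_len(nrow(m$points)), function(i) {
    c0 <- round(m$points$x_um[i] / px + 0.5)
    r0 <- round(m$points$y_um[i] / px + 0.5)
    rr <- max(1, r0 - 2):min(nrow(img$intensity), r0 + 2)
    cc <- max(1, c0 - 2):min(ncol(img$intensity), c0 + 2)
    pk <- which(img$intensity[rr, cc] == max(img$intensity[rr, cc]),
                arr.ind = TRUE)
    max(abs(pk[1, ] - c(r0 - rr[1] + 1, c0 - cc[1] + 1))) <= 1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("render warns on coarse rasters and rejects oversize spots", {
  m <- generate_mosaic(15000, 128, seed = 2)
  m$pixel_size_um <- 4
  expect_warning(render_enface(m, spot_fwhm_um = 3.5), "coarser")
  expect_error(render_enface(m, spot_fwhm_um = 3 * m$spacing_um), "twice")
})

test_that("speckle noise is multiplicative and seeded", {
  m <- generate_mosaic(15000, 128, seed = 2)
  i1 <- render_enface(m, noise_cv = 0.2, seed = 9)
  i2 <- render_enface(m, noise_cv = 0.2, seed = 9)
  expect_identical(i1$intensity, i2$intensity)
  i3 <- render_enface(m, noise_cv = 0.2, seed = 10)
  expect_false(identical(i1$intensity, i3$intensity))
  clean <- render_enface(m)
  # zero-intensity background stays zero under multiplicative speckle
  expect_true(all(i1$intensity[clean$intensity == 0] == 0))
})
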
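test_that("square grid metrics match brute-force geometry", {
  # 5x5 grid spacing 10 um: 9 interior cells of 100 um^2, spacing 10 um
  vm <- voronoi_metrics(grid_points(5, 10), window = c(0, 40, 0, 40))
  expect_equal(vm$n_cells_counted, 9)
  expect_equal(vm$mean_cell_area_um2, 100)
  expect_equal(vm$density_cells_mm2, 10000)
  expect_equal(vm$mean_spacing_um, 10)
  expect_equal(vm$analyzed_area_mm2, 9e-4)
  # boundary cells flagged, not counted
  expect_equal(sum(vm$cells$boundary), 16)
})

test_that("interior square-grid cells have rook adjacency only", {
  vm <- voronoi_metrics(grid_points(5, 10), window = c(0, 40, 0, 40))
  inner <- vm$cells[vm$cells$included, ]
  center <- inner[abs(inner$x_um - 20) < 1e-9 & abs(inner$y_um - 20) < 1e-9, ]
  expect_equal(center$n_neighbors, 4)
})

test_that("hexagonal mosaic density matches the analytic lattice value", {
  m <- generate_mosaic(11547, 400, jitter_frac = 0, seed = 2)
  vm <- voronoi_metrics(m)
  expect_equal(vm$density_cells_mm2, 11547, tolerance = 0.01)
  expect_equal(vm$mean_spacing_um, 10, tolerance = 0.01)
  expect_equal(vm$mean_cell_area_um2, sqrt(3) / 2 * 100, tolerance = 0.01)
})

test_that("density is intensive: vessel masking halves counts, not density", {
  m <- generate_mosaic(20000, 250, seed = 6)
  base <- voronoi_metrics(m)
  half <- matrix(FALSE, 250, 250)
  half[, 1:125] <- TRUE
  masked <- voronoi_metrics(m, vessel_mask = half, mask_pixel_size_um = 1)
  expect_equal(masked$density_cells_mm2, base$density_cells_mm2,
               tolerance = 0.03)
  expect_equal(masked$n_cells_counted / base$n_cells_counted, 0.5,
               tolerance = 0.1)
})

test_that("metrics are invariant to translation and rotation", {
  m <- generate_mosaic(15000, 250, seed = 8)
  base <- voronoi_metrics(m)
  shifted <- m
  shifted$points$x_um <- m$points$x_um + 1000
  shifted$points$y_um <- m$points$y_um - 500
  shifted$window <- m$window + c(1000, 1000, -500, -500)
  tr <- voronoi_metrics(shifted)
  expect_equal(tr$density_cells_mm2, base$density_cells_mm2, tolerance = 1e-9)
  # rigid rotation of the point set about the window center (fresh window)
  th <- 0.3
  cx <- 125; cy <- 125
  xr <- cx + (m$points$x_um - cx) * cos(th) - (m$points$y_um - cy) * sin(th)
  yr <- cy + (m$points$x_um - cx) * sin(th) + (m$points$y_um - cy) * cos(th)
  keep <- xr > 0 & xr < 250 & yr > 0 & yr < 250
  rot <- voronoi_metrics(data.frame(x_um = xr[keep], y_um = yr[keep]),
                         window = c(0, 250, 0, 250))
  expect_equal(rot$density_cells_mm2, base$density_cells_mm2,
               tolerance = 0.01)
})

test_that("jittered mosaics keep spacing near sqrt(2/(sqrt(3) D))", {
  for (jf in c(0.05, 0.15)) {
    m <- generate_mosaic(25000, 250, jitter_frac = jf, seed = round(jf * 1e3))
    vm <- voronoi_metrics(m)
    expect_equal(vm$mean_spacing_um, sqrt(2 / (sqrt(3) * 25000e-6)),
                 tolerance = 0.05)
  }
})

test_that("degenerate inputs raise informative errors", {
  expect_error(voronoi_metrics(grid_points(3, 10), window = c(0, 20, 0, 20)),
               "fewer than 10")
  line <- data.frame(x_um = seq(5, 95, length.out = 12), y_um = rep(50, 12))
  expect_error(voronoi_metrics(line, window = c(0, 100, 0, 100)), "collinear")
  dup <- grid_points(4, 10)
  dup[16, ] <- dup[1, ]
  expect_error(voronoi_metrics(dup, window = c(0, 30, 0, 30)), "duplicate")
})
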
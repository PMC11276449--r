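#' Voronoi tessellation metrics for a cell mosaic
#'
#' Tessellates the cell centers, excludes cells whose polygon touches the
#' window boundary or intersects the vessel mask, and summarizes the mosaic:
#' density (included cells over summed included polygon area), mean cell
#' area, and cell-to-cell spacing over Voronoi-adjacent included pairs.
#' Using the summed polygon area, rather than the window area, as the
#' denominator removes the bias from partially observed boundary cells.
#'
#' @param mosaic A `cell_mosaic`, or a data.frame with `x_um`, `y_um`
#'   columns (then `window` must be given).
#' @param window Analysis window in um; defaults to the mosaic's window.
#' @param vessel_mask Optional logical raster (TRUE = excluded); defaults to
#'   the mosaic's mask.
#' @param mask_pixel_size_um Raster scale of `vessel_mask` when it is passed
#'   as a bare matrix.
#' @return A `mosaic_metrics` object: list with `density_cells_mm2`,
#'   `mean_cell_area_um2`, `mean_spacing_um`, `n_cells_counted`,
#'   `analyzed_area_mm2`, and `cells`, a per-cell data.frame
#'   (id, x_um, y_um, area_um2, n_neighbors, boundary, vessel, included).
#' @export
voronoi_metrics <- function(mosaic, window = NULL, vessel_mask = NULL,
                            mask_pixel_size_um = 1) {
  if (inherits(mosaic, "cell_mosaic")) {
    pts <- mosaic$points
    if (is.null(window)) window <- mosaic$window
    if (is.null(vessel_mask)) {
      vessel_mask <- mosaic$vessel_mask
      if (!is.null(vessel_mask)) {
        mask_pixel_size_um <- attr(vessel_mask, "pixel_size_um") %||% mask_pixel_size_um
      }
    }
  } else if (inherits(mosaic, "detection_result")) {
    pts <- mosaic$points
    if (is.null(window)) stop("window must be supplied for detection results")
  } else {
    pts <- as.data.frame(mosaic)
    if (is.null(window)) stop("window must be supplied for bare point sets")
  }
  window <- as_window(window)
  if (nrow(pts) < 10) stop("insufficient data: fewer than 10 points")
  xy <- cbind(pts$x_um, pts$y_um)
  if (anyDuplicated(xy)) stop("duplicate cell centers")
  # degenerate (collinear) configurations have no 2-D tessellation
  sv <- svd(scale(xy, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) stop("degenerate input: points are collinear")
  inside <- xy[, 1] >= window[1] & xy[, 1] <= window[2] &
            xy[, 2] >= window[3] & xy[, 2] <= window[4]
  if (!all(inside)) stop("all points must lie inside the window")

  vc <- voronoi_cells_cpp(xy, window)

  vessel <- rep(FALSE, nrow(xy))
  if (!is.null(vessel_mask)) {
    vessel <- vapply(seq_len(nrow(xy)), function(i) {
      polygon_hits_mask(vc$polygons[[i]], vessel_mask, window,
                        mask_pixel_size_um)
    }, logical(1))
  }
  included <- !vc$boundary & !vessel
  n_inc <- sum(included)
  if (n_inc < 3) stop("insufficient data: fewer than 3 usable cells after exclusions")

  area_um2 <- vc$area
  dens <- n_inc / (sum(area_um2[included]) * 1e-6)

  # spacing over Voronoi-adjacent pairs with both members included
  idx <- which(included)
  pair_d <- numeric(0)
  incl_set <- logical(nrow(xy)); incl_set[idx] <- TRUE
  for (i in idx) {
    nb <- vc$neighbors[[i]]
    nb <- nb[nb > i & incl_set[nb]]
    if (length(nb)) {
      pair_d <- c(pair_d, sqrt((xy[nb, 1] - xy[i, 1])^2 +
                               (xy[nb, 2] - xy[i, 2])^2))
    }
  }

  cells <- data.frame(
    id = if (!is.null(pts$id)) pts$id else seq_len(nrow(xy)),
    x_um = xy[, 1], y_um = xy[, 2],
    area_um2 = area_um2,
    n_neighbors = vapply(vc$neighbors, length, integer(1)),
    boundary = vc$boundary, vessel = vessel, included = included
  )
  structure(
    list(density_cells_mm2 = dens,
         mean_cell_area_um2 = mean(area_um2[included]),
         mean_spacing_um = if (length(pair_d)) mean(pair_d) else NA_real_,
         n_cells_counted = n_inc,
         analyzed_area_mm2 = sum(area_um2[included]) * 1e-6,
         cells = cells),
    class = "mosaic_metrics"
  )
}

#' @export
print.mosaic_metrics <- function(x, ...) {
  cat(sprintf("Mosaic metrics: %d cells over %.4f mm^2\n",
              x$n_cells_counted, x$analyzed_area_mm2))
  cat(sprintf("  density %.0f cells/mm^2, mean area %.1f um^2, spacing %.2f um\n",
              x$density_cells_mm2, x$mean_cell_area_um2, x$mean_spacing_um))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# does a convex polygon (um coordinates) intersect the TRUE region of a
# raster mask? Sampled at vertices, edge midpoints and the centroid; vessel
# bands are wide relative to cells so this sampling is adequate.
polygon_hits_mask <- function(poly, mask, window, pixel_size_um) {
  px <- poly[, 1]; py <- poly[, 2]
  mx <- 0.5 * (px + c(px[-1], px[1])); my <- 0.5 * (py + c(py[-1], py[1]))
  sx <- c(px, mx, mean(px)); sy <- c(py, my, mean(py))
  cc <- pmin(ncol(mask), pmax(1L, ceiling((sx - window[1]) / pixel_size_um)))
  rr <- pmin(nrow(mask), pmax(1L, ceiling((sy - window[3]) / pixel_size_um)))
  any(mask[cbind(rr, cc)])
}

#' Mosaic density from the power spectrum (Yellott's ring)
#'
#' Estimates cell density from the annular spectral peak of a quasi-regular
#' mosaic: the image is mean-subtracted, Hann-windowed, Fourier transformed,
#' and the power is radially averaged; the ring is the highest radial peak
#' inside a physical frequency band derived from an expected-density hint.
#' Density follows from the ring's radial frequency `f` (row frequency of the
#' hexagonal packing) as `D = (sqrt(3)/2) * f^2`.
#'
#' @param image An `enface_image` (square, side >= 128 px).
#' @param expected_density_hint Approximate density in cells/mm^2; sets the
#'   search band and prevents DC leakage or harmonic capture.
#' @param band Search band as multiples of the expected ring frequency.
#' @param vessel_mask Optional logical raster; masked pixels are replaced by
#'   the unmasked mean before the transform.
#' @param floor_factor The peak must exceed `floor_factor` times the median
#'   radial power in the band, else a no-ring error is raised.
#' @return List with `density_cells_mm2`, `ring_frequency_cyc_mm`,
#'   `radial_profile` (data.frame freq_cyc_mm, power) and `band_cyc_mm`.
#' @export
power_spectrum_density <- function(image, expected_density_hint,
                                   band = c(0.3, 2), vessel_mask = NULL,
                                   floor_factor = 2) {
  stopifnot(inherits(image, "enface_image"))
  img <- image$intensity
  n <- nrow(img)
  if (ncol(img) != n) stop("image must be square")
  if (n < 128) stop("image side must be >= 128 px")
  if (!is.null(vessel_mask)) {
    vm <- resize_mask(vessel_mask, n, n)
    img[vm] <- mean(img[!vm])
  }
  img <- img - mean(img)
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  img <- img * outer(hann, hann)
  P <- Mod(stats::fft(img))^2

  px_mm <- image$pixel_size_um * 1e-3
  df <- 1 / (n * px_mm)                      # cycles/mm per frequency bin
  fi <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  fr <- sqrt(outer(fi^2, fi^2, "+")) * df
  bin <- round(fr / df)
  prof <- as.numeric(tapply(as.numeric(P), as.numeric(bin), mean))
  freqs <- sort(unique(as.numeric(bin))) * df

  f_exp <- sqrt(2 * expected_density_hint / sqrt(3)) * 1  # cycles/mm (row freq)
  lo <- band[1] * f_exp; hi <- band[2] * f_exp
  in_band <- which(freqs >= lo & freqs <= hi)
  if (length(in_band) < 3) stop("no ring: search band too narrow for this raster")
  pk <- in_band[which.max(prof[in_band])]
  if (!is.finite(prof[pk]) || prof[pk] <= 0 ||
      prof[pk] < floor_factor * stats::median(prof[in_band])) {
    stop("no ring: no spectral peak above the noise floor in the search band")
  }
  # 3-point parabolic refinement of the ring radius
  f_peak <- freqs[pk]
  if (pk > 1 && pk < length(prof)) {
    y1 <- prof[pk - 1]; y2 <- prof[pk]; y3 <- prof[pk + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && den < 0) {
      f_peak <- f_peak + 0.5 * (y1 - y3) / den * df
    }
  }
  list(density_cells_mm2 = sqrt(3) / 2 * f_peak^2,
       ring_frequency_cyc_mm = f_peak,
       radial_profile = data.frame(freq_cyc_mm = freqs, power = prof),
       band_cyc_mm = c(lo, hi))
}
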
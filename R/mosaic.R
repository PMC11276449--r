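# Synthetic cell mosaics: jittered hexagonal point processes emulating the
# quasi-crystalline packing of cone photoreceptor and RPE cell arrays.

# Run expr with a fixed RNG state, restoring the caller's stream afterwards,
# so generators are pure functions of (parameters, seed).
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

as_window <- function(window) {
  if (length(window) == 1L) window <- c(0, window, 0, window)
  if (length(window) == 2L) window <- c(0, window[1], 0, window[2])
  stopifnot(length(window) == 4L, window[2] > window[1], window[4] > window[3])
  as.numeric(window)
}

#' Hexagonal lattice spacing for a target cell density
#'
#' For an ideal hexagonal mosaic of density `D` (cells/mm^2) the
#' center-to-center spacing is `a = sqrt(2 / (sqrt(3) * D))`.
#'
#' @param density_cells_mm2 Cell density in cells/mm^2.
#' @return Lattice spacing in um.
#' @export
hex_spacing_um <- function(density_cells_mm2) {
  sqrt(2 / (sqrt(3) * density_cells_mm2 * 1e-6))
}

#' Generate a jittered hexagonal cell mosaic
#'
#' Places points on a hexagonal lattice whose spacing matches the requested
#' density, rotates the lattice by a seeded random angle, and perturbs each
#' point with isotropic Gaussian jitter. The result emulates the
#' quasi-regular packing of cone and RPE mosaics; with moderate jitter it
#' retains the spectral ring (Yellott's ring) that the power-spectrum density
#' estimator relies on.
#'
#' @param density_cells_mm2 Target density in cells/mm^2.
#' @param window Analysis window in um: a side length, a `c(w, h)` pair or
#'   `c(xmin, xmax, ymin, ymax)`.
#' @param jitter_frac Jitter SD as a fraction of the lattice spacing
#'   (default 0.10).
#' @param seed Integer seed; identical seeds give identical mosaics.
#' @param cell_class `"cone"` or `"rpe"`.
#' @param pixel_size_um Raster scale used when the mosaic is rendered.
#' @param eccentricity_deg Temporal eccentricity label carried in metadata.
#' @param min_sep_frac Minimum pairwise separation as a fraction of spacing
#'   (default 0.5, a hard-core constraint reflecting the physical size of
#'   cell somata); jittered points violating it are re-drawn.
#' @return A `cell_mosaic`: list with `points` (data.frame id, x_um, y_um),
#'   `cell_class`, `window`, `pixel_size_um`, `vessel_mask` (NULL until set),
#'   `eccentricity_deg`, and `spacing_um` (the generating lattice constant).
#' @export
generate_mosaic <- function(density_cells_mm2, window, jitter_frac = 0.10,
                            seed = 1L, cell_class = c("cone", "rpe"),
                            pixel_size_um = 1, eccentricity_deg = 0,
                            min_sep_frac = 0.5) {
  cell_class <- match.arg(cell_class)
  stopifnot(density_cells_mm2 > 0, jitter_frac >= 0)
  window <- as_window(window)
  w <- window[2] - window[1]; h <- window[4] - window[3]
  area_mm2 <- w * h * 1e-6
  if (density_cells_mm2 * area_mm2 < 20) {
    stop("window too small: fewer than 20 cells expected at this density")
  }
  a <- hex_spacing_um(density_cells_mm2)
  pts <- local_seed(seed, {
    theta <- runif(1, 0, pi / 3)
    # lattice covering the window with margin, centered on the window
    half <- sqrt(w^2 + h^2) / 2 + 3 * a
    iy <- seq(-ceiling(half / (a * sqrt(3) / 2)), ceiling(half / (a * sqrt(3) / 2)))
    ix <- seq(-ceiling(half / a) - 1, ceiling(half / a) + 1)
    g <- expand.grid(ix = ix, iy = iy)
    x0 <- (g$ix + ifelse(g$iy %% 2 == 0, 0, 0.5)) * a
    y0 <- g$iy * a * sqrt(3) / 2
    keep0 <- abs(x0) <= half & abs(y0) <= half
    x0 <- x0[keep0]; y0 <- y0[keep0]
    cx <- mean(window[1:2]); cy <- mean(window[3:4])
    xr <- cx + x0 * cos(theta) - y0 * sin(theta)
    yr <- cy + x0 * sin(theta) + y0 * cos(theta)
    sj <- jitter_frac * a
    if (sj > 0) {
      x0 <- xr; y0 <- yr
      xr <- x0 + rnorm(length(xr), 0, sj)
      yr <- y0 + rnorm(length(yr), 0, sj)
      # hard-core constraint: re-draw offending jitters from their lattice
      # sites until all pairs are separated by at least min_sep
      min_sep <- min_sep_frac * a
      for (it in seq_len(200)) {
        bad <- close_pair_members(xr, yr, min_sep)
        if (length(bad) == 0) break
        xr[bad] <- x0[bad] + rnorm(length(bad), 0, sj)
        yr[bad] <- y0[bad] + rnorm(length(bad), 0, sj)
      }
    }
    keep <- xr >= window[1] & xr <= window[2] & yr >= window[3] & yr <= window[4]
    data.frame(id = seq_len(sum(keep)), x_um = xr[keep], y_um = yr[keep])
  })
  structure(
    list(points = pts, cell_class = cell_class, window = window,
         pixel_size_um = pixel_size_um, vessel_mask = NULL,
         eccentricity_deg = eccentricity_deg, spacing_um = a,
         density_requested = density_cells_mm2, seed = seed),
    class = "cell_mosaic"
  )
}

#' @export
print.cell_mosaic <- function(x, ...) {
  w <- x$window
  cat(sprintf("Cell mosaic (%s): %d points in %.0f x %.0f um window\n",
              x$cell_class, nrow(x$points), w[2] - w[1], w[4] - w[3]))
  cat(sprintf("  lattice spacing %.2f um, eccentricity %g deg\n",
              x$spacing_um, x$eccentricity_deg))
  invisible(x)
}

# indices of points participating in any pair closer than min_sep (one member
# of each offending pair, for re-drawing)
close_pair_members <- function(x, y, min_sep) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(xs)
  bad <- integer(0)
  j0 <- 1L
  for (i in seq_len(n)) {
    while (xs[i] - xs[j0] > min_sep) j0 <- j0 + 1L
    if (j0 < i) {
      jj <- j0:(i - 1L)
      hit <- jj[(xs[i] - xs[jj])^2 + (ys[i] - ys[jj])^2 < min_sep^2]
      if (length(hit)) bad <- c(bad, o[i])
    }
  }
  unique(bad)
}

# nearest-neighbor distances (sorted-x sweep; exact)
nn_distances <- function(x, y) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  d <- rep(Inf, n)
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && (xs[j] - xs[i])^2 < d[i]) {
      d2 <- (xs[j] - xs[i])^2 + (ys[j] - ys[i])^2
      if (d2 < d[i]) d[i] <- d2
      if (d2 < d[j]) d[j] <- d2
      j <- j + 1L
    }
    j <- i - 1L
    while (j >= 1L && (xs[i] - xs[j])^2 < d[i]) {
      d2 <- (xs[i] - xs[j])^2 + (ys[i] - ys[j])^2
      if (d2 < d[i]) d[i] <- d2
      j <- j - 1L
    }
  }
  out <- numeric(n)
  out[o] <- sqrt(d)
  out
}

#' Generate a vessel shadow exclusion mask
#'
#' Draws `n_vessels` smooth curvilinear bands of the given width across the
#' window, emulating the dark shadows retinal blood vessels cast on the
#' photoreceptor and RPE layers. Masked (TRUE) pixels are excluded from cell
#' counting and filled before spectral analysis.
#'
#' @param window Window in um (see [generate_mosaic()]).
#' @param n_vessels Number of vessel bands (0 gives an all-FALSE mask).
#' @param width_um Band width in um.
#' @param seed Integer seed.
#' @param pixel_size_um Raster scale of the mask.
#' @param curvature_sd SD of the per-step heading increment (radians);
#'   0 gives straight bands.
#' @return Logical matrix (rows = y, cols = x) with attributes
#'   `pixel_size_um`, `window` and `excluded_fraction`.
#' @export
generate_vessel_mask <- function(window, n_vessels, width_um, seed = 1L,
                                 pixel_size_um = 1, curvature_sd = 0.03) {
  window <- as_window(window)
  w <- window[2] - window[1]; h <- window[4] - window[3]
  stopifnot(width_um < min(w, h))
  nx <- max(1L, round(w / pixel_size_um))
  ny <- max(1L, round(h / pixel_size_um))
  mask <- matrix(FALSE, ny, nx)
  if (n_vessels > 0) {
    mask <- local_seed(seed, {
      m <- mask
      rad <- width_um / 2 / pixel_size_um
      ir <- ceiling(rad)
      patch <- expand.grid(dr = -ir:ir, dc = -ir:ir)
      patch <- patch[patch$dr^2 + patch$dc^2 <= rad^2, ]
      for (v in seq_len(n_vessels)) {
        transpose <- runif(1) < 0.5
        nalong <- if (transpose) ny else nx
        nacross <- if (transpose) nx else ny
        heading <- runif(1, -pi / 12, pi / 12)
        pos <- runif(1, 0.1, 0.9) * nacross
        step <- 1
        cc <- seq_len(nalong)
        across <- numeric(nalong)
        for (i in cc) {
          heading <- heading + rnorm(1, 0, curvature_sd)
          heading <- max(-pi / 3, min(pi / 3, heading))
          pos <- pos + step * tan(heading)
          across[i] <- pos
        }
        for (i in cc) {
          r0 <- round(across[i]) + patch$dr
          c0 <- i + patch$dc
          if (transpose) { tmp <- r0; r0 <- c0; c0 <- tmp }
          ok <- r0 >= 1 & r0 <= ny & c0 >= 1 & c0 <= nx
          m[cbind(r0[ok], c0[ok])] <- TRUE
        }
      }
      m
    })
  }
  structure(mask, pixel_size_um = pixel_size_um, window = window,
            excluded_fraction = mean(mask))
}

#' Attach a vessel mask to a mosaic
#'
#' @param mosaic A `cell_mosaic`.
#' @param mask A logical raster from [generate_vessel_mask()].
#' @return The mosaic with `vessel_mask` set.
#' @export
set_vessel_mask <- function(mosaic, mask) {
  stopifnot(inherits(mosaic, "cell_mosaic"), is.logical(mask))
  mosaic$vessel_mask <- mask
  mosaic
}

#' Render an en-face intensity image of a mosaic
#'
#' Sums a Gaussian reflectance spot at every cell center on the mosaic's
#' raster, darkens vessel-masked regions, and applies multiplicative
#' lognormal speckle. This emulates the average-intensity en-face projection
#' of the cone (IS/OS + COST) or RPE layer.
#'
#' @param mosaic A `cell_mosaic` (its `pixel_size_um` sets the raster).
#' @param spot_fwhm_um Spot full width at half maximum in um; default is half
#'   the lattice spacing. Must be under twice the lattice spacing.
#' @param noise_cv Speckle coefficient of variation (0 = noiseless).
#' @param seed Integer seed for the speckle field.
#' @param vessel_attenuation Intensity multiplier inside the vessel mask.
#' @return An `enface_image`: list with `intensity` (matrix, rows = y),
#'   `pixel_size_um`, `window`.
#' @export
render_enface <- function(mosaic, spot_fwhm_um = NULL, noise_cv = 0,
                          seed = 1L, vessel_attenuation = 0.15) {
  stopifnot(inherits(mosaic, "cell_mosaic"))
  px <- mosaic$pixel_size_um
  if (is.null(spot_fwhm_um)) spot_fwhm_um <- 0.5 * mosaic$spacing_um
  if (spot_fwhm_um >= 2 * mosaic$spacing_um) {
    stop("spot_fwhm_um must be below twice the lattice spacing")
  }
  if (px > spot_fwhm_um) {
    warning("raster coarser than the spot FWHM; spots will be undersampled")
  }
  window <- mosaic$window
  nx <- max(1L, round((window[2] - window[1]) / px))
  ny <- max(1L, round((window[4] - window[3]) / px))
  img <- matrix(0, ny, nx)
  sigma <- spot_fwhm_um / 2.35482 / px
  ir <- max(1L, ceiling(3 * sigma))
  dd <- -ir:ir
  # pixel-center coordinates of each cell in raster units
  cx <- (mosaic$points$x_um - window[1]) / px + 0.5
  cy <- (mosaic$points$y_um - window[3]) / px + 0.5
  for (i in seq_along(cx)) {
    c0 <- round(cx[i]); r0 <- round(cy[i])
    cols <- c0 + dd; rows <- r0 + dd
    okc <- cols >= 1 & cols <= nx; okr <- rows >= 1 & rows <= ny
    if (!any(okc) || !any(okr)) next
    gx <- exp(-((cols - cx[i])^2) / (2 * sigma^2))[okc]
    gy <- exp(-((rows - cy[i])^2) / (2 * sigma^2))[okr]
    img[rows[okr], cols[okc]] <- img[rows[okr], cols[okc]] + outer(gy, gx)
  }
  if (!is.null(mosaic$vessel_mask)) {
    vm <- resize_mask(mosaic$vessel_mask, ny, nx)
    img[vm] <- img[vm] * vessel_attenuation
  }
  if (noise_cv > 0) {
    img <- local_seed(seed, {
      sdlog <- sqrt(log(1 + noise_cv^2))
      img * matrix(exp(rnorm(ny * nx, -sdlog^2 / 2, sdlog)), ny, nx)
    })
  }
  if (max(img) > 0) img <- img / max(img)
  structure(list(intensity = img, pixel_size_um = px, window = window),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("En-face image: %d x %d px at %.3f um/px\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um))
  invisible(x)
}

# nearest-neighbor rescale of a logical mask to a target raster
resize_mask <- function(mask, ny, nx) {
  if (nrow(mask) == ny && ncol(mask) == nx) return(mask)
  ri <- pmin(nrow(mask), pmax(1L, ceiling(seq_len(ny) * nrow(mask) / ny)))
  ci <- pmin(ncol(mask), pmax(1L, ceiling(seq_len(nx) * ncol(mask) / nx)))
  mask[ri, ci, drop = FALSE]
}
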
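# Readers and writers for the package's on-disk formats: point tables as
# CSV, masks and en-face images as TIFF/PNG, volumes as multi-page TIFF with
# a JSON sidecar, and ground truth as CSV plus a JSON manifest.

#' Write cell positions to CSV
#'
#' Columns `id, x_um, y_um` — the dialect shared by the generator and the
#' detector, making their outputs interchangeable.
#'
#' @param x A `cell_mosaic`, `detection_result`, or data.frame with
#'   `x_um`, `y_um`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(x, path) {
  pts <- if (inherits(x, "cell_mosaic")) x$points
         else if (inherits(x, "detection_result")) x$points
         else as.data.frame(x)
  if (is.null(pts$id)) pts$id <- seq_len(nrow(pts))
  utils::write.csv(pts[, c("id", "x_um", "y_um")], path, row.names = FALSE)
  invisible(path)
}

#' Read cell positions from CSV into a mosaic
#'
#' @param path CSV with columns `id, x_um, y_um`.
#' @param window Window in um; default the bounding box of the points.
#' @param cell_class `"cone"` or `"rpe"`.
#' @param pixel_size_um Raster scale for derived images.
#' @param eccentricity_deg Eccentricity label.
#' @param spacing_um Lattice spacing; default the median nearest-neighbor
#'   distance.
#' @return A `cell_mosaic`.
#' @export
read_points_csv <- function(path, window = NULL, cell_class = "cone",
                            pixel_size_um = 1, eccentricity_deg = 0,
                            spacing_um = NULL) {
  pts <- utils::read.csv(path)
  stopifnot(all(c("x_um", "y_um") %in% names(pts)))
  if (is.null(pts$id)) pts$id <- seq_len(nrow(pts))
  if (is.null(window)) {
    window <- c(min(pts$x_um), max(pts$x_um), min(pts$y_um), max(pts$y_um))
  }
  if (is.null(spacing_um)) {
    spacing_um <- stats::median(nn_distances(pts$x_um, pts$y_um))
  }
  structure(
    list(points = pts[, c("id", "x_um", "y_um")], cell_class = cell_class,
         window = as_window(window), pixel_size_um = pixel_size_um,
         vessel_mask = NULL, eccentricity_deg = eccentricity_deg,
         spacing_um = spacing_um),
    class = "cell_mosaic"
  )
}

#' Write an en-face image or mask to TIFF
#'
#' Intensities are rescaled to `[0, 1]`; the scale factor is recorded in a
#' JSON sidecar next to the image.
#'
#' @param image An `enface_image` or numeric/logical matrix.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_enface_tiff <- function(image, path) {
  if (inherits(image, "enface_image")) {
    m <- image$intensity
    px <- image$pixel_size_um
    win <- image$window
  } else {
    m <- image
    px <- attr(image, "pixel_size_um") %||% 1
    win <- attr(image, "window") %||% c(0, ncol(m) * px, 0, nrow(m) * px)
  }
  if (is.logical(m)) m <- m * 1
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  sc <- max(m, 1e-12)
  tiff::writeTIFF(m / sc, path, bits.per.sample = 32L)
  meta <- list(scale = sc, pixel_size_um = px, window = win)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an en-face image written by [write_enface_tiff()]
#'
#' @param path TIFF path (JSON sidecar expected alongside).
#' @return An `enface_image`.
#' @export
read_enface_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(intensity = m * meta$scale,
                 pixel_size_um = meta$pixel_size_um,
                 window = as_window(meta$window)),
            class = "enface_image")
}

#' Write a volume as multi-page TIFF with a JSON sidecar
#'
#' One page per depth slice; pixel sizes, window and the intensity scale go
#' to `<path>.json`.
#'
#' @param volume An `ao_volume`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "ao_volume"))
  v <- volume$intensity
  sc <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = sc, axial_pixel_um = volume$axial_pixel_um,
         lateral_pixel_um = volume$lateral_pixel_um, window = volume$window),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path TIFF path (JSON sidecar expected alongside).
#' @return An `ao_volume`.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) v[z, , ] <- pages[[z]] * meta$scale
  ao_volume(v, meta$axial_pixel_um, meta$lateral_pixel_um,
            as_window(meta$window))
}

#' Write cohort ground truth (CSV + JSON manifest)
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$subject_effects,
                   file.path(dir, "subject_effects.csv"), row.names = FALSE)
  sp <- cohort$spec
  jsonlite::write_json(
    list(n_subjects = sp$n_subjects,
         eccentricities_deg = sp$eccentricities_deg,
         cone_model = as.list(sp$cone_model),
         rpe_model = as.list(sp$rpe_model),
         osl_model = as.list(sp$osl_model),
         between_subject_cv = as.list(sp$between_subject_cv),
         within_session_cv = as.list(sp$within_session_cv),
         seed = sp$seed),
    file.path(dir, "cohort_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read cohort ground truth written by [write_ground_truth()]
#'
#' @param dir Directory containing `ground_truth.csv`,
#'   `subject_effects.csv` and `cohort_manifest.json`.
#' @return A `cohort`.
#' @export
read_ground_truth <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
                             simplifyVector = TRUE)
  spec <- cohort_spec(
    n_subjects = man$n_subjects,
    eccentricities_deg = man$eccentricities_deg,
    cone_model = unlist(man$cone_model),
    rpe_model = unlist(man$rpe_model),
    osl_model = unlist(man$osl_model),
    between_subject_cv = unlist(man$between_subject_cv),
    within_session_cv = unlist(man$within_session_cv),
    seed = man$seed)
  structure(
    list(spec = spec,
         truth = utils::read.csv(file.path(dir, "ground_truth.csv")),
         subject_effects = utils::read.csv(file.path(dir, "subject_effects.csv"))),
    class = "cohort")
}
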
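#' Eye biometry for retinal magnification scaling
#'
#' Bundles the per-eye quantities needed to convert between angular units on
#' the retina (degrees of visual field) and physical units (micrometers):
#' the axial length of the eye, the angular extent of the imaging field, and
#' the number of lateral samples (A-scans) across that field.
#'
#' @param axial_length_mm Axial length of the eye in mm. Must exceed 1.82 mm,
#'   the schematic-eye distance between the second nodal point and the
#'   anterior retina that the Bennett small-angle relation subtracts out.
#' @param fov_deg Scan field of view in degrees (default 2).
#' @param samples_per_fov Number of lateral pixels (A-scans) spanning the
#'   field (default 512).
#' @param id Optional subject identifier.
#' @return An object of class `eye_biometry`.
#' @examples
#' b <- eye_biometry(24.13)
#' microns_per_degree(b)
#' lateral_pixel_size(b)
#' @export
eye_biometry <- function(axial_length_mm, fov_deg = 2, samples_per_fov = 512L,
                         id = NULL) {
  if (!is.numeric(axial_length_mm) || length(axial_length_mm) != 1L ||
      !is.finite(axial_length_mm) || axial_length_mm <= 1.82) {
    stop("invalid biometry: axial_length_mm must be a finite number > 1.82 mm")
  }
  if (!is.numeric(fov_deg) || length(fov_deg) != 1L || fov_deg <= 0) {
    stop("invalid biometry: fov_deg must be > 0")
  }
  samples_per_fov <- as.integer(samples_per_fov)
  if (is.na(samples_per_fov) || samples_per_fov < 2L) {
    stop("invalid biometry: samples_per_fov must be an integer >= 2")
  }
  structure(
    list(id = id, axial_length_mm = axial_length_mm, fov_deg = fov_deg,
         samples_per_fov = samples_per_fov),
    class = "eye_biometry"
  )
}

#' @export
print.eye_biometry <- function(x, ...) {
  cat("Eye biometry", if (!is.null(x$id)) paste0("[", x$id, "]"), "\n")
  cat(sprintf("  axial length : %.2f mm\n", x$axial_length_mm))
  cat(sprintf("  field of view: %g deg, %d samples\n",
              x$fov_deg, x$samples_per_fov))
  cat(sprintf("  scale        : %.1f um/deg, %.3f um/pixel\n",
              microns_per_degree(x), lateral_pixel_size(x)))
  invisible(x)
}

#' Retinal magnification from axial length (Bennett eye model)
#'
#' Converts visual angle to retinal distance with the small-angle Bennett
#' schematic-eye relation `q = 0.01306 * (AL - 1.82)` mm/deg, returned in
#' micrometers per degree. Refraction-corrected variants are out of scope;
#' only the axial length enters.
#'
#' @param biometry An [eye_biometry()] object.
#' @return Retinal magnification in um/degree.
#' @export
microns_per_degree <- function(biometry) {
  stopifnot(inherits(biometry, "eye_biometry"))
  1000 * 0.01306 * (biometry$axial_length_mm - 1.82)
}

#' Lateral pixel size of the en-face raster
#'
#' @param biometry An [eye_biometry()] object.
#' @return Lateral pixel size in um/pixel: `q * fov / samples`.
#' @export
lateral_pixel_size <- function(biometry) {
  stopifnot(inherits(biometry, "eye_biometry"))
  microns_per_degree(biometry) * biometry$fov_deg / biometry$samples_per_fov
}

#' Convert a cell count over a pixel area to physical density
#'
#' @param cell_count Number of cells counted.
#' @param area_px2 Analyzed area in squared pixels. Must be > 0.
#' @param pixel_size_um Lateral pixel size in um/pixel.
#' @return Density in cells/mm^2.
#' @export
counts_to_density <- function(cell_count, area_px2, pixel_size_um) {
  if (!is.numeric(area_px2) || any(area_px2 <= 0)) {
    stop("area_px2 must be > 0")
  }
  if (!is.numeric(pixel_size_um) || any(pixel_size_um <= 0)) {
    stop("pixel_size_um must be > 0")
  }
  cell_count / (area_px2 * pixel_size_um^2 * 1e-6)
}

#' Read eye biometry from a JSON or YAML config file
#'
#' Expects fields `axial_length_mm` and optionally `id`, `fov_deg`,
#' `samples_per_fov`. A list of such records yields a list of biometries.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `eye_biometry` or list of them.
#' @export
read_biometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported biometry format: ", ext)
  )
  as_one <- function(r) {
    eye_biometry(
      axial_length_mm = r$axial_length_mm,
      fov_deg = if (is.null(r$fov_deg)) 2 else r$fov_deg,
      samples_per_fov = if (is.null(r$samples_per_fov)) 512L else r$samples_per_fov,
      id = r$id
    )
  }
  if (is.data.frame(raw)) {
    lapply(seq_len(nrow(raw)), function(i) as_one(as.list(raw[i, ])))
  } else if (!is.null(raw$axial_length_mm)) {
    as_one(raw)
  } else {
    lapply(raw, as_one)
  }
}
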
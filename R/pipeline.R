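# End-to-end synthetic study pipeline: simulate a cohort, detect and measure
# cells, fit the topography, assess reproducibility, and report. Stages
# communicate only through serialized files, so a run can be restarted at
# any stage.

#' Build and validate a pipeline run configuration
#'
#' Defaults mirror a typical study design: 13 regions of interest from the
#' fovea to 12 degrees temporal at ~1 degree spacing, cones quantified from
#' 1 degree outward, RPE at all locations, and a 7-subject, 3-session
#' reproducibility arm at the fovea and 7.5 degrees.
#'
#' @param out_dir Output directory for the run.
#' @param seed Integer seed; recorded in every manifest.
#' @param n_subjects,eccentricities_deg,cone_model,rpe_model,osl_model,
#'   between_subject_cv,within_session_cv Cohort settings (see
#'   [cohort_spec()]).
#' @param al_mean_mm,al_sd_mm Axial length distribution for simulated
#'   biometry (mm).
#' @param fov_deg,samples_per_fov Imaging field and lateral sampling.
#' @param cone_window_um,rpe_window_um Analysis window side (um).
#' @param volume_window_um Side of the central subregion used for per-cone
#'   OSL measurement (um).
#' @param jitter_frac Mosaic jitter fraction.
#' @param enface_noise_cv,volume_noise_cv Speckle CV for images and volumes.
#' @param vessel_min_ecc_deg,n_vessels,vessel_width_um Vessel shadow
#'   settings (vessels are drawn at eccentricities >= `vessel_min_ecc_deg`).
#' @param threshold_quantile,min_sep_frac Detector settings.
#' @param osl_cell_sd_um Per-cone SD of true OSL within an ROI (um).
#' @param isos_depth_um,axial_pixel_um Volume geometry.
#' @param rel_n_subjects,rel_k,rel_locations_deg Reproducibility arm.
#' @param grader_cv Per-grader multiplicative noise for the simulated
#'   two-grader RPE comparison.
#' @param verbose Print per-ROI progress.
#' @return A validated `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       n_subjects = 11,
                       eccentricities_deg = 0:12,
                       cone_model = default_topography_models()$cone,
                       rpe_model = default_topography_models()$rpe,
                       osl_model = default_topography_models()$osl,
                       between_subject_cv = c(cone = 0.10, rpe = 0.08, osl = 0.07),
                       within_session_cv = c(pr_density = 0.016, osl = 0.020,
                                             rpe_density = 0.023),
                       al_mean_mm = 24.37, al_sd_mm = 1.28,
                       fov_deg = 2, samples_per_fov = 512L,
                       cone_window_um = 250, rpe_window_um = 250,
                       volume_window_um = 120,
                       jitter_frac = 0.10,
                       enface_noise_cv = 0.15, volume_noise_cv = 0.15,
                       vessel_min_ecc_deg = 5, n_vessels = 1,
                       vessel_width_um = 12,
                       threshold_quantile = 0.80, min_sep_frac = 0.6,
                       osl_cell_sd_um = 2.4,
                       isos_depth_um = 40, axial_pixel_um = 1.0,
                       rel_n_subjects = 7, rel_k = 3,
                       rel_locations_deg = c(0, 7.5),
                       grader_cv = 0.05,
                       verbose = FALSE) {
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1L) {
    stop("invalid config: out_dir must be a single path")
  }
  if (length(eccentricities_deg) == 0) {
    stop("invalid config: empty eccentricity list")
  }
  if (is.unsorted(eccentricities_deg)) {
    stop("invalid config: eccentricities must be ascending")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("invalid config: seed must be an integer")
  spec <- cohort_spec(n_subjects, eccentricities_deg, cone_model, rpe_model,
                      osl_model, between_subject_cv, within_session_cv, seed)
  stopifnot(cone_window_um > 0, rpe_window_um > 0, volume_window_um > 0,
            axial_pixel_um > 0, rel_k >= 2, rel_n_subjects >= 3)
  structure(
    list(out_dir = out_dir, seed = seed, cohort = spec,
         al_mean_mm = al_mean_mm, al_sd_mm = al_sd_mm, fov_deg = fov_deg,
         samples_per_fov = as.integer(samples_per_fov),
         cone_window_um = cone_window_um, rpe_window_um = rpe_window_um,
         volume_window_um = volume_window_um, jitter_frac = jitter_frac,
         enface_noise_cv = enface_noise_cv, volume_noise_cv = volume_noise_cv,
         vessel_min_ecc_deg = vessel_min_ecc_deg, n_vessels = n_vessels,
         vessel_width_um = vessel_width_um,
         threshold_quantile = threshold_quantile, min_sep_frac = min_sep_frac,
         osl_cell_sd_um = osl_cell_sd_um, isos_depth_um = isos_depth_um,
         axial_pixel_um = axial_pixel_um,
         rel_n_subjects = rel_n_subjects, rel_k = rel_k,
         rel_locations_deg = rel_locations_deg, grader_cv = grader_cv,
         verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Any field of [run_config()] may appear; missing fields take defaults.
#'
#' @param path Config file (`.yaml`, `.yml` or `.json`).
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = , yml = yaml::read_yaml(path),
    stop("unsupported config format: ", ext))
  for (f in c("cone_model", "rpe_model", "osl_model", "between_subject_cv",
              "within_session_cv")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("invalid config: unknown fields ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

roi_tag <- function(s, e) sprintf("s%02d_e%04.1f", s, e)

#' Simulate stage: cohort, biometry and mosaics on disk
#'
#' Writes the cohort ground truth, per-subject biometry, per-ROI cone and
#' RPE mosaic CSVs, vessel masks, and a manifest with all parameters.
#'
#' @param config A `run_config`.
#' @return The simulate directory, invisibly.
#' @export
pipeline_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- file.path(config$out_dir, "simulate")
  dir.create(file.path(dir, "mosaics"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE, recursive = TRUE)

  cohort <- generate_cohort(config$cohort)
  write_ground_truth(cohort, dir)

  ns <- config$cohort$n_subjects
  bio <- local_seed(config$seed + 77L, {
    al <- pmin(28, pmax(21, stats::rnorm(ns, config$al_mean_mm, config$al_sd_mm)))
    data.frame(id = sprintf("S%02d", seq_len(ns)), axial_length_mm = round(al, 2),
               fov_deg = config$fov_deg, samples_per_fov = config$samples_per_fov)
  })
  jsonlite::write_json(bio, file.path(dir, "biometry.json"), digits = NA)

  files <- character(0)
  for (i in seq_len(nrow(cohort$truth))) {
    tr <- cohort$truth[i, ]
    px <- lateral_pixel_size(eye_biometry(bio$axial_length_mm[tr$subject],
                                          config$fov_deg,
                                          config$samples_per_fov))
    tag <- roi_tag(tr$subject, tr$eccentricity_deg)
    if (is.finite(tr$cone_density)) {
      m <- generate_mosaic(tr$cone_density, config$cone_window_um,
                           jitter_frac = config$jitter_frac,
                           seed = tr$roi_seed, cell_class = "cone",
                           pixel_size_um = px,
                           eccentricity_deg = tr$eccentricity_deg)
      files <- c(files, write_points_csv(
        m, file.path(dir, "mosaics", paste0("cone_", tag, ".csv"))))
    }
    m <- generate_mosaic(tr$rpe_density, config$rpe_window_um,
                         jitter_frac = config$jitter_frac,
                         seed = tr$roi_seed + 1L, cell_class = "rpe",
                         pixel_size_um = px,
                         eccentricity_deg = tr$eccentricity_deg)
    files <- c(files, write_points_csv(
      m, file.path(dir, "mosaics", paste0("rpe_", tag, ".csv"))))
    if (tr$eccentricity_deg >= config$vessel_min_ecc_deg &&
        config$n_vessels > 0) {
      vm <- generate_vessel_mask(config$cone_window_um, config$n_vessels,
                                 config$vessel_width_um,
                                 seed = tr$roi_seed + 2L, pixel_size_um = px)
      files <- c(files, write_enface_tiff(
        unclass(vm), file.path(dir, "masks", paste0("vessel_", tag, ".tif"))))
    }
  }
  write_manifest(config, dir, files, "simulate")
  invisible(dir)
}

#' Analyze stage: detect cells and measure every ROI
#'
#' For each ROI: renders the en-face images from the simulated mosaics,
#' detects cells, computes Voronoi metrics (with vessel exclusion), the
#' power-spectrum density for the cone layer, and per-cone OSL from a
#' rendered outer-retina volume of the central subregion (with a seeded
#' tilt that the flattening step must undo). Per-ROI failures are logged
#' and skipped without aborting the run.
#'
#' @param config A `run_config`.
#' @return Path of the written `roi_metrics.csv`, invisibly.
#' @export
pipeline_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- file.path(config$out_dir, "simulate")
  dir <- file.path(config$out_dir, "analyze")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!file.exists(file.path(sim, "ground_truth.csv"))) {
    stop("missing simulate stage: run pipeline_simulate() first")
  }
  cohort <- read_ground_truth(sim)
  bio <- jsonlite::read_json(file.path(sim, "biometry.json"),
                             simplifyVector = TRUE)
  models <- list(cone = config$cohort$cone_model,
                 rpe = config$cohort$rpe_model,
                 osl = config$cohort$osl_model)

  rows <- list(); log_lines <- character(0)
  for (i in seq_len(nrow(cohort$truth))) {
    tr <- cohort$truth[i, ]
    tag <- roi_tag(tr$subject, tr$eccentricity_deg)
    res <- tryCatch(
      analyze_roi(config, sim, tr, bio, models),
      error = function(e) e)
    if (inherits(res, "error")) {
      log_lines <- c(log_lines, sprintf("ROI %s FAILED: %s", tag,
                                        conditionMessage(res)))
      next
    }
    log_lines <- c(log_lines, sprintf(
      "ROI %s: %d PR, %d RPE cells counted; %d boundary/vessel/invalid exclusions",
      tag, res$n_pr %||% 0L, res$n_rpe, res$n_excluded))
    rows[[length(rows) + 1L]] <- res$row
    if (config$verbose) message(utils::tail(log_lines, 1))
  }
  metrics <- do.call(rbind, rows)
  out <- file.path(dir, "roi_metrics.csv")
  utils::write.csv(metrics, out, row.names = FALSE)
  writeLines(log_lines, file.path(dir, "analyze_log.txt"))
  write_manifest(config, dir, out, "analyze")
  invisible(out)
}

analyze_roi <- function(config, sim, tr, bio, models) {
  e <- tr$eccentricity_deg
  tag <- roi_tag(tr$subject, e)
  px <- lateral_pixel_size(eye_biometry(bio$axial_length_mm[tr$subject],
                                        config$fov_deg,
                                        config$samples_per_fov))
  mask_path <- file.path(sim, "masks", paste0("vessel_", tag, ".tif"))
  vm <- NULL
  if (file.exists(mask_path)) {
    vm <- read_enface_tiff(mask_path)$intensity > 0.5
  }

  # --- RPE layer ---
  rpe_mos <- read_points_csv(
    file.path(sim, "mosaics", paste0("rpe_", tag, ".csv")),
    window = config$rpe_window_um, cell_class = "rpe", pixel_size_um = px,
    eccentricity_deg = e)
  if (!is.null(vm)) rpe_mos$vessel_mask <- structure(vm, pixel_size_um = px)
  rpe_img <- render_enface(rpe_mos, noise_cv = config$enface_noise_cv,
                           seed = tr$roi_seed + 3L)
  rpe_hint <- eval_topography_model(models$rpe, e)
  rpe_det <- detect_cells(rpe_img, hex_spacing_um(rpe_hint),
                          threshold_quantile = config$threshold_quantile,
                          min_sep_frac = config$min_sep_frac)
  rpe_vm <- voronoi_metrics(rpe_det, window = rpe_mos$window,
                            vessel_mask = rpe_mos$vessel_mask,
                            mask_pixel_size_um = px)

  row <- data.frame(
    subject = tr$subject, eccentricity_deg = e,
    pr_density = NA_real_, rpe_density = rpe_vm$density_cells_mm2,
    osl_mean = NA_real_, osl_sd = NA_real_, pr_rpe_ratio = NA_real_,
    pr_spacing = NA_real_, rpe_spacing = rpe_vm$mean_spacing_um,
    rpe_area = rpe_vm$mean_cell_area_um2, ps_density = NA_real_,
    n_pr = NA_integer_, n_rpe = rpe_vm$n_cells_counted,
    osl_n_valid = NA_integer_)
  n_excluded <- sum(!rpe_vm$cells$included)
  n_pr <- NULL

  # --- cone PR layer (not resolved at the fovea) ---
  if (is.finite(tr$cone_density)) {
    cone_mos <- read_points_csv(
      file.path(sim, "mosaics", paste0("cone_", tag, ".csv")),
      window = config$cone_window_um, cell_class = "cone",
      pixel_size_um = px, eccentricity_deg = e)
    if (!is.null(vm)) cone_mos$vessel_mask <- structure(vm, pixel_size_um = px)
    cone_img <- render_enface(cone_mos, noise_cv = config$enface_noise_cv,
                              seed = tr$roi_seed + 4L)
    cone_hint <- eval_topography_model(models$cone, max(e, 1))
    cone_det <- detect_cells(cone_img, hex_spacing_um(cone_hint),
                             threshold_quantile = config$threshold_quantile,
                             min_sep_frac = config$min_sep_frac)
    cone_vm <- voronoi_metrics(cone_det, window = cone_mos$window,
                               vessel_mask = cone_mos$vessel_mask,
                               mask_pixel_size_um = px)
    row$pr_density <- cone_vm$density_cells_mm2
    row$pr_spacing <- cone_vm$mean_spacing_um
    row$n_pr <- cone_vm$n_cells_counted
    n_pr <- cone_vm$n_cells_counted
    n_excluded <- n_excluded + sum(!cone_vm$cells$included)
    row$pr_rpe_ratio <- pr_rpe_ratio(row$pr_density, row$rpe_density)
    ps <- tryCatch(
      power_spectrum_density(cone_img, cone_vm$density_cells_mm2,
                             vessel_mask = cone_mos$vessel_mask),
      error = function(e2) NULL)
    if (!is.null(ps)) row$ps_density <- ps$density_cells_mm2

    # per-cone OSL on the central subregion volume
    vw <- config$volume_window_um
    ctr <- c(mean(cone_mos$window[1:2]), mean(cone_mos$window[3:4]))
    sub_win <- c(ctr[1] - vw / 2, ctr[1] + vw / 2,
                 ctr[2] - vw / 2, ctr[2] + vw / 2)
    keep <- cone_mos$points$x_um >= sub_win[1] & cone_mos$points$x_um <= sub_win[2] &
            cone_mos$points$y_um >= sub_win[3] & cone_mos$points$y_um <= sub_win[4]
    sub_mos <- cone_mos
    sub_mos$points <- cone_mos$points[keep, ]
    sub_mos$window <- sub_win
    sub_mos$vessel_mask <- NULL
    tilt_amp <- 6  # um across the field, undone by flattening
    vol <- render_volume(
      sub_mos, osl_um = tr$osl_um, isos_depth_um = config$isos_depth_um,
      axial_pixel_um = config$axial_pixel_um,
      noise_cv = config$volume_noise_cv, seed = tr$roi_seed + 5L,
      osl_sd_um = config$osl_cell_sd_um,
      tilt_um = function(y, x) tilt_amp * (x - sub_win[1]) / vw)
    flat <- flatten_volume(vol)
    dp <- cone_det$points
    margin <- 2
    dp <- dp[dp$x_um >= sub_win[1] + margin & dp$x_um <= sub_win[2] - margin &
             dp$y_um >= sub_win[3] + margin & dp$y_um <= sub_win[4] - margin, ]
    rec <- measure_osl(flat$volume, dp)
    os <- osl_summary(rec)
    row$osl_mean <- os$mean_um
    row$osl_sd <- os$sd_um
    row$osl_n_valid <- os$n_valid
    n_excluded <- n_excluded + os$n_invalid
  }
  list(row = row, n_pr = n_pr, n_rpe = row$n_rpe, n_excluded = n_excluded)
}

#' Topography stage: cohort table and normative fits
#'
#' @param config A `run_config`.
#' @return Path of the topography directory, invisibly.
#' @export
pipeline_topography <- function(config) {
  stopifnot(inherits(config, "run_config"))
  src <- file.path(config$out_dir, "analyze", "roi_metrics.csv")
  if (!file.exists(src)) stop("missing analyze stage: run pipeline_analyze() first")
  dir <- file.path(config$out_dir, "topography")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- utils::read.csv(src)
  topo <- build_topography_table(metrics)
  utils::write.csv(topo$table, file.path(dir, "topography_table.csv"),
                   row.names = FALSE)
  # per-subject RPE density slopes (individual eccentricity fits)
  subj <- sort(unique(metrics$subject))
  slopes <- do.call(rbind, lapply(subj, function(s) {
    d <- metrics[metrics$subject == s & is.finite(metrics$rpe_density), ]
    if (nrow(d) < 3) return(NULL)
    f <- fit_topography(d$eccentricity_deg, d$rpe_density, "linear")
    data.frame(subject = s, slope = f$coefficients[["slope"]],
               intercept = f$coefficients[["intercept"]],
               r2_pearson = f$r2_pearson)
  }))
  utils::write.csv(slopes, file.path(dir, "subject_rpe_slopes.csv"),
                   row.names = FALSE)
  if (!is.null(topo$ratio_of_means)) {
    utils::write.csv(topo$ratio_of_means,
                     file.path(dir, "ratio_of_means.csv"), row.names = FALSE)
  }
  fits <- lapply(topo$fits, function(f) {
    list(model = f$model, coefficients = as.list(f$coefficients),
         coef_se = as.list(f$coef_se),
         r2_pearson = f$r2_pearson, r2_spearman = f$r2_spearman,
         r2_spearman_raw = f$r2_spearman_raw, p_value = f$p_value, n = f$n)
  })
  jsonlite::write_json(fits, file.path(dir, "topography_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(config, dir,
                 file.path(dir, c("topography_table.csv",
                                  "topography_fits.json",
                                  "subject_rpe_slopes.csv")), "topography")
  invisible(dir)
}

#' Reliability stage: inter-session and inter-grader statistics
#'
#' Simulates the reproducibility arm (k sessions per subject at the
#' configured locations, within-session CVs per metric), computes the
#' absolute-agreement average-measures ICC and the mean-normalized SD per
#' metric, and a simulated two-grader RPE comparison scored with Lin's
#' concordance.
#'
#' @param config A `run_config`.
#' @return Path of `reliability.json`, invisibly.
#' @export
pipeline_reliability <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- file.path(config$out_dir, "reliability")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- config$cohort
  wcv <- sp$within_session_cv
  bcv <- sp$between_subject_cv
  locs <- config$rel_locations_deg
  arms <- list(
    list(metric = "pr_density", model = "cone", cv = wcv[["pr_density"]],
         bcv = bcv[["cone"]], locations = max(locs)),
    list(metric = "osl", model = "osl", cv = wcv[["osl"]],
         bcv = bcv[["osl"]], locations = max(locs)),
    list(metric = "rpe_density", model = "rpe", cv = wcv[["rpe_density"]],
         bcv = bcv[["rpe"]], locations = locs)
  )
  out <- list(); sess_rows <- list()
  sd_by_metric <- list()
  kseed <- config$seed + 900L
  for (arm in arms) {
    for (loc in arm$locations) {
      true <- eval_topography_model(
        arm$model, max(loc, if (arm$model == "rpe") 0 else 1),
        list(cone = sp$cone_model, rpe = sp$rpe_model, osl = sp$osl_model))
      kseed <- kseed + 13L
      tab <- generate_repeat_sessions(true, k = config$rel_k,
                                      within_cv = arm$cv,
                                      n_subjects = config$rel_n_subjects,
                                      between_cv = arm$bcv, seed = kseed)
      icc <- icc_agreement(tab)
      nsd <- normalized_sd(tab)
      key <- sprintf("%s_%gdeg", arm$metric, loc)
      out[[key]] <- list(metric = arm$metric, location_deg = loc,
                         icc = icc$estimate, icc_ci = c(icc$ci_low, icc$ci_high),
                         icc_label = icc$label, normalized_sd = nsd,
                         k = config$rel_k, n = config$rel_n_subjects)
      sd_by_metric[[arm$metric]] <- c(sd_by_metric[[arm$metric]], nsd)
      df <- as.data.frame(as.table(tab))
      names(df) <- c("subject", "session", "value")
      df$metric <- arm$metric; df$location_deg <- loc
      sess_rows[[key]] <- df
    }
  }
  # simulated two-grader RPE counts across the cohort's ROIs
  sim <- file.path(config$out_dir, "simulate")
  lcc <- NULL
  if (file.exists(file.path(sim, "ground_truth.csv"))) {
    truth <- read_ground_truth(sim)$truth
    gr <- local_seed(config$seed + 501L, {
      d <- truth$rpe_density
      list(g1 = d * (1 + stats::rnorm(length(d), 0, config$grader_cv)),
           g2 = d * (1 + stats::rnorm(length(d), 0, config$grader_cv)))
    })
    l <- lin_ccc(gr$g1, gr$g2)
    lcc <- list(estimate = l$estimate, ci = c(l$ci_low, l$ci_high),
                n = l$n, grader_cv = config$grader_cv)
  }
  report <- list(
    sessions = out,
    normalized_sd_overall = lapply(sd_by_metric, mean),
    lcc_rpe_density = lcc,
    k = config$rel_k, n_subjects = config$rel_n_subjects, seed = config$seed)
  path <- file.path(dir, "reliability.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(do.call(rbind, sess_rows),
                   file.path(dir, "session_tables.csv"), row.names = FALSE)
  write_manifest(config, dir, path, "reliability")
  invisible(path)
}

write_manifest <- function(config, dir, files, stage) {
  cfg <- unclass(config)
  cfg$cohort <- unclass(cfg$cohort)
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         package_version = as.character(utils::packageVersion("aomosaic")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         parameters = cfg,
         files = basename(files)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(NULL)
}

#' Run the full pipeline
#'
#' simulate, analyze, topography, reliability, report — in order, each
#' stage reading only the previous stage's serialized outputs.
#' Deterministic for a fixed seed.
#'
#' @param config A `run_config`.
#' @param report Also render the report figures (default TRUE).
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config, report = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", config$out_dir)
  }
  pipeline_simulate(config)
  pipeline_analyze(config)
  pipeline_topography(config)
  pipeline_reliability(config)
  if (report) pipeline_report(config$out_dir)
  invisible(config$out_dir)
}
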
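# Report stage: figures and figure-data tables summarizing a pipeline run.
# Plots are presentation artifacts only; every number they show comes from
# the serialized CSV/JSON of the earlier stages.

#' Render the report for a completed pipeline run
#'
#' Produces per-metric eccentricity panels (cohort mean +- SD with the
#' fitted normative curve overlaid, evaluated from the serialized fit
#' coefficients) and a reliability dot plot, plus the exact data frames
#' behind each figure as CSV.
#'
#' @param run_dir Directory of a completed [run_pipeline()] run.
#' @return Named list of written file paths, invisibly.
#' @export
pipeline_report <- function(run_dir) {
  topo_csv <- file.path(run_dir, "topography", "topography_table.csv")
  fits_json <- file.path(run_dir, "topography", "topography_fits.json")
  rel_json <- file.path(run_dir, "reliability", "reliability.json")
  if (!file.exists(topo_csv)) stop("missing topography stage output: ", topo_csv)
  if (!file.exists(fits_json)) stop("missing topography stage output: ", fits_json)
  if (!file.exists(rel_json)) stop("missing reliability stage output: ", rel_json)
  dir <- file.path(run_dir, "report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  tab <- utils::read.csv(topo_csv)
  fits <- jsonlite::read_json(fits_json, simplifyVector = TRUE)
  rel <- jsonlite::read_json(rel_json, simplifyVector = TRUE)

  panels <- list(
    pr_density = list(metric = "pr_density", fit = "pr_density",
                      ylab = "Cone PR density (cells/mm²)"),
    rpe_density = list(metric = "rpe_density", fit = "rpe_density",
                       ylab = "RPE density (cells/mm²)"),
    osl = list(metric = "osl_mean", fit = "osl",
               ylab = "Outer segment length (µm)"),
    pr_rpe_ratio = list(metric = "pr_rpe_ratio", fit = "pr_rpe_ratio",
                        ylab = "PR/RPE ratio"))
  written <- list()
  for (nm in names(panels)) {
    p <- panels[[nm]]
    sub <- tab[tab$metric == p$metric, ]
    if (nrow(sub) == 0) next
    fit <- fits[[p$fit]]
    curve <- NULL
    if (!is.null(fit)) {
      ee <- seq(max(min(sub$eccentricity_deg),
                    if (fit$model == "power") 1 else 0),
                max(sub$eccentricity_deg), length.out = 100)
      cf <- fit$coefficients
      yy <- switch(fit$model,
        power = cf$a * ee^cf$b,
        linear = cf$intercept + cf$slope * ee,
        poly2 = cf$c0 + cf$c1 * ee + cf$c2 * ee^2)
      curve <- data.frame(eccentricity_deg = ee, fit = yy)
    }
    gg <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$eccentricity_deg,
                                            y = .data$mean)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             width = 0.2, na.rm = TRUE) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = "Temporal eccentricity (deg)", y = p$ylab) +
      ggplot2::theme_classic()
    if (!is.null(curve)) {
      gg <- gg + ggplot2::geom_line(data = curve,
                                    ggplot2::aes(y = .data$fit),
                                    linewidth = 0.8)
    }
    fig <- file.path(dir, paste0(nm, ".pdf"))
    ggplot2::ggsave(fig, gg, width = 4.5, height = 3.5)
    dat <- file.path(dir, paste0(nm, "_data.csv"))
    utils::write.csv(sub, dat, row.names = FALSE)
    if (!is.null(curve)) {
      utils::write.csv(curve, file.path(dir, paste0(nm, "_fit.csv")),
                       row.names = FALSE)
    }
    written[[nm]] <- fig
  }

  # reliability dot plot from the serialized session summaries
  ss <- rel$sessions
  if (length(ss)) {
    rd <- do.call(rbind, lapply(names(ss), function(k) {
      data.frame(arm = k, icc = ss[[k]]$icc,
                 lo = ss[[k]]$icc_ci[1], hi = ss[[k]]$icc_ci[2])
    }))
    gg <- ggplot2::ggplot(rd, ggplot2::aes(x = .data$icc, y = .data$arm)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                              height = 0.15, na.rm = TRUE) +
      ggplot2::xlim(0, 1) +
      ggplot2::labs(x = "ICC(A,k)", y = NULL) +
      ggplot2::theme_classic()
    fig <- file.path(dir, "reliability.pdf")
    ggplot2::ggsave(fig, gg, width = 4.5, height = 2.5)
    utils::write.csv(rd, file.path(dir, "reliability_data.csv"),
                     row.names = FALSE)
    written$reliability <- fig
  }
  invisible(written)
}
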
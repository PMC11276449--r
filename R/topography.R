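# Topographic model fitting: eccentricity relationships of the PR-RPE
# complex (power law for cone density and PR/RPE ratio, linear for RPE
# density, second-order polynomial for outer segment length).

#' Fit an eccentricity relationship
#'
#' Least-squares fit of one of three model families: `power`
#' (`y = a * E^b`, via nonlinear least squares initialized from log-log
#' regression), `linear` (`y = intercept + slope * E`) or `poly2`
#' (`y = c0 + c1 * E + c2 * E^2`). Goodness of fit is reported as the
#' squared Pearson and squared Spearman correlations of observed versus
#' predicted values (and, labeled separately, Spearman on the raw
#' eccentricity-value pairs), with a two-sided p-value for the Pearson
#' correlation.
#'
#' @param ecc_deg Eccentricities in degrees.
#' @param values Metric values (same length).
#' @param model One of `"power"`, `"linear"`, `"poly2"`.
#' @return A `topography_fit`: list with `model`, `coefficients`, `coef_se`
#'   (standard errors), `r2_pearson`, `r2_spearman`, `r2_spearman_raw`,
#'   `p_value`, `n`, `fitted`, `degenerate`.
#' @export
fit_topography <- function(ecc_deg, values, model = c("power", "linear", "poly2")) {
  model <- match.arg(model)
  ok <- is.finite(ecc_deg) & is.finite(values)
  E <- as.numeric(ecc_deg[ok]); y <- as.numeric(values[ok])
  n <- length(y)
  n_min <- switch(model, linear = 3, power = 3, poly2 = 4)
  if (n < n_min) stop("need at least ", n_min, " points for a ", model, " fit")

  if (stats::sd(y) == 0) {
    cf <- switch(model,
      linear = c(intercept = y[1], slope = 0),
      power = c(a = y[1], b = 0),
      poly2 = c(c0 = y[1], c1 = 0, c2 = 0))
    return(structure(list(model = model, coefficients = cf,
                          coef_se = cf * NA_real_,
                          r2_pearson = NA_real_, r2_spearman = NA_real_,
                          r2_spearman_raw = NA_real_, p_value = NA_real_,
                          n = n, fitted = rep(y[1], n), degenerate = TRUE),
                     class = "topography_fit"))
  }

  if (model == "power") {
    if (any(E <= 0) || any(y <= 0)) {
      stop("power model requires strictly positive eccentricities and values")
    }
    ll <- stats::lm(log(y) ~ log(E))
    start <- list(a = exp(stats::coef(ll)[[1]]), b = stats::coef(ll)[[2]])
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ a * E^b, start = start,
                   control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      cf <- c(a = start$a, b = start$b)
      se <- cf * NA_real_
    } else {
      co <- stats::coef(fit)
      cf <- c(a = co[["a"]], b = co[["b"]])
      se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                     error = function(e) cf * NA_real_)
      names(se) <- names(cf)
    }
    pred <- cf[["a"]] * E^cf[["b"]]
  } else if (model == "linear") {
    X <- cbind(1, E)
    if (qr(X)$rank < 2) stop("rank-deficient design")
    fit <- stats::lm(y ~ E)
    co <- stats::coef(fit)
    cf <- c(intercept = co[[1]], slope = co[[2]])
    se <- stats::coef(suppressWarnings(summary(fit)))[, "Std. Error"]
    names(se) <- names(cf)
    pred <- stats::fitted(fit)
  } else {
    X <- cbind(1, E, E^2)
    if (qr(X)$rank < 3) stop("rank-deficient design")
    fit <- stats::lm(y ~ E + I(E^2))
    co <- stats::coef(fit)
    cf <- c(c0 = co[[1]], c1 = co[[2]], c2 = co[[3]])
    se <- stats::coef(suppressWarnings(summary(fit)))[, "Std. Error"]
    names(se) <- names(cf)
    pred <- stats::fitted(fit)
  }

  r2p <- stats::cor(y, pred)^2
  pv <- if (stats::sd(pred) > 0) {
    stats::cor.test(y, pred)$p.value
  } else NA_real_
  r2s <- if (stats::sd(pred) > 0) {
    stats::cor(y, pred, method = "spearman")^2
  } else NA_real_
  r2s_raw <- stats::cor(E, y, method = "spearman")^2
  structure(list(model = model, coefficients = cf, coef_se = se,
                 r2_pearson = r2p, r2_spearman = r2s,
                 r2_spearman_raw = r2s_raw, p_value = pv, n = n,
                 fitted = as.numeric(pred), degenerate = FALSE),
            class = "topography_fit")
}

#' @export
print.topography_fit <- function(x, ...) {
  cat(sprintf("Topography fit (%s), n = %d%s\n", x$model, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  cat("  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  if (!x$degenerate) {
    cat(sprintf("  Rp^2 = %.3f, Rs^2 = %.3f (raw %.3f), p = %.3g\n",
                x$r2_pearson, x$r2_spearman, x$r2_spearman_raw, x$p_value))
  }
  invisible(x)
}

#' Predict from a topography fit
#'
#' @param object A `topography_fit`.
#' @param ecc_deg Eccentricities at which to evaluate the model.
#' @param ... Unused.
#' @return Predicted values.
#' @export
predict.topography_fit <- function(object, ecc_deg, ...) {
  cf <- object$coefficients
  switch(object$model,
    power = cf[["a"]] * ecc_deg^cf[["b"]],
    linear = cf[["intercept"]] + cf[["slope"]] * ecc_deg,
    poly2 = cf[["c0"]] + cf[["c1"]] * ecc_deg + cf[["c2"]] * ecc_deg^2)
}

#' Photoreceptor-to-RPE density ratio
#'
#' @param pr_density Cone photoreceptor density (cells/mm^2).
#' @param rpe_density RPE density (cells/mm^2); must be positive.
#' @return Elementwise `pr_density / rpe_density`.
#' @export
pr_rpe_ratio <- function(pr_density, rpe_density) {
  if (any(!is.na(rpe_density) & rpe_density <= 0)) {
    stop("RPE density must be positive")
  }
  pr_density / rpe_density
}

#' Assemble the cohort topography table and normative fits
#'
#' Summarizes per-ROI metrics to per-eccentricity cohort means and SDs and
#' fits the normative models to the mean data: power law for cone density
#' (from 1 degree outward) and PR/RPE ratio, a line for RPE density (all
#' eccentricities), and a second-order polynomial for OSL. The PR/RPE curve
#' uses per-subject ratios averaged per eccentricity (mean of ratios); the
#' ratio of cohort-mean densities is reported alongside.
#'
#' @param roi_metrics data.frame with columns `subject`, `eccentricity_deg`
#'   and metric columns `pr_density`, `rpe_density`, `osl_mean` (others are
#'   summarized too if present).
#' @return List with `table` (long data.frame metric, eccentricity_deg,
#'   mean, sd, n), `fits` (named list of `topography_fit`s),
#'   `ratio_of_means` (data.frame), and `excluded` (log of skipped cells).
#' @export
build_topography_table <- function(roi_metrics) {
  req <- c("subject", "eccentricity_deg")
  stopifnot(all(req %in% names(roi_metrics)))
  if (length(unique(roi_metrics$subject)) < 2) stop("need at least 2 subjects")
  if (length(unique(roi_metrics$eccentricity_deg)) < 4) {
    stop("need at least 4 eccentricities")
  }
  df <- roi_metrics
  if (!("pr_rpe_ratio" %in% names(df)) &&
      all(c("pr_density", "rpe_density") %in% names(df))) {
    df$pr_rpe_ratio <- pr_rpe_ratio(df$pr_density, df$rpe_density)
  }
  metric_cols <- setdiff(names(df), c("subject", "eccentricity_deg"))
  metric_cols <- metric_cols[vapply(df[metric_cols], is.numeric, logical(1))]

  rows <- list(); excluded <- character(0)
  for (m in metric_cols) {
    for (e in sort(unique(df$eccentricity_deg))) {
      v <- df[[m]][df$eccentricity_deg == e]
      v <- v[is.finite(v)]
      if (length(v) == 0) {
        excluded <- c(excluded, sprintf("%s at %g deg: no finite values", m, e))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, eccentricity_deg = e, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_, n = length(v))
    }
  }
  tab <- do.call(rbind, rows)

  mean_of <- function(m, emin = -Inf) {
    s <- tab[tab$metric == m & tab$eccentricity_deg >= emin, ]
    s[order(s$eccentricity_deg), ]
  }
  fits <- list()
  try_fit <- function(name, s, model) {
    f <- tryCatch(fit_topography(s$eccentricity_deg, s$mean, model),
                  error = function(e) {
                    excluded <<- c(excluded, sprintf(
                      "%s %s fit skipped: %s", name, model,
                      conditionMessage(e)))
                    NULL
                  })
    if (!is.null(f)) fits[[name]] <<- f
  }
  if ("pr_density" %in% metric_cols) {
    try_fit("pr_density", mean_of("pr_density", 1), "power")
  }
  if ("rpe_density" %in% metric_cols) {
    try_fit("rpe_density", mean_of("rpe_density"), "linear")
  }
  if ("osl_mean" %in% metric_cols) {
    try_fit("osl", mean_of("osl_mean", 1), "poly2")
  }
  if ("pr_rpe_ratio" %in% metric_cols) {
    try_fit("pr_rpe_ratio", mean_of("pr_rpe_ratio", 1), "power")
  }

  rom <- NULL
  if (all(c("pr_density", "rpe_density") %in% metric_cols)) {
    pr <- mean_of("pr_density", 1); rp <- mean_of("rpe_density", 1)
    ee <- intersect(pr$eccentricity_deg, rp$eccentricity_deg)
    rom <- data.frame(
      eccentricity_deg = ee,
      ratio_of_means = pr$mean[match(ee, pr$eccentricity_deg)] /
        rp$mean[match(ee, rp$eccentricity_deg)])
  }
  list(table = tab, fits = fits, ratio_of_means = rom, excluded = excluded)
}
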
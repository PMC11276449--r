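# Synthetic study cohorts: subject-level variation around the normative
# topographic models, plus repeat-session tables for reproducibility work.

#' Default topographic models of the PR-RPE complex
#'
#' Cone density follows a power law `D = a * E^b` (cells/mm^2, E in degrees,
#' anchored at 1 degree), RPE density a line `D = intercept + slope * E`,
#' and outer segment length a second-order polynomial
#' `OSL = c0 + c1 * E + c2 * E^2` constrained to decrease monotonically over
#' 1-12 degrees (vertex placed at 12 degrees).
#'
#' @return Named list with `cone`, `rpe`, `osl` coefficient vectors.
#' @export
default_topography_models <- function() {
  c2 <- 15.3 / 121
  c1 <- -24 * c2
  list(
    cone = c(a = 53329, b = -0.731),
    rpe = c(intercept = 6913, slope = -123),
    osl = c(c0 = 33.3 - c1 - c2, c1 = c1, c2 = c2)
  )
}

#' Evaluate a topographic model at given eccentricities
#'
#' @param model `"cone"`, `"rpe"` or `"osl"`, or a coefficient vector of the
#'   corresponding shape.
#' @param ecc_deg Eccentricities in degrees.
#' @param models Model list as from [default_topography_models()].
#' @return Model values (cells/mm^2 or um).
#' @export
eval_topography_model <- function(model, ecc_deg,
                                  models = default_topography_models()) {
  if (is.character(model)) {
    kind <- model; cf <- models[[model]]
  } else {
    cf <- model
    kind <- if (!is.null(names(cf)) && "a" %in% names(cf)) "cone"
            else if (length(cf) == 2) "rpe" else "osl"
  }
  switch(kind,
    cone = cf[["a"]] * ecc_deg^cf[["b"]],
    rpe = cf[["intercept"]] + cf[["slope"]] * ecc_deg,
    osl = cf[["c0"]] + cf[["c1"]] * ecc_deg + cf[["c2"]] * ecc_deg^2
  )
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param eccentricities_deg Sampled eccentricities (degrees, ascending).
#' @param cone_model,rpe_model,osl_model Model coefficients (see
#'   [default_topography_models()]).
#' @param between_subject_cv Named multiplicative between-subject CVs
#'   (fractions) for `cone`, `rpe`, `osl`.
#' @param within_session_cv Named within-subject between-session CVs for
#'   `pr_density`, `osl`, `rpe_density`.
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 11,
                        eccentricities_deg = 0:12,
                        cone_model = default_topography_models()$cone,
                        rpe_model = default_topography_models()$rpe,
                        osl_model = default_topography_models()$osl,
                        between_subject_cv = c(cone = 0.10, rpe = 0.08, osl = 0.07),
                        within_session_cv = c(pr_density = 0.016, osl = 0.020,
                                              rpe_density = 0.023),
                        seed = 1L) {
  stopifnot(n_subjects >= 1, length(eccentricities_deg) >= 1,
            all(between_subject_cv >= 0), all(within_session_cv >= 0))
  if (cone_model[["b"]] >= 0) stop("cone power-law exponent must be negative")
  if (rpe_model[["slope"]] >= 0) stop("RPE density slope must be negative")
  structure(
    list(n_subjects = as.integer(n_subjects),
         eccentricities_deg = sort(as.numeric(eccentricities_deg)),
         cone_model = cone_model, rpe_model = rpe_model, osl_model = osl_model,
         between_subject_cv = between_subject_cv,
         within_session_cv = within_session_cv,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic cohort with recorded ground truth
#'
#' Draws per-subject multiplicative effects (lognormal, mean 1, SD set by
#' the between-subject CV) for each metric and evaluates the topographic
#' models at each eccentricity. Cone density and OSL are defined from
#' 1 degree outward (cones are not resolved at the fovea); RPE density at
#' all eccentricities. Fully reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort`: list with `spec`, `truth` (data.frame subject,
#'   eccentricity_deg, cone_density, rpe_density, osl_um, roi_seed) and
#'   `subject_effects`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(spec$eccentricities_deg) == 0) stop("empty eccentricity list")
  ns <- spec$n_subjects
  ecc <- spec$eccentricities_deg
  local_seed(spec$seed, {
    ef <- data.frame(
      subject = seq_len(ns),
      cone = rlnorm_cv(ns, spec$between_subject_cv[["cone"]]),
      rpe = rlnorm_cv(ns, spec$between_subject_cv[["rpe"]]),
      osl = rlnorm_cv(ns, spec$between_subject_cv[["osl"]])
    )
    g <- expand.grid(subject = seq_len(ns), eccentricity_deg = ecc,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[order(g$subject, g$eccentricity_deg), ]
    rownames(g) <- NULL
    cone_ok <- g$eccentricity_deg >= 1
    g$cone_density <- ifelse(
      cone_ok,
      eval_topography_model(spec$cone_model, pmax(g$eccentricity_deg, 1)) *
        ef$cone[g$subject],
      NA_real_)
    g$rpe_density <- eval_topography_model(spec$rpe_model, g$eccentricity_deg) *
      ef$rpe[g$subject]
    g$osl_um <- ifelse(
      cone_ok,
      eval_topography_model(spec$osl_model, pmax(g$eccentricity_deg, 1)) *
        ef$osl[g$subject],
      NA_real_)
    g$roi_seed <- spec$seed + seq_len(nrow(g)) * 101L
    structure(list(spec = spec, truth = g, subject_effects = ef),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d eccentricities (seed %d)\n",
              x$spec$n_subjects, length(x$spec$eccentricities_deg),
              x$spec$seed))
  invisible(x)
}

#' Generate a subjects-by-sessions measurement table
#'
#' Each subject receives a lognormal mean (between-subject CV about
#' `true_value`); each session observation is that mean times
#' `1 + N(0, within_cv)`.
#'
#' @param true_value Population mean of the metric.
#' @param k Number of sessions (>= 2).
#' @param within_cv Within-subject between-session CV (fraction).
#' @param n_subjects Number of subjects.
#' @param between_cv Between-subject CV (fraction).
#' @param seed Integer seed.
#' @return Numeric matrix (subjects x sessions) with attribute
#'   `true_value`.
#' @export
generate_repeat_sessions <- function(true_value, k = 3, within_cv = 0.02,
                                     n_subjects = 7, between_cv = 0.08,
                                     seed = 1L) {
  stopifnot(k >= 2, n_subjects >= 1, within_cv >= 0, between_cv >= 0)
  local_seed(seed, {
    mu <- true_value * rlnorm_cv(n_subjects, between_cv)
    tab <- mu * matrix(1 + stats::rnorm(n_subjects * k, 0, within_cv),
                       n_subjects, k)
    dimnames(tab) <- list(subject = paste0("S", seq_len(n_subjects)),
                          session = paste0("V", seq_len(k)))
    attr(tab, "true_value") <- true_value
    tab
  })
}
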
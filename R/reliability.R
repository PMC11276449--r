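# Reproducibility statistics: absolute-agreement intraclass correlation for
# inter-session precision, Lin's concordance for inter-grader agreement, and
# the mean-normalized between-session SD.

reliability_label <- function(est) {
  if (!is.finite(est)) return(NA_character_)
  if (est < 0.5) "poor"
  else if (est < 0.75) "moderate"
  else if (est <= 0.9) "good"
  else "excellent"
}

reliability_result <- function(estimate, ci_low, ci_high, method, n, k = NA) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 method = method, n = n, k = k,
                 label = reliability_label(estimate)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("%s = %.3f", x$method, x$estimate))
  if (is.finite(x$ci_low)) {
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci_low, x$ci_high))
  }
  if (!is.na(x$label)) cat(sprintf(" [%s reliability]", x$label))
  cat("\n")
  invisible(x)
}

#' Intraclass correlation, absolute agreement, average of k sessions
#'
#' McGraw-Wong ICC(A,k): from the two-way ANOVA mean squares of a complete
#' subjects-by-sessions table (rows MS_R, columns MS_C, error MS_E),
#' `ICC = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)`. The confidence
#' interval is the standard F-based interval for absolute-agreement
#' average-measures ICC (single-measures bounds stepped up by
#' Spearman-Brown). The mixed-versus-random distinction does not change the
#' point estimate for this form.
#'
#' @param table Numeric matrix, rows = subjects (>= 3), columns = sessions
#'   (k >= 2), complete.
#' @param confidence Confidence level (default 0.95).
#' @return A `reliability_result` with a reliability label
#'   (<0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, >0.9 excellent).
#' @export
icc_agreement <- function(table, confidence = 0.95) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("session table must be complete (no missing cells)")
  n <- nrow(table); k <- ncol(table)
  if (n < 3) stop("need at least 3 subjects")
  if (k < 2) stop("need at least 2 sessions")
  grand <- mean(table)
  if (sum((table - grand)^2) == 0) {
    stop("ICC undefined: the table has zero total variance")
  }
  rowm <- rowMeans(table); colm <- colMeans(table)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  SSE <- sum((table - grand)^2) - k * sum((rowm - grand)^2) -
    n * sum((colm - grand)^2)
  MSE <- max(SSE, 0) / ((n - 1) * (k - 1))
  est <- (MSR - MSE) / (MSR + (MSC - MSE) / n)

  ci <- c(NA_real_, NA_real_)
  alpha <- 1 - confidence
  if (MSE > 0) {
    r1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    a <- k * r1 / (n * (1 - r1))
    b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    L1 <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    U1 <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(L1 * k / (1 + (k - 1) * L1), U1 * k / (1 + (k - 1) * U1))
    ci <- pmin(pmax(ci, -1), 1)
    ci <- c(min(ci[1], est), max(ci[2], est))
  } else if (est == 1) {
    ci <- c(1, 1)
  }
  reliability_result(est, ci[1], ci[2], "ICC(A,k)", n, k)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two raters about the identity line:
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' n-divisor moments. The confidence interval uses the Fisher z transform
#' with Lin's variance.
#'
#' @param x,y Paired measurements (length >= 3).
#' @param confidence Confidence level (default 0.95).
#' @return A `reliability_result` (method `"LCC"`).
#' @export
lin_ccc <- function(x, y, confidence = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need equal-length vectors of >= 3 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) stop("LCC undefined: both vectors are constant")
  rho_c <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)

  ci <- c(NA_real_, NA_real_)
  if (abs(rho_c) < 1 && sx2 > 0 && sy2 > 0 && n > 2) {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mx - my) / (sx2 * sy2)^0.25
    z <- atanh(rho_c)
    sz2 <- ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
            4 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
            2 * rho_c^4 * u^4 / (r^2 * (1 - rho_c^2)^2)) / (n - 2)
    if (is.finite(sz2) && sz2 > 0) {
      zc <- stats::qnorm(1 - (1 - confidence) / 2)
      ci <- tanh(c(z - zc * sqrt(sz2), z + zc * sqrt(sz2)))
    }
  } else if (rho_c == 1) {
    ci <- c(1, 1)
  }
  reliability_result(rho_c, ci[1], ci[2], "LCC", n)
}

#' Mean-normalized between-session standard deviation
#'
#' Per-subject SD across sessions divided by the per-subject mean, averaged
#' over subjects with equal weights. Reported as a fraction (0.016 = 1.6%).
#'
#' @param table Numeric matrix, rows = subjects, columns = sessions;
#'   complete.
#' @return Normalized SD (fraction).
#' @export
normalized_sd <- function(table) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("session table must be complete (no missing cells)")
  mu <- rowMeans(table)
  if (any(mu == 0)) stop("normalized SD undefined: zero subject mean")
  mean(apply(table, 1, stats::sd) / mu)
}
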
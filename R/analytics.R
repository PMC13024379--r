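#' Fit the concentration-intensity calibration curve
#'
#' Ordinary least squares of luminescence intensity on analyte concentration
#' across the calibrator series, on raw (untransformed) axes. The clinical
#' instrument this emulates is calibrated with a single linear fit spanning
#' roughly four decades of concentration; a log-log mode is available for
#' diagnostic comparison but is off by default.
#'
#' @param points a data frame with columns `concentration` and `intensity`
#'   (at least 2 rows with distinct concentrations), or two vectors passed
#'   via `concentration`/`intensity`.
#' @param concentration,intensity alternative vector interface.
#' @param log_log if `TRUE`, fit `log10(intensity) ~ log10(concentration)`
#'   (requires strictly positive data). Default `FALSE`.
#' @return A `calibration_curve` object: `slope`, `intercept`, `r_squared`,
#'   `n_points`, `residuals`, `fitted`, `log_log`.
#' @examples
#' conc <- c(0, 1, 2)
#' fit_calibration(data.frame(concentration = conc, intensity = 2 * conc + 3))
#' @export
fit_calibration <- function(points = NULL, concentration = NULL,
                            intensity = NULL, log_log = FALSE) {
  if (!is.null(points)) {
    concentration <- points$concentration
    intensity <- points$intensity
  }
  if (length(concentration) < 2 || length(concentration) != length(intensity)) {
    stop("fit_calibration: need >= 2 (concentration, intensity) pairs",
         call. = FALSE)
  }
  if (length(unique(concentration)) < 2) {
    stop("fit_calibration: all concentrations identical (rank deficient)",
         call. = FALSE)
  }
  x <- concentration
  y <- intensity
  if (log_log) {
    if (any(x <= 0) || any(y <= 0)) {
      stop("fit_calibration: log-log mode needs strictly positive data",
           call. = FALSE)
    }
    x <- log10(x); y <- log10(y)
  }
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r_squared_of(fit, y),
         n_points = length(x),
         residuals = unname(stats::residuals(fit)),
         fitted = unname(stats::fitted(fit)),
         log_log = log_log),
    class = "calibration_curve"
  )
}

# 1 - SS_res/SS_tot from the fit; avoids summary.lm's perfect-fit warning
# on noiseless calibrators. Constant response with a perfect fit -> 1.
r_squared_of <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> y = %.6g x + %.6g, R^2 = %.6f, n = %d%s\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              if (x$log_log) " (log-log)" else ""))
  invisible(x)
}

#' Coefficient of variation of replicate measurements
#'
#' Replicate precision statistic: `cv = 100 * sd / mean`, using the sample
#' standard deviation (n - 1 divisor, the clinical-laboratory convention for
#' small replicate sets).
#'
#' @param replicates numeric vector of replicate intensities, length >= 2,
#'   with non-zero mean.
#' @return A `precision_result` with `mean`, `sd`, `cv` (percent) and `n`.
#' @examples
#' coefficient_of_variation(c(8, 12))$cv  # ~28.28
#' @export
coefficient_of_variation <- function(replicates) {
  if (length(replicates) < 2) {
    stop("coefficient_of_variation: need at least 2 replicates",
         call. = FALSE)
  }
  if (anyNA(replicates)) {
    stop("coefficient_of_variation: NA replicates not allowed", call. = FALSE)
  }
  m <- mean(replicates)
  if (m == 0) {
    stop("coefficient_of_variation: mean is zero; CV undefined",
         call. = FALSE)
  }
  s <- stats::sd(replicates)
  structure(
    list(mean = m, sd = s, cv = 100 * s / abs(m), n = length(replicates)),
    class = "precision_result"
  )
}

#' Method comparison against a reference platform
#'
#' Ordinary least squares of the test method's results on the reference
#' method's results across shared samples, with the coefficient of
#' determination equal to the squared Pearson correlation. (Agreement/bias
#' analysis such as Bland-Altman is out of scope.)
#'
#' @param reference,test numeric vectors of paired results, length >= 3.
#' @return A list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
compare_methods <- function(reference, test) {
  if (length(reference) != length(test) || length(reference) < 3) {
    stop("compare_methods: need >= 3 paired values", call. = FALSE)
  }
  if (stats::var(reference) == 0) {
    stop("compare_methods: reference values have zero variance",
         call. = FALSE)
  }
  fit <- stats::lm(test ~ reference)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r_squared_of(fit, test),
       n = length(reference))
}

#' Select the optimal fluidic condition from a velocity sweep
#'
#' Operationalizes "coverage is high and its standard deviation minimized":
#' among sweep points retaining at least `alpha` of the maximum observed
#' coverage, pick the one with the smallest uniformity SD, breaking ties by
#' lower flow velocity.
#'
#' @param sweep a data frame with columns `flow_velocity` (uL/s),
#'   `coverage` (percent), `sd` (percent), and optionally
#'   `acceleration_time` (s).
#' @param alpha coverage-retention fraction in (0, 1]. Default 0.9.
#' @return The selected row of `sweep` (single-row data frame).
#' @export
select_optimal_condition <- function(sweep, alpha = 0.9) {
  if (is.null(sweep) || nrow(sweep) == 0) {
    stop("select_optimal_condition: empty sweep", call. = FALSE)
  }
  if (!all(c("flow_velocity", "coverage", "sd") %in% names(sweep))) {
    stop("select_optimal_condition: sweep needs flow_velocity, coverage, sd",
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha <= 1)) {
    stop("select_optimal_condition: alpha must be in (0, 1]", call. = FALSE)
  }
  cand <- sweep[sweep$coverage >= alpha * max(sweep$coverage), , drop = FALSE]
  cand <- cand[order(cand$sd, cand$flow_velocity), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Relative change between two conditions
#'
#' `100 * (treated - baseline) / baseline`, e.g. the luminescence-intensity
#' change produced by switching from one fluidic condition to another at
#' matched bead coverage.
#'
#' @param baseline non-zero reference quantity.
#' @param treated quantity under the changed condition.
#' @return Percent change.
#' @export
percent_change <- function(baseline, treated) {
  if (!is.finite(baseline) || baseline == 0) {
    stop("percent_change: baseline must be finite and non-zero",
         call. = FALSE)
  }
  100 * (treated - baseline) / baseline
}
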
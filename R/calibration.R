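#' Calibrate delta-15N measurements against internal nitrite standards
#'
#' Isotope-ratio runs are calibrated and blank-corrected against in-laboratory
#' nitrite standards of known delta-15N bracketing the sample range (the
#' reference run used four standards at -76.9, -35.6, 1.7 and 36.7 per mil).
#' An ordinary-least-squares line `known = a * measured + b` is fitted to the
#' standards; applying the fitted line to raw sample values yields calibrated
#' delta-15N.
#'
#' @param measured Numeric vector of raw sample delta-15N values (per mil) to
#'   correct; may be `numeric(0)` if only the calibration is wanted.
#' @param standards_measured Measured delta-15N of the standards (per mil).
#' @param standards_known Accepted delta-15N of the same standards (per mil),
#'   same length and order as `standards_measured`.
#' @return An object of class `delta_calibration`: a list with elements
#'   `slope`, `intercept`, `standards_known`, `standards_measured`,
#'   `residual_sd` (per mil, 0 when fewer than 3 standards), and `corrected`,
#'   a tibble of the input samples with their calibrated values.
#' @examples
#' std <- c(-76.9, -35.6, 1.7, 36.7)
#' cal <- calibrate_delta(c(10, 20), std + 5, std)  # constant +5 offset
#' cal$corrected$d15n_calibrated                    # 5, 15
#' @seealso [apply_calibration()], [nitrite_standards()]
#' @export
calibrate_delta <- function(measured, standards_measured, standards_known) {
  if (length(standards_measured) < 2 || length(standards_known) < 2) {
    rlang::abort("insufficient standards: at least 2 required")
  }
  if (length(standards_measured) != length(standards_known)) {
    rlang::abort("standards_measured and standards_known must have equal length")
  }
  if (stats::sd(standards_measured) == 0) {
    rlang::abort("zero variance in measured standards: cannot fit calibration")
  }
  fit <- stats::lm(standards_known ~ standards_measured)
  n <- length(standards_known)
  res_sd <- if (n > 2) sqrt(sum(stats::residuals(fit)^2) / (n - 2)) else 0
  cal <- structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      standards_known = standards_known,
      standards_measured = standards_measured,
      residual_sd = res_sd
    ),
    class = "delta_calibration"
  )
  cal$corrected <- tibble::tibble(
    d15n_measured = measured,
    d15n_calibrated = apply_calibration(measured, cal)
  )
  cal
}

#' Apply a fitted delta calibration to raw values
#'
#' @param d15n Raw delta-15N values, per mil.
#' @param calibration A `delta_calibration` from [calibrate_delta()], or
#'   `NULL` for the identity (already-calibrated data).
#' @return Calibrated delta-15N values, per mil.
#' @export
apply_calibration <- function(d15n, calibration) {
  if (is.null(calibration)) {
    return(d15n)
  }
  stopifnot(inherits(calibration, "delta_calibration"))
  calibration$slope * d15n + calibration$intercept
}

#' Accepted values of the four internal nitrite isotope standards
#'
#' The delta-15N values (per mil, air scale) of the four in-laboratory NO2-
#' standards used to calibrate and blank-correct isotope runs.
#'
#' @return Numeric vector of length 4.
#' @export
nitrite_standards <- function() {
  c(-76.9, -35.6, 1.7, 36.7)
}

#' @export
print.delta_calibration <- function(x, ...) {
  cat("<delta_calibration>\n")
  cat(sprintf("  known = %.6g * measured + %.6g\n", x$slope, x$intercept))
  cat(sprintf("  standards: %d, residual SD %.3g permil\n",
              length(x$standards_known), x$residual_sd))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a delta calibration
#'
#' @param x A `delta_calibration`.
#' @param ... Unused.
#' @return A tibble with one row per standard: known, measured, fitted and
#'   residual values.
#' @method tidy delta_calibration
#' @export
tidy.delta_calibration <- function(x, ...) {
  fitted <- apply_calibration(x$standards_measured, x)
  tibble::tibble(
    standard_known = x$standards_known,
    standard_measured = x$standards_measured,
    fitted = fitted,
    residual = x$standards_known - fitted
  )
}

#' Glance at a delta calibration
#'
#' @param x A `delta_calibration`.
#' @param ... Unused.
#' @return A one-row tibble with slope, intercept, residual SD and the number
#'   of standards.
#' @method glance delta_calibration
#' @export
glance.delta_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    residual_sd = x$residual_sd,
    n_standards = length(x$standards_known)
  )
}
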
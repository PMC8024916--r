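#' Fit a calibration (standard) curve
#'
#' Ordinary least-squares line through (concentration, signal) calibration
#' points, used to convert assay signal (fluorescence, absorbance, or
#' internal-standard-normalised MS intensity) to product concentration.
#'
#' @param points Data frame with columns `conc` and `signal`.
#' @param analyte Optional analyte label carried in the object.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `analyte`, `fit` (the underlying `lm`), `sigma` (residual
#'   standard deviation).
#' @seealso [apply_curve()], [invert_curve()]
#' @examples
#' sc <- fit_standard_curve(data.frame(conc = 0:5, signal = 2 * (0:5) + 1))
#' invert_curve(sc, apply_curve(sc, 3))
#' @export
fit_standard_curve <- function(points, analyte = NA_character_) {
  stopifnot(is.data.frame(points), all(c("conc", "signal") %in% names(points)))
  if (length(unique(points$conc)) < 2L) {
    abort("standard curve needs at least two distinct concentrations")
  }
  fit <- lm(signal ~ conc, data = points)
  slope <- unname(coef(fit)[["conc"]])
  if (slope <= 0) abort("standard-curve slope must be positive")
  structure(
    list(slope = slope, intercept = unname(coef(fit)[["(Intercept)"]]),
         analyte = analyte, fit = fit,
         sigma = suppressWarnings(summary(fit)$sigma)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve%s> signal = %.6g * conc + %.6g (sigma %.3g)\n",
              if (is.na(x$analyte)) "" else paste0(": ", x$analyte),
              x$slope, x$intercept, x$sigma))
  invisible(x)
}

#' Convert concentration to expected signal
#' @param curve A `standard_curve`.
#' @param conc Concentrations.
#' @return Signals.
#' @export
apply_curve <- function(curve, conc) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$slope * conc + curve$intercept
}

#' Convert signal to concentration
#' @param curve A `standard_curve`.
#' @param signal Signals.
#' @return Concentrations.
#' @export
invert_curve <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"))
  (signal - curve$intercept) / curve$slope
}

#' Identity calibration curve (signal == concentration)
#'
#' Convenience constructor for simulated data already expressed in
#' concentration units.
#' @param analyte Optional analyte label.
#' @return A `standard_curve` with slope 1 and intercept 0.
#' @export
unit_curve <- function(analyte = NA_character_) {
  fit_standard_curve(data.frame(conc = c(0, 1), signal = c(0, 1)), analyte)
}
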
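#' Construct a calibration curve from known coefficients
#'
#' An affine map `attenuation = a + b * concentration` between X-ray
#' attenuation (microCT gray levels or clinical-CT Hounsfield units) and
#' effective iodine concentration in mgI/mL. Use this constructor when the
#' coefficients are already known (e.g. from a previously fitted phantom
#' scan); use [fit_linear_calibration()] to estimate them from measurements.
#'
#' @param a intercept, in attenuation units.
#' @param b slope, attenuation units per mgI/mL. Must be positive for a
#'   usable curve (iodine increases attenuation).
#' @param units `"GL"` (microCT gray levels) or `"HU"` (Hounsfield units).
#' @param r2 coefficient of determination of the fit that produced the
#'   coefficients, if known.
#' @param n number of calibration points, if known.
#' @return An object of class `calibration_curve` with fields `a`, `b`,
#'   `r2`, `r` (signed correlation, `sign(b) * sqrt(r2)`) and `units`.
#' @export
#' @examples
#' calibration_curve(a = -5.589, b = 23.537, units = "HU")
calibration_curve <- function(a, b, units = c("GL", "HU"), r2 = NA_real_,
                              n = NA_integer_) {
  units <- match.arg(units)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stopf("`a` must be a single finite number")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b == 0)
    stopf("`b` must be a single nonzero finite number")
  if (b < 0)
    warning("calibration slope b < 0: attenuation decreasing with iodine ",
            "concentration is physically implausible", call. = FALSE)
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stopf("`r2` must lie in [0, 1]")
  structure(
    list(a = a, b = b, r2 = r2, r = sign(b) * sqrt(r2), units = units,
         n = as.integer(n)),
    class = "calibration_curve"
  )
}

#' Fit the linear attenuation-concentration calibration
#'
#' Ordinary least-squares fit of `attenuation = a + b * concentration` to
#' phantom measurements of contrast-agent solutions at known iodine
#' concentrations. The same model is used at both scales: gray levels
#' against mgI/mL for microCT, Hounsfield units against mgI/mL for clinical
#' CT.
#'
#' `r2` is the squared Pearson correlation between observed and fitted
#' attenuations (identical to the regression R-squared for a straight-line
#' fit); the signed correlation is also exposed as `r` since both
#' conventions appear in practice.
#'
#' @param concentration iodine concentrations, mgI/mL (>= 2 distinct values).
#' @param attenuation measured mean attenuations, same length.
#' @inheritParams calibration_curve
#' @return A [calibration_curve()] object.
#' @export
#' @examples
#' conc <- c(0, 1, 2, 5, 10, 20)
#' att <- 0.7531 + 1.6189 * conc
#' fit_linear_calibration(conc, att, units = "GL")
fit_linear_calibration <- function(concentration, attenuation,
                                   units = c("GL", "HU")) {
  units <- match.arg(units)
  if (length(concentration) != length(attenuation))
    stopf("concentration (%d) and attenuation (%d) lengths differ",
          length(concentration), length(attenuation))
  if (length(concentration) < 2L)
    stopf("at least 2 calibration points are required")
  if (length(unique(concentration)) < 2L)
    stopf("all concentrations are equal: slope is undefined")
  fit <- stats::lm(attenuation ~ concentration)
  ab <- unname(coef(fit))
  fitted <- ab[1] + ab[2] * concentration
  tss <- sum((attenuation - mean(attenuation))^2)
  r2 <- if (tss == 0) 1 else 1 - sum((attenuation - fitted)^2) / tss
  r2 <- min(max(r2, 0), 1)
  calibration_curve(a = ab[1], b = ab[2], units = units, r2 = r2,
                    n = length(concentration))
}

#' Convert attenuation to iodine concentration (and back)
#'
#' Applies the inverse calibration `c = (value - a) / b`, or the forward map
#' `value = a + b * c`. Negative predicted concentrations are returned
#' as-is with a warning rather than clamped, so that downstream fits (e.g.
#' washout) are not biased; segmentation is expected to exclude such voxels.
#'
#' @param curve a [calibration_curve()].
#' @param value attenuation value(s), in `curve$units`.
#' @return Concentration(s) in mgI/mL.
#' @export
#' @examples
#' cc <- calibration_curve(-5.589, 23.537, "HU")
#' attenuation_to_concentration(cc, 229.781)  # 10 mgI/mL
attenuation_to_concentration <- function(curve, value) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$b == 0) stopf("calibration slope is zero; cannot invert")
  conc <- (value - curve$a) / curve$b
  if (any(conc < 0, na.rm = TRUE))
    warning("negative predicted concentration(s) returned unclamped",
            call. = FALSE)
  conc
}

#' @rdname attenuation_to_concentration
#' @param concentration concentration(s) in mgI/mL.
#' @export
concentration_to_attenuation <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$a + curve$b * concentration
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Linear calibration (%s): attenuation = %.6g + %.6g * c[mgI/mL]\n",
              x$units, x$a, x$b))
  if (!is.na(x$r2)) cat(sprintf("  r2 = %.6g (n = %s)\n", x$r2,
                                ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}
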
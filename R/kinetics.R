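#' Subtract the pre-contrast baseline from a planar series
#'
#' Replaces every image by `image - baseline`, isolating the attenuation
#' attributable to the contrast agent (the shared tissue/holder/saline
#' background cancels). The result is flagged, and subtracting an
#' already-subtracted series is an error — double subtraction would
#' silently corrupt the signal.
#'
#' @param series a [planar_series()].
#' @return The subtracted [planar_series()] (signed values; the baseline
#'   is retained for reference).
#' @export
subtract_baseline <- function(series) {
  stopifnot(inherits(series, "planar_series"))
  if (isTRUE(series$subtracted))
    stopf("series is already baseline-subtracted")
  if (is.null(series$baseline)) stopf("series has no baseline image")
  series$images <- lapply(series$images, function(im) im - series$baseline)
  series$subtracted <- TRUE
  series
}

#' Mean attenuation over a region of interest
#'
#' Mean, SD and pixel count over exactly those pixels whose centers fall
#' inside the ROI. The canonical uptake read-out uses a rectangular ROI
#' 100 pixels wide centered in the image, with its height matched to the
#' cartilage band (see [default_cartilage_roi()]).
#'
#' @param image numeric matrix.
#' @param roi a [roi_spec()]; must lie inside the image.
#' @return List with `mean`, `sd`, `n`.
#' @export
roi_mean <- function(image, roi) {
  sel <- roi_pixels(roi, dim(image))
  vals <- image[sel]
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
       n = length(vals))
}

#' @rdname roi_mean
#' @param series a [planar_series()] with geometry, used to center the
#'   default rectangular ROI on the cartilage band.
#' @param width ROI width in pixels.
#' @export
default_cartilage_roi <- function(series, width = 100) {
  stopifnot(inherits(series, "planar_series"))
  geo <- series$geometry
  if (is.null(geo)) stopf("series carries no geometry; supply an roi_spec")
  rows <- geo$cartilage_rows
  roi_spec("rect", center = c(mean(range(rows)), (geo$n_cols + 1) / 2),
           width = width, height = diff(range(rows)) + 1)
}

#' Fit the saturating-exponential uptake model
#'
#' Nonlinear least-squares fit of the Fickian uptake surrogate
#' `A(t) = a * (1 - exp(-t / tau))` to baseline-subtracted ROI means
#' against immersion time. `a` is the plateau attenuation and `tau` the
#' characteristic diffusion time — the time at which the curve reaches
#' `1 - e^-1` (about 63%, conventionally quoted as 65%) of its plateau.
#' The saturation time `tau95 = 5 * tau` is attached (see
#' [saturation_time()]).
#'
#' Initialization: `a0 = max(values)`; `tau0` is the earliest time at
#' which the signal reaches `(1 - e^-1) * a0`, falling back to a third of
#' the time span; bounded restarts at `tau0 * c(1, 0.5, 2)` guard against
#' local minima. Time zero (where the subtracted signal is identically 0
#' by construction) is excluded. A fit that fails to converge after all
#' restarts returns an object of class `fit_failure` — never a silent
#' `NA`.
#'
#' @param times immersion times, hours.
#' @param values baseline-subtracted mean attenuations.
#' @return An object of class `uptake_fit`: `a`, `tau` (h), `tau95` (h),
#'   `r2`, `residuals`, `cov` (2x2 covariance of `(a, tau)`), `n`; or a
#'   `fit_failure` object with a `message`.
#' @export
#' @examples
#' t <- cect_time_grid()
#' fit <- fit_uptake_curve(t, 10 * (1 - exp(-t / 0.4)))
#' c(fit$a, fit$tau, fit$tau95)
fit_uptake_curve <- function(times, values) {
  if (length(times) != length(values))
    stopf("times (%d) and values (%d) lengths differ",
          length(times), length(values))
  keep <- times > 0
  times <- times[keep]; values <- values[keep]
  if (length(times) < 3L)
    stopf("at least 3 positive-time points are required")
  if (length(unique(values)) == 1L)
    stopf("values are all equal; uptake model is degenerate")

  a0 <- max(values)
  thr <- (1 - exp(-1)) * a0
  above <- which(values >= thr)
  tau0 <- if (length(above)) times[min(above)] else max(times) / 3
  if (tau0 <= 0) tau0 <- max(times) / 3

  best <- NULL
  for (t0 in tau0 * c(1, 0.5, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(values ~ a * (1 - exp(-times / tau)),
                        start = list(a = a0, tau = t0),
                        lower = c(a = 1e-12, tau = 1e-12),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best))
    return(structure(
      list(message = "uptake fit failed to converge after bounded restarts"),
      class = c("uptake_fit_failure", "fit_failure")))

  est <- coef(best)
  res <- stats::resid(best)
  tss <- sum((values - mean(values))^2)
  covm <- tryCatch(vcov(best), error = function(e)
    matrix(NA_real_, 2, 2, dimnames = list(c("a", "tau"), c("a", "tau"))))
  structure(
    list(a = unname(est["a"]), tau = unname(est["tau"]),
         tau95 = 5 * unname(est["tau"]),
         r2 = if (tss > 0) 1 - sum(res^2) / tss else 1,
         residuals = as.numeric(res), cov = covm, n = length(times)),
    class = "uptake_fit"
  )
}

#' Saturation time of an uptake fit
#'
#' The conventional saturation time is `tau95 = 5 * tau`, the read-out
#' used to decide how long samples must remain immersed before imaging.
#' Note that `1 - e^-5` is 0.993, not 0.95: the mathematically exact time
#' to reach 95% of the plateau is `ln(20) * tau` (about `3 * tau`),
#' available via `exact = TRUE`. Both conventions are preserved
#' deliberately; the 5-tau form is canonical here.
#'
#' @param fit an `uptake_fit`.
#' @param exact return `ln(20) * tau` instead of `5 * tau`.
#' @return Saturation time in hours.
#' @export
saturation_time <- function(fit, exact = FALSE) {
  if (inherits(fit, "fit_failure")) stopf("cannot derive a saturation time: %s",
                                          fit$message)
  stopifnot(inherits(fit, "uptake_fit"))
  if (exact) log(20) * fit$tau else 5 * fit$tau
}

#' Depth-wise attenuation profile of a subtracted image
#'
#' Averages a baseline-subtracted image across the ROI width at each row
#' of the cartilage band and maps the band onto a normalized depth axis:
#' 0 at the articular surface (first band row), 1 at the tidemark (last
#' band row).
#'
#' @param image numeric matrix (baseline-subtracted).
#' @param cartilage_band integer row range, ordered surface to tidemark.
#' @param cols optional column range (ROI width); defaults to all columns.
#' @param time_h optional acquisition-time label, hours.
#' @return An object of class `depth_profile`: `depth` (in `[0, 1]`),
#'   `attenuation`, `time_h`.
#' @export
depth_profile <- function(image, cartilage_band, cols = NULL,
                          time_h = NA_real_) {
  if (length(cartilage_band) == 0L) stopf("empty cartilage band")
  if (min(cartilage_band) < 1 || max(cartilage_band) > nrow(image))
    stopf("cartilage band rows outside the image")
  cols <- cols %||% seq_len(ncol(image))
  prof <- rowMeans(image[cartilage_band, cols, drop = FALSE])
  structure(
    list(depth = seq(0, 1, length.out = length(cartilage_band)),
         attenuation = unname(prof), time_h = time_h),
    class = "depth_profile"
  )
}

#' Tertile layer summary of a depth profile
#'
#' Mean attenuation over the superficial, mid and deep thirds of the
#' normalized depth axis (`[0, 1/3)`, `[1/3, 2/3)`, `[2/3, 1]`),
#' reflecting the three visually distinct cartilage layers. The
#' count-weighted average of the three layer means equals the profile
#' mean.
#'
#' @param profile a [depth_profile()].
#' @return Named numeric: `superficial`, `mid`, `deep`.
#' @export
layer_summary <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  idx <- findInterval(profile$depth, c(1 / 3, 2 / 3)) + 1L
  c(superficial = mean(profile$attenuation[idx == 1L]),
    mid = mean(profile$attenuation[idx == 2L]),
    deep = mean(profile$attenuation[idx == 3L]))
}

#' Cartilage-to-bath concentration ratio
#'
#' The relative iodine concentration: retained cartilage concentration
#' divided by the bath concentration at the same time point. Values above
#' 1 indicate partitioning into the tissue.
#'
#' @param c_cart cartilage concentration, mgI/mL.
#' @param c_bath bath concentration, mgI/mL (> 0).
#' @return Dimensionless ratio.
#' @export
relative_concentration <- function(c_cart, c_bath) {
  if (any(c_bath <= 0)) stopf("`c_bath` must be positive")
  c_cart / c_bath
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat(sprintf("Uptake fit: a = %.5g, tau = %.5g h, tau95 = %.5g h, r2 = %.4f (n = %d)\n",
              x$a, x$tau, x$tau95, x$r2, x$n))
  invisible(x)
}

#' @export
print.fit_failure <- function(x, ...) {
  cat("Fit failure:", x$message, "\n")
  invisible(x)
}
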
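#' Geometry of the simulated planar radiograph
#'
#' Describes the row layout of a planar microCT projection of an
#' osteochondral plug immersed under a contrast-agent bath: a bath band at
#' the top of the image, the articular cartilage band below it (rows map
#' linearly to depth, surface at the first cartilage row, tidemark at the
#' last) and subchondral bone at the bottom. Baseline gray levels encode
#' the pre-contrast attenuation of each band; bath (saline) and cartilage
#' are nearly identical, which is precisely why the contrast agent is
#' needed.
#'
#' @param n_rows,n_cols image size in pixels.
#' @param bath_rows,cartilage_rows,bone_rows integer row ranges of the
#'   three bands; must partition `1:n_rows` without overlap.
#' @param baseline_gl named numeric: pre-contrast gray levels for `bath`,
#'   `cartilage`, `bone`.
#' @param pixel_size pixel pitch in mm (default 11.52 um).
#' @return An object of class `planar_geometry`.
#' @export
planar_geometry <- function(n_rows = 256L, n_cols = 256L,
                            bath_rows = 1:60, cartilage_rows = 61:234,
                            bone_rows = 235:256,
                            baseline_gl = c(bath = 100, cartilage = 105,
                                            bone = 400),
                            pixel_size = 0.01152) {
  check_scalar_pos(pixel_size, "pixel_size")
  all_rows <- sort(c(bath_rows, cartilage_rows, bone_rows))
  if (!identical(all_rows, seq_len(n_rows)))
    stopf("bath/cartilage/bone rows must partition 1:%d", n_rows)
  if (!all(c("bath", "cartilage", "bone") %in% names(baseline_gl)))
    stopf("baseline_gl must name bath, cartilage and bone levels")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         bath_rows = as.integer(bath_rows),
         cartilage_rows = as.integer(cartilage_rows),
         bone_rows = as.integer(bone_rows),
         baseline_gl = baseline_gl, pixel_size = pixel_size),
    class = "planar_geometry"
  )
}

baseline_image <- function(geometry) {
  img <- matrix(0, geometry$n_rows, geometry$n_cols)
  img[geometry$bath_rows, ] <- geometry$baseline_gl[["bath"]]
  img[geometry$cartilage_rows, ] <- geometry$baseline_gl[["cartilage"]]
  img[geometry$bone_rows, ] <- geometry$baseline_gl[["bone"]]
  img
}

#' Construct a planar radiograph time series
#'
#' Container for a stack of 2-D grayscale images with acquisition times and
#' the separate pre-contrast baseline image. All images must share the
#' baseline's dimensions, and there must be one time per image.
#'
#' @param images list of numeric matrices (gray levels).
#' @param times acquisition times in hours, one per image.
#' @param pixel_size pixel pitch, mm.
#' @param baseline pre-contrast image, same dimensions.
#' @param geometry optional [planar_geometry()] carried for downstream ROI
#'   defaults.
#' @return An object of class `planar_series`.
#' @export
planar_series <- function(images, times, pixel_size, baseline,
                          geometry = NULL) {
  if (!is.list(images) || length(images) == 0L)
    stopf("`images` must be a nonempty list of matrices")
  if (length(images) != length(times))
    stopf("image/time count mismatch: %d vs %d",
          length(images), length(times))
  dm <- dim(baseline)
  ok <- vapply(images, function(im) identical(dim(im), dm), logical(1))
  if (!all(ok)) stopf("all images must share the baseline dimensions")
  check_scalar_pos(pixel_size, "pixel_size")
  structure(
    list(images = images, times = as.numeric(times),
         pixel_size = pixel_size, baseline = baseline,
         geometry = geometry, subtracted = FALSE),
    class = "planar_series"
  )
}

#' Render a simulated diffusion field as a planar radiograph series
#'
#' Forward model of planar image formation: within the thin-sample,
#' monochromatic regime, attenuation is linear in local iodine
#' concentration, so each band of the image adds a contrast increment on
#' top of its baseline tissue pattern. The cartilage band samples
#' `c(x, t)` (rows mapped linearly to depth), the bath band uses
#' `c_bath(t)`, bone is unaffected. Additive Gaussian detector noise with
#' standard deviation `noise_sd` is applied independently to every image
#' (including the baseline) when `noise_sd > 0`.
#'
#' Two intercept conventions for the contrast increment are supported,
#' mirroring the two ways an affine calibration can be applied to
#' subtracted data:
#' * `"difference"` (default): increment `= b * c`. The calibration
#'   intercept is an absolute offset shared by baseline and contrast image,
#'   so it cancels in the subtraction.
#' * `"absolute"`: increment `= a + b * c` wherever `c > 0`. The intercept
#'   rides on top of the contrast signal, matching an analysis that applies
#'   the full affine map directly to subtracted values.
#'
#' @param field a `concentration_field` from [solve_slab_diffusion()].
#' @param calib a [calibration_curve()] in gray-level units.
#' @param geometry a [planar_geometry()].
#' @param noise_sd additive Gaussian noise SD, gray levels (>= 0).
#' @param seed integer seed for the noise.
#' @param intercept `"difference"` or `"absolute"` (see Details).
#' @return A [planar_series()] whose `times` are the field's output times.
#' @export
render_planar_series <- function(field, calib, geometry = planar_geometry(),
                                 noise_sd = 0, seed = NULL,
                                 intercept = c("difference", "absolute")) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(calib, "calibration_curve"),
            inherits(geometry, "planar_geometry"))
  intercept <- match.arg(intercept)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stopf("`noise_sd` must be a single nonnegative number")

  cart_rows <- geometry$cartilage_rows
  n_band <- length(cart_rows)
  depth_mm <- seq(0, field$config$L, length.out = n_band)
  base <- baseline_image(geometry)
  increment <- function(conc) {
    switch(intercept,
           difference = calib$b * conc,
           absolute = ifelse(conc > 0, calib$a + calib$b * conc, 0))
  }

  with_seed(seed, {
    images <- vector("list", length(field$times))
    for (ti in seq_along(field$times)) {
      img <- base
      c_depth <- stats::approx(field$depth_grid, field$c[ti, ],
                               xout = depth_mm, rule = 2)$y
      img[cart_rows, ] <- img[cart_rows, ] + increment(c_depth)
      img[geometry$bath_rows, ] <-
        img[geometry$bath_rows, ] + increment(field$c_bath[ti])
      if (noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
      images[[ti]] <- img
    }
    if (noise_sd > 0)
      base <- base + matrix(rnorm(length(base), 0, noise_sd), nrow(base))
    planar_series(images, field$times, geometry$pixel_size, base, geometry)
  })
}

#' @export
print.planar_series <- function(x, ...) {
  cat(sprintf("Planar series: %d images %dx%d, pixel %g mm, t in [%g, %g] h%s\n",
              length(x$images), nrow(x$baseline), ncol(x$baseline),
              x$pixel_size, min(x$times), max(x$times),
              if (isTRUE(x$subtracted)) " (baseline-subtracted)" else ""))
  invisible(x)
}
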
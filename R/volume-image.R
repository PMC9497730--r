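#' 3-D scalar volume with physical geometry
#'
#' Container for a reconstructed CT volume: a 3-D array of voxel values
#' plus voxel size and world origin in mm. Conventions, used consistently
#' throughout the package: the first array index (x) varies fastest,
#' indices are 1-based, and the world coordinate of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * voxel_size` — i.e. coordinates refer to
#' voxel centers.
#'
#' @param voxels 3-D numeric array.
#' @param voxel_size length-3 positive voxel pitch `(dx, dy, dz)`, mm.
#' @param origin length-3 world coordinate of the first voxel center, mm.
#' @param units units tag, e.g. `"HU"`, `"mgI/mL"`, `"mask"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, voxel_size, origin = c(0, 0, 0),
                         units = "HU") {
  if (length(dim(voxels)) != 3L)
    stopf("`voxels` must be a 3-D array (got %d dimension(s))",
          length(dim(voxels)))
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stopf("`voxel_size` must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("`origin` must be 3 finite values (mm)")
  structure(
    list(voxels = voxels, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), units = units),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Volume image %dx%dx%d, voxel (%s) mm, origin (%s) mm, units %s\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size, digits = 4), collapse = ", "),
              paste(format(x$origin, digits = 4), collapse = ", "),
              x$units))
  invisible(x)
}

#' Region- and volume-of-interest specifications
#'
#' `roi_spec()` describes a 2-D region on an image: a `"rect"` (center,
#' width, height) or a `"circle"` (center, radius). `voi_spec()` describes
#' a 3-D `"cylinder"` in a volume: an axis-aligned circular cylinder with a
#' center, radius and half-length along the cylinder axis. All coordinates
#' are in pixel/voxel index units (1-based, matching array indices);
#' membership is decided by pixel/voxel centers.
#'
#' @param shape `"rect"` or `"circle"` (ROI); `"cylinder"` (VOI).
#' @param center ROI: `(row, col)`; VOI: `(i, j, k)` voxel indices (may be
#'   fractional).
#' @param width,height rectangle dimensions in pixels.
#' @param radius circle/cylinder radius in pixels/voxels.
#' @param axis cylinder axis: 1, 2 or 3 (array dimension).
#' @param half_length cylinder half-length along `axis`, voxels.
#' @return An object of class `roi_spec` or `voi_spec`.
#' @export
roi_spec <- function(shape = c("rect", "circle"), center, width = NULL,
                     height = NULL, radius = NULL) {
  shape <- match.arg(shape)
  if (length(center) != 2L) stopf("`center` must be (row, col)")
  if (shape == "rect") {
    check_scalar_pos(width, "width"); check_scalar_pos(height, "height")
  } else {
    check_scalar_pos(radius, "radius")
  }
  structure(list(shape = shape, center = as.numeric(center), width = width,
                 height = height, radius = radius),
            class = "roi_spec")
}

#' @rdname roi_spec
#' @export
voi_spec <- function(shape = "cylinder", center, radius, axis = 1L,
                     half_length) {
  shape <- match.arg(shape)
  if (length(center) != 3L) stopf("`center` must be (i, j, k)")
  check_scalar_pos(radius, "radius")
  check_scalar_pos(half_length, "half_length")
  if (!axis %in% 1:3) stopf("`axis` must be 1, 2 or 3")
  structure(list(shape = shape, center = as.numeric(center),
                 radius = radius, axis = as.integer(axis),
                 half_length = half_length),
            class = "voi_spec")
}

# Logical membership arrays -------------------------------------------------

roi_pixels <- function(roi, dim_img) {
  stopifnot(inherits(roi, "roi_spec"))
  rows <- seq_len(dim_img[1]); cols <- seq_len(dim_img[2])
  if (roi$shape == "rect") {
    inr <- abs(rows - roi$center[1]) <= roi$height / 2
    inc <- abs(cols - roi$center[2]) <= roi$width / 2
    lo_r <- roi$center[1] - roi$height / 2; hi_r <- roi$center[1] + roi$height / 2
    lo_c <- roi$center[2] - roi$width / 2; hi_c <- roi$center[2] + roi$width / 2
    if (lo_r < 0.5 || hi_r > dim_img[1] + 0.5 ||
        lo_c < 0.5 || hi_c > dim_img[2] + 0.5)
      stopf("ROI exceeds image bounds")
    outer(inr, inc, `&`)
  } else {
    lo <- roi$center - roi$radius; hi <- roi$center + roi$radius
    if (any(lo < 0.5) || hi[1] > dim_img[1] + 0.5 || hi[2] > dim_img[2] + 0.5)
      stopf("ROI exceeds image bounds")
    outer((rows - roi$center[1])^2, (cols - roi$center[2])^2, `+`) <=
      roi$radius^2
  }
}

voi_voxels <- function(voi, dim_vol) {
  stopifnot(inherits(voi, "voi_spec"))
  ax <- voi$axis
  tr <- setdiff(1:3, ax)
  lo <- numeric(3); hi <- numeric(3)
  lo[ax] <- voi$center[ax] - voi$half_length
  hi[ax] <- voi$center[ax] + voi$half_length
  lo[tr] <- voi$center[tr] - voi$radius
  hi[tr] <- voi$center[tr] + voi$radius
  if (any(lo < 0.5) || any(hi > dim_vol + 0.5))
    stopf("VOI exceeds volume bounds")
  idx <- lapply(dim_vol, seq_len)
  along <- abs(idx[[ax]] - voi$center[ax]) <= voi$half_length
  r2 <- outer((idx[[tr[1]]] - voi$center[tr[1]])^2,
              (idx[[tr[2]]] - voi$center[tr[2]])^2, `+`)
  disc <- r2 <= voi$radius^2
  perm <- order(c(ax, tr))
  full <- outer(along, disc, `&`)            # ax x tr1 x tr2
  aperm(array(full, c(length(idx[[ax]]), dim(disc))), perm)
}
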
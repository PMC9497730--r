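#' Rigid transforms in 3-D
#'
#' A rigid (proper) transform `y = R x + t` with `R` a rotation matrix
#' (orthonormal, determinant +1) and `t` a translation in mm. Used to
#' describe the misalignment between paired CT acquisitions and its
#' estimate from fiducial markers.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stopf("`rotation` must be a 3x3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stopf("`rotation` is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stopf("`rotation` must be proper (det = +1), reflections excluded")
  if (length(translation) != 3L || any(!is.finite(translation)))
    stopf("`translation` must be a finite length-3 vector")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param axis rotation axis (length 3, need not be normalized).
#' @param angle_deg rotation angle, degrees.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply, invert and compose rigid transforms
#'
#' `transform_points()` maps an `n x 3` matrix (or length-3 vector) of mm
#' coordinates through the transform; `invert_rigid()` returns the inverse
#' transform; `compose_rigid(f, g)` returns the transform `x -> f(g(x))`;
#' `rotation_angle_deg()` extracts the rotation angle.
#'
#' @param transform a [rigid_transform()].
#' @param points `n x 3` matrix or length-3 vector, mm.
#' @return Transformed points / transforms / angle in degrees.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, 1L) else as.matrix(points)
  if (ncol(pts) != 3L) stopf("`points` must have 3 columns")
  out <- pts %*% t(transform$rotation) +
    matrix(transform$translation, nrow(pts), 3L, byrow = TRUE)
  if (vec) drop(out) else out
}

#' @rdname transform_points
#' @export
invert_rigid <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' @rdname transform_points
#' @param f,g [rigid_transform()]s; the composition applies `g` first.
#' @export
compose_rigid <- function(f, g) {
  stopifnot(inherits(f, "rigid_transform"), inherits(g, "rigid_transform"))
  rigid_transform(f$rotation %*% g$rotation,
                  as.numeric(f$rotation %*% g$translation) + f$translation)
}

#' @rdname transform_points
#' @export
rotation_angle_deg <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  ct <- (sum(diag(transform$rotation)) - 1) / 2
  acos(min(max(ct, -1), 1)) * 180 / pi
}

#' Least-squares rigid transform from fiducial markers
#'
#' Estimates the rigid transform `T` minimizing
#' `sum_i || T(src_i) - dst_i ||^2` over paired marker coordinates, by the
#' closed-form SVD (Kabsch) solution on centered point sets. Reflections
#' are excluded by construction (the sign of the smallest singular
#' direction is flipped if needed), so the result is always a proper
#' rotation plus translation — no scaling. At least three non-collinear
#' markers are required; four well-spread markers (the usual experimental
#' setup) give a well-conditioned estimate.
#'
#' @param src,dst `n x 3` matrices of paired marker coordinates, mm
#'   (`n >= 3`).
#' @return A [rigid_transform()] with an extra field `rms`, the root mean
#'   square fiducial registration error in mm.
#' @export
#' @examples
#' src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
#' tf <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(1, 2, 3))
#' est <- fit_rigid_from_fiducials(src, transform_points(tf, src))
#' est$rms  # ~0
fit_rigid_from_fiducials <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (ncol(src) != 3L || ncol(dst) != 3L)
    stopf("marker coordinates must have 3 columns")
  if (nrow(src) != nrow(dst))
    stopf("marker count mismatch: %d vs %d", nrow(src), nrow(dst))
  if (nrow(src) < 3L) stopf("at least 3 marker pairs are required")
  cs <- colMeans(src); cd <- colMeans(dst)
  X <- sweep(src, 2L, cs); Y <- sweep(dst, 2L, cd)
  sv_src <- svd(X)$d
  if (sv_src[2] <= 1e-8 * max(sv_src[1], 1e-300))
    stopf("markers are collinear or coincident; rotation is not identifiable")
  H <- crossprod(X, Y)                     # sum src_c dst_c^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tv <- cd - as.numeric(Rm %*% cs)
  tf <- rigid_transform(Rm, tv)
  res <- transform_points(tf, src) - dst
  tf$rms <- sqrt(mean(rowSums(res^2)))
  tf
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: rotation %.4g deg, translation (%s) mm%s\n",
              rotation_angle_deg(x),
              paste(format(x$translation, digits = 4), collapse = ", "),
              if (!is.null(x$rms)) sprintf(", fit RMS %.4g mm", x$rms) else ""))
  invisible(x)
}
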
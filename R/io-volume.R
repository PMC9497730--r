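#' Read and write volumes as NIfTI-1
#'
#' `write_volume()` stores a [volume_image()] losslessly (float64 voxels,
#' or uint8 when `vol$units == "mask"`), with the voxel size in the NIfTI
#' pixdim and the world origin in the sform/qform offset.
#' `read_volume()` reconstructs the `volume_image`; files whose payload is
#' not 3-D are rejected.
#'
#' @param vol a [volume_image()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param units units tag to attach on read (the NIfTI-1 header has no
#'   slot for HU-vs-concentration semantics).
#' @return `read_volume()`: a [volume_image()]. `write_volume()`: `path`,
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$voxel_size
  xf <- diag(4)
  diag(xf)[1:3] <- vol$voxel_size
  xf[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  dtype <- if (identical(vol$units, "mask")) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, units = "HU") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopf("expected a 3-D volume, got %d dimension(s)", length(d))
  vox <- as.array(img)
  attributes(vox) <- list(dim = d)
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  volume_image(vox, voxel_size = RNifti::pixdim(img)[1:3],
               origin = as.numeric(xf[1:3, 4]), units = units)
}
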
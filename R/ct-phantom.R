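#' Default clinical-CT calibration used by the phantom generator
#'
#' Affine Hounsfield-unit calibration of the cationic contrast agent at
#' 70 keV virtual monochromatic energy, as obtained from a concentration
#' phantom scan: intercept -5.589 HU, slope 23.537 HU per mgI/mL.
#'
#' @return A [calibration_curve()] in HU units.
#' @export
clinical_calibration <- function() {
  calibration_curve(a = -5.589, b = 23.537, units = "HU", r2 = 0.9969^2)
}

#' @rdname clinical_calibration
#' @return `microct_calibration()`: the gray-level calibration
#'   (intercept 0.7531 GL, slope 1.6189 GL per mgI/mL).
#' @export
microct_calibration <- function() {
  calibration_curve(a = 0.7531, b = 1.6189, units = "GL", r2 = 0.9955)
}

#' Build a paired pre/post contrast CT phantom
#'
#' Generates a synthetic tibial-plateau-like volume pair emulating a
#' clinical CECT experiment. The pre-contrast volume contains four tissue
#' compartments on the clinical voxel grid: air background, connective
#' tissue, subchondral bone (much denser than both soft tissues) and a
#' cartilage shell of spatially varying thickness sitting on the bone
#' surface. Pre-contrast, cartilage and connective tissue are nearly
#' indistinguishable (a few HU apart) — the experimental motivation for
#' contrast enhancement. The post-contrast volume adds the
#' calibration-forward HU increment of a known iodine map inside
#' cartilage, is then moved by a known rigid transform (simulating
#' repositioning between scans) and resampled, and both volumes receive
#' independent Gaussian noise. Four non-coplanar fiducial marker
#' coordinates are recorded in both frames; `fiducials_post` is exactly
#' the true transform applied to `fiducials_pre`.
#'
#' Geometry: array axis 1 (x) is the depth/thickness direction, emulating
#' a slab of tibial plateau imaged while immersed. Subchondral bone
#' occupies `x <= bone_top` voxels across the whole field, the cartilage
#' carpet the next `t(y, z)` voxels of each column (t between 5 and 9
#' voxels, i.e. 1.6-2.9 mm at 0.32 mm), connective tissue up to
#' `soft_top`, and saline bath (~0 HU background) above. Bone is nowhere
#' in contact with the low-attenuation background, mirroring a specimen
#' whose bright bone is embedded in soft tissue — this keeps
#' subtraction artifacts at misregistered high-contrast edges (the
#' voxels a manual operator would discard) from dominating the
#' difference volume.
#'
#' @param shape volume dimensions `(nx, ny, nz)` in voxels.
#' @param voxel_size voxel pitch, mm; defaults to the clinical grid
#'   `(0.32, 0.32, 0.625)`.
#' @param concentration true cartilage iodine concentration, mgI/mL.
#' @param calib HU [calibration_curve()] for the forward model.
#' @param intercept intercept convention of the forward increment, see
#'   [render_planar_series()].
#' @param rotation_axis,rotation_deg,translation the true rigid motion
#'   between scans (rotation about the volume center).
#' @param noise_sd_hu additive Gaussian noise SD, HU.
#' @param hu baseline tissue values, named `(background, connective,
#'   cartilage, bone)`; background defaults to 0 HU (saline bath).
#' @param bone_top number of bone voxels at the bottom of each column.
#' @param soft_top last tissue voxel along x; background above.
#' @param fiducials optional `4 x 3` matrix of marker coordinates (mm, pre
#'   frame); defaults to four well-spread non-coplanar markers on the bone
#'   side. Degenerate (collinear/coincident) placements are rejected.
#' @param seed integer seed; the generator is bitwise reproducible given
#'   `(arguments, seed)`.
#' @return An object of class `ct_phantom_pair`: list with `pre`, `post`
#'   ([volume_image()]s), `true_transform` ([rigid_transform()]),
#'   `true_iodine` (array, mgI/mL, pre frame), `tissue_labels` (integer
#'   array: 0 background, 1 connective, 2 bone, 3 cartilage),
#'   `fiducials_pre`, `fiducials_post` (mm), `thickness_vox`
#'   (ny x nz integer matrix of true cartilage thickness in voxels, NA
#'   outside the sample), `bone_top`, `concentration`, `calib`,
#'   `intercept`, `noise_sd_hu`.
#' @export
build_ct_phantom_pair <- function(shape = c(96L, 96L, 64L),
                                  voxel_size = c(0.32, 0.32, 0.625),
                                  concentration = 10,
                                  calib = clinical_calibration(),
                                  intercept = c("difference", "absolute"),
                                  rotation_axis = c(0.3, 0.5, 0.8),
                                  rotation_deg = 2,
                                  translation = c(0.2, -0.15, 0.3),
                                  noise_sd_hu = 20,
                                  hu = c(background = 0, connective = 40,
                                         cartilage = 55, bone = 1200),
                                  bone_top = 28L, soft_top = 80L,
                                  fiducials = NULL, seed = NULL) {
  intercept <- match.arg(intercept)
  stopifnot(inherits(calib, "calibration_curve"))
  if (!identical(calib$units, "HU"))
    stopf("phantom forward model requires an HU calibration")
  shape <- as.integer(shape)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  if (soft_top >= nx || bone_top + 10L > soft_top)
    stopf("need bone_top + cartilage < soft_top < nx")

  # tissue labels: 0 background (saline), 1 connective, 2 bone, 3 cartilage
  jj <- matrix(seq_len(ny), ny, nz)
  kk <- matrix(seq_len(nz), ny, nz, byrow = TRUE)
  thick <- round(1.5 * sin(2 * pi * (jj - 1) / ny) *
                   cos(2 * pi * (kk - 1) / nz)) + 7
  storage.mode(thick) <- "integer"
  ii <- array(rep(seq_len(nx), ny * nz), shape)
  tarr <- array(rep(thick, each = nx), shape)
  labels <- array(1L, shape)
  labels[ii > soft_top] <- 0L
  labels[ii <= bone_top] <- 2L
  labels[ii > bone_top & ii <= bone_top + tarr] <- 3L

  pre_clean <- array(hu[["background"]], shape)
  pre_clean[labels == 1L] <- hu[["connective"]]
  pre_clean[labels == 2L] <- hu[["bone"]]
  pre_clean[labels == 3L] <- hu[["cartilage"]]

  true_iodine <- array(0, shape)
  true_iodine[labels == 3L] <- concentration
  dhu <- switch(intercept,
                difference = calib$b * concentration,
                absolute = calib$a + calib$b * concentration)
  post_aligned <- pre_clean
  post_aligned[labels == 3L] <- post_aligned[labels == 3L] + dhu

  # true rigid motion, rotation about the volume center
  ctr <- (shape - 1) / 2 * voxel_size
  Rm <- rotation_about_axis(rotation_axis, rotation_deg)
  true_transform <- rigid_transform(Rm, ctr - as.numeric(Rm %*% ctr) +
                                      translation)

  if (is.null(fiducials))
    fiducials <- rbind(c(3.0, 8.0, 8.0), c(6.5, 24.0, 12.0),
                       c(4.2, 12.0, 30.0), c(7.8, 20.0, 33.0))
  fiducials <- as.matrix(fiducials)
  if (nrow(fiducials) != 4L || ncol(fiducials) != 3L)
    stopf("exactly 4 fiducial markers with 3 coordinates are required")
  sv <- svd(sweep(fiducials, 2L, colMeans(fiducials)))$d
  if (sv[2] <= 1e-8 * max(sv[1], 1e-300))
    stopf("degenerate fiducial placement: markers are collinear/coincident")
  fid_post <- transform_points(true_transform, fiducials)

  pre_vol <- volume_image(pre_clean, voxel_size, units = "HU")
  post_vol <- resample_volume(
    volume_image(post_aligned, voxel_size, units = "HU"),
    invert_rigid(true_transform), fill = hu[["background"]])

  with_seed(seed, {
    if (noise_sd_hu > 0) {
      pre_vol$voxels <- pre_vol$voxels +
        array(rnorm(prod(shape), 0, noise_sd_hu), shape)
      post_vol$voxels <- post_vol$voxels +
        array(rnorm(prod(shape), 0, noise_sd_hu), shape)
    }
    structure(
      list(pre = pre_vol, post = post_vol, true_transform = true_transform,
           true_iodine = true_iodine, tissue_labels = labels,
           fiducials_pre = fiducials, fiducials_post = fid_post,
           thickness_vox = thick, bone_top = as.integer(bone_top),
           concentration = concentration, calib = calib,
           intercept = intercept, noise_sd_hu = noise_sd_hu),
      class = "ct_phantom_pair"
    )
  })
}

#' Default cylindrical VOIs in the phantom's cartilage mid-thickness
#'
#' Places `n` cylindrical VOIs (axis along the depth direction) at fixed
#' lateral positions inside the phantom's cartilage shell, centered at
#' mid-thickness so that every member voxel lies strictly inside cartilage
#' for all generated thickness values. Used for VOI concentration and
#' thickness read-outs.
#'
#' @param pair a [build_ct_phantom_pair()] result.
#' @param radius cylinder radius, voxels.
#' @param half_length cylinder half-length along the depth axis, voxels.
#' @return List of [voi_spec()]s.
#' @export
default_vois <- function(pair, radius = 5, half_length = 1) {
  stopifnot(inherits(pair, "ct_phantom_pair"))
  d <- dim(pair$tissue_labels)
  ys <- round(seq(0.2, 0.8, length.out = 3) * d[2])
  zs <- round(seq(0.3, 0.7, length.out = 2) * d[3])
  out <- list()
  for (z in zs) for (y in ys) {
    t_here <- pair$thickness_vox[y, z]
    cx <- pair$bone_top + ceiling(t_here / 2)
    out[[length(out) + 1L]] <-
      voi_spec(center = c(cx, y, z), radius = radius, axis = 1L,
               half_length = half_length)
  }
  out
}

#' Ground-truth VOI thickness of a phantom
#'
#' The generator's true cartilage thickness for each VOI, averaged over
#' the VOI footprint columns (the same columns
#' [estimate_cartilage_thickness()] averages over), in mm.
#'
#' @param pair a [build_ct_phantom_pair()] result.
#' @param vois list of [voi_spec()]s with axis 1.
#' @return Numeric vector, one thickness per VOI.
#' @export
phantom_voi_thickness <- function(pair, vois) {
  stopifnot(inherits(pair, "ct_phantom_pair"))
  dx <- pair$pre$voxel_size[1]
  d <- dim(pair$tissue_labels)
  vapply(vois, function(voi) {
    if (voi$axis != 1L) stopf("phantom thickness is defined along axis 1")
    foot <- apply(voi_voxels(voi, d), c(2, 3), any)
    mean(pair$thickness_vox[foot]) * dx
  }, numeric(1))
}

#' Sample per-tissue attenuation values through circular ROIs
#'
#' Emulates the ROI-based tissue comparison of a clinical acquisition:
#' for each requested tissue, circular ROIs of the given radius are drawn
#' at random in-tissue positions across several consecutive slices (axial
#' index fixed per ROI) and the member voxel values are pooled. ROI
#' centers are chosen so the full disc lies inside the tissue label.
#'
#' @param vol a [volume_image()] to sample (e.g. phantom `pre` or `post`).
#' @param labels tissue label array from the phantom.
#' @param tissue label value to sample (1 connective, 2 bone, 3 cartilage).
#' @param n_rois number of ROIs (default 24: 6 ROIs on 4 slices).
#' @param radius ROI radius, voxels.
#' @param seed integer seed.
#' @return Numeric vector of pooled voxel values.
#' @export
tissue_roi_values <- function(vol, labels, tissue, n_rois = 24L, radius = 5,
                              seed = NULL) {
  stopifnot(inherits(vol, "volume_image"))
  d <- dim(labels)
  with_seed(seed, {
    vals <- list()
    # erode in-plane (y, z) so the disc fits inside the tissue
    cand <- which(labels == tissue, arr.ind = TRUE)
    if (nrow(cand) == 0L) stopf("no voxels with tissue label %s", tissue)
    r <- ceiling(radius)
    ok <- cand[, 2] > r & cand[, 2] <= d[2] - r &
      cand[, 3] > r & cand[, 3] <= d[3] - r
    cand <- cand[ok, , drop = FALSE]
    off <- expand.grid(dj = -r:r, dk = -r:r)
    off <- off[off$dj^2 + off$dk^2 <= radius^2, ]
    for (n in seq_len(n_rois)) {
      repeat {
        ctr <- cand[sample.int(nrow(cand), 1L), ]
        jj <- ctr[2] + off$dj; kk <- ctr[3] + off$dk
        lab <- labels[cbind(ctr[1], jj, kk)]
        if (all(lab == tissue)) break
      }
      vals[[n]] <- vol$voxels[cbind(ctr[1], jj, kk)]
    }
    unlist(vals)
  })
}

#' @export
print.ct_phantom_pair <- function(x, ...) {
  d <- dim(x$tissue_labels)
  cat(sprintf("CT phantom pair %dx%dx%d, cartilage %d voxels at %g mgI/mL\n",
              d[1], d[2], d[3], sum(x$tissue_labels == 3L), x$concentration))
  cat(sprintf("  true motion: %.3g deg rotation, |t| = %.3g mm, noise %g HU\n",
              rotation_angle_deg(x$true_transform),
              sqrt(sum((x$true_transform$translation)^2)), x$noise_sd_hu))
  invisible(x)
}

#' Simulate a contrast-agent washout curve
#'
#' Forward model of cartilage washout after transfer to a contrast-free
#' bath: retained concentration decays exponentially,
#' `c(t) = c0 * exp(-bw * t)`, sampled at the given times with optional
#' additive Gaussian noise. The default three-point grid (0, 24, 48 h)
#' mirrors the washout protocol this simulator emulates.
#'
#' @param c0 initial retained concentration, mgI/mL (> 0).
#' @param bw decay rate, 1/h (> 0).
#' @param times sampling times, hours (nonempty).
#' @param noise_sd additive Gaussian noise SD, mgI/mL.
#' @param seed integer seed.
#' @return List with `times` (h) and `concentration` (mgI/mL).
#' @export
#' @examples
#' simulate_washout_curve(10, 0.01, times = c(0, 24, 48))
simulate_washout_curve <- function(c0, bw, times = c(0, 24, 48),
                                   noise_sd = 0, seed = NULL) {
  check_scalar_pos(c0, "c0"); check_scalar_pos(bw, "bw")
  if (length(times) == 0L) stopf("`times` must be nonempty")
  if (noise_sd < 0) stopf("`noise_sd` must be nonnegative")
  with_seed(seed, {
    conc <- c0 * exp(-bw * times)
    if (noise_sd > 0) conc <- conc + rnorm(length(times), 0, noise_sd)
    list(times = as.numeric(times), concentration = conc)
  })
}
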
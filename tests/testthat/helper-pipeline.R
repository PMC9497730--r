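# Shared end-to-end volumetric runner: noiseless scene built once, fresh
# noise realizations per seed (volume noise + fiducial localization noise),
# then register -> subtract -> segment -> map -> morphometry.
make_clean_phantom <- function(...) {
  pair0 <- build_ct_phantom_pair(noise_sd_hu = 0, ...)
  list(pair = pair0,
       truth = pair0$tissue_labels == 3L,
       vois = default_vois(pair0),
       th_true = phantom_voi_thickness(pair0, default_vois(pair0)))
}

run_volumetric_once <- function(scene, seed, noise_sd_hu = 20,
                                fiducial_sd_mm = 0.1) {
  pair0 <- scene$pair
  shape <- dim(pair0$tissue_labels)
  set.seed(seed)
  pre <- pair0$pre; post <- pair0$post
  pre$voxels <- pre$voxels + array(rnorm(prod(shape), 0, noise_sd_hu), shape)
  post$voxels <- post$voxels + array(rnorm(prod(shape), 0, noise_sd_hu), shape)
  fidn <- matrix(rnorm(12, 0, fiducial_sd_mm), 4, 3)
  est <- fit_rigid_from_fiducials(pair0$fiducials_pre,
                                  pair0$fiducials_post + fidn)
  post_reg <- resample_volume(post, est, fill = NA_real_)
  dif <- subtract_volumes(post_reg, pre)
  # half-height threshold: partial-volume-unbiased edge criterion
  mask <- segment_iodine_mask(
    dif, threshold_hu = pair0$calib$b * pair0$concentration / 2)
  conc <- map_iodine(dif, pair0$calib, mask, intercept = pair0$intercept)
  vs <- voi_statistics(conc, scene$vois)
  th <- estimate_cartilage_thickness(mask, scene$vois, axis = 1L,
                                     pixel_size = pre$voxel_size[1])
  c(dice = dice_coefficient(mask, scene$truth),
    conc_rel_err = abs(vs$pooled$mean - pair0$concentration) /
      pair0$concentration,
    vol_err_vox = abs(sum(mask) - sum(scene$truth)),
    th_max_err_mm = max(abs(th$per_voi - scene$th_true)))
}
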
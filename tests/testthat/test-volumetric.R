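test_that("rigid fits recover exact and known transforms", {
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  id <- fit_rigid_from_fiducials(src, src)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(id$translation)), 1e-12)
  expect_lt(id$rms, 1e-12)

  tf <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(1, 2, 3))
  est <- fit_rigid_from_fiducials(src, transform_points(tf, src))
  expect_lt(max(abs(est$rotation - tf$rotation)), 1e-9)
  expect_lt(max(abs(est$translation - tf$translation)), 1e-9)
  expect_lt(est$rms, 1e-9)
})

test_that("rigid fits reject degenerate marker sets", {
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(fit_rigid_from_fiducials(line, line), "collinear")
  expect_error(fit_rigid_from_fiducials(line[1:2, ], line[1:2, ]),
               "at least 3")
  expect_error(fit_rigid_from_fiducials(line, line[1:3, ]), "mismatch")
})

test_that("rigid transforms compose, invert and validate", {
  tf <- rigid_transform(rotation_about_axis(c(1, 2, 3), 25), c(4, -1, 2))
  comp <- compose_rigid(invert_rigid(tf), tf)
  expect_lt(max(abs(comp$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(comp$translation)), 1e-12)
  expect_equal(rotation_angle_deg(tf), 25, tolerance = 1e-9)
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "proper")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("resampling is exact on lattice-aligned motions", {
  set.seed(5)
  v <- volume_image(array(rnorm(24 * 20 * 16), c(24, 20, 16)),
                    c(0.32, 0.32, 0.625))
  r <- resample_volume(v, rigid_transform())
  expect_identical(r$voxels, v$voxels)
  sh <- resample_volume(v, rigid_transform(translation = c(0.32, 0, 0)))
  expect_equal(sh$voxels[1:23, , ], v$voxels[2:24, , ], tolerance = 1e-12)
  expect_true(all(is.na(sh$voxels[24, , ])))
})

test_that("transform + inverse round-trip is bounded by field smoothness", {
  d <- c(32, 32, 24)
  g <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  smooth <- array(sin(g$i / 4) * cos(g$j / 5) + 0.5 * sin(g$k / 3), d)
  v <- volume_image(smooth, c(0.5, 0.5, 0.5))
  tf <- rigid_transform(rotation_about_axis(c(0, 0, 1), 3),
                        c(0.21, -0.13, 0.17))
  rt <- resample_volume(resample_volume(v, tf), invert_rigid(tf))
  interior <- rt$voxels[5:28, 5:28, 5:20]
  # local second difference bounds the trilinear interpolation error
  second_diff <- max(abs(diff(diff(smooth))))
  expect_lt(max(abs(interior - v$voxels[5:28, 5:28, 5:20]), na.rm = TRUE),
            2 * second_diff)
})

test_that("volume subtraction demands a shared grid and propagates NA", {
  v1 <- volume_image(array(1, c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(subtract_volumes(v1, v1)$voxels == 0))
  v2 <- volume_image(array(1, c(4, 4, 5)), c(1, 1, 1))
  expect_error(subtract_volumes(v2, v1), "grid")
  v3 <- v1; v3$voxels[1, 1, 1] <- NA
  expect_true(is.na(subtract_volumes(v3, v1)$voxels[1, 1, 1]))
})

test_that("segmentation thresholds and prunes small components", {
  z <- volume_image(array(0, c(10, 10, 10)), c(1, 1, 1))
  expect_false(any(segment_iodine_mask(z, threshold_hu = 5)))

  v <- array(0, c(12, 12, 12))
  v[4:9, 4:9, 4:9] <- 100        # 216-voxel block
  v[1, 1, 1] <- 100              # isolated speckle
  vol <- volume_image(v, c(1, 1, 1))
  m <- segment_iodine_mask(vol, threshold_hu = 50,
                           min_component_voxels = 27)
  expect_true(all(m[4:9, 4:9, 4:9]))
  expect_false(m[1, 1, 1])
  expect_identical(sum(m), 216L)
})

test_that("noiseless identity phantom segments to the exact label", {
  p <- build_ct_phantom_pair(rotation_deg = 0, translation = c(0, 0, 0),
                             noise_sd_hu = 0)
  d <- subtract_volumes(p$post, p$pre)
  m <- segment_iodine_mask(d, threshold_hu = p$calib$b * p$concentration / 2)
  expect_identical(m, p$tissue_labels == 3L)
  conc <- map_iodine(d, p$calib, m)
  expect_lt(max(abs(conc$voxels[m] - p$concentration)), 1e-9)
  expect_true(all(is.na(conc$voxels[!m])))
})

test_that("VOI statistics agree with brute-force membership", {
  v <- volume_image(array(2.5, c(30, 30, 20)), c(1, 1, 1))
  vois <- list(voi_spec(center = c(15, 10, 10), radius = 5, axis = 1,
                        half_length = 2),
               voi_spec(center = c(15, 20, 10), radius = 3, axis = 1,
                        half_length = 4))
  vs <- voi_statistics(v, vois)
  expect_true(all(vs$per_voi$mean == 2.5))
  expect_true(all(vs$per_voi$sd == 0))
  expect_identical(vs$per_voi$n[1], disc_center_count(5) * 5L)
  expect_identical(vs$per_voi$n[2], disc_center_count(3) * 9L)
  expect_identical(vs$pooled$n, vs$per_voi$n[1] + vs$per_voi$n[2])

  empty <- voi_statistics(v, list())
  expect_identical(nrow(empty$per_voi), 0L)
  expect_error(voi_statistics(v, list(voi_spec(center = c(1, 1, 1),
                                               radius = 5, axis = 1,
                                               half_length = 2))), "bounds")
})

test_that("map_iodine enforces units and the intercept convention", {
  v <- volume_image(array(-5.589, c(4, 4, 4)), c(1, 1, 1), units = "HU")
  mask <- array(TRUE, c(4, 4, 4))
  out <- map_iodine(v, clinical_calibration(), mask, intercept = "absolute")
  expect_lt(max(abs(out$voxels)), 1e-12)
  expect_error(map_iodine(v, microct_calibration(), mask), "unit mismatch")
})

test_that("volume estimation is exact arithmetic on the mask", {
  expect_identical(estimate_cartilage_volume(array(FALSE, c(4, 4, 4)),
                                             c(0.32, 0.32, 0.625)), 0)
  m <- array(FALSE, c(20, 20, 10))
  m[sample.int(4000, 1000)] <- TRUE
  expect_equal(estimate_cartilage_volume(m, c(0.32, 0.32, 0.625)), 0.064,
               tolerance = 1e-12)
  # invariance under a lattice-aligned shift
  m2 <- array(FALSE, c(20, 20, 10))
  m2[2:20, , ] <- m[1:19, , ]
  m2[1, , ] <- m[20, , ]
  expect_equal(estimate_cartilage_volume(m2, c(0.32, 0.32, 0.625)),
               estimate_cartilage_volume(m, c(0.32, 0.32, 0.625)))
})

test_that("thickness measures the longest contiguous run per column", {
  m <- array(FALSE, c(30, 20, 20))
  m[10:16, , ] <- TRUE                     # uniform 7-voxel slab
  vois <- list(voi_spec(center = c(13, 10, 10), radius = 4, axis = 1,
                        half_length = 3))
  th <- estimate_cartilage_thickness(m, vois, axis = 1, pixel_size = 0.32)
  expect_equal(th$mean, 2.24, tolerance = 1e-12)
  # speckle far from the slab must not inflate the run length
  m[25, , ] <- TRUE
  th2 <- estimate_cartilage_thickness(m, vois, axis = 1, pixel_size = 0.32)
  expect_equal(th2$mean, 2.24, tolerance = 1e-12)
  empty <- array(FALSE, c(30, 20, 20))
  expect_warning(
    th0 <- estimate_cartilage_thickness(empty, vois, axis = 1,
                                        pixel_size = 0.32),
    "no segmented voxels")
  expect_identical(th0$mean, 0)
})

test_that("phantom morphometry matches generator bookkeeping", {
  p <- build_ct_phantom_pair(rotation_deg = 0, translation = c(0, 0, 0),
                             noise_sd_hu = 0)
  truth <- p$tissue_labels == 3L
  vol <- estimate_cartilage_volume(truth, p$pre$voxel_size)
  expect_equal(vol, sum(p$thickness_vox) * prod(p$pre$voxel_size) / 1000,
               tolerance = 1e-12)
  vois <- default_vois(p)
  th <- estimate_cartilage_thickness(truth, vois, axis = 1,
                                     pixel_size = p$pre$voxel_size[1])
  expect_lt(max(abs(th$per_voi - phantom_voi_thickness(p, vois))), 1e-12)
})
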
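test_that("baseline subtraction zeroes identical images and guards reuse", {
  base <- matrix(5, 4, 4)
  ser <- planar_series(list(base, base), times = c(1, 2), pixel_size = 0.01,
                       baseline = base)
  sub <- subtract_baseline(ser)
  for (im in sub$images) expect_true(all(im == 0))
  expect_error(subtract_baseline(sub), "already")
})

test_that("baseline subtraction recovers a known added increment", {
  set.seed(9)
  base <- matrix(runif(64, 90, 110), 8, 8)
  inc <- matrix(runif(64, 0, 30), 8, 8)
  ser <- planar_series(list(base + inc), times = 1, pixel_size = 0.01,
                       baseline = base)
  sub <- subtract_baseline(ser)
  expect_equal(sub$images[[1]], inc, tolerance = 1e-12)
})

test_that("roi_mean matches hand arithmetic and the lattice oracle", {
  img <- matrix(7.5, 20, 20)
  rect <- roi_spec("rect", center = c(10.5, 10.5), width = 10, height = 10)
  rm <- roi_mean(img, rect)
  expect_equal(rm$mean, 7.5)
  expect_equal(rm$sd, 0)

  img2 <- matrix(c(1, 3, 2, 4), 2, 2)   # block {1, 2, 3, 4}
  full <- roi_spec("rect", center = c(1.5, 1.5), width = 2, height = 2)
  expect_equal(roi_mean(img2, full)$mean, 2.5)

  img3 <- matrix(1, 31, 31)
  circ <- roi_spec("circle", center = c(16, 16), radius = 5)
  expect_identical(roi_mean(img3, circ)$n, disc_center_count(5))

  expect_error(roi_mean(img2, roi_spec("rect", center = c(1, 1),
                                       width = 10, height = 10)), "bounds")
})

test_that("uptake fit recovers model-true parameters", {
  t <- cect_time_grid()
  fit <- fit_uptake_curve(t, 10 * (1 - exp(-t / 2)))
  expect_lt(abs(fit$a - 10), 1e-6)
  expect_lt(abs(fit$tau - 2), 1e-6)
  expect_gt(fit$r2, 1 - 1e-10)
  # at t = tau the fitted model sits at (1 - 1/e) of the plateau
  expect_equal(fit$a * (1 - exp(-fit$tau / fit$tau)),
               (1 - exp(-1)) * fit$a, tolerance = 1e-12)
})

test_that("uptake fit error shrinks as noise vanishes", {
  t <- cect_time_grid()
  truth <- 10 * (1 - exp(-t / 0.4))
  errs <- sapply(c(0.5, 0.05, 0.005), function(sd) {
    set.seed(21)
    fit <- fit_uptake_curve(t, truth + rnorm(length(t), 0, sd))
    abs(fit$tau - 0.4)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("uptake fit rejects unusable inputs", {
  expect_error(fit_uptake_curve(c(1, 2), c(1, 2)), "3")
  expect_error(fit_uptake_curve(c(1, 2, 3), c(4, 4, 4)), "equal")
  expect_error(fit_uptake_curve(c(1, 2), c(1, 2, 3)), "differ")
})

test_that("saturation time follows both conventions", {
  fit <- structure(list(a = 1, tau = 1, tau95 = 5), class = "uptake_fit")
  expect_identical(saturation_time(fit), 5)
  expect_equal(saturation_time(fit, exact = TRUE), log(20),
               tolerance = 1e-12)
  fit$tau <- 0.38
  expect_equal(saturation_time(fit), 1.9, tolerance = 1e-12)
  fit$tau <- 0.52
  expect_equal(saturation_time(fit), 2.6, tolerance = 1e-12)
  fail <- structure(list(message = "no"), class = "fit_failure")
  expect_error(saturation_time(fail), "no")
})

test_that("depth profiles map bands onto [0, 1] faithfully", {
  img <- matrix(3, 30, 10)
  p <- depth_profile(img, 5:24)
  expect_equal(range(p$depth), c(0, 1))
  expect_true(all(p$attenuation == 3))

  ramp <- matrix(rep(seq_len(30), 10), 30, 10)
  p2 <- depth_profile(ramp, 5:24)
  expect_equal(p2$attenuation[1], 5)
  expect_equal(p2$attenuation[20], 24)
  expect_true(all(diff(p2$attenuation) > 0))

  expect_error(depth_profile(img, integer(0)), "empty")
  expect_error(depth_profile(img, 25:40), "outside")
})

test_that("layer summary splits tertiles and preserves the mean", {
  img <- matrix(4, 30, 10)
  p <- depth_profile(img, 1:30)
  expect_equal(unname(layer_summary(p)), c(4, 4, 4))

  ramp <- depth_profile(matrix(rep(1:30, 10), 30, 10), 1:30)
  ls <- layer_summary(ramp)
  expect_true(ls["superficial"] < ls["mid"])
  expect_true(ls["mid"] < ls["deep"])
  counts <- table(findInterval(ramp$depth, c(1 / 3, 2 / 3)))
  expect_equal(sum(ls * as.numeric(counts)) / length(ramp$depth),
               mean(ramp$attenuation), tolerance = 1e-12)
})

test_that("early-time diffusion loads the superficial layer first", {
  cfg <- slab_diffusion_config(times = c(0.05, 26), nx = 120)
  f <- solve_slab_diffusion(cfg)
  ser <- subtract_baseline(render_planar_series(f, microct_calibration(),
                                                noise_sd = 0))
  early <- layer_summary(depth_profile(ser$images[[1]],
                                       ser$geometry$cartilage_rows))
  expect_gt(early["superficial"], early["deep"])
  # at saturation the profile is flat at kappa * c_bath through calibration
  late <- depth_profile(ser$images[[2]], ser$geometry$cartilage_rows)
  expected <- microct_calibration()$b * cfg$kappa * f$c_bath[2]
  expect_lt(max(abs(late$attenuation - expected)) / expected, 1e-3)
})

test_that("the single-exponential surrogate fits the slab series solution", {
  # infinite bath, depth-mean uptake sampled uniformly out to theta_max
  L <- 2; D <- 0.86
  for (theta_max in c(3, 5)) {
    times <- seq(0.02, theta_max, length.out = 40) * L^2 / D
    cfg <- slab_diffusion_config(D = D, L = L, kappa = 5,
                                 finite_bath = FALSE, times = times,
                                 nx = 150)
    f <- solve_slab_diffusion(cfg)
    fit <- fit_uptake_curve(f$times, mean_uptake(f))
    expect_gt(fit$r2, 0.98)
  }
})

test_that("relative concentration is a guarded ratio", {
  expect_equal(relative_concentration(10, 10), 1)
  expect_equal(relative_concentration(0, 5), 0)
  expect_equal(relative_concentration(21.2, 3.3432), 6.3412,
               tolerance = 1e-4)
  expect_error(relative_concentration(1, 0), "positive")
})
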
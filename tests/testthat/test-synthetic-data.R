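test_that("slab simulation starts empty with a full bath", {
  cfg <- slab_diffusion_config(times = c(0, 0.1, 0.5), nx = 60)
  f <- solve_slab_diffusion(cfg)
  expect_identical(f$times[1], 0)
  expect_true(all(f$c[1, ] == 0))
  expect_identical(f$c_bath[1], cfg$c_bath0)
})

test_that("infinite-bath simulation equilibrates at kappa * c_bath0", {
  cfg <- slab_diffusion_config(D = 0.86, L = 2, c_bath0 = 10, kappa = 4,
                               finite_bath = FALSE,
                               times = 5 * 2^2 / 0.86, nx = 80)
  f <- solve_slab_diffusion(cfg)
  expect_lt(max(abs(f$c[1, ] / (4 * 10) - 1)), 1e-3)
})

test_that("finite-bath equilibrium matches the algebraic mass balance", {
  kap <- kappa_for_equilibrium(21.2, c_bath0 = 10, V_bath = 0.5,
                               V_cart = 0.157)
  hand <- equilibrium_hand(10, 0.5, 0.157, kap)
  expect_equal(unname(hand["c_cart"]), 21.2, tolerance = 1e-12)
  cfg <- slab_diffusion_config(kappa = kap, times = c(48, 96), nx = 120)
  f <- solve_slab_diffusion(cfg)
  ratio <- mean_uptake(f)[2] / f$c_bath[2]
  expect_equal(ratio, unname(hand["c_cart"] / hand["c_bath"]),
               tolerance = 1e-4)
  # the equilibrium cartilage-to-bath ratio is about 6.35
  expect_equal(ratio, 6.34, tolerance = 0.01)
})

test_that("analytic mean uptake matches its limits and a frozen value", {
  expect_lt(abs(analytic_mean_uptake(0, 200)), 1e-6)
  expect_equal(analytic_mean_uptake(50), 1)
  # brute-force series evaluation at theta = 1 gives 0.93127
  expect_equal(analytic_mean_uptake(1, 50), 0.9313, tolerance = 1e-4)
  expect_error(analytic_mean_uptake(-0.1), "nonnegative")
})

test_that("finite-difference solver agrees with the analytic series", {
  thetas <- c(0.02, 0.1, 0.5, 1.5)
  L <- 2; D <- 0.86
  cfg <- slab_diffusion_config(D = D, L = L, c_bath0 = 10, kappa = 5,
                               finite_bath = FALSE,
                               times = thetas * L^2 / D, nx = 200)
  f <- solve_slab_diffusion(cfg)
  num <- mean_uptake(f) / (5 * 10)
  ana <- analytic_mean_uptake(thetas, 100)
  expect_lt(max(abs(num - ana) / ana), 1e-4)
})

test_that("finite-bath simulations conserve iodine mass", {
  for (nx in c(50, 200)) {
    cfg <- slab_diffusion_config(times = cect_time_grid(), nx = nx)
    f <- solve_slab_diffusion(cfg)
    m <- total_iodine_mass(f)
    expect_lt(max(abs(m - m[1]) / m[1]), 1e-6)
  }
})

test_that("mean uptake is nondecreasing for a constant bath", {
  cfg <- slab_diffusion_config(finite_bath = FALSE, kappa = 5,
                               times = cect_time_grid(), nx = 100)
  f <- solve_slab_diffusion(cfg)
  expect_true(all(diff(mean_uptake(f)) > -1e-12))
})

test_that("solver rejects invalid configurations", {
  expect_error(slab_diffusion_config(times = c(1, 1, 2)),
               "strictly increasing")
  expect_error(slab_diffusion_config(times = c(-1, 2)), "nonnegative")
  expect_error(slab_diffusion_config(nx = 5), "10")
  expect_error(slab_diffusion_config(D = -1), "positive")
  expect_warning(slab_diffusion_config(kappa = 0.5), "kappa < 1")
})

test_that("renderer reproduces the baseline when no contrast is present", {
  cfg <- slab_diffusion_config(times = c(1, 2), nx = 50)
  f <- solve_slab_diffusion(cfg)
  f$c[] <- 0; f$c_bath[] <- 0
  ser <- render_planar_series(f, microct_calibration(), noise_sd = 0)
  for (im in ser$images) expect_identical(im, ser$baseline)
})

test_that("the difference-convention forward model is linear in c", {
  cfg <- slab_diffusion_config(times = c(0.5, 4), nx = 80)
  f <- solve_slab_diffusion(cfg)
  ser1 <- render_planar_series(f, microct_calibration(), noise_sd = 0)
  f2 <- f; f2$c <- 2 * f$c; f2$c_bath <- 2 * f$c_bath
  ser2 <- render_planar_series(f2, microct_calibration(), noise_sd = 0)
  for (i in seq_along(ser1$images))
    expect_equal(ser2$images[[i]] - ser2$baseline,
                 2 * (ser1$images[[i]] - ser1$baseline), tolerance = 1e-12)
})

test_that("absolute-convention render of 10 mgI/mL adds 16.942 gray levels", {
  cfg <- slab_diffusion_config(c_bath0 = 10, kappa = 1, finite_bath = FALSE,
                               times = 200, nx = 60)
  f <- solve_slab_diffusion(cfg)   # uniform 10 mgI/mL at equilibrium
  ser <- render_planar_series(f, microct_calibration(), noise_sd = 0,
                              intercept = "absolute")
  d <- ser$images[[1]] - ser$baseline
  # hand arithmetic: 0.7531 + 1.6189 * 10
  expect_equal(mean(d[ser$geometry$cartilage_rows, ]), 16.942,
               tolerance = 1e-3)
})

test_that("renderer rejects a negative noise level", {
  cfg <- slab_diffusion_config(times = c(1), nx = 50)
  f <- solve_slab_diffusion(cfg)
  expect_error(render_planar_series(f, microct_calibration(),
                                    noise_sd = -1), "nonnegative")
})

test_that("phantom difference is confined to cartilage for identity motion", {
  p <- build_ct_phantom_pair(rotation_deg = 0, translation = c(0, 0, 0),
                             noise_sd_hu = 0, seed = 1)
  d <- subtract_volumes(p$post, p$pre)
  expect_true(all(d$voxels[p$tissue_labels != 3L] == 0))
  step <- p$calib$b * p$concentration
  expect_equal(mean(d$voxels[p$tissue_labels == 3L]), step,
               tolerance = 1e-9)
  expect_true(all(p$true_iodine[p$tissue_labels != 3L] == 0))
})

test_that("phantom fiducials transform exactly and reject degeneracy", {
  p <- build_ct_phantom_pair(noise_sd_hu = 0)
  expect_lt(max(abs(p$fiducials_post -
                      transform_points(p$true_transform,
                                       p$fiducials_pre))), 1e-9)
  bad <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_error(build_ct_phantom_pair(fiducials = bad), "degenerate")
})

test_that("absolute-convention phantom carries the full affine increment", {
  p <- build_ct_phantom_pair(rotation_deg = 0, translation = c(0, 0, 0),
                             noise_sd_hu = 0, intercept = "absolute")
  d <- subtract_volumes(p$post, p$pre)
  # hand arithmetic: -5.589 + 23.537 * 10 = 229.781
  expect_equal(mean(d$voxels[p$tissue_labels == 3L]), 229.781,
               tolerance = 1e-9)
})

test_that("generators are bitwise reproducible for a fixed seed", {
  p1 <- build_ct_phantom_pair(seed = 7)
  p2 <- build_ct_phantom_pair(seed = 7)
  expect_identical(p1$pre$voxels, p2$pre$voxels)
  expect_identical(p1$post$voxels, p2$post$voxels)
  cfg <- slab_diffusion_config(times = c(0.5, 2), nx = 60)
  f <- solve_slab_diffusion(cfg)
  s1 <- render_planar_series(f, microct_calibration(), noise_sd = 2, seed = 3)
  s2 <- render_planar_series(f, microct_calibration(), noise_sd = 2, seed = 3)
  expect_identical(s1$images, s2$images)
  w1 <- simulate_washout_curve(10, 0.01, noise_sd = 0.5, seed = 5)
  w2 <- simulate_washout_curve(10, 0.01, noise_sd = 0.5, seed = 5)
  expect_identical(w1, w2)
})

test_that("washout simulator follows the exponential decay", {
  w <- simulate_washout_curve(10, 0.01, times = c(0, 24, 48))
  expect_equal(w$concentration[1], 10)
  # hand evaluation: 10 * exp(-0.48) = 6.1878
  expect_equal(w$concentration[3], 6.1878, tolerance = 1e-4)
  expect_error(simulate_washout_curve(10, 0), "positive")
  expect_error(simulate_washout_curve(10, 0.01, times = numeric(0)),
               "nonempty")
  w2 <- simulate_washout_curve(10, 100, times = 24)
  expect_lt(w2$concentration, 1e-6)
})
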
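# cartidiff

Quantitative contrast-enhanced CT (CECT) of articular cartilage in R.

Cartilage is invisible in plain CT: it attenuates X-rays like the soft
tissue around it. A cationic iodinated contrast agent — electrostatically
attracted to the negatively charged proteoglycans of the cartilage
matrix — diffuses in from a bath, concentrates to several times the bath
level, and makes the tissue radiopaque in proportion to its local iodine
content. `cartidiff` implements the complete analysis chain for such
experiments, at both the microCT (planar) and clinical-CT (volumetric)
scales, plus a synthetic phantom generator that simulates the diffusion
physics and both imaging geometries with known ground truth.

## What the package computes

* **Calibration** — OLS fit and inversion of the affine map
  `attenuation = a + b · c` between detector units (GL or HU) and iodine
  concentration (mgI/mL): `fit_linear_calibration()`,
  `attenuation_to_concentration()`.
* **Uptake kinetics** — baseline subtraction, ROI means and
  nonlinear fits of the Fickian uptake surrogate
  `A(t) = a (1 − e^(−t/τ))`, with the saturation time `τ95 = 5τ`
  (exact `ln(20)·τ` variant available), depth profiles from surface to
  tidemark and tertile layer summaries: `fit_uptake_curve()`,
  `saturation_time()`, `depth_profile()`, `layer_summary()`.
* **Volumetric pipeline** — fiducial-based rigid registration (Kabsch),
  trilinear resampling, pre/post subtraction, iodine segmentation
  (threshold + 26-connected component pruning), concentration mapping,
  and cartilage volume/thickness morphometry:
  `fit_rigid_from_fiducials()`, `resample_volume()`,
  `segment_iodine_mask()`, `map_iodine()`,
  `estimate_cartilage_volume()`, `estimate_cartilage_thickness()`.
* **Washout and statistics** — exponential washout fits
  `c(t) = a_w e^(−b_w t)` with the 5% washout time, Cohen's d,
  two-sample Kolmogorov–Smirnov and Mann–Whitney tests, and a
  Lilliefors-corrected normality check: `fit_washout()`,
  `washout_time()`, `cohens_d()`, `two_sample_tests()`,
  `tissue_distinguishability()`.
* **Synthetic data** — a finite-difference solver for slab diffusion
  with bath partitioning and mass balance (`solve_slab_diffusion()`,
  validated against the closed-form series `analytic_mean_uptake()`),
  planar radiograph rendering (`render_planar_series()`), paired
  pre/post CT phantoms with fiducials and known rigid motion
  (`build_ct_phantom_pair()`), and washout curves
  (`simulate_washout_curve()`).
* **I/O** — 16-bit multi-page TIFF + CSV sidecar for planar series,
  NIfTI-1 for volumes, JSON for configurations; all round-trips
  lossless on their declared dtypes.

## Worked example

Simulate the bench uptake experiment (0.5 mL bath at 10 mgI/mL over a
2 mm cartilage slab), render the planar series, and recover the
saturation time:

```r
library(cartidiff)

cfg <- slab_diffusion_config(times = cect_time_grid(), seed = 1)
field <- solve_slab_diffusion(cfg)
series <- render_planar_series(field, microct_calibration(),
                               noise_sd = 1, seed = 1)
sub <- subtract_baseline(series)
roi <- default_cartilage_roi(sub)          # 100 px wide, cartilage band
vals <- sapply(sub$images, function(im) roi_mean(im, roi)$mean)
fit <- fit_uptake_curve(sub$times, vals)
fit
#> Uptake fit: a = 32.958, tau = 0.31043 h, tau95 = 1.5522 h, r2 = 0.9090 (n = 17)
saturation_time(fit)                # 1.55 h  (5 tau convention)
saturation_time(fit, exact = TRUE)  # 0.93 h  (ln 20 · tau)
```

The fitted plateau of ~33.0 GL corresponds through the gray-level
calibration (slope 1.6189 GL per mgI/mL) to ~20.4 mgI/mL retained in
cartilage — about 6.1 times the depleted bath concentration, the
partitioning effect that makes the tissue visible. The modest r² reflects
the finite bath: the surface concentration starts high and falls as the
bath depletes, a transient a single saturating exponential cannot
represent.

The volumetric arm is exercised the same way from a phantom pair:

```r
pair <- build_ct_phantom_pair(seed = 42)
est <- fit_rigid_from_fiducials(pair$fiducials_pre, pair$fiducials_post)
post_reg <- resample_volume(pair$post, est, fill = NA)
diff <- subtract_volumes(post_reg, pair$pre)
mask <- segment_iodine_mask(diff, threshold_hu = 117.7)  # half-height
conc <- map_iodine(diff, pair$calib, mask)
voi_statistics(conc, default_vois(pair))$pooled$mean   # 9.998 mgI/mL
dice_coefficient(mask, pair$tissue_labels == 3)        # 0.977
```

See `vignettes/cartilage-cect-pipeline.Rmd` for the models, the numerical
choices and the design decisions.

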
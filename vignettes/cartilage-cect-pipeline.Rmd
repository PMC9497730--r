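---
title: "Quantitative contrast-enhanced CT of articular cartilage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative contrast-enhanced CT of articular cartilage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartidiff)
```

## The measurement problem

Articular cartilage attenuates X-rays almost exactly like the soft tissue
around it, so plain CT cannot delineate it. A cationic, iodinated contrast
agent changes that: attracted by the fixed negative charge of cartilage
proteoglycans, it diffuses in from a bath, accumulates to concentrations
*above* the bath concentration, and makes the tissue radiopaque in
proportion to its local iodine content. Quantifying that process involves
four distinct measurement tasks, each with its own model:

1. **Calibration** — mapping detector units (microCT gray levels or CT
   Hounsfield units) to iodine concentration;
2. **Uptake kinetics** — how fast the agent saturates the tissue, which
   fixes the immersion time of any subsequent experiment;
3. **Volumetric quantification** — isolating the cartilage signal in 3-D
   by subtracting a pre-contrast scan, and reading out concentration,
   volume and thickness;
4. **Washout and statistics** — how fast the agent leaves, and whether
   enhanced cartilage is statistically distinguishable from bone and
   connective tissue.

`cartidiff` implements all four, together with a synthetic-data module
that simulates the underlying diffusion physics and both imaging
geometries with known ground truth. Every claim the package makes about
its own correctness is a property checked against that ground truth or
against an independent closed-form oracle; the test suite and
`scripts/acceptance.R` recompute them from scratch.

## Diffusion model and its solver

Transport into the tissue is modelled as 1-D Fickian diffusion across the
cartilage thickness \(L\):
\[
\frac{\partial c}{\partial t} = D \frac{\partial^2 c}{\partial x^2},
\qquad 0 \le x \le L,
\]
with a partition-equilibrium boundary at the articular surface,
\(c(0, t) = \kappa\, c_\mathrm{bath}(t)\), and a no-flux condition at the
tidemark \(x = L\). The dimensionless partition coefficient \(\kappa\)
lumps the electrostatic attraction into a single equilibrium ratio; it is
the reason enhanced cartilage can end up several times more concentrated
than its bath. With a finite bath the bath concentration evolves by mass
balance; at equilibrium
\(V_b c_b + V_c \kappa c_b = V_b c_{b,0}\), which
`kappa_for_equilibrium()` inverts.

Numerically, `solve_slab_diffusion()` uses second-order central
differences on `nx` nodes and Crank–Nicolson time stepping, with four
backward-Euler quarter-steps at the start (Rannacher smoothing) because
the surface concentration jumps discontinuously at \(t = 0\) and plain
Crank–Nicolson would ring. The scheme is unconditionally stable, so the
ragged experimental acquisition grid (2 min to 26 h) needs no special
treatment. Two numerical choices matter:

* **Quadrature.** Depth means and the cartilage mass in the bath balance
  both use composite-Simpson weights. With the default `nx = 200` this
  keeps the depth-mean uptake within \(4 \times 10^{-5}\) (relative) of
  the closed-form series solution `analytic_mean_uptake()` over
  \(\theta = Dt/L^2 \in [0.01, 2]\); node-based trapezoid quadrature
  alone would exhaust the error budget at small \(\theta\), where the
  concentration boundary layer is thin.
* **Exact conservation.** In the finite-bath step the new bath
  concentration is *derived from* the discrete mass balance (two
  tridiagonal solves plus one scalar equation), so total iodine is
  conserved to round-off by construction rather than approximately.

The default time-step ceiling is \(\Delta\theta = 10^{-3}\); halving it
changes the reported uptake curves in the sixth decimal.

### Default physical parameters

| parameter | default | unit | why |
|---|---|---|---|
| `D` | 0.86 | mm²/h | effective diffusivity of a large iodinated solute in cartilage; gives a saturation time in the 1.5–2 h range for a 2 mm slab under this protocol |
| `L` | 2 | mm | typical bovine articular cartilage thickness |
| `c_bath0` | 10 | mgI/mL | mid-range bath concentration of the emulated protocol |
| `kappa` | ≈6.34 | – | chosen so the finite-bath equilibrium cartilage concentration is 21.2 mgI/mL under the default geometry |
| `V_bath`, `V_cart` | 0.5, 0.157 | mL | bath-over-plug bench geometry (bath ≈ 3× cartilage volume) |
| `nx` | 200 | – | spatial error ≪ the 1e-4 oracle budget |

The protocol quantities — the 17-point acquisition grid
(`cect_time_grid()`), the 11.52 µm planar pixel, the
0.32 × 0.32 × 0.625 mm clinical voxel — are defaults throughout and
collected in `default_run_config()`.

## Uptake fitting and the two saturation conventions

Measured uptake curves are summarized by the saturating exponential
\(A(t) = a(1 - e^{-t/\tau})\). This is a *surrogate*: the true slab
solution is a series of exponentials. On uniformly sampled depth-mean
curves out to \(\theta_{\max} \ge 3\) the surrogate fits with
\(r^2 > 0.98\), which is why a single \(\tau\) is an adequate protocol
read-out. Fits use Levenberg–Marquardt with \(a_0 = \max(A)\),
\(\tau_0\) the earliest time the signal crosses \((1 - e^{-1}) a_0\)
(fallback: a third of the span), and bounded restarts at
\(\tau_0 \times \{1, 0.5, 2\}\); a fit that still fails returns an
explicit failure object. \(t = 0\) is excluded — the subtracted signal is
identically zero there by construction.

Two conventions coexist for the saturation time and both are preserved
deliberately: the conventional read-out is \(\tau_{95} = 5\tau\), although
\(1 - e^{-5} = 0.993\); the mathematically exact time to 95% is
\(\ln(20)\,\tau \approx 3\tau\), available via
`saturation_time(fit, exact = TRUE)`. Similarly \(\tau\) is often quoted
as the "65%" time although \(1 - e^{-1} = 63.2\%\). The package reports
the conventional quantities and documents the inconsistency rather than
reinterpreting either.

## Image formation and the intercept question

Planar rendering assumes attenuation linear in local iodine
concentration (valid in the thin-sample, effectively monochromatic
regime), so a contrast-bearing band adds an increment on top of its
baseline tissue pattern. An affine calibration
\(y = a + b\,c\) leaves an ambiguity for *subtracted* data: does the
intercept cancel in the subtraction (increment \(= b\,c\)), or does the
full affine map apply to the difference signal
(increment \(= a + b\,c\))? Published calibrations with nonzero
intercepts do not always say. Both conventions are implemented
(`intercept = "difference"` / `"absolute"` in the renderers and in
`map_iodine()`); the simulator and the analysis stay self-consistent for
whichever is selected, `"difference"` being the default because a shared
offset physically cancels in baseline subtraction. Noise is additive
Gaussian in detector units; photon (Poisson) noise is deliberately out of
scope since no exposure model is assumed.

## The CT phantom pair and the volumetric pipeline

`build_ct_phantom_pair()` builds a 96 × 96 × 64 voxel scene on the
clinical grid: a subchondral bone slab (1200 HU), a cartilage carpet of
spatially varying thickness (5–9 voxels, 1.6–2.9 mm), connective tissue
(40 HU) with cartilage pre-contrast at 55 HU — nearly indistinguishable,
which is the experimental motivation — and a saline bath (0 HU) above.
The post-contrast volume adds the calibration-forward increment of a
known iodine map, is moved by a known rigid transform (default 2°
rotation plus a sub-millimetre translation, i.e. careful repositioning of
a fixed specimen) and resampled, and both volumes receive independent
Gaussian noise (20 HU). Four non-coplanar fiducial markers are recorded
in both frames.

Two geometric choices deserve comment:

* **Bone is embedded, never bath-facing.** Subtraction of misregistered
  volumes leaves halo artifacts at high-contrast edges; against a
  −1000 HU air background these reach hundreds of HU and would dominate
  any automated segmentation — precisely the "spurious pixels" a manual
  operator removes. Immersed specimens have no interior air interface,
  and with saline at 0 HU the remaining soft-tissue edges produce halos
  below any sensible threshold. The halo-prone configuration is still
  reachable by passing custom `hu` values; it is simply not the default
  condition.
* **Segmentation thresholds.** `segment_iodine_mask()` thresholds the
  difference volume and drops 26-connected components smaller than 27
  voxels (the automated stand-in for manual artifact removal; both
  parameters in config). Its default threshold, 3× the MAD-estimated
  noise SD, is a *detection* criterion. For morphometry the pipeline uses
  the half-height threshold — 50% of the expected contrast step — the
  standard partial-volume-unbiased edge criterion in CT morphometry:
  a detection threshold well below half-height systematically dilates
  the mask at smoothed edges, biasing volume and thickness.

Registration maps the post scan into the pre (baseline) frame — the
baseline frame is canonical — via the closed-form Kabsch solution on the
four markers (reflections excluded by construction); resampling is
trilinear with lattice snapping, so identity and whole-voxel motions are
exact. Thickness is measured per VOI as the mean over footprint columns
of the longest contiguous segmented run along the depth axis — the
longest-run rule makes the estimate immune to isolated speckle, at the
cost of ignoring genuinely fragmented columns, which do not occur in
this geometry. Volume is the voxel count times the voxel volume.

Under the default conditions (contrast step 235 HU, difference-volume
noise ≈ 28 HU, SNR ≈ 8) the 200-seed end-to-end medians are: Dice ≈ 0.97
against the true cartilage label, VOI concentration error well under 1%,
volume error below half a voxel per cartilage column, and per-VOI
thickness error below half an in-plane voxel. These are the quantities
`scripts/acceptance.R` recomputes.

## Washout and the statistical battery

Washout is fitted as a single-compartment decay
\(c(t) = a_w e^{-b_w t}\), initialized by log-linear regression (exact on
noiseless data) with a direct NLS fallback when non-positive
concentrations preclude the log transform. The washout time solves
\(a_w e^{-b_w t} = 0.05\,c_\mathrm{ref}\); with \(c_\mathrm{ref} = a_w\)
this is \(\ln(20)/b_w\), an identity the tests check to 1e-12. A constant
series is flagged degenerate (the decay rate sits on the \(b_w = 0\)
boundary) rather than fitted. Three points at 0/24/48 h — the emulated
protocol's design — identify the model exactly but leave no residual
degree of freedom; the Monte-Carlo robustness checks therefore use a
7-point grid out to 144 h, a span commensurate with the ~1/b_w time
scale.

Tissue distinguishability uses Cohen's d with pooled SD (reported as a
magnitude, matching convention), the two-sided two-sample
Kolmogorov–Smirnov test (asymptotic p), and the two-sided Mann–Whitney
test — exact for both samples ≤ 8 without ties, otherwise the normal
approximation with midranks and tie correction, since CT integers
produce ties. The one-sample normality check defaults to the
Lilliefors-corrected KS (normal parameters estimated from the sample);
the naive standardized-sample KS is available as `reference = "standard"`
and its anti-conservatism is documented, the choice always being recorded
in the output. No multiple-testing correction is applied across tissue
pairs, matching the emulated analysis. Type-I error of both two-sample
tests is verified by simulation (2000 null replicates at n = 50) to sit
at the nominal 5% within Monte-Carlo error.

## What the synthetic data does and does not establish

The generators reproduce the *structure* of the real experiments: the
diffusion physics with partitioning and bath depletion, linear image
formation, the acquisition grids and voxel geometries, repositioning
between paired scans, fiducial localization error, and additive detector
noise. They deliberately omit: polychromatic beam hardening, scatter,
photon-count (Poisson) statistics, scanner point-spread functions,
spatially heterogeneous proteoglycan distributions (real depth profiles
carry a gradient; simulated equilibrium profiles are flat), cartilage
anisotropy and swelling, and any deformable component of repositioning.
Passing tests therefore demonstrate that the *analysis chain is correct
and well-conditioned under its stated model*, not that the model captures
every feature of scanner data. Quantities tied to real tissue —
calibration slopes, measured saturation times, reported washout times —
enter only as plausible parameter regimes for the simulations, and the
recovery properties are what is asserted.

## Problem sizes

Simulation sizes used by the test suite and acceptance script — planar
images 256 × 256, volumes 96 × 96 × 64, 200-seed Monte-Carlo for
recovery medians, 2000 replicates for test size — were chosen as the
smallest sizes at which every asserted property is comfortably resolved
(e.g. ≥ 5 voxels across the thinnest cartilage, Monte-Carlo SEs an order
of magnitude below the tolerances they police).
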
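---
title: "Quantifying tissue stress from hydrogel-sensor MR images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue stress from hydrogel-sensor MR images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanomr)
```

## The measurement problem

Compressible alginate hydrogel microparticles seeded with magnetic
nanoparticles act as in situ stress gauges: mechanical compression of a
particle concentrates its nanoparticles, shortens local T2\*, and darkens
the particle's spot in a T2\*-weighted MR volume. `mechanomr` implements the
full quantification chain for such sensors:

1. detect single-particle dark spots in an MR volume;
2. quantify each spot by the reciprocal-intensity signal-to-background
   ratio (SBR) of a fixed manual ROI protocol;
3. invert an empirical biexponential stress--signal calibration to obtain
   local compressive stress in kPa;
4. link detections of the same physical particle across longitudinal
   imaging sessions and compute stress-change (loading-rate) statistics;
5. register MR-frame sensor coordinates onto a cleared-tissue fluorescence
   volume by coherent point drift (CPD) and compare stress between
   fluorescence-defined tissue regions.

A synthetic-data module generates every input with known ground truth, so
each stage is testable end to end without scanner or microscope data.

## The stress--signal law

The calibration maps stress $S$ (kPa) to the normalized T2\* signal

$$\mathrm{signal}(S) = a_1 e^{-b_1 S} + a_2 e^{-b_2 S},$$

with the default coefficients $a_1 = 0.1344$, $b_1 = 0.926\ \mathrm{kPa^{-1}}$,
$a_2 = 0.864$, $b_2 = 0.0405\ \mathrm{kPa^{-1}}$ — the empirical fit for the
characterised sensor lot, valid on $[0, 15]$ kPa. The decay is treated as
purely empirical: no attempt is made to model the underlying relaxation
physics. The zero-stress value $a_1 + a_2 = 0.9984$ is the anchor for signal
normalization.

Two conventions resolve ambiguities of biexponential models:

* **Component order.** $(a_1, b_1)$ is always the faster-decaying component
  ($b_1 > b_2$); `calibration_model()` and `fit_calibration()` enforce this,
  removing the label-swap symmetry.
* **Extrapolation.** Stress above 15 kPa triggers a warning, not an error:
  in vivo estimates legitimately approach the upper end of the range.

**Fitting** (`fit_calibration`) uses Levenberg--Marquardt least squares with
positivity bounds. Starting values come from a log-linear fit of the slow
tail (stress levels in the upper half of the range) for $(a_2, b_2)$, then a
log-linear fit of the positive residual for $(a_1, b_1)$; a failed fit is
retried once from a perturbed start. At least six distinct stress levels
spanning half the validity range are required — fewer levels cannot separate
two exponentials.

**Inversion** (`invert_signal`) solves $\mathrm{signal}(S) = y$ by
Newton--Raphson started at the midpoint of the validity range. Because the
forward model is strictly decreasing, a bracketing interval is maintained
and any Newton iterate that escapes it is replaced by a bisection step, so
convergence is guaranteed for attainable signals; the tolerance is
$10^{-8}$ on the signal residual. Signals outside the attainable range
raise an error by default; with `clamp = TRUE` they are clamped to the
range end and flagged (`out_of_range`), which is the behaviour the pipeline
uses — measurement noise routinely pushes an unstressed sensor's signal
slightly above the zero-stress value, and such records should be kept at
0 kPa, not dropped.

## ROI quantification and the aggregation filter

The SBR reproduces a manual protocol: the sensor signal is the mean gray
intensity of a 3×3-pixel in-plane ROI on the two axial slices bracketing
the spot center ("upper and lower images"); background is taken from four
3×3 windows offset diagonally by 5 pixels (configurable). The statistic is
formed from reciprocal intensities, which are proportional to relaxation
rate:

$$\mathrm{SBR} = \frac{1/I_{roi} - 1/I_{bg}}{1/I_{bg}} = \frac{I_{bg}}{I_{roi}} - 1 .$$

Interpretation choices, made once and kept:

* "Upper and lower images" are the two slices with integer indices
  bracketing the continuous axial centroid (off-grid centroids are the
  rule, not the exception).
* The reciprocal is applied to the ROI *means*, not per voxel — this
  matches the protocol's order of operations and is far more noise-robust.
* The four background windows are summarised by the **median** of their
  means rather than the pooled mean. The protocol requires *non-particle*
  background areas; in densely seeded tumors a diagonal window is
  occasionally grazed by a neighbouring sensor's tail, and the median
  discards such windows automatically. On clean backgrounds the two
  summaries agree.
* Normalization to the Fig-style "normalized T2\* signal" is cohort-level:
  a measured SBR is divided by the mean zero-stress SBR of a calibration
  cohort and multiplied by $\mathrm{signal}(0) = 0.9984$. Per-particle
  self-referencing would remove particle-to-particle contrast variation but
  requires observing every particle unstressed, which in vivo data do not
  provide.

**Aggregation exclusion.** Clumped sensors inflate both the SBR and the
spot footprint. A detection is excluded when SBR $> 2.5$ **and** its
contiguous dark area exceeds 9 pixels (a 3×3 region) — strict exceedance,
so boundary values are retained. The conjunction is deliberate. At the
stated scales (300 µm full-width spots on 0.1 mm pixels) the half-depth
contour of a *genuine single particle* covers 4--12 pixels depending on its
sub-pixel position — it straddles the 9-pixel bound — while its SBR stays
two orders of magnitude below 2.5. An either-symptom rule would therefore
discard a noticeable fraction of valid singles on footprint alone;
requiring both symptoms keeps them while still catching aggregates, whose
near-black merged cores satisfy both criteria at once. The either-symptom
variant remains available (`logic = "or"`), and both thresholds are
configurable.

The contiguous dark area itself is measured on the mean of the same two
ROI slices (halving contour noise), as the 8-connected flood-filled region
around the spot center below
$I_{bg} - 0.5\,(I_{bg} - I_{min})$, with $I_{min}$ the local minimum — a
half-depth criterion on a quantity the protocol leaves unspecified.

**Detection** (`detect_particles`) is deliberately simple: candidate voxels
below a contrast threshold (default 4% of the median background) on a
lightly smoothed volume, ranked by darkness, non-maximum-suppressed at a
0.7 mm radius, and refined to sub-voxel centroids by a contrast-weighted
center of mass computed on the smoothed volume (shallow, strongly
compressed spots get unstable centroids on raw voxels). Detections whose
measurement ROI would touch the volume boundary are dropped, since the
protocol is undefined there.

## Device mechanics: the analytic Neo-Hookean surrogate

The compression device applies a plate displacement $\Delta x$ to a gel
cylinder (default 10 mm diameter and height). Instead of finite elements,
the package uses the closed analytic reduction of a compressible
Neo-Hookean solid under homogeneous frictionless uniaxial compression —
justified because the stress field in this geometry is essentially uniform.
The energy density is

$$W = \tfrac{G}{2}(I_1 - 3) - G \ln J + \tfrac{\Lambda}{2} (\ln J)^2,
\qquad \Lambda = \frac{2 G \nu}{1 - 2\nu},$$

a standard Lamé-parameterised compressible variant. With axial stretch
$\lambda = 1 - \Delta x / h$ and lateral stretch $\mu$, zero lateral
traction gives $G(\mu^2 - 1) + \Lambda \ln J = 0$ (solved by bracketed
root-finding), and the axial Cauchy stress magnitude is
$|G(\lambda^2 - 1) + \Lambda \ln J| / J$. In the small-strain limit this
reproduces isotropic linear elasticity with $E = 2G(1 + \nu)$, which the
tests verify to 2% for all three tabulated agarose grades
($\nu = 0.31$; $G = 0.4, 1.5, 4.7$ kPa at 0.5, 1.0, 2.0% w/v, log--log
interpolated in between). The inverse map (`stress_to_displacement`) is
root-finding on the forward map.

The surrogate reports axial Cauchy stress; whether the reference
finite-element analyses extracted axial or von Mises stress is not
documented, so displacement--stress agreement with the device's nominal
set-points is reported by the analysis scripts but not hard-asserted.

## The particle strain model (optical arm)

The confocal readout measures particle deformation directly. The package
uses a two-parameter saturating law
$\epsilon(S) = \epsilon_{max}\, S / (S + k)$ with defaults
$k = 7.5$ kPa and $\epsilon_{max} = 0.5$, chosen so the curve rises
steeply below ~5 kPa and flattens towards 15 kPa, qualitatively matching
the measured single-particle strain profile. It is explicitly a stand-in —
no functional form or particle modulus is published for the sensor lot —
and its closed-form inverse makes the optical stress estimate exact up to
measurement noise (multiplicative, 3% s.d. by default, a realistic
precision for confocal diameter measurements of ~100 µm particles).

## Synthetic scenes: what is emulated, what is not

`noise_spec()` fixes the study conditions of every rendered volume:

| parameter | default | meaning |
|---|---|---|
| `background_mean` | 100 | gel/tissue intensity (arbitrary scanner units) |
| `spot_depth` | 10 | zero-stress ROI-level spot contrast |
| `sigma` | `spot_depth / 9.5` ≈ 1.05 | per-voxel noise s.d. |
| `model` | `"rician"` | magnitude-MR noise law (Gaussian optional) |
| `psf_fwhm_mm` | 0.3 | spot full width at half maximum |

The noise s.d. is *calibrated*, not free: it is set so that the
single-particle signal-to-noise ratio, measured exactly as the detection
module measures it (ROI-level contrast over the per-voxel background
noise s.d.), equals the reported value 9.5. Under that constraint, error
propagation through the reciprocal SBR (18 ROI voxels, 4×18 background
voxels) bounds the achievable repeat-measurement CV below by
$\frac{1}{9.5}\sqrt{1/72 + (I_{bg}/I_{roi})^2/18} \approx 2.8\%$, slightly
above the reported 2.4% — the defaults land near 3%, inside the stated
±1-point tolerance, and the discrepancy is documented rather than tuned
away. Voxels are 0.1 × 0.1 mm in-plane with 0.2 mm slices, axis order
(z, y, x), voxel centers at (index − ½) × voxel size.

Spots are isotropic Gaussian dips. The renderer chooses each dip's peak
amplitude so that the SBR measured by `compute_sbr` on the noiseless volume
equals $\mathrm{sbr}_0 \cdot \mathrm{signal}(S)/\mathrm{signal}(0)$
*exactly* for that particle's sub-voxel position (the ROI attenuation
factor is computed against the same window-selection rule the measurement
uses). This makes the forward signal law hold at the measurement level, so
noiseless stress recovery is exact to numerical precision — a deliberate
separation of rendering fidelity from measurement noise. Aggregates are
two merged spots at 0.25 mm separation with 8× single-particle contrast,
clipping to near-black, so that both exclusion symptoms fire.

Scene generators cover: calibration phantoms (`generate_calibration_phantom`,
minimum pairwise separation three spot widths, dart-throwing placement with
a capacity error); tumor time series (`generate_tumor_timeseries`,
constellation growth about the centroid, per-session random-walk motion,
stress trajectories from loading profiles or explicit matrices);
registration scenes (`generate_registration_scene`, a bumpy-ellipsoid tumor
surface — asymmetric so rotations are identifiable — warped into the CFM
frame by a similarity transform plus a Gaussian-kernel displacement field,
with patchy region labels from a thresholded smoothed Gaussian random
field); and the two-region study (`generate_region_study`, per-region
stress draws from censored normals, 3.5 ± 2.8 kPa in fluorescence-positive
and 7.4 ± 2.8 kPa in negative regions by default). "Truncated at zero" is
implemented as censoring (`max(0, ·)`): unloaded sensors are physically
meaningful, and censoring keeps the positive-group population mean near
the nominal 3.5 kPa (resampling truncation would shift it to ~4.1).

A sensor's ground-truth region membership uses the same 0.3 mm
ball-majority rule as the assignment stage — a 300 µm particle occupies a
volume, not a point — so region-statistics errors reflect genuine
registration and measurement error, not a labelling convention mismatch.

Not emulated: MR sequence physics (k-space, bias fields, motion
artifacts), scanner drift between sessions, intensity inhomogeneity,
vasculature or immune structure in the label fields, and particle
degradation. Passing tests therefore demonstrate the *analysis chain* is
correct and well-calibrated under controlled conditions; they do not
certify performance on scanner data with artifacts the generator omits.

## Loading profiles and rate statistics

The two compression regimens share a 5 kPa peak at 48 h but differ in
trajectory: the `gradual` profile steps up every 6 h (maximum interval
rate 2.5 kPa/day), while the `acute` profile holds a 0.5 kPa baseline for
48 h and ramps to 5 kPa within 1 h (108 kPa/day). Δ-stress over a window
is later-minus-earlier stress; the loading rate divides by the window
length in days. `classify_loading` calls a trajectory acute when its
maximum interval rate exceeds a threshold (no canonical value exists; the
default 5 kPa/day sits between the two regimens' maxima, and the threshold
is a required argument of any serious use). The retrospective
"pre-induction" statistic is the Δ-stress across the two sessions
immediately preceding a declared induction day, with both endpoints
configurable, since the windowing convention is ambiguous in the source
material.

## Tracking

`link_particles` uses greedy mutual-nearest-neighbour matching between
consecutive sessions — transparent and adequate at the 6--45 particles per
tumor this application sees. Growth correction first aligns consecutive
constellations by an isotropic scale about the centroid (RMS-radius ratio)
plus a centroid shift, then gates matches at `max_displacement`
(default 1 mm). Unmatched detections start or terminate trajectories;
nothing is force-linked. The matching is permutation-invariant by
construction (mutual nearest neighbours do not depend on row order).

## Coherent point drift

`register_cpd` implements the standard EM formulation over a
Gaussian-mixture correspondence model with a uniform outlier component
(weight `w`, default 0.1). Both clouds are translated to a common origin
(centroid subtraction) before EM, mirroring the mesh-alignment protocol.
Rigid mode solves the closed-form similarity transform (rotation via SVD
with a determinant guard, optional isotropic scale); non-rigid mode solves
the kernel-regularized displacement field
$(\mathrm{d}(P\mathbf{1})G + \lambda\sigma^2 I)W = PX - \mathrm{d}(P\mathbf{1})Y$
with Gaussian kernel width `beta` (default 2 mm) and coherence weight
`lambda` (default 3). Iteration stops when the relative change in
$\sigma^2$ falls below `tol` ($10^{-5}$) or at `max_iter` (100);
$\sigma^2$ collapsing to numerical zero (exact overlap) also terminates.
The penalized negative log-likelihood is recorded each iteration; the
tests assert it never increases. Defaults were fixed once at values common
in CPD practice — the source protocol names none. Transforms apply to
arbitrary points: rigid exactly, non-rigid by evaluating the same Gaussian
kernel against the source points, which is what maps sensor coordinates
(not part of the surface clouds) into the CFM frame.

Numerical notes: correspondence denominators are floored at `1e-300`;
collinear source clouds are rejected in rigid mode (rotation
unidentifiable); matrix products under a multi-threaded BLAS can vary at
the $10^{-3}$ mm level between runs due to summation order — single-thread
execution is bit-reproducible.

## Region assignment and statistics

A registered sensor takes the majority label among label-volume voxels
within a 0.3 mm ball (the particle scale) of its position, along with the
mean fluorescence in that ball; ties fall back to the nearest voxel, and
points outside the volume are flagged unassigned. `region_stats` reports
per-group n, mean and s.d. and the negative-minus-positive mean
difference — descriptive statistics only, by design; inferential testing
beyond this is out of scope.

## Problem sizes and runtime

The shipped analyses and checks use desk-scale sizes chosen to keep the
full suite in minutes: phantom volumes of 24--48 × 96--128² voxels with
25--100 particles, 10 noise realizations for repeatability statistics,
tumors of 45 sensors with ~500-point surface clouds for CPD, 6--20
replicate tumors for pooled region statistics, and 1500 particles for the
dual-readout regression. Monte-Carlo standard errors at these sizes are
small against every stated tolerance (for example ~0.15 kPa against
±0.7 kPa for the region means).

## Known limitations

* The strain--stress law and the MR noise/PSF models are package defaults,
  not published facts; conclusions that depend on their exact shape should
  be re-derived once lot-specific measurements exist.
* The repeat-measurement CV floor (~2.8% at SNR 9.5) means the generator
  cannot reproduce both reported signal-quality figures exactly; the SNR
  is matched exactly and the CV lands within one percentage point.
* Greedy mutual-NN tracking has no global-assignment fallback for dense
  constellations or large inter-session motion beyond the similarity
  correction.
* CPD here subsamples nothing: clouds beyond a few thousand points will be
  slow (dense $M \times N$ posteriors).
* The aggregation filter's dark-area criterion is intrinsically marginal
  for single particles at this PSF/pixel ratio; with the default
  conjunction this is harmless, but `logic = "or"` users should expect a
  few percent of singles excluded on footprint noise.
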
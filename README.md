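# mechanomr

Quantification of local mechanical stress in tissue from T2\*-weighted MR
volumes containing compressible hydrogel micro-sensors.

Magnetic-nanoparticle-loaded alginate microparticles darken T2\*-weighted
images in proportion to how strongly the surrounding tissue compresses
them. `mechanomr` turns volumes of such dark spots into per-particle stress
estimates and downstream statistics. It is written for researchers running
(or simulating) sensor-based solid-stress measurements in phantoms,
spheroid compression devices, and longitudinal tumor imaging.

The pipeline:

* **Detection** of single-particle dark spots with sub-voxel centroids
  (`detect_particles`).
* **SBR quantification** by the reciprocal-intensity protocol — 3×3 ROI on
  the two slices bracketing the spot, four diagonal background windows:
  `SBR = (1/I_roi − 1/I_bg) / (1/I_bg)` (`compute_sbr`), with the
  aggregation filter excluding clumped sensors when both `SBR > 2.5` and
  the contiguous dark area exceeds a 3×3-pixel region
  (`filter_aggregates`).
* **Calibration inversion.** The normalized signal follows the empirical
  biexponential law `signal(S) = 0.1344 e^(−0.926 S) + 0.864 e^(−0.0405 S)`
  (S in kPa, valid on 0–15 kPa), fitted by constrained nonlinear least
  squares (`fit_calibration`) and inverted by safeguarded Newton–Raphson
  (`invert_signal`).
* **Longitudinal tracking** of particles across sessions with growth
  correction, Δ-stress and loading-rate statistics, and gradual/acute
  regimen classification (`link_particles`, `compute_loading_rate`,
  `classify_loading`).
* **Registration** of MR-frame sensor coordinates onto fluorescence
  volumes by rigid or non-rigid coherent point drift, region assignment
  and region-wise stress summaries (`register_cpd`, `transform_points`,
  `assign_regions`, `region_stats`).
* **Device mechanics**: an analytic compressible Neo-Hookean model converts
  compression-device plate displacement to applied stress for agarose of a
  given concentration (`agarose_material`, `displacement_to_stress`).
* **Synthetic data** with known ground truth for every stage
  (`generate_calibration_phantom`, `generate_tumor_timeseries`,
  `generate_registration_scene`, `generate_region_study`,
  `generate_cfm_observations`).

## Worked example

Simulate a phantom with twelve sensors at 1–12 kPa, detect the spots, and
recover stress from the MR signal alone:

```r
library(mechanomr)
model <- calibration_model()

ph   <- generate_calibration_phantom(n_particles = 12,
                                     stresses = seq(1, 12, 1), seed = 7)
det  <- detect_particles(ph$volume)
keep <- filter_aggregates(det)$retained

# zero-stress cohort reference for signal normalization
ref  <- generate_calibration_phantom(30, 0, seed = 8)
sbr0 <- estimate_reference_sbr0(
  filter_aggregates(detect_particles(ref$volume))$retained)

sig <- normalize_signal(keep$sbr, sbr0, model)
S   <- invert_signal(model, sig, clamp = TRUE, clamp_slack = Inf)
data.frame(sbr = keep$sbr, signal = sig, stress_kPa = as.numeric(S))
```

which prints (ordered by stress):

```
  y_mm x_mm    sbr signal stress_kPa
  3.97 1.73 0.0979 0.8791       1.05
  2.74 7.14 0.0915 0.8220       1.92
  8.57 2.14 0.0827 0.7425       3.87
  2.17 2.65 0.0823 0.7396       3.95
  1.57 4.44 0.0769 0.6907       5.56
  ...
  3.84 7.57 0.0563 0.5060      13.21
```

Each row is one detected sensor: its measured SBR, the SBR normalized to
the zero-stress cohort reference (`sbr0 = 0.1112` here, so an unstressed
sensor maps to signal 0.9984), and the stress recovered by inverting the
biexponential law. The true stresses were 1–12 kPa; per-sensor errors of a
few tenths to ~1 kPa at the high end reflect the default scanner-noise
model (single-particle SNR 9.5).

The numbered scripts under `analysis/` run the full studies — calibration
self-recovery, phantom signal quality, device mechanics, longitudinal
tracking under the gradual and acute loading regimens, and the two-region
registration analysis — each printing what it finds and writing its tables
under `results/`:

```sh
Rscript analysis/01_calibration_fit.R
Rscript analysis/02_phantom_quantification.R
Rscript analysis/03_device_mechanics.R
Rscript analysis/04_tumor_tracking.R
Rscript analysis/05_region_registration.R
```

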
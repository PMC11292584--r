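---
title: "PD-US perfusion analysis: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PD-US perfusion analysis: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the measurement model behind `pdus`, the rationale
for every default parameter, the realism limits of the synthetic data
generator, and the numerical design decisions — including the conventions
chosen where the underlying methodology leaves room for interpretation.

## 1. Measurement model

### Signal chain

A recording is a 12-s sequence of 96 Doppler frames at 8 Hz. Each Doppler
frame is a color-flow acquisition group of 17 echo frames at 1000 fps; the
pipeline takes one echo frame per group (`assemble_ensembles()`,
`frame_index = 1`), forming an 8 Hz *slow-time* sequence that is cut into
six 16-frame, 2-s ensembles.

Within an ensemble the echo signal at each spatial sample is modeled as

    s(x, t) = c(x, t) + b(x, t) + n(x, t)

with tissue clutter `c` (strong, spatially coherent, rigidly moving), blood
echoes `b` (weak, diffusely moving), and white noise `n`. The processing
chain is:

1. **Registration.** Rigid in-plane translation of each frame relative to
   frame 1 is estimated by FFT cross-correlation with sub-sample refinement
   and removed by Fourier phase-shift resampling, which preserves RF phase.
2. **Clutter filtering.** The registered ROI samples form a Casorati matrix
   `M` (space × slow time). After registration the clutter is nearly
   rank-one in slow time, so subtracting the leading singular component
   (`svd_filter()`, `n_removed = 1`) removes it.
3. **Power estimation.** The PD-US index for the ensemble/ROI is the mean
   squared filtered sample value (`pdus_power()`), equal to the integral of
   the slow-time Doppler PSD by Parseval's relation.
4. **Normalization.** Within a mouse, per-ensemble powers are averaged on
   the linear scale per time point and expressed in dB relative to the
   pre-ligation baseline (`normalize_profile()`). Constant offsets — such
   as the noise floor, which dominates the filtered power — cancel in the
   ratio, so the profile tracks *changes* in blood echo power.

### Doppler scales

`acquisition_relations()` makes the implied scales explicit: a 2-s ensemble
gives 0.5 Hz resolution; the 8 Hz slow-time rate gives a ±4 Hz Nyquist
band; through `v = f c / (2 f0)` one 0.5 Hz bin at 24 MHz corresponds to
≈ 0.016 mm/s axial velocity; and at 0.5 dB/(cm·MHz), a 2 mm deep target
sees ≈ 4.8 dB (~5 dB) of round-trip attenuation.

### Ischemic parameters

From a baseline-normalized profile on the canonical schedule
(`pdus_schedule()`: pre, 10–60 min, days 1–28):

- **P_max** — the 20-min point minus a quadratic trend in log10(minutes)
  fitted through the pre, 10-, 30-, and 60-min points (the 20-min point is
  excluded from the fit). Uncertainty is the sd of replicate 20-min
  measurements when available.
- **P_min** — the minimum *measured* post-ligation value (never a fitted
  value).
- **T** — the upward 0-dB crossing, within (1, 28] days, of a quadratic in
  log10(days) fitted through days 1, 2, 3, 7, and 14; censored if the fit
  never reaches baseline.

## 2. Parameters: units, defaults, rationale

### `acquisition_geometry()`

| Parameter | Default | Rationale |
|---|---|---|
| `transmit_freq_hz` | 24 MHz | high-frequency small-animal linear array |
| `sound_speed_m_per_s` | 1540 | soft tissue |
| `axial_sample_freq_hz` | 96 MHz | 4 × carrier, the minimum at which real RF represents the oscillation; axial spacing c/(2·fs) ≈ 0.008 mm |
| `line_pitch_mm` | 0.05 | fine-pitch high-frequency array; 3 lines per lateral PSF width |
| `doppler_frame_rate_hz` | 8 | color-flow Doppler frame rate; sets the ±4 Hz slow-time band |
| `echo_frames_per_doppler_frame`, `intra_frame_rate_hz` | 17, 1000 | color-flow group structure; the pipeline uses one frame per group |
| `n_doppler_frames` | 96 | 12-s recording = 6 ensembles |
| `psf_axial_mm`, `psf_lateral_mm` | 0.10, 0.15 | FWHM of the Gaussian PSF envelope, resolution-cell scale at 24 MHz |
| `n_axial`, `n_lines` | 256, 48 | ≈ 2.1 × 2.4 mm field — large enough for an interior 1 mm² ROI, small enough for desk-scale simulation. Frame size is a package choice, not a physical constraint. |

### `ground_truth_spec()`

| Parameter | Default | Rationale |
|---|---|---|
| `clutter_power_db` | 40 | tissue echoes ~40 dB above blood |
| `blood_power_db` | 0 | blood baseline defines the 0 dB reference |
| `noise_power_db` | 25 | echo SNR = clutter − noise = 15 dB |
| `respiration_amplitude_mm` | 0.010 | residual periodic tissue motion under anesthesia |
| `respiration_period_s` | 0.4 | ~150 breaths/min; 2.5 Hz lands inside the ±4 Hz band |
| `blood_speed_mm_per_s` | 1.0 | capillary flow in muscle is below 2 mm/s |
| `scatterer_density_per_mm2` | 600 | ~10 scatterers per resolution cell → fully developed speckle |

The defaults *are* the study conditions; validation simulations use them
unchanged, and individual components can be disabled with `-Inf` power.

### Speckle calibration

Scatterer amplitudes are scaled analytically so a component renders at its
specified mean power: for density ρ and a separable Gaussian PSF with axial
carrier, `E[power per sample] = ρ A² (√π σ_z / 2)(√π σ_x)` (the cos²
carrier averages to 1/2). This keeps the power ledger exact in expectation
without empirical renormalization.

## 3. Generator realism and limits

The simulator is built for *validation with known ground truth*, not for
photorealism. Known limits:

- Tissue motion is rigid in-plane translation only — no elevational motion,
  shear, or deformation. This matches the rigid registration model by
  construction, so registration results on simulated data are a best case.
- Blood motion is an isotropic Gaussian random walk (RMS speed), not
  directed flow in vessels; it decorrelates blood echoes in slow time
  without imposing a Doppler shift.
- The PSF is separable, Gaussian, and shift-invariant; no depth-dependent
  focusing, attenuation, or reverberation.
- Noise is white and Gaussian; no acquisition artifacts.
- With the default ledger, blood echoes sit 25 dB below the noise floor, so
  *profile-level* perfusion changes are not recoverable from the RF
  simulator; perfusion profiles are generated directly at the profile level
  (`simulate_mouse_profile()`, `simulate_cohort()`) with an
  `ischemic_perfusion_curve()` whose branches are exact quadratics in
  log-time, making closed-loop estimator validation exact in the noiseless
  case.

## 4. Numerical design decisions

- **Tapered cross-correlation.** The FFT cross-correlation is circular; the
  mismatched wrap-around content at frame edges biases broad sub-sample
  peaks toward zero lag (we measured 20–30 % shrinkage of lateral
  estimates). Frames are therefore multiplied by a separable Tukey window
  (α = 0.25) before correlation, and a second pass re-estimates the
  residual shift after undoing the first estimate, canceling the
  shift-proportional bias of the stationary taper. Recovered motion is then
  accurate to well under 1 µm at 15 dB SNR.
- **Sub-sample peak refinement** evaluates the cross-correlation on a
  ±0.75-sample neighborhood at 1/100-sample resolution via a local matrix
  DFT — no interpolation model beyond the signal's own band limit.
- **Fourier phase-shift resampling** preserves RF phase exactly for
  band-limited signals; the Nyquist bins are symmetrized to keep the output
  real (so signals with energy exactly at Nyquist are attenuated there).
  Edge rows/columns shifted in from outside the field are zeroed; interior
  ROIs are unaffected at micron-scale motion.
- **SVD filter** subtracts the leading singular component(s) explicitly
  (`M − u₁ s₁ v₁ᵀ`), which equals the trailing-component reconstruction to
  numerical precision and conserves energy (`Σ sᵢ² = ‖M‖²`).
- **Doppler PSD** is an untapered, spatially averaged periodogram without
  mean removal: the 0 Hz bin belongs to the filtered spectrum, and the PSD
  sums exactly to the mean power (Parseval), keeping spectrum and power
  estimates consistent.
- **Exact rank tests.** For combined n ≤ 12 the Wilcoxon and Kruskal-Wallis
  null distributions are enumerated exactly (midranks under ties; two-sided
  p = 2·min(tails) for the rank sum, `P(H ≥ obs)` for KW); beyond that the
  standard large-sample references are used.
- **Permutation ANCOVA.** The exact rank-based ANCOVA algorithm referenced
  by the methodology is not restated there; `ancova_adjusted_comparison()`
  implements a clearly-labeled stand-in: rank-transform the response,
  residualize response and group indicator against the covariates, and
  compare the absolute residual cross-product against its permutation
  distribution (Freedman-Lane style). Type-I error calibrates to ≈ 5 %.
- **Box-Cox** uses the standard `(x^λ − 1)/λ` form with profile-likelihood
  λ ∈ (0.1, 1.1); dB values are offset to positivity (`x + 1 + |min|`)
  first, with the offset recorded.

## 5. Conventions where the methodology is underspecified

These choices are documented conventions, not claims:

- **Fit abscissa.** The polynomial fits use log10(time), consistent with
  log-time plotting of recovery data; linear time is not offered as a
  default because the 10–60 min and 1–28 day points would be wildly
  unbalanced on it.
- **The "pre" point sits at 1 min** on the log-time axis for the P_max fit
  (it must occupy a finite abscissa). All estimators treat it as the 0-dB
  baseline regardless of this placement.
- **Root selection for T**: the upward crossing (positive slope) within
  (1, 28] days, ties broken toward the earlier crossing; an all-baseline
  profile reports the day-1 boundary with a warning.
- **ROI-restricted filtering.** The SVD filter is applied to the ROI's
  Casorati matrix (not the full frame) by default: the rank-one clutter
  model is most accurate locally, and the ROI is where power is read out.
- **Group-curve uncertainty** is the across-mice standard error of the dB
  values per time point (within-mouse averaging happens on linear power
  before dB conversion).
- **RH baseline** is the *average* of the pre-cuff power estimates (a
  single-estimate baseline is more volatile); the peak is searched within
  5 min of cuff release. Both windows are configurable.
- **Classification thresholds are inclusive** at the lower normal edges
  (FMD ≥ 0.13, RH ≥ 3.9 dB count as normal) and configurable.
- **Diabetic classification reference test.** The AUC-elevation criterion
  is implemented as a rank test of the non-diabetic reference AUCs against
  the mouse's value at p < 0.05, combined with the fasting-baseline gate
  (> 200 mg/dL); the reference cohort and test were not specified by the
  methodology and this stand-in is configurable.

## 6. Problem sizes

All validation targets run at desk scale on one CPU: single ensembles
simulate in under a second; the full test suite (including 200-seed
parameter-recovery and 500-simulation calibration batches) completes in
about a minute; the 20-seed registration acceptance run takes ~15 s. These
sizes are the package's own choices for fast, deterministic validation and
can be scaled up through the same interfaces.
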
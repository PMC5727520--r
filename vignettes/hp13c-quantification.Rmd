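---
title: "Quantifying hyperpolarized [1-13C] pyruvate CSI of the injured mouse brain"
author: "hpcsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyperpolarized [1-13C] pyruvate CSI of the injured mouse brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpcsi)
```

## The measurement

Hyperpolarized (HP) [1-13C] pyruvate imaging reports cerebral glycolytic
state in vivo: after an intravenous bolus of hyperpolarized pyruvate,
lactate dehydrogenase exchanges the 13C label into lactate, and the ratio
of the two resonances' signals is a real-time index of pyruvate-to-lactate
conversion. In focal brain injury, the injured cortex shows an elevated
lactate-to-pyruvate ratio relative to the animal's own contralateral
hemisphere, which serves as an internal reference.

`hpcsi` implements the full quantification chain for dynamic 2D chemical
shift imaging (CSI) of this experiment, together with a synthetic-data
module so every stage is testable without animal data:

1. **`synthetic_data`** — digital phantoms with known exchange kinetics,
   forward-modeled to raw complex k-space (`make_phantom()`,
   `simulate_dynamics()`, `synthesize_kspace()`).
2. **`recon`** — spatial zero-filling, centered inverse spatial DFT,
   spectral FFT, and summation over dynamic frames (`zero_fill()`,
   `reconstruct()`, `sum_over_time()`).
3. **`spectral_fit`** — Lorentzian fitting of the pyruvate and lactate
   resonances and AUC-ratio maps (`fit_lorentzian_pair()`, `ratio_map()`).
4. **`maps_roi`** — anatomical-resolution heatmaps, hemisphere ROI means
   and percent-of-contralateral normalization (`interpolate_heatmap()`,
   `roi_mean()`, `percent_of_contralateral()`).
5. **`anatomy_volumes`** — lesion / cavity / ventricle volumetry from
   anatomical label masks (`label_volume()`, `percent_volume_change()`).
6. **`stats`** — one-way, two-way and repeated-measures ANOVA with Tukey
   HSD post-hoc correction, and two-group t-tests (`two_way_anova()`,
   `tukey_hsd()`, ...).

## The kinetic model

Each tissue class evolves under two-site exchange with longitudinal
relaxation and per-excitation RF depletion:

$$\frac{dP}{dt} = u(t) - (k_{PL} + R_{1P})\,P, \qquad
  \frac{dL}{dt} = k_{PL}\,P - R_{1L}\,L,$$

with both magnetizations multiplied by $\cos\alpha$ at every excitation.
Between excitations the linear system is advanced with its exact
closed-form solution (the degenerate case $k_{PL}+R_{1P}=R_{1L}$ uses the
analytic $t\,e^{-at}$ limit), splitting the integration at bolus
breakpoints, so no ODE solver tolerance enters the simulator. The test
suite checks the trajectories against an independently coded
matrix-exponential propagator to below $10^{-8}$ relative error.

Key parameters and defaults (`kinetic_params()`):

* `kpl_per_s = 0.114` — apparent exchange rate. This is an *effective
  lumped* rate chosen once so that the time-summed lactate-to-pyruvate AUC
  ratio of a normal-tissue voxel is about 0.4 under the default
  acquisition, the scale commonly reported for rodent-brain HP pyruvate
  studies. It deliberately absorbs perfusion and compartment effects the
  generator does not model, so it is larger than apparent in vivo
  $k_{PL}$ estimates.
* `r1p_per_s = 1/30`, `r1l_per_s = 1/25` — literature-scale 13C
  longitudinal relaxation at high field.
* `t2star_s = 1/(40*pi)` per metabolite — 40 Hz Lorentzian full width at
  half maximum, a typical in vivo linewidth at 14.1 T.
* Bolus: rectangular input over 12 s starting at $t = 0$, mirroring a 12 s
  intravenous injection; a gamma-variate shape is available via
  `bolus_shape = "gamma"` (evaluated as a fine piecewise-constant input).

## The acquisition model

`csi_config()` mirrors a 14.1 T mouse protocol: TE/TR = 1.2/60 ms,
2500 Hz spectral width, 128 FID points, 10° flip angle, 24 × 24 mm² FOV,
8 × 8 phase encodes, 5 mm slice, one frame every 4 s, 16 frames (~1 min).
The acquired matrix side of 8 follows from the factor-of-two zero-fill
producing a 16 × 16 analysis grid. Where protocol sources disagree on the
frame period (4 s in the protocol listing versus 3 s in narrative text),
the Methods-style listing wins and `frame_period_s` stays configurable.
Pyruvate and lactate sit at −920 and +920 Hz about the carrier (≈12.2 ppm
apart for 13C at 14.1 T), both inside the sampled bandwidth; the offsets
are configurable because the protocol itself does not state them.

Frames are ideal snapshots: all 64 phase encodes of a frame share the
magnetization at the frame's first excitation, while RF depletion and
relaxation continue across the frame. This keeps the spatial encoding
separable (k-space per frame is an exact 2D DFT of a static image) and
therefore round-trip testable; the cost is that intra-frame signal decay
is not encoded, a second-order effect at a 10° flip angle.

Noise is i.i.d. complex Gaussian in k-space under a single seed. Because
in vivo reports rarely quantify SNR in a reusable way,
`noise_sd_for_snr()` parameterizes it as the *pyruvate peak SNR of the
time-summed voxel spectrum* of normal tissue — the quantity the fits
actually see. The unitary spatial transform propagates k-space noise
unchanged; zero-filling halves both the voxel amplitude and the voxel
noise (only a quarter of the padded samples carry noise), so the peak SNR
is zero-fill invariant.

## Reconstruction conventions

* k-space is DC-centered (zero frequency at index $n/2+1$); with even
  matrices the zero-fill block placement leaves the extra zero row and
  column on the high-frequency side automatically.
* The spatial transform is unitary ($1/\sqrt{N}$ both ways), so
  Parseval's identity holds exactly between image and k-space — asserted
  to $10^{-10}$ in the tests.
* The spectral FFT is a plain forward FFT with an fftshift, giving a
  monotone frequency axis over ±1250 Hz.
* No apodization, line broadening, or B0/phase drift correction is
  applied.
* Frames are summed complex by default; magnitude summation is available
  (`sum_over_time(..., magnitude = TRUE)`) because whether the original
  chain summed complex or magnitude spectra is not documented.

Zero-filling in this convention is a pure interpolation: fine-grid samples
at the original sample positions reproduce the coarse image exactly (the
tests assert this to $10^{-10}$).

## Lineshape fitting

Each voxel's time-summed spectrum is fitted with a
two-Lorentzian-plus-constant-baseline model by bounded
Levenberg–Marquardt least squares (`minpack.lm`), restricted to ±300 Hz
windows around the two configured offsets. Three design choices deserve
explanation:

* **Both quadratures, free zero-order phase.** The absorption channel of a
  decaying resonance is Lorentzian; its magnitude is
  $A/\sqrt{1+x^2}$, whose heavy tails bleed strongly into the weaker
  lactate window — on noiseless synthetic data, magnitude-mode fitting
  biased the lactate-to-pyruvate ratio by roughly −70 %, which is why the
  package fits the phased complex spectrum (absorption model on the real
  channel, dispersion on the imaginary channel) instead. The global
  zero-order phase is a fit parameter, initialized at the tallest peak's
  bin; fitting it matters because the true peak center generally falls
  between frequency bins, and the residual phase error of a bin-wise
  estimate leaks dispersion into the absorption channel.
* **Periodic lineshape for sampled data.** The DFT spectrum of a sampled
  FID is exactly the bandwidth-periodic summation of the continuous
  lineshape (Poisson summation). At 2500 Hz bandwidth the two resonances
  are 1840 Hz apart, so each peak's first aliased replica sits only
  660 Hz from the other peak and its tail is not negligible.
  `ratio_map()` therefore fits `lineshape = "periodic"` (replicas at ±1
  bandwidth); `fit_lorentzian_pair()` defaults to the plain Lorentzian,
  which is exact for directly constructed lineshapes.
* **AUC convention.** Every converged peak reports the closed-form area
  $A \cdot \pi \cdot \mathrm{FWHM}/2$ of the un-aliased line; the identity
  is exact by construction and cross-checked against numerical quadrature.

Bounds keep centers inside their windows, FWHM between one bin and the
window width, and amplitudes non-negative; optimizer failure is reported
as `converged = FALSE` (with `NA` AUC), never as an exception. If an
unbounded optimizer ever returned a negative amplitude it would be clipped
to zero and flagged non-converged.

Voxels enter the ratio map only if both fits converge and the pyruvate AUC
exceeds a floor, by default five times the median "background AUC" (the
area a Lorentzian of the median fitted pyruvate width would have at the
typical off-window magnitude). Masked voxels carry `NA`, never a silent
zero.

## ROI analysis and heatmaps

Hemisphere ROIs are drawn at anatomical resolution (256 × 256 over a
30 mm FOV) and transferred to the CSI analysis grid by majority vote of
the anatomical pixels covering each voxel; both FOVs are assumed
concentric (shared gradient isocenter), and no registration is performed.
Hemisphere summaries are the arithmetic mean of quality-masked voxel
ratios — voxel-wise fits first, then averaging — and each animal's injured
hemisphere is expressed as
$100 \times (\text{injured} - \text{contralateral}) / \text{contralateral}$.

`interpolate_heatmap()` produces display-resolution maps by bilinear
interpolation with physical voxel-center alignment; pixels outside the CSI
footprint are missing, and masked voxels are never interpolated across.
Color rendering is left to the user.

## Volumetry

`label_volume()` counts labeled voxels exactly and multiplies by
$(\mathrm{FOV}/\mathrm{matrix})^2 \times \text{slice thickness}$ — binary
labels with no partial-volume weighting, matching manual delineation
practice; mesh-based smoothing is deliberately not implemented.
`percent_volume_change()` uses the shrinkage-positive convention (a lesion
that halves is a +50 % decrease).

## Statistics

The group layer mirrors a standard preclinical analysis: fixed-effects
two-way ANOVA (hemisphere × time) with interaction, one-way ANOVA,
within-subject repeated-measures ANOVA with the animal as a blocking
factor (no sphericity correction; noted here rather than silently
assumed), and the unpaired two-group t-test. Tukey HSD follows every
ANOVA; summaries never report unadjusted post-hoc p-values, and the
adjusted value uses the studentized range with the Tukey–Kramer standard
error, cross-checked in the tests against an independent numerical
integration of the studentized-range distribution. Degenerate inputs
follow explicit conventions: an effect with zero sum of squares reports
$F = 0, p = 1$ even when the residual variance is also zero, and a
zero-variance t-test with equal means reports $t = 0, p = 1$.

Whether the original hemisphere-by-time analysis treated time as repeated
within animal is not documented; the fixed-effects form is the default
and the repeated-measures variant is exported.

## The synthetic cohort and what passing tests show

`simulate_tbi_cohort()` builds per-animal phantoms whose injured tissue is
calibrated (`calibrate_lesion_kpl()`, a one-dimensional root find on the
monotone ratio-vs-rate curve) to a programmed AUC-ratio elevation, applies
a shared lognormal between-animal multiplier (CV 0.1) to all exchange
rates, adds noise at a stated spectral SNR and runs the full measurement
chain. `simulate_ratio_table()` generates cohort-level ratio tables
directly (between-animal SD 0.04, per-record noise SD 0.05 around a base
ratio of 0.40, with injured-hemisphere elevations of 0/23/36/37/15 % at
baseline/12 h/24 h/7 d/28 d) for exercising the statistics layer at
Monte-Carlo scale.

The generator emulates bolus delivery, exchange, relaxation, RF depletion,
Fourier encoding and thermal noise. It does **not** model B0/B1
inhomogeneity, coil sensitivity, a vascular/perfusion compartment, motion,
frequency drift, or partial-volume anatomy beyond class labels — so
passing tests demonstrate the correctness and calibration of the
*measurement chain*, not robustness to every in vivo artifact.

Problem sizes used by the test suite and the acceptance script: 8 × 8
acquisitions with 128-point FIDs and 16 frames; cohorts of 10 animals at
spectral SNR 20 and 10; 1000-replicate null calibrations and
200-replicate detection runs for the statistics layer. On noiseless data
the full chain recovers a programmed +40 % lesion elevation (≈+14.5 % at
hemisphere level after dilution by normal tissue) to within about one
percentage point; at SNR 20 the cohort median lands within ±5 points.

## Known limitations

* The effective `kpl_per_s` calibration means simulated rate constants
  should not be compared numerically with in vivo $k_{PL}$ fits.
* Ratio estimates at voxels near the quality floor are noise-limited and
  upward-biased (non-negative amplitude bounds rectify noise); hemisphere
  means at SNR ≤ 10 inherit a few percentage points of positive bias.
* The snapshot encoding model ignores intra-frame depletion ordering, so
  k-space phase-encode ordering effects are not represented.
* Fixed-effects ANOVA treats repeated animals as independent unless the
  repeated-measures variant is used.
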
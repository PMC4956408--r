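---
title: "Linking widefield imaging signals to pooled V1 activity: model, generator, and pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking widefield imaging signals to pooled V1 activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(widefieldpool)
```

Widefield fluorescence imaging of visual cortex measures, at each pixel,
the summed activity of thousands of neurons. Two widely used indicators
report different biophysical quantities: voltage-sensitive dyes (VSD)
track membrane potential, while genetically encoded calcium indicators
(GCaMP) track spiking. `widefieldpool` implements the quantitative link
between these mesoscopic signals and single-neuron physiology: a
population-pooling model with a power-law spiking nonlinearity, a
synthetic-cortex generator so every analysis stage can be validated
against known ground truth, the standard widefield analysis pipeline, and
least-squares estimation of the model's two free parameters.

## The single-neuron model

Membrane-potential responses are separable descriptive tuning functions
of contrast $c$, cortical position $x$, and orientation $\theta$:

$$
L_c = \frac{c}{\sqrt{c^2 + C_{50}^2}}, \qquad
L_x = \exp\!\left(-2\ln 4\,\Big(\frac{x - x_0}{\hat W_x}\Big)^2\right), \qquad
L_\theta = \hat f_\theta \exp\!\left(-2\ln 4\,\Big(\frac{\Delta\theta}{\hat W_\theta}\Big)^2\right) + (1 - \hat f_\theta),
$$

where $C_{50}$ is the contrast semi-saturation constant, $x_0$ the
receptive-field (RF) center, $\hat W$ the full widths at half maximum
(FWHM), $\hat f_\theta$ the tuned fraction, and $\Delta\theta$ the minimal
circular distance on the 180° orientation circle. Spiking responses are
obtained by a power law, $R = L^{n_s}$.

Tuning parameters are reported in the literature for spikes, so the
potential-referenced ("hatted") values are derived by undoing the
nonlinearity:

$$
\hat W_x = W_x \sqrt{n_s}, \qquad
\hat W_\theta = W_\theta \sqrt{n_s}, \qquad
\hat f_\theta = 1 - (1 - f_\theta)^{1/n_s}.
$$

The $\sqrt{n_s}$ width rule is exact for a pure Gaussian; with an untuned
pedestal it is the standard approximation (raising the pedestal curve to
$n_s$ does not yield an exactly Gaussian tuned component). The tests
assert the exact cases (position; orientation with $f_\theta = 1$; the
tuned-fraction identity $(1-\hat f_\theta)^{n_s} = 1 - f_\theta$).

Defaults are the literature means: $W_x = 2$ mm of cortex,
$W_\theta = 40$°, $f_\theta = 0.9$, $n_s = 3$.

```{r}
derive_potential_params(single_neuron_params())
```

## Population pooling

The signal at one imaged location is a weighted sum of neurons with
heterogeneous tuning. Three scatter distributions are used, one per
stimulus dimension (the dimensions are probed in separate experiments, so
only the matched scatter applies to each pooled curve):

- **Contrast semi-saturation**: power-function decay
  $w_c(C_{50}) \propto C_{50}^{-p_{50}}$ with $p_{50} = 0.5$. The support
  is not constrained by the single printed fact — the mean
  $\overline{C_{50}} = 30\%$ — so the default grid (1–82% contrast in 1%
  steps) was calibrated once so that the $p_{50} = 0.5$ weights have a
  30% mean (29.9%).
- **RF-center position**: Gaussian,
  $w_x(x_0) \propto \exp(-x_0^2 / 2\sigma_{x0}^2)$, on a ±6 mm grid with
  0.05 mm steps.
- **Preferred orientation**: von Mises. Written with $\cos\theta_0$ the
  density would be 360°-periodic on a 180°-periodic domain, so the
  package uses the doubled angle,
  $w_\theta(\theta_0) \propto \exp(\kappa_\theta \cos 2\theta_0)$, which
  respects orientation periodicity and reduces to the same shape near
  $\theta_0 = 0$ for concentrated distributions. Grid: 1° steps over one
  180° cycle.

All weight vectors are stored normalized to sum to 1. Pooled curves are
the weighted sums of $L$ (potential-like, VSD) or $L^{n_s}$
(spiking-like, GCaMP), peak-normalized:

```{r}
po <- pooled_tuning_curve("orientation", "potential")
sp <- pooled_tuning_curve("orientation", "spiking")
rbind(potential = unlist(curve_summary(po)[c("fwhm", "floor")]),
      spiking = unlist(curve_summary(sp)[c("fwhm", "floor")]))
```

Because the exponent acts per neuron before the sum, the spiking pool is
narrower in orientation and position, has a smaller untuned floor, and
saturates later in contrast than the potential pool — the qualitative
signature that distinguishes the two indicators. `curve_summary()`
measures FWHM at half height *above the curve floor* (pooled potential
orientation curves have floors above 0.5, so an absolute half-maximum
crossing does not exist); for a floorless curve this is the usual half
maximum.

The grid discretizations (1% contrast, 0.05 mm, 1°) put well over ten
support points per FWHM of every kernel involved; agreement of the
discrete sums with Monte-Carlo pools of $10^5$ sampled neurons is part of
the test suite.

The two scatter widths, $\sigma_{x0}$ and $\kappa_\theta$, are the only
free parameters; defaults are $\sigma_{x0} = 0.5$ mm and
$\kappa_\theta = 2$ (chosen once: they give a pooled position FWHM of
~3.7 mm and an orientation-scatter SD of ~20°, plausible for mesoscopic
population tuning; no fitted values are published to adopt).

## The synthetic cortex and recordings

The generator exists so that every pipeline stage can be validated in a
closed loop. It emulates:

- **Orientation-preference map**: band-pass-filtered complex Gaussian
  noise (annulus at $1/\text{period}$, default period 0.7 mm, relative
  bandwidth 0.15). Preferred orientation is half the complex argument;
  the map is semi-periodic and contains pinwheels of both charges, and
  preferred orientations are uniform on $[0°, 180°)$. Selectivity is the
  field magnitude compressed to saturate at 1 above its 0.2 quantile:
  real maps are strongly selective almost everywhere, with weak
  selectivity confined to pinwheel cores, whereas the raw
  Rayleigh-distributed magnitude would spread columnar-band energy into
  the orientation-independent part of every response map.
- **Retinotopy**: an affine visual-field-to-cortex map (default
  magnification 1.5 mm/deg, patch center at (2.5°, −2.5°), parafoveal
  lower field). Real V1 retinotopy is log-polar; over a patch a few mm
  wide the affine approximation is standard.
- **Stimuli**: full-field gratings (contrast ladders, 12 orientations in
  15° steps) and Gabor patches along a radial trajectory, flashed at 4 Hz
  (100/150 ms, calcium, 20 Hz frames), 5 Hz (60/140 ms, VSD, 100 Hz
  frames), or 2 Hz (200/300 ms, contrast/position runs), with randomly
  interleaved repeats and blank trials.
- **Temporal kernels**: difference of exponentials, rise/decay 50/400 ms
  (calcium-like — the response does not return to baseline between 4 Hz
  flashes and builds up across the train) and 15/60 ms (VSD-like —
  returns below 10% within 200 ms). The kernels are the simplest shapes
  with separable rise and decay; no published impulse response is
  available to copy.
- **Amplitude calibration**: each trial's temporal profile (flash train
  convolved with the kernel) is normalized to unit peak, so `peak_dff` is
  exactly the peak evoked dF/F of a full-contrast preferred stimulus.
  Defaults 0.05 (calcium) and 0.01 (VSD) encode the reported ~5× amplitude
  ratio between the two signals.
- **Noise**: i.i.d. Gaussian per pixel and frame, SD expressed as a
  fraction of `peak_dff`. The default 0.15 is calibrated so the best
  pixel's single-trial first-harmonic response d′ is ≈3.6 (≈11 for
  10-trial averages), matching the signal quality reported for
  high-contrast gratings.
- **Optical blur**: Gaussian point-spread, default SD 0.2 mm, the
  widefield pooling scale.

Each pixel's response amplitude for a condition is the product of the
pooled contrast, position (Gabor only), and orientation responses at that
pixel's map values, scaled by the pixel's selectivity. Selectivity enters
as a pure per-pixel gain — every pixel traces the same normalized pooled
curve — which is what makes exact closed-loop validation possible: after
ROI averaging and peak normalization the analysis must return the
generating pooled curve up to discretization. In real pinwheel
physiology, low selectivity reflects *mixing* of preferences rather than
a gain change; consequently the synthetic data are easier for the
pipeline than real data near pinwheels, and closed-loop agreement should
be read as validating the analysis code, not as a statement about
pinwheel-core biology.

Also deliberately not emulated: vascular artifacts, hemodynamic signals,
heartbeat locking, photobleaching, eye-movement jitter, laminar
structure, and any topographic organization of $C_{50}$. Passing tests
therefore validate the computational chain under the model's own
assumptions, not robustness to these nuisances.

Everything is deterministic given the seed: maps, trial order, and noise
reproduce bit-identically, and the seed is recorded in each recording's
provenance.

## The analysis pipeline

The pipeline follows standard widefield practice:

1. **Blank subtraction**: trials are averaged within condition, then the
   mean blank time course is subtracted frame-wise. This happens before
   any amplitude estimate. A recording without blanks errors unless a
   zero-baseline fallback is requested explicitly.
2. **Response amplitudes**: for contrast and position runs, the mean over
   a 200 ms window starting 35 ms after each flash onset (a frame belongs
   to the window iff its midpoint falls inside — at 20 Hz this selects
   the 4 frames with midpoints 75–225 ms); for orientation runs, the
   first-harmonic Fourier amplitude $2|X(f)|/N$ at the flash frequency,
   which returns A for a sinusoid of amplitude A and requires an integer
   number of cycles per trial.
3. **d′ and ROIs**: per-pixel mean single-trial amplitude over its
   across-trial SD (sample SD; NA when degenerate), maximized over
   conditions. ROI rules: a 1.6 mm square at the d′ peak (calcium
   contrast/orientation), all pixels with d′ > 3 (VSD), or a 0.75 mm
   square at a retinotopic location (position). Square sides are rounded
   to the nearest pixel count (1.6 mm at 0.05 mm/pixel → 32 px) and
   clipped at the patch edge.
4. **Maps**: a spatial bandpass (0.8–3 cyc/mm annulus, raised-cosine
   transition bands of 20% of each cutoff, DC removed exactly) isolates
   the columnar scale; the composite map is the per-pixel doubled-angle
   vector sum over the 12 band-passed single-condition maps, and
   grayscale maps are $\sin 2\theta_{\text{pref}}$.
5. **Tuning curves**: orientation responses are re-indexed per pixel by
   $\Delta\theta$ to the composite-map preference, folded to [0°, 90°],
   binned at the 15° stimulus spacing, averaged over the ROI, and
   peak-normalized. Curve magnitudes come from the *raw* harmonic
   amplitudes — the bandpass only defines preferences — because the
   bandpass removes DC and would delete the untuned floor, which is a
   central quantity. Position curves are plotted against the signed
   cortical distance between each stimulus' retinotopic center and the
   ROI center (negative toward the foveal representation).
6. **Cycle collapsing**: responses are split into flash cycles, each
   anchored by subtracting its mean over an initial window (50 ms / 1
   frame at 20 Hz; 36 ms / 4 frames at 100 Hz), then averaged.

Pairwise Pearson correlations between band-passed single-condition maps,
averaged per orientation difference, fall monotonically with
$\Delta\theta$ and are negative at 90° — the classic columnar signature —
for the default generator settings; correlations are computed over all
finite pixels (full patch) unless a mask is supplied.

## Fitting the scatter parameters

`fit_scatter()` estimates $(\sigma_{x0}, \kappa_\theta)$ by least squares
on peak-normalized curves, jointly over all supplied position and
orientation curves of both signal kinds (one parameter pair must explain
both indicators under the linking hypothesis; weights default to equal).
Position curves depend only on $\sigma_{x0}$ and orientation curves only
on $\kappa_\theta$, so the joint SSE separates and each parameter is
found by an exhaustive search over a 30-point log-spaced grid
($\sigma_{x0}$: 0.05–1.5 mm; $\kappa_\theta$: 0.1–20) followed by
bracketed 1-D minimization around the best grid point. Grid search plus
bracketed refinement avoids derivative and local-minimum pitfalls at this
scale and is deterministic. An optimum on a grid edge is flagged and
warned about, never silently returned. Contrast curves are independent of
both parameters and act as a pure goodness-of-fit term.

`recovery_report()` quantifies estimator quality: replicates of
model-generated position and orientation curves (both signals, on
measurement-like axes: ±3 mm in 0.75 mm steps; 0–90° in 15° steps)
corrupted by multiplicative Gaussian noise, refit, and summarized by
median, bias, and RMSE. Noise draws depend only on the seed and replicate
index, so different noise levels reuse paired realizations and RMSE is
monotone in noise level by construction of the comparison. At 5% noise
and 100 replicates the median estimates recover $\sigma_{x0}$ within a
few percent (well inside ±20%) and $\kappa_\theta$ within ~1% (well
inside ±30%).

An `"imaging"` mode runs each replicate through the full generate →
analyze → fit chain instead. With the default optical blur this returns a
markedly smaller *effective* $\kappa_\theta$ than the generative value:
the fitted orientation scatter absorbs optical pooling, which is exactly
how the scatter functions should be read — as lumping all sources of
population broadening (true tuning scatter, scatter within the pooling
volume, optical blur), not as a pure tuning-diversity parameter.

## Numerical choices and degenerate inputs

- $\sigma_{x0} = 0$ degenerates to a point mass at the grid value nearest
  0; $\kappa_\theta = 0$ gives uniform orientation weights.
- Normalized curves have max exactly 1 (the peak sample is set to 1 after
  division to absorb rounding); weight vectors sum to 1 within 1e-12.
- Non-single-peaked curves are flagged by `curve_summary()` and their
  summary fields set to NA rather than guessed.
- Composite-map pixels with all-zero amplitudes get NA preference and
  zero selectivity; constant planes are excluded from correlations with a
  warning, and correlating a constant map is an error.
- The harmonic amplitude refuses frequencies that are not exact DFT bins;
  cycle collapsing refuses non-integer frames per cycle; kernels with
  decay ≤ rise are rejected as non-physical.
- Orientation-map recovery: at noise SD ≤ 0.2 (blur off) the composite
  map agrees with ground truth at circular correlation > 0.9. The default
  0.2 mm blur itself lowers agreement to ~0.8 by blending preferences
  near column borders — an intrinsic property of mesoscopic imaging at a
  0.7 mm column period, not an analysis defect.

## Problem sizes

The validation suite runs the full chain at desk scale: 4.8 mm patches at
0.1 mm/pixel (48×48) for movie-based tests, 6.4 mm at 0.05 mm (128×128)
for map-period measurements, 2–10 trials per condition depending on
whether the test is noise-free, and 100 curve-level replicates for the
recovery study. These sizes keep every closed-loop comparison within its
stated tolerance while the whole suite runs in well under a minute.

## Limitations

The model is a descriptive one-dimension-at-a-time account: no
spatiotemporal RFs, surround suppression, cross-orientation interactions,
laminar or cell-type structure, and no cross-dimension pooling (contrast
pooling ignores position/orientation scatter and vice versa). The
generator's selectivity-as-gain simplification and the absence of
physiological nuisances mean real-data performance of the pipeline —
especially near pinwheels and blood vessels — must be established
separately. Fitted scatter parameters are effective quantities specific
to the measurement (indicator, optics, analysis), as the imaging-level
recovery mode makes explicit.
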
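# widefieldpool

Widefield fluorescence imaging of primate V1 measures, at each pixel, the
pooled activity of thousands of neurons — but *which* activity depends on
the indicator: voltage-sensitive dyes (VSD) report membrane potential,
calcium indicators (GCaMP) report spiking. `widefieldpool` is for
imaging groups and modelers who need the quantitative bridge between
these mesoscopic signals and single-neuron physiology: it predicts what
each signal should look like given known V1 single-unit properties,
generates fully synthetic widefield experiments with ground truth,
analyzes trial movies the standard way, and estimates the model's free
parameters from measured tuning curves.

## The model

Single-neuron membrane-potential responses to contrast c, cortical
position x, and orientation θ:

    L_c = c / sqrt(c² + C50²)
    L_x = exp(−2 ln4 ((x − x0)/Ŵ_x)²)
    L_θ = f̂_θ exp(−2 ln4 (Δθ/Ŵ_θ)²) + (1 − f̂_θ)

with spiking R = L^ns (power-law nonlinearity, ns = 3). Spiking-referenced
literature values (W_x = 2 mm, W_θ = 40°, f_θ = 0.9) convert to
potential-referenced ones by Ŵ = W·√ns and f̂_θ = 1 − (1 − f_θ)^(1/ns).

Each imaged location pools neurons with scattered properties:
C50 values with power-law weights w_c ∝ C50^(−p50) (p50 = 0.5, mean
C50 = 30%), RF centers with Gaussian scatter (SD σ_x0), and preferred
orientations with a 180°-periodic von Mises scatter
w_θ ∝ exp(κ_θ cos 2θ0). A VSD-like signal pools L; a GCaMP-like signal
pools L^ns. The exponent acts before the sum, so the spiking pool is
narrower, has a smaller untuned floor, and saturates at higher contrast —
the measurable signature separating the two indicators. σ_x0 and κ_θ are
the only free parameters and are fit by least squares.

## Worked example

Model predictions for both signal kinds:

```r
library(widefieldpool)

for (sig in c("potential", "spiking")) {
  s <- curve_summary(pooled_tuning_curve("orientation", sig))
  cat(sprintf("%-9s orientation pool: FWHM %.1f deg, floor %.3f\n",
              sig, s$fwhm, s$floor))
}
#> potential orientation pool: FWHM 80.2 deg, floor 0.587
#> spiking   orientation pool: FWHM 72.4 deg, floor 0.209
```

The spiking (GCaMP-like) pool is narrower and far less pedestal-dominated
than the potential (VSD-like) pool; the contrast semi-response points are
21.5% vs 9.5% contrast, and the position FWHMs 2.3 vs 3.7 mm.

A complete synthetic experiment — orientation and position suites
simulated at 48×48 pixels (0.1 mm/pixel), analyzed, and refit:

```r
cfg <- pipeline_config(list(
  seed = 1, outdir = "demo-run",
  grid = list(pixel_size = 0.1, ny = 48, nx = 48),
  suites = c("orientation", "position")))
res <- run_full(cfg)
res$fit
#> Scatter-parameter fit (least squares)
#>   sigma_x0_hat    = 0.5977 mm
#>   kappa_theta_hat = 0.3140
#>   sse             = 0.00222926
```

The generative parameters were σ_x0 = 0.5 and κ_θ = 2. Position scatter
comes back close to truth, while the fitted orientation concentration is
much smaller than the generative one: the 0.2 mm optical blur mixes
preferences across the 0.7 mm columns, and the fitted κ_θ absorbs it.
That is the correct reading of the scatter parameters — effective widths
lumping tuning diversity *and* optical pooling. Fitting curves that never
passed through the optics recovers the generative values:

```r
recovery_report(n_rep = 100, noise = 0.05, seed = 1)
#> Parameter recovery: 100 replicates, 5% noise (curves level)
#>        param truth    median        bias       rmse median_rel_err
#>     sigma_x0   0.5 0.4867355 -0.01495251 0.07381524      0.1013606
#>  kappa_theta   2.0 2.0263495  0.08848315 0.29641304      0.0918345
```

Other entry points: `make_orientation_map()` (pinwheel maps, ~0.7 mm
period), `generate_experiment_suite()` (multi-trial movies),
`single_condition_maps()` / `composite_orientation_map()` /
`pairwise_map_correlation()` (columnar map analysis),
`orientation_tuning_curve()` and friends (ROI tuning curves),
`collapse_cycles()` (flash-cycle dynamics). The vignette
(`vignettes/pooling-model.Rmd`) documents the model, the generator's
assumptions, and every analysis default.

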
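# nanostorm

Single-molecule localization microscopy (STORM/dSTORM) of pathological
tissue sections poses two problems that standard reconstruction software
handles poorly: a strong, spatially heterogeneous autofluorescent
background, and the need to turn the resulting localization maps into
per-nucleus numbers that can be compared across disease stages.
**nanostorm** addresses both for students of chromatin organisation: it
reconstructs localization tables from raw camera stacks under heavy
background, and quantifies the nanoscale organisation of chromatin —
nucleosome nanocluster size, pair correlation, Voronoi density, watershed
nanodomains, nuclear coverage, two-colour colocalization — per nucleus,
plus DNA occupancy in 3D structured-illumination volumes. A full
synthetic-data path makes every stage testable without microscope data.

## The methods in brief

**Background estimation from temporal minima.** Over an `N`-frame substack
(default 100) the per-pixel temporal minimum `m` is an order statistic of
the background alone. Approximating the Poisson(λ) background as
N(λ, λ), the expected minimum is `λ + d_N·√λ` with `d_N < 0` the expected
minimum of `N` standard normals (Blom approximation); inverting gives the
closed-form estimator

```
√λ̂ = (|d_N| + √(d_N² + 4m)) / 2,      corrected = max(0, photons − λ̂).
```

**Deflation + gradient fitting.** Candidates are local maxima above
`3√λ̂`. For each candidate (brightest first) the preliminary Gaussian
models of neighbouring candidates are subtracted from its ROI, and the
centre is estimated in one closed-form step from the radial-symmetry
condition on the intensity gradients — every gradient line of an ideal
spot passes through its centre, so the centre is the weighted
least-squares point of closest approach of all gradient lines. Valid
molecules are rendered as a 13 nm count histogram.

**Quantification.** Per nucleus: Gaussian-mixture nanoclusters with BIC
model selection (size = 2·√(geometric mean of covariance eigenvalues), a
2σ effective diameter); mask-edge-corrected pair correlation `g(r)` with a
1/e correlation length; Voronoi polygon density maps (σ = 2 px smoothing);
watershed nanodomain segmentation (regional maxima → disk-5 dilation →
distance transform ×2 + binary support → watershed on the negative, area
< 20 px rejected); coverage = fraction of mask pixels above 0.5 after σ = 1
smoothing; Mann–Whitney U group comparisons. In 3D: median-filter
background removal, radial-gradient nucleus segmentation, occupancy above
`3√background`, and condensed-focus mean intensities.

## Worked example

Simulate a sparse tissue acquisition, reconstruct it, and inspect the
result:

```r
library(nanostorm)

gt  <- chromatin_preset("easy", seed = 7)          # 150 uniform emitters
acq <- acquisition_model(n_frames = 100L, fov_px = c(65L, 65L),
                         background_field = 10, on_probability = 0.015,
                         seed = 8)
sim <- simulate_stack(gt, acq)
sim$stack
#> frame_stack: 100 frames of 65x65 px (100 nm/px), unit counts

out <- reconstruct_pipeline(sim$stack)
out$background
#> background_model: 1 substack(s) of <=100 frames, mean lambda 11.61
cat(out$manifest$n_fits, "fits,", out$manifest$n_kept, "kept\n")
#> 1371 fits, 221 kept
out$render
#> rendered_image: 500x500 px at 13 nm, 221 molecules
```

The background model recovers the simulated 10 photons/frame level
(11.6 estimated; the excess is the emitters' own contribution to pixel
statistics). Raw fits include sub-threshold noise candidates; the photon
and width filters keep 221 molecules, matching the ~225 true blinks
expected from 150 emitters × 100 frames × 0.015 on-probability. Kept
localizations land within tens of nanometres of true emitter positions:

```r
head(as.data.frame(out$locs[out$locs$keep, 1:5]), 3)
#>    frame     x_nm      y_nm  photons sigma_nm
#> 1      0 5693.447 3266.4037 886.4449 120.7737
#> 18     1 3589.926 2736.3109 890.9615 126.3499
#> 19     1 2971.797  918.4803 927.8574 118.0246
```

Downstream, `quantify_pipeline(locs, mask)` returns one row per nucleus
with `mean_cluster_size_nm`, `nnd_nm`, `correlation_length_nm`,
`domain_count`, `median_domain_diameter_nm` and `coverage_fraction`;
`preset_trend()` runs the whole quantification suite across the
normal / early / tumor compaction presets. A command-line front end for
the same pipelines lives at `inst/cli/nanostorm.R`.

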
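---
title: "Methods: tissue STORM reconstruction and chromatin nanostructure metrics"
author: "nanostorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue STORM reconstruction and chromatin nanostructure metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and assumptions
behind each stage of the package. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinate and unit conventions

All coordinates are in nanometres, x rightward, y downward, origin at the
top-left corner of the field of view. Pixel (row *i*, col *j*) — 0-based in
files, 1-based inside R — covers the half-open square
$[j p, (j+1)p) \times [i p, (i+1)p)$ for pixel size $p$. Rendered images use
$p = 13$ nm. Every module shares this convention; localization tables are
comma-delimited with header
`frame,x_nm,y_nm,photons,sigma_nm,bg_photons,channel,keep`.

## Camera model and background estimation

Raw counts convert to photons as
$\mathrm{photons} = \max(0, (\mathrm{counts} - \mathrm{offset})/\mathrm{gain})$.
Negative values are clipped because downstream detection assumes
non-negative intensities; the clipping also floors the corrected stack
after background subtraction, which gives the corrected per-pixel temporal
mean a small positive floor of about $\sqrt{\lambda/2\pi}$ photons on pure
background — the tests check against exactly this clipped-residual
expectation rather than zero.

Tissue autofluorescence produces a strong background that varies slowly in
time. Over a substack of $N$ frames (default 100, chosen so the background
is quasi-static), the per-pixel temporal minimum $m$ is an order statistic
of the background alone whenever the pixel is emitter-free in at least one
frame. Approximating the Poisson($\lambda$) background as
$\mathcal N(\lambda, \lambda)$, the expected minimum of $N$ draws is
$\lambda + d_N\sqrt{\lambda}$ with $d_N < 0$ the expected minimum of $N$
standard normals, computed once by Blom's quantile approximation
$d_N = -\Phi^{-1}\!\big((N - 0.375)/(N + 0.25)\big)$ (agreeing with Monte
Carlo to better than 1% at $N = 100$). Inverting
$m = \lambda - |d_N|\sqrt\lambda$ gives the closed-form estimator
$\sqrt{\hat\lambda} = \big(|d_N| + \sqrt{d_N^2 + 4m}\big)/2$, which is
monotone in $m$ and never negative. Trailing frames form a final shorter
substack with its own $d_{N'}$.

A pixel containing an always-on emitter (for instance a fiducial bead) has
no background-only frame, so its minimum is not background. Such pixels
are recognised by an estimate inconsistent with the pixel's own temporal
statistics — $\hat\lambda > \mathrm{median} + 3\sqrt{\mathrm{median}+1}$, a
rule that essentially never fires on clean Poisson pixels — and capped at
the substack's per-pixel 10th-percentile value. This bounds the estimate;
it cannot recover the true background under a permanently occupied pixel.
Read noise is assumed negligible relative to shot noise, a deliberate
simplification for EMCCD/sCMOS data at the photon levels simulated here.

## Detection, deflation and gradient fitting

Candidates are 8-connected local maxima of the background-corrected frame
with amplitude above $k\sqrt{\hat\lambda}$ (default $k = 3$). Ties between
equal neighbouring maxima break toward the smallest (row, col) in
lexicographic order, making detection deterministic.

Overlapping molecules are handled by one deflation pass: candidates are
processed brightest first, and for each target the preliminary Gaussian
model of every neighbouring candidate (amplitude from its observed peak,
width from the PSF prior, centre at its pixel centre) is subtracted from
the target's ROI. The pass is amplitude-only, with no iterative
re-estimation; brightness ordering was chosen because the preliminary
models of bright emitters are relatively most accurate.

The cleaned ROI is fit in a single closed-form step using the radial
symmetry of an ideal spot's intensity gradients: every gradient vector
points through the centre, so the centre is the weighted least-squares
point of closest approach of all gradient lines, computed from
cross-diagonal derivatives on the half-pixel grid with 3×3 smoothing and
inverse-distance weighting (a 2×2 linear solve). Photons are the cleaned
ROI sum and the width comes from second moments about the fitted centre.
The estimator is validated against an iterative least-squares fit of the
pixel-integrated Gaussian (agreement within 0.05 px on a 21×21 grid of
noiseless sub-pixel offsets) and against the numerically evaluated
Cramér–Rao bound for the pixel-integrated Gaussian model with Poisson
noise (empirical sd within 1.3× the bound at 1000 photons on a
10 photon/pixel background); bit-identity to any particular published
implementation is not claimed. Default filter bounds — minimum 300
photons, width within 0.5–2× the PSF prior, edge-clipped fits rejected —
are documented assumptions.

## Drift and chromatic registration

Fiducial beads are tracked by nearest-neighbour linking within a 500 nm
gate anchored at each track's last known position; per-frame drift is the
mean over beads of the displacement from each track's first observation,
gaps are linearly interpolated, and the trajectory is smoothed with a
local linear (Savitzky–Golay, order 1) filter over a 10-frame window. A
plain moving average was rejected because any centred window is either
biased or unsmoothed at the trajectory endpoints, exactly where drift
correction matters most; the local linear fit with shifted windows is
unbiased for linear drift everywhere.

Chromatic registration fits a least-squares 2D polynomial (degree 2 by
default, degree 1 below 6 beads) from channel-B to channel-A bead
positions matched by mutual nearest neighbour within 500 nm. One
outlier-rejection pass (residual above 5× the median) removes the
occasional swapped pair produced by close bead doublets. With $n$ beads of
localization noise $\sigma$ per coordinate, the recovered transform has a
truth-recovery floor of about $\sigma\sqrt{2p/n}$ over the field ($p$
terms per coordinate) — about 1.6 nm for 20 beads at 3 nm noise with an
affine fit — which is the number the validation suite measures.

## Nanostructure quantification

**GMM nanoclusters.** Localizations are clustered per nucleus by Gaussian
mixtures with the component count selected by BIC over a configurable
range (mclust). Four robustness measures matter in the dense
many-component regime (all are opt-in arguments, enabled by the pipeline
and the trend benchmark). First, a conjugate prior with a small fixed
covariance scale (100 nm²) regularises covariances; without any prior EM
fails outright (NA likelihood) at larger component counts when a
component collapses onto near-duplicate localizations, while mclust's
default data-scaled prior target — the pattern's variance divided by the
component count, orders of magnitude above nanocluster scale — inflates
every fitted size by roughly `scale/(G n_k)` and hits small sparse
clusters hardest. Second, a
uniform (Poisson) noise component absorbs the diffuse non-clustered
fraction, initialised from a k-nearest-neighbour distance rule and
refined by EM; without it, diffuse localizations are soaked up by a few
enormous Gaussian components that dominate any size average. Third,
initialisation: the fit takes the best BIC across the deterministic
hierarchical initialisation, random-subset restarts, and kmeans starts on
the non-noise points — on cluster-plus-noise mixtures the hierarchical
initialisation alone regularly stalls in a merged local optimum several
hundred BIC units below the kmeans solution. Fourth, an optional robust
size estimate (`robust_size`): the component size is computed from its
assigned points after an iterated 90% central trim, because a few distant
mis-assigned points inflate a fitted variance enough to keep themselves
plausibly assigned — a self-sustaining EM local optimum that no amount of
refitting escapes. The trim shrinks even clean Gaussian components by a
fixed factor (~0.86), so trimmed sizes are comparable only with other
trimmed sizes; relative trends are unaffected.

The cluster "size" definition is not standardised; here it is twice the
square root of the geometric mean of the covariance eigenvalues — a
2$\sigma$ effective diameter — with eigenvalues floored at 1 nm² so
degenerate clusters report the floor. Absolute sizes are comparable only
within this package; relative trends are the validated quantity. The
default covariance family is fully general (`"VVV"`); the trend benchmark
uses the spherical family (`"VII"`) because the simulated nanoclusters
are isotropic by construction and the lighter parameterisation lets BIC
resolve ~28-point clusters that the 6-parameter-per-component general
family cannot justify splitting. Per-nucleus size summaries average
components holding at least 10 localizations, excluding spurious
components fit to chance coincidences in the diffuse pool.

**Pair correlation.** $g(r)$ is estimated as pair counts in annuli of
width `dr` divided by $N\rho\,a_i(r)$, where $a_i(r)$ is each point's
annulus area inside the nucleus mask, evaluated by sampling the mid-radius
circle at 64 angles against the mask raster. Without this edge correction
the CSR normalisation fails near borders. The correlation length — not
defined by any standard — is reported as the smallest radius past the peak
where $g(r) - 1$ falls below $(g_{\text{peak}} - 1)/e$, linearly
interpolated; for a Gaussian cluster of spread $\sigma$ this sits at
$2\sigma$.

**Voronoi density.** The tessellation is computed on unique coordinates
(deldir), each polygon's density $1/\mathrm{area}$ is placed at the
point's raster position, and the map is Gaussian-smoothed with sd 2 px.
Cells clipped by the tessellation window — the former unbounded border
cells — are flagged and excluded from statistics.

**Watershed nanodomains.** The segmentation follows a fixed recipe:
regional maxima of the smoothed density map (plateau-correct, 8-connected);
dilation with a disk of diameter 5 px, which merges maxima closer than the
disk; distance transform of the inverse dilated map; amplification by 2
and addition of the binary (map > 0) support; watershed on the negative of
the sum (EBImage primitives, tolerance 0.1; ties on flooding plateaus
resolve deterministically by processing order); rejection of segments
outside the support and of segments under 20 px. Equivalent diameter is
$2\sqrt{\mathrm{area}\cdot p^2/\pi}$ at $p = 13$ nm. Two properties of the
recipe matter for interpretation: domain size cannot exceed the typical
spacing of smoothed-map maxima (~12 px here), so clusters are resolved as
single domains only when their footprint is below that scale; and the
smoothing kernel adds a constant margin to every blob, so small absolute
size differences compress.

**Coverage and colocalization.** Coverage smooths the 13 nm render with a
Gaussian (sd 1 px, normalized discrete kernel, replicated edges — constants
are preserved exactly) and reports the fraction of mask pixels above 0.5
smoothed counts. A single isolated localization never counts as covered:
the smoothed unit impulse peaks at $\approx 1/2\pi \approx 0.159$.
Colocalization reports both directional overlap fractions of two binary
maps; an empty map makes its direction undefined rather than an error.
Group comparisons use the two-tailed Mann–Whitney U test (exact for small
samples without ties).

## 3D volumes

Background is removed by a 3D median filter of 5 µm radius (evaluated on a
coarse grid with subsampled neighbourhoods and trilinearly interpolated —
adequate for a background varying on the filter scale), recording the mean
estimated level. Nucleus segmentation starts from a manual seed: the
axial profile around the seed locates the maximum-intensity plane; rays
cast from the centre place the border at the maximum-magnitude intensity
gradient along each ray (0.25-voxel sampling of a 1-voxel-presmoothed
volume; the relative gradient threshold keeps the result invariant to
global intensity scaling); successive planes re-centre and restrict the
search to 0.5–1.5× the previous radius, stopping when the plane peak falls
below 20% of the global axial peak (the stop criterion and the radial band
are choices of this package). Rays with no detectable gradient are
interpolated from their angular neighbours.

DNA occupancy is the fraction of nuclear voxels above
$3\sqrt{\mathrm{background}}$. "Condensed" heterochromatin foci are not
defined by a standard threshold; here they are 26-connected components of
valid-signal voxels above the 75th valid-signal intensity percentile with
at least 50 voxels (configurable) — directionality across conditions, not
absolute values, is the tested property.

## The simulator and what passing tests do not show

The simulator draws nucleosome nanoclusters as isotropic Gaussian clouds
inside a polygonal nuclear boundary (rejection sampling keeps every
emitter inside), adds a diffuse non-clustered fraction, and renders frames
as $\mathrm{gain}\cdot\mathrm{Poisson}(\mathrm{background} + \sum
\mathrm{PSF}) + \mathrm{offset}$ with the PSF integrated over pixel areas
(erf-difference form — this matches physical cameras and makes the fitting
oracle exact). Blinking is a memoryless per-frame Bernoulli; drift is
linear unless a trajectory is supplied; fiducials are always-on bright
emitters. A fast path (`simulate_localizations()`) skips frames and
applies detection thinning plus Gaussian jitter directly.

The compaction presets fix the total at 1260 localizations per nucleus
(2000 nm radius) and fragment it along normal → early → tumor as
20 clusters of $\sigma$ = 50 nm × 60 points + 60 diffuse,
25 × 35 nm × 42 + 210 diffuse, and 30 × 22 nm × 28 + 420 diffuse:
nanoclusters become smaller, sparser and more numerous while the released
signal joins the diffuse pool — decompacted chromatin spreading over the
nucleus, which is what carries the rising coverage fraction. The
parameters keep every readout in its resolvable regime: at least 28
points per cluster so BIC can justify splitting them, cluster footprints
below the watershed recipe's maxima-spacing ceiling, and σ steps wide
relative to the size estimator's residual noise. Trend benchmarks
simulate two acquisitions of each truth: single-blink localizations at
10 nm precision for the cluster metrics (as after photon filtering) and a
mean-15-blink stream at 20 nm precision for the density-map metrics.
These scales — tens-of-nanometre nanoclusters, per-nucleus localization
counts in the thousands — were chosen as plausible for antibody-labelled
heterochromatin in cleared FFPE tissue; the densities are assumptions,
not reproductions of any dataset.

The simulator does **not** model dark-state photophysics, 3D/astigmatic
PSFs, tissue scattering, read noise, or labelling efficiency. Passing
tests therefore demonstrate internal correctness of the estimators and the
direction of compaction trends under this generative model — not
performance on any particular tissue dataset.

## Problem sizes

Validation runs use deliberately desk-scale problems: 65×65 px stacks of
100–150 frames, 10⁴-point patterns for point-process closed forms, 2000
Monte-Carlo spots for the precision bound, 20 nuclei per group for trend
statistics, and 40³-voxel phantoms in 3D.
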
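---
title: "Models and methods behind octapipe"
author: "octapipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind octapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

octapipe implements a complete spectral-domain OCT angiography (SD-OCTA)
image-computation chain for small-animal retinal imaging, together with a
synthetic retina phantom that makes every stage testable against ground
truth. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate about real data.

## The acquisition model

An SD-OCTA volume is a raster of repeated B-scans: `n_alines_per_bscan`
A-lines along the fast axis (default 500), `n_positions` slow-axis positions
(default 400), and `n_repeats` frames per position (default 5), so a default
volume holds 2000 cross-sectional frames. The spectrometer samples each
A-line with `n_spectral` pixels (default 2048), reconstructed into
`n_spectral / 2` depth bins. Defaults mirror a high-resolution rodent
protocol with roughly 2 um axial and 5 um lateral pixels.

## The retina phantom

The phantom renders a layered axial reflectivity profile — GCL, IPL, INL,
OPL, ONL, a photoreceptor debris layer, and the RPE — shifted per column by
a smooth surface topography, with one vessel tree per plexus: superficial
(in the GCL), intermediate (IPL), and deep (OPL). Vessel trees are grown as
branching random walks whose segments meet only at their end nodes, so
endpoint and junction ground truth is a node-degree computation, and the
en-face rasterization provides exact per-plexus vessel masks, window
densities, and lumen voxel lists.

Layer reflectivities are free parameters of the phantom (tissue-mimicking
values in `[0, 1]`). The defaults are chosen so that the three reference
interfaces a gradient-based segmentation must find — vitreous/GCL, the
bright-to-dark IPL/INL junction, and the debris/RPE step — are the dominant
axial gradients, with the RPE the brightest layer; the debris layer is kept
close to the ONL in reflectivity so that it does not compete with the RPE
edge.

**Speckle.** Every voxel is a sum of sub-resolution random-phase
scatterers. The default draws the many-scatterer limit directly (circular
complex Gaussian with variance equal to the local reflectivity); a
finite-scatterer phasor sum (`speckle_model = "phasor"`,
`scatterers_per_voxel`) is available and behaves identically in all
contrast tests. Static tissue keeps its speckle realization across repeats
*exactly* — inter-repeat decorrelation of static tissue is zero by
construction.

**Flow.** A fraction `flow_decorrelation` (per plexus, default 1) of each
lumen voxel's scatterer content is re-randomized between repeats. This is
the simplest mechanism that produces complex-difference contrast, and it
gives a clean monotone knob: contrast at 0 is exactly zero, and rises
monotonically to full decorrelation. The inter-repeat time spacing of real
systems is not modelled; decorrelation is phenomenological, not
velocity-calibrated.

**Noise.** Independent complex Gaussian noise (`noise_floor` SD per
component, default 0.02) is added to every voxel of every repeat.

**Degeneration.** A `degeneration_schedule` drives three processes per
timepoint: ONL thinning (non-increasing scale), deep-plexus pruning
(non-decreasing fraction of removed segment length), and fragmentation
(Poisson breaks per 100 px of surviving vessel, each removing a 3 px gap).
The superficial and intermediate plexuses never change. The default
schedule spans eight sessions at ages 3-12 weeks with pruning rising from 0
to 0.7, fragmentation from 0 to 5 breaks per 100 px, and ONL thickness
falling to 15% — emulating the known time course of photoreceptor
degeneration in the RCS rat, where the deep capillary plexus is complete by
week 4 and then prunes and fragments while the superficial plexus is
stable. A control schedule (`control_degeneration_schedule()`) holds
everything constant.

Pruning order and break positions are drawn from an *eye-level* seed with a
nested construction (a fixed removal permutation; break candidates from a
maximal-rate Poisson process thinned by uniform marks). Consequently, for a
fixed eye the vessel loss at a later timepoint is a superset of the loss at
an earlier one, and the rendered deep vessel density is non-increasing
along any monotone schedule for every seed — not merely in expectation.
Speckle and noise realizations use per-(subject, eye, timepoint) child
seeds (`child_seed()`), so each session remains independently reproducible.

## Reconstruction

Spectral fringes are synthesized (for testing) on a wavelength-uniform
spectrometer calibration — the usual source of non-uniform wavenumber
sampling — and reconstructed by cubic-spline resampling to a uniform
wavenumber grid followed by a per-A-line FFT with mean (DC) subtraction and
positive-frequency truncation. Cubic splines are standard SD-OCT practice;
their amplitude error grows as roughly the fourth power of the fringe
frequency relative to Nyquist, which is negligible (well under 1%) at
realistic retinal depths on a 2048-pixel spectrometer but visible near
Nyquist. Dispersion compensation is deliberately absent. The removed DC bin
means a reflector at depth bin 0 is unrecoverable; the phantom never places
tissue there.

Structural images are amplitude decibels (`20 log10(|c| + 1e-12)`) averaged
over repeats. Because overall signal strength drifts between B-scans on
real systems, each frame is affinely remapped so its 1st/99th percentiles
land on a common reference range before OCTA-related segmentation; the map
is logged per frame and the operation is idempotent. Acquisition
protocols typically say only that frames should share a comparable dynamic
range; percentile matching is this package's concrete interpretation of
that requirement. Image quality is scored as the 99th-percentile tissue
signal minus the median of the top ten (tissue-free) depth rows, in dB,
with a configurable 15 dB pass threshold — quality-exclusion rules are
rarely stated precisely, so the score is likewise our operationalization.

## Angiography

Flow contrast is the voxelwise mean magnitude of the complex difference
between *sequential* repeats (4 pairs at the default protocol). Magnitude
of the complex difference — not intensity difference — is used, and the
pair set is sequential rather than all-pairs. A per-A-line bulk phase
alignment (multiplying each later frame by the unit phase of its inner
product with the first) is on by default, since real interferometers
jitter in bulk phase; disabling it reproduces the strictly literal
pipeline. No thresholding happens at this stage.

## Segmentation

The three reference surfaces are found per B-scan as minimum-cost depth
paths over axial-gradient evidence (dynamic programming with a
`smoothness` penalty of 0.5 dB per pixel of inter-A-line jump, maximum
jump 3):

1. the retinal surface, on the dark-to-bright gradient channel (the
   vitreous entry is by far the strongest edge);
2. the RPE: first the RPE *body* as the brightest-band path at least
   `min_retina_px` (30) below the surface, then the RPE surface as the
   strongest dark-to-bright gradient within a `[-6, +2]` px window around
   the body — searching the body first prevents the INL/OPL interface from
   capturing the path in thinned retinas;
3. the IPL/INL junction, on the bright-to-dark channel, restricted to the
   upper 55% of the surface-to-RPE span (which excludes the OPL/ONL edge).

Evidence is pre-smoothed anisotropically: axial sigma 1.5 px, lateral
sigma 3 px, and slow-axis sigma 2.5 px. The slow-axis smoothing matters
most: static speckle is *not* reduced by repeat averaging (the pattern is
frozen), but it decorrelates between B-scan positions, so averaging across
neighbouring positions suppresses the dominant noise source while the
surfaces vary slowly. Blur kernels are truncated and renormalized at the
field edges (replication padding would flatten tilted surfaces there; odd
reflection would amplify speckle). Each DP path is then snapped to the
local evidence maximum within 2 px (the path tracks robustly, the snap
localizes without the quantization lag DP exhibits on flat-peaked
evidence), refined to sub-pixel by parabolic interpolation (+0.5 px to
convert the gradient vertex, centered between the two voxels of a step, to
the first voxel of the new layer), and median-filtered 5x5 across the
en-face plane. The ordering surface < junction < RPE is enforced as a hard
constraint and re-validated by the container class.

Accuracy on noiseless phantoms is speckle-limited: the vitreous/GCL edge is
recovered to about 0.02 px worst-case, while the weaker interior edges
(IPL/INL at -4.4 dB, debris/RPE) reach about 0.5 px RMS with occasional
~1-1.5 px columns — the localization floor of a few-dB edge under fully
developed static speckle at this smoothing scale.

**Slab masks.** The superficial slab spans `[surface, surface +
widen_px)`; the deep slab spans `widen_px` bins symmetric (shallow-resolved)
about `junction + shift_px`. `widen_px` defaults to 15 with 10-20
recommended. The deep shift is tuned per dataset on real systems; the
pipeline's simulation configs derive it from the phantom geometry
(`geometry_deep_shift()`: INL thickness plus half the OPL, 21 bins at 2 um
pixels), and an OCTA-driven automatic mode (`shift_px = "auto"`, centering
the slab on the depth of maximal mean OCTA between junction and RPE) is
provided as a clearly-labelled extension. Slabs clip at the depth limits
with the clipped columns logged.

## Projection and quantification

OCTA slabs collapse to en-face maps by maximum intensity projection;
structural volumes use mean projection (in-mask voxels only, when a mask is
given). Binarization is global Otsu (256 bins) by default with a
fixed-threshold override; a constant map yields all-background with a
warning rather than an error.

Vessel area density tiles the binary map with non-overlapping windows
(default 20x20 px) anchored at the image origin; partial edge windows are
dropped and logged, which makes the conservation identity exact: window
densities times the window area sum to the white-pixel count of the tiled
region.

Skeleton metrics thin the map to a 1-px 8-connected skeleton (Zhang-Suen;
written in-package because no installed image library provides 2-D
thinning). Endpoints are skeleton pixels with exactly one 8-neighbour;
branch points are pixels with three or more neighbours, merged into
junction clusters by 8-connectivity so thick junctions are not
double-counted; total length is the skeleton pixel count (a
diagonal-weighted variant is available but not default); and the number of
disconnected skeleton pieces is reported alongside. The piece count is the
"number of vessel slabs" of the degeneration literature: under
pruning-plus-fragmentation, junction counts can only fall (breaks never
create junctions) while endpoints and pieces rise — so the fragmentation
time course is carried by endpoints and pieces, with the junction count
reported for completeness. Zhang-Suen erodes the ends of thick bars by a
few pixels; length oracles therefore allow ~3 px of end effects.

## Longitudinal statistics

The time-course analysis treats each eye as a unit by default
(`average_eyes = TRUE` averages eyes within a rat; the nesting choice is a
flag, not a commitment). Three procedures mirror the standard longitudinal
treatment:

* `rm_anova_gg()` — one-way repeated-measures ANOVA (F from `aov` with a
  unit error stratum) with the Greenhouse-Geisser epsilon estimated from
  the double-centered sample covariance of the repeated measures; both the
  uncorrected and the GG-corrected p are reported, and the implementation
  agrees with `car::Anova` to numerical precision. Two caveats are worth
  knowing: epsilon-hat is strongly biased downward when the unit count is
  not large relative to the number of timepoints (with 6 units and 8
  timepoints the GG-corrected test rejects a true null well below the
  nominal 5%, about 0.5% in simulation — conservative, never inflated),
  and the textbook inequality "GG p is at least the uncorrected p" holds in
  the rejection region but can genuinely invert when F < 1.
* `tukey_posthoc()` — all pairwise timepoint contrasts with studentized-
  range adjustment, using the classical repeated-measures error term (the
  unit-by-timepoint interaction mean square), starred at 0.05 / 0.01 /
  0.001.
* `linear_trend()` — ordinary least squares of a metric on age in weeks,
  pooling eyes. With a balanced design, per-eye intercept differences are
  orthogonal to age, so eye-to-eye variation inflates the residual (making
  the test conservative) without biasing the slope.

Type-I calibration is checked by simulation: with subject intercepts and
no timepoint effect, the uncorrected RM-ANOVA rejects at the nominal rate
(it is exact under sphericity) and the pooled OLS trend rejects at ~5%.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script simulations are sized for a single
CPU: unit tests use 48x32 lateral fields with 192 depth bins; the
longitudinal acceptance cohort runs the full design of 6 subjects x 2 eyes
x 8 timepoints at 128 x 128 x 256 voxels with 5 repeats in both the
acceptance script and the test suite, and the superficial-stability
replicate sweep uses 20 cohorts of 3 subjects at 32 x 32. The round-trip fidelity checks use the full 2048-pixel
spectrometer. These sizes were chosen as the smallest at which the deep
plexus is a resolved capillary mesh (a few hundred to ~1500 px of vessel
per eye) rather than a handful of segments; below that, eye-to-eye
variability dominates the trend statistics.

## What passing tests do and do not show

The phantom emulates the features the pipeline's correctness depends on:
layered reflectivity with realistic edge contrasts, fully developed
speckle that is static in tissue and decorrelated in lumens, surface
topography, three plexuses at distinct depths, and a programmed
degeneration time course with exact ground truth. It deliberately omits:
eye motion and bulk-motion artifacts beyond per-A-line phase jitter,
sensitivity roll-off and dispersion, projection ("tail") artifacts of
superficial vessels onto deeper slabs, vessel-diameter changes,
choroidal neovascular tufts, and session-to-session variance sources
(focus, alignment, opacity). Two consequences deserve emphasis: measured
superficial metrics are essentially noiseless within an eye here, which
real repeat-session data never are; and the absence of projection
artifacts means deep-plexus densities are cleaner than in vivo, where
superficial shadows inflate them. Passing the suite therefore shows the
computation is correct and the statistical behaviour is as designed — not
that the pipeline is robust to every artifact of live imaging.
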
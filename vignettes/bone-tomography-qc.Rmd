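---
title: "Methods: image quality and specimen characterization for bone tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image quality and specimen characterization for bone tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonetomoqc)
```

## Scope and approach

`bonetomoqc` quantifies image quality and specimen state in neutron and
X-ray tomography of bone: edge sharpness from edge-spread-function (ESF)
fits, contrast-to-noise ratios (CNR) between material phases, grey-value
phase histograms with peak detection, bone volume fraction (BV/TV)
morphometry, stress–strain analysis of trabecular plug compression tests,
and drying/rehydration weight kinetics. Archived beamline volumes are large
and instrument-bound, so every stage of the pipeline is driven and validated
by a synthetic phantom generator with known ground truth: a phantom declares
phases (geometry + mean grey value), a Gaussian point-spread blur, and
additive Gaussian noise, and the generator returns both the simulated
reconstruction and the pre-blur label map. All tests and the acceptance
script run on phantoms; nothing requires external data.

Reconstruction itself (filtered back-projection), manual volume alignment,
and the downstream linear mixed-effects model are out of scope: the package
ends at a tidy export table (response, log response, BV/TV, (BV/TV)²,
hydration group, campaign) for external statistics software.

## Edge sharpness

The intensity profile across a sharp material boundary (the ESF) is the
integral of the line spread function (LSF). For a Gaussian LSF the ESF is a
Gaussian CDF,

$$\Phi(x;\mu,\sigma) = \tfrac12\left(1 + \mathrm{erf}\!\left(\tfrac{x-\mu}{\sigma\sqrt2}\right)\right),$$

so `fit_edge()` fits $a + (b-a)\,\Phi(x;\mu,\sigma)$ by
Levenberg–Marquardt least squares with an analytic Jacobian (fitting the
CDF rather than the differentiated profile avoids amplifying noise). Edge
sharpness is reported as $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma \approx
2.3548\,\sigma$ — lower is sharper — and goodness of fit as NRMSE. Choices
the ESF literature leaves open, fixed here:

* **Profile conditioning.** Profiles are transversely averaged at
  extraction (default width 11 px — an odd, centred rendering of the
  common "average 10 pixels" practice), Savitzky–Golay smoothed (span 9,
  polynomial order 3 — order unstated in common protocols; order 3
  preserves the sigmoid inflection) and cubic-spline upsampled 4× for
  sub-pixel localization. Conditioning is a protocol choice with a known
  cost: although the order-3 kernel preserves second moments, least-squares
  CDF fits to span-9-smoothed profiles overestimate $\sigma$ for edges
  sharper than about 2 px at unit-pixel sampling (by ~50 % at
  $\sigma = 1$ px, ~8 % at 2 px, negligible beyond 3 px), because the
  kernel's negative side lobes reshape the edge flanks. Conditioned FWHM
  values are therefore comparable *within* a fixed conditioning protocol;
  parameter-recovery validation fits raw profiles, and raw fits remain
  available for sensitivity checks on real data.
* **NRMSE normalizer.** RMSE divided by the observed range inside the fit
  window, making fit quality comparable across grey scales.
* **Windows.** Fit windows are explicit configuration;
  `propose_edge_windows()` suggests candidates from gradient-magnitude
  peaks but proposals are meant to be confirmed, not applied blindly.
* **Initialisation.** $\mu$ at the largest absolute first difference,
  $\sigma$ = window span/10, plateaus from the window-end means; $\sigma$
  is bounded positive, $\mu$ to the window. A fit that pushes $\sigma$
  into a bound is flagged unconverged rather than reported.
* **Units.** FWHM is reported in the profile's abscissa units (pixels or
  µm, always recorded); published FWHM tables without units are not
  reproduced numerically.

On noiseless generated edges the fitted $\sigma$ matches the generator to
better than $10^{-4}$ relative; at 5 % contrast noise the median relative
error over 50 seeded replicates stays below 10 % for
$\sigma \in \{0.5, 1, 2, 4\}$ px (quarter-pixel sampling over ±20 px,
emulating transversely averaged, spline-resampled profiles).

## Contrast-to-noise ratio

$$\mathrm{CNR} = \frac{|\overline{S_1} - \overline{S_2}|}{\sqrt{s_1^2 + s_2^2}}$$

over declared rectangular ROIs in named representative slices, with sample
$(n-1)$ SDs and a 30-voxel ROI floor for stable SD estimates. Per-slice
values and their mean ± SD over the (typically three) slices are both
reported, since either aggregation convention appears in practice. The
noise level of a volume is estimated as the SD of a background-only ROI.
Grey values near the bit-depth limits are clipped during generation, which
truncates the noise distribution; the phantom configurations used for
quantitative CNR checks keep all phases several SDs away from the limits,
and the tibia configurations (whose background sits 1.8–3.4 SD above zero)
are used only for ordering checks.

## Phase histograms

Histograms use 250 bins over the masked min–max range (a fixed-range mode
exists for cross-specimen overlays), excluding exterior background. The
background-exclusion procedure is a two-pass flood fill: a provisional
threshold at the border-shell median + 6·1.4826·MAD, then a final threshold
at the midpoint between the background level and the 10 % quantile of the
provisional interior. The midpoint places the mask boundary at the 50 %
point of the darkest specimen–background transition, which is unbiased
under symmetric blur; a plain robust-SD threshold inflates the mask by the
width of the blurred transition band, and a global Otsu threshold (offered
as an alternative) can land between interior phases of a trimodal volume
and let the flood fill leak into the specimen. Interior voids are never
reached by the border flood fill, so they stay inside the mask regardless
of their grey value.

Peaks are local maxima of lightly smoothed counts (5-bin moving average,
for bin-level location stability) with prominence ≥ 5 % of the modal count,
labelled void < bone < marrow in grey order (the neutron-image ordering;
configurable where it inverts). With anchor grey values the labels map to
the nearest detected peak within 10 % of the histogram range, so a missing
phase is reported absent; without anchors, missing peaks drop the darkest
labels first, since voids are the phase that vanishes when filled. Two
labels on one peak, or adjacent labelled peaks with a valley-to-peak
separation score $1 - \min(\text{valley})/\min(\text{peak heights})$ below
0.2, are flagged merged. Histograms are computed per volume (per-slice
histograms would only add estimation noise at these specimen sizes).

## BV/TV morphometry

Volumes are median-filtered (radius 2, cubic 5×5×5 structuring element —
the cube matches common plugin behaviour and is cheap; the element is
recorded in the output), thresholded with inclusive instrument presets
(`"next"` = 30375–65535, `"4dlab"` = 53500–65535 on 16-bit volumes), and
BV/TV is bone ∩ specimen over specimen voxels. Total volume is the specimen
mask, not the image, because plugs do not fill the field of view. The
morphometry phantom uses a three-axis rod lattice with 9-voxel rod radius
(~240 µm at 13.5 µm/voxel, i.e. thick bovine-femur trabeculae): at that
radius the median filter's curvature erosion (≈ σ_w²/2r ≈ 0.1 px of
boundary shift) costs well under 0.01 of BV/TV, and the recovered fraction
stays within about 0.01 of the recorded lattice ground truth across BV/TV
0.1–0.4 at 2 % contrast noise — comfortably inside the ±0.02 recovery
target. The lattice solves its base rod radius by bisection against the
voxelized achieved fraction, so the recorded ground truth is exact with
respect to the label map.

## Compression mechanics

Force–displacement records are normalized to stress–strain using the plug
geometry (Ø 6 mm × 10 mm): samples before the 15 N preload are discarded
and displacement is re-zeroed at the linearly interpolated preload
crossing (interpolation removes sampling-grid bias). Failure is the first
clear peak — the first local maximum whose drop on both sides exceeds 5 %
of the global maximum stress; monotone records are flagged and excluded
rather than assigned a failure point. Peak detection runs on a 5-sample
moving average so single-sample noise spikes on densely sampled records do
not masquerade as failure. The elastic modulus is the maximum least-squares
slope over sliding windows of 0.005 strain restricted to pre-failure data
(max-slope automatically skips a concave-up toe); to avoid the selection
bias of maximizing over many overlapping noisy windows, the window is
selected on a smoothed copy of the stress (span ≈ one window of samples)
and the reported slope is then estimated from the raw data in that window.
Toughness is the trapezoidal integral of stress over strain to failure
(MPa × strain ≡ MJ/m³).

The curve generator rises linearly to 80 % of the peak stress, rounds over
a quadratic cap, then softens linearly by a configurable fraction of the
peak; with zero softening the curve is non-decreasing and exercises the
exclusion rule. Modulus and strength scale with (BV/TV)² — the standard
power-law behaviour of trabecular bone, consistent with a quadratic BV/TV
term in downstream models. The displacement rate (1 mm/s) is carried as
metadata only; no rate dependence is modelled.

## Hydration kinetics

Weight change is $C = (w_{\text{after}} - w_{\text{initial}})/
w_{\text{initial}} \times 100$. The fraction of lost weight regained at
rehydration time $t$ is $100\,(w(t) - w_{\text{dry}})/(w_{\text{initial}}
- w_{\text{dry}})$ with linear interpolation between discrete weighings
(logs hold 3-hourly weighings). Cohort summaries report mean ± sample SD
and list specimens missing a stage instead of failing. The generator uses
single-exponential approach kinetics with defaults fixed to the study
conditions: 10 % asymptotic drying loss with 97 % of the loss in the first
3 h, and a rehydration rate that regains 48.9 % of the lost weight at 3 h.
A single exponential that matches the 3 h rehydration point overshoots the
reported 48 h recovery (it gives ~99 % rather than ~82 %); real rehydration
is at least bi-exponential (free vs bound water), which the generator
deliberately does not model, so only the 3 h statistic is treated as
quantitative.

## What the phantoms do and do not show

Phantoms live in reconstructed-image space: they emulate phase contrast,
point-spread blur (applied in physical units, mirror boundary handling so
no dark rim biases edge fits) and additive Gaussian noise — consistent
with reporting image noise as a background SD — but not neutron transport,
projection acquisition, reconstruction artifacts, beam hardening, or
anatomically realistic trabecular microarchitecture (the rod lattice is
analytically controllable, not biological). Per-phase grey values are not
published quantities; the hydration-state configurations fix them once so
that the qualitative state-to-state behaviour is reproduced — the dry
state's bone/marrow peak merging (means within one noise-FWHM), the soaked
state's missing void peak, void prevalence dry > rehydrated > soaked, and
the decrease of cortex–background CNR with increasing rehydration (lowest
liquid–cortex contrast in the free-liquid state). Tests against these
configurations therefore assert orderings and structural features, never
absolute grey-dependent values. Passing them shows the estimators are
correct on data satisfying their model assumptions; robustness to
reconstruction artifacts or real microarchitecture is not claimed.

Problem sizes were chosen so the whole suite runs comfortably on a laptop:
64³ plug phantoms for histograms, 144³ for morphometry (a few lattice
cells at every target fraction), 30-curve mechanical cohorts, 10-specimen
weight cohorts, 50 replicates per noise condition for edge fits.

## Numerical choices and degenerate inputs

* CNR with two zero SDs: 0 for equal means, flagged infinite otherwise;
  ROI floors reject unstable small samples.
* Zero observed range makes NRMSE undefined and is an error, as is a
  weight log with no drying loss in `fraction_regained()`.
* `separation_score()` is clamped to [0, 1] and NA for coincident peaks.
* Overlapping phantom primitives resolve by declaration order (later
  wins); a voxel claimed by no phase is a configuration error.
* Histogram end bins absorb out-of-range voxels in fixed-range mode, so
  count conservation holds exactly in every mode.
* 16-bit TIFF round-trips quantize grey values to at most one grey level
  of error; volumes carry voxel size and bit depth in a JSON sidecar.
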
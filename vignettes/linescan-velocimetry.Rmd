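---
title: "Spatial-frequency velocimetry and transit-time mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-frequency velocimetry and transit-time mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(microvel)
```

# The measurement problem

Two-photon line scanning along the axis of a single capillary produces a
space-time image (kymograph): one axis is position along the vessel
(sampling interval $\Delta x$, 0.06-0.20 µm/pixel), the other is time
($\Delta t$, 0.25-1 ms/pixel). The blood plasma is fluorescently labelled;
red blood cells are not, so each moving RBC leaves a slanted dark streak.
A cell moving at speed $v$ traces the pixel-space line

$$ i = i_0 + m\,j, \qquad m = \frac{v\,\Delta t}{\Delta x}
   \ \text{rows/column}, $$

and the population-mean slope of the streaks encodes the mean RBC speed.
Slope-fitting individual streaks fails at low contrast-to-noise; the
spectral approach below uses all streaks at once and needs no cell
detection or vessel cropping.

# The spectral estimator

`estimate_speed()` composes four steps, each exposed as its own function.

**Power spectrum** (`compute_power_spectrum`). The image mean is
subtracted and the squared modulus of the 2D DFT computed, with the
zero-frequency bin shifted to the array center. A family of parallel
streaks concentrates spectral energy on a central line perpendicular (in
frequency coordinates) to the streak direction. Mean subtraction zeroes
the DC bin exactly; without it, and without excluding the $r = 0$ sample
from the radial sum, the DC term dominates every direction equally and
axis-aligned leakage can create spurious maxima at $\theta = 0$ or
$\pm\pi/2$.

**Polar summation** (`polar_sum`). The power $F(r, \theta)$ is sampled by
bilinear interpolation along rays from the center and summed:

$$ g(\theta) = \sum_{r=1}^{R} F(r, \theta), \qquad
   \theta \in [-\tfrac{\pi}{2}, \tfrac{\pi}{2}),\ \text{step } \pi/180 .$$

The grid covers a half circle only because the spectrum of a real image
is point-symmetric; the suite verifies $g$ over $[\pi/2, 3\pi/2)$ matches
by brute force. $R$ defaults to $\lfloor \min(\text{dim})/2 \rfloor - 1$,
the largest radius fully inside the array (255 for 512×512), and the sum
is unweighted over $r$ — no per-angle normalisation — matching the
method's published form. Samples falling outside the array contribute
zero.

**Peak detection** (`find_peak_angle`). The grid angle maximising $g$;
ties break deterministically to the smallest index. An identically zero
profile (constant image) raises a `microvel_no_signal` error rather than
returning a silent 0. The peak-to-median ratio of $g$ is attached as a
prominence diagnostic.

**Speed conversion** (`speed_from_angle`). With $\theta$ the angle
between the spectral line and the temporal-frequency axis,

$$ v = \frac{\Delta x}{\Delta t}\,\lvert\cot\theta\rvert , $$

and µm/ms equals mm/s. $\theta = \pm\pi/2$ means stationary streaks
($v = 0$); $\theta = 0$ means streaks parallel to the space axis, i.e.
unbounded speed, and is rejected as out of measurable range. The
rendered algebra is pinned by construction: the generator's exact
ground-truth angle, fed to `speed_from_angle()`, returns the programmed
speed to machine precision, and `arccot(5.5)` at
$\Delta x = 0.20,\ \Delta t = 1$ gives the representative 1.1 mm/s.

**Aspect correction for non-square windows.** The angular grid lives in
array-index space, where one index step is $1/N_s$ cycles/pixel along
the space axis but $1/N_t$ along the time axis. For square images the
two coincide; for short temporal windows they do not, so the peak angle
is converted to physical frequency units,
$\theta_{\text{phys}} = \operatorname{atan2}(\sin\theta/N_s,
\cos\theta/N_t)$, before the cotangent. Without this, windowed estimates
would depend on the window length itself.

**Design choices.** No apodization by default (an optional Hann flag
exists because rectangular-window leakage can dominate for very short
windows). Speed is reported as a magnitude with the flow direction as a
separate sign flag. Temporal extents under 8 pixels are rejected; 8-31
pixels warn, reflecting the window study below.

# Comparator estimators

Both comparators work in image space, where the streak angle from the
time axis is $\varphi = \arctan m$ and $v = (\Delta x/\Delta t)
\lvert\tan\varphi\rvert$; they are deliberately minimal, behaviourally
faithful reimplementations used for benchmarking, not reference copies
of their original publications.

*Radon* (`radon_speed`): the mean-subtracted image is projected over a
$\pi/180$ grid of directions (rotation with bilinear interpolation and
zero fill, then column sums); the projection variance is maximal when
the integration direction runs along the streaks.

*Rotation/SVD* (`svd_speed`): over the same grid of candidate angles the
image is rotated and its singular-value spectrum computed; when streaks
are axis-aligned the image is nearly separable, so the separability
$\sigma_1/\sum_i \sigma_i$ peaks. Separability is invariant under
quarter turns — a separable image stays separable rotated by 90° — so
the winning angle is ambiguous between $\varphi$ and
$\varphi \pm \pi/2$; the implementation disambiguates with a single
projection-variance comparison of the two candidates. This ambiguity is
inherent to a pure rotation-separability search and is one reason the
projection and spectral methods are more robust in practice.

# The synthetic line-scan generator

`make_linescan()` draws streak intercepts as a Poisson process (expected
linear density 80 cells/mm, a typical capillary RBC spacing) over a
range wide enough that streaks entering or leaving the window are
included and clipped, as in a real acquisition. Each streak has a
Gaussian cross-profile of 4 µm FWHM (RBC scale; the target vessels are
sub-6 µm capillaries) and dips the unit plasma background by the
contrast (default 0.5); overlapping dips saturate rather than sum past
full darkness. Additive Gaussian noise (default SD 0.05 of background)
models detector noise; Poisson shot noise is available behind a flag.
The generator returns the exact streak slope in both image and spectral
conventions, so every estimator is testable against construction-time
truth, and identical parameters plus seed give bit-identical images.

With `nonvascular_fraction > 0` the bottom rows become uncorrelated
Gaussian noise (SD 0.3) centred slightly below the vessel-band mean
(deficit 0.08), emulating an uncropped field of view whose non-vascular
tissue autofluoresces a little dimmer than labelled plasma. These two
values are not published anywhere and were fixed once from pilot
simulations of the uncropped-field experiment; they matter because a
*static* brightness offset between the bands places energy exactly on
the spatial-frequency axis (for the spectral method) and in the
zero-angle projection (for Radon). In this regime the spectral profile
keeps a unique peak at the streak angle while the Radon variance
profile's peak barely exceeds the static component — its peak-to-axis
margin collapses from roughly 65 (cropped, vessel rows only) to about
1.3 — which is the behaviour the robustness suite asserts (with the
"dominant peak" margin fixed at 1.25). At substantially larger offsets
(≳ 0.2 of background) the static term overwhelms both methods; a
high-pass `bandpass_filter()` removes it, which is the recommended
pre-processing for fields with strong static structure.

What the generator does **not** model: optical point-spread, depth
scattering, pulsatile or fluctuating flow, hematocrit-dependent streak
statistics, scanner distortions. Passing tests therefore demonstrate
correctness of the estimators under the stated streak model, not
performance on any particular microscope.

# Window-size behaviour

Estimates from one long acquisition can be windowed
(`estimate_speed(..., window_pixels = W)`). The suite quantifies the
dependence at 1 mm/s with default noise: the fraction of estimates
within 15% of truth stays above ~0.9 for $W \ge 32$ pixels and collapses
for shorter windows (near zero at $W = 8$), for the spectral and Radon
paths alike — hence the 32-pixel warning threshold. The mechanism is
resolution, not noise alone: at $W = 16$ the radial sum has only
$R = 7$ usable radii.

# The AVTT pipeline

A fluorescent bolus is imaged at the cortical surface (e.g. 14.2
frames/s, 512×512). Per pixel, the pipeline computes:

1. **Denoising** (`denoise_stack`): per-frame 2D median filter, default
   3×3 (kernel width unstated in the source protocol; 3×3 is the
   smallest that removes single-pixel photomultiplier shot noise;
   spatial only — no temporal mixing that would bias arrival times).
2. **Baseline** (`baseline_stats`): mean and sample SD (n−1; the
   denominator is a documented choice) over the pre-injection frames.
3. **Appearance time** (`appearance_time`): the earliest post-baseline
   frame whose intensity *and* the `persistence = 5` subsequent frames
   all *strictly* exceed mean + `k_sd = 2`·SD — a 6-frame run, read
   literally from the stated rule; runs extending past the last frame
   do not qualify, and pixels with no qualifying frame are excluded
   rather than assigned a default. Raising `k_sd` can only invalidate
   pixels or delay appearances (tested as a monotonicity property).
   Time is measured from the first post-baseline frame; only
   differences enter the AVTT, so the origin cancels.
4. **Segments** (`segment_stats`, `compute_avtt`): appearance-time
   mean/SD/median and area fraction per mask, then AVTT = venous −
   arterial (mean-based and median-based). Segmentation is mask-driven
   — vessels are traced from the spatial continuity of appearance time,
   historically by hand; `segment_assist()` optionally automates that
   tracing by region growing with a tolerance on the deviation from the
   region's running-mean appearance time. It presumes the continuity it
   automates: it recovers segments whose internal arrival spread is
   comparable to the tolerance, not segments with large uncorrelated
   per-pixel scatter.

# The synthetic bolus generator

`make_bolus_stack()` assigns each vessel pixel an arrival time drawn
from its segment's truncated normal (truncated at zero; only mean ± SD
summaries are available to emulate, and negative arrivals are
unphysical). Defaults follow the representative animal: arterial
0.29 ± 0.28 s, venous 1.43 ± 0.48 s, 14.2 frames/s, 10 baseline frames,
70 frames, 96×96 with ≥2000-pixel arterial (left quarter) and venous
(right 40%) bands approximating the ~1:2 arterial:venous area ratio
seen on the cortical surface.

The wash-in is a sharp-onset saturating exponential,
$\text{baseline} + A\,(1 - e^{-(t - t_a)/\tau})$ for $t \ge t_a$
(default $\tau$ = 0.1 s; a step when $\tau = 0$), rather than a
logistic sigmoid: a logistic's infinite left tail leaks dye into the
pre-injection baseline for arterial pixels arriving near zero, which
would corrupt the very statistics the threshold is built from, and it
has no well-defined onset to serve as ground truth.

Two systematic offsets are worth stating because the pipeline's output
is *not* expected to equal the difference of the nominal means exactly.
First, truncation at zero raises the arterial mean from 0.29 to
0.367 s, so the generator's true segment-mean difference is 1.065 s
rather than 1.14 s. Second, frame quantization and the finite rise time
delay each detection by up to one frame plus a small threshold-crossing
lag — but these biases are common to both segments and cancel in the
difference. The pipeline accordingly recovers the generator's true
difference to within ~0.01 s (about 1.04-1.08 s across seeds), which
also sits inside the ±0.1 s band around the nominal 1.14 s used in the
recovery checks.

# Numerical choices and degenerate inputs

* Bilinear interpolation everywhere a non-grid sample is needed (polar
  transform, rotations), with out-of-array samples contributing zero.
* Argmax ties break to the smallest index for determinism.
* Angular bins are registered at $\theta_k = -\pi/2 + k\,\pi/180$.
* Constant images, all-zero profiles and flat projections raise typed
  `microvel_no_signal` errors; empty segments raise
  `microvel_empty_segment`.
* All randomness flows through a single seed per scene; scenes are
  reproducible bit for bit.
* Problem sizes in the test suite: 512×512 images where the
  representative acquisition is being emulated, 96-256 pixel scenes for
  comparator and property studies, 96×96×70 bolus stacks (these keep
  every property measurable at desk scale while the generators remain
  size-agnostic).

# Known limitations

* One orientation per window: fields containing multiple flow patterns
  need windowing or region selection before estimation.
* Angular quantization bounds accuracy near the axes: a half-bin of
  $\pi/360$ produces a relative speed error of roughly
  $\Delta\theta/(\sin\theta\cos\theta)$, which exceeds 5% once
  $\theta$ is within ~10° of either axis. Fast vessels should be
  acquired with a shorter $\Delta t$ (the protocol's 0.25-1 ms/pixel
  range exists for exactly this reason).
* Angular localisation also depends on the radial extent of the
  spectral line, which scales as $N/(2\pi\sigma_{px})$ for a Gaussian
  streak cross-section of $\sigma_{px}$ pixels: wide streaks in small
  images confine the line to a few radii and the peak can wander by a
  bin or two. At the representative 512-pixel field with 4 µm streaks
  the localisation is reliably within one bin; desk-scale test scenes
  shrink the streak width together with the field to stay in the same
  regime.
* The AVTT is a relative transit measure; it does not deconvolve bolus
  dispersion and is not an absolute flow measurement.
* Wall-clock timings logged by the command-line interface are
  informational; they depend on hardware and are never asserted.
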
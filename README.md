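# microvel

Quantifies microvascular perfusion from two-photon microscopy in two
complementary ways:

* **Line-scan velocimetry.** Repeated line scanning along a capillary
  produces a space–time image in which unlabelled red blood cells (RBCs)
  moving through fluorescently labelled plasma leave slanted dark
  streaks. `microvel` estimates the mean RBC speed from the dominant
  orientation of the image's 2D power spectrum: the power is summed along
  rays from the spectral center, $g(\theta) = \sum_{r=1}^{R} F(r,\theta)$
  over $\theta \in [-\pi/2, \pi/2)$ at $\pi/180$ resolution, and the peak
  angle $\hat\theta$ (measured from the temporal-frequency axis) gives

  $$ v = \frac{\Delta x}{\Delta t}\,\bigl|\cot\hat\theta\bigr| \quad
     \text{(µm/ms} \equiv \text{mm/s)} , $$

  with $\Delta x$ (µm/pixel) and $\Delta t$ (ms/pixel) the sampling
  intervals. No cell detection, cropping, or prior information is needed,
  which makes the approach robust at low contrast-to-noise and in fields
  containing non-vascular tissue. Radon-transform and rotation/SVD
  estimators are included as comparators, plus a frequency-domain
  bandpass filter for suppressing static background.

* **Arteriovenous transit time (AVTT).** After an intravenous dye bolus,
  time-lapse imaging of the cortical surface is reduced to a per-pixel
  dye *appearance time*: the earliest frame at which the intensity and
  the five following frames all exceed the pixel's pre-injection
  baseline mean + 2 SD. The AVTT is the difference between the mean
  (or median) appearance times of the venous and arterial segments; its
  inverse tracks capillary perfusion speed.

Seeded synthetic generators (`make_linescan()`, `make_bolus_stack()`)
produce both kinds of data with exact ground truth, so every estimator
and the whole AVTT pipeline are verifiable at desk scale.

## Worked example

```r
library(microvel)

# a 512x512 line scan at the representative settings:
# dx 0.20 um/pixel, dt 1 ms/pixel, true speed 1.1 mm/s
scene <- streak_scene(speed_mm_s = 1.1, dx_um = 0.20, dt_ms = 1.0,
                      contrast = 0.5, noise_sd = 0.05, seed = 1)
sim <- make_linescan(scene)
estimate_speed(sim$image)
#> <speed_estimate> 1.134 mm/s  [fft method]
#>   theta = -0.1745 rad (-10.00 deg), prominence 50.8, window 512 px
```

The estimate differs from the programmed 1.1 mm/s only by the $\pi/180$
angular quantization (the peak landed on the −10° bin; the true angle is
−10.3°). The prominence is the peak-to-median ratio of $g(\theta)$ — a
value this large means a single, unambiguous orientation.

```r
# bolus time-lapse at 14.2 frames/s with arterial arrivals 0.29+/-0.28 s
# and venous arrivals 1.43+/-0.48 s (truncated at 0)
bsim <- make_bolus_stack(bolus_scene(seed = 1))
map  <- appearance_time(denoise_stack(bsim$stack, 3), k_sd = 2,
                        persistence = 5)
art  <- segment_stats(map, bsim$truth$arterial_mask, "arterial")
ven  <- segment_stats(map, bsim$truth$venous_mask, "venous")
compute_avtt(art, ven)
#> <avtt_result> AVTT = 1.07 s (mean), 1.13 s (median)
#> <segment_stats> arterial: 2304 px (25% of image), 0.317 +/- 0.12 s (median 0.282)
#> <segment_stats> venous: 3648 px (40% of image), 1.39 +/- 0.223 s (median 1.41)
```

Truncating the arterial arrival distribution at zero raises its true
mean to 0.37 s, so the generator's true venous−arterial difference is
about 1.07 s; the pipeline recovers it to ~0.01 s (detection biases are
common to both segments and cancel in the difference). See the methods
vignette (`vignettes/linescan-velocimetry.Rmd`) for the model details.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/microvel.R speed --input img.tif --dx-um 0.2 --dt-ms 1.0 --method fft
Rscript inst/cli/microvel.R avtt --input stack.tif --frame-rate-hz 14.2 \
    --baseline-frames 10 --arterial-mask a.txt --venous-mask v.txt
Rscript inst/cli/microvel.R simulate-linescan --output img.tif --seed 1 --speed 1.1
```

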
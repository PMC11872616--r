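---
title: "Measuring extraction kinetics by ROI video colorimetry"
author: "sonoKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring extraction kinetics by ROI video colorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoKinetics)
```

## The measurement model

The experiment this package quantifies is simple to film and hard to
eyeball: a colored sample (a sugar-coated candy glued into a water-filled
holder) sheds its coating slowly under water alone and very quickly once
power ultrasound is switched on. A fixed camera records the whole run at a
constant frame rate (25 fps in the reference protocol).

The analysis chain is:

1. **ROI averaging.** Each frame is an `n × m` matrix of RGB triples. A
   circular region of interest around the sample — deliberately smaller
   than the holder, to stay clear of edge reflections — is rasterized into
   a 0/1 mask, and each channel is reduced to its mean over the mask
   pixels. This is done in floating point; nothing is truncated back to 8
   bits.
2. **Normalization.** The mean RGB of the *intact* sample at time zero is
   the reference color; every later frame is expressed per channel as a
   percentage of it. At `t = 0` each channel reads 100 by construction,
   and any global illumination gain cancels exactly.
3. **Phase-wise regression.** The percentage of the candy's dominant
   channel is fitted against time by ordinary least squares separately in
   two half-open windows: the conventional (water-only) phase and the
   ultrasonic phase. Each slope is an extraction speed in %/s; their
   quotient is the enhancement ratio.

The model's assumptions are equally simple: constant frame rate (no
dropped-frame handling; timestamps are `index / fps`), a stationary sample
and camera (one ROI for the whole run), and kinetics that are adequately
linear *within* each phase window. Nothing nonlinear (first-order decay,
Peleg, …) is fitted, and no color-space conversion or white-balance
correction is applied — the measurement lives in raw RGB, which is exactly
what makes it robust to the things that cancel (global gain) and honest
about the things that do not (flicker, saturation).

## Parameters that matter

- **ROI center and radius** (pixels, 0-based, x = column / y = row, origin
  top-left). Mandatory input: in the original workflow they come from an
  interactive click, so the package takes them as explicit configuration
  and never guesses silently. `autoDetectROI()` exists as a labelled
  convenience (largest bright blob), not as part of the method. A disk
  that would cross the frame edge is rejected, not clipped — a clipped
  disk would bias the mean with background pixels. Membership is the
  closed disk `(x−cx)² + (y−cy)² ≤ r²` evaluated at integer pixel
  centers, so a radius of 0 still covers one pixel and sub-pixel centers
  are legal.
- **Phase windows** (seconds, half-open `[start, end)`). Defaults
  `[0, 25)` and `[25, 60)`: in the reference protocol water acts alone
  for the first 25 s of the one-minute recording and ultrasound for the
  remainder. The acquisition protocol also mentions a 40 s ultrasound
  interval before cropping, so `[25, 50)` is an equally defensible
  ultrasonic window; both are one `phaseWindows()` call away, and the
  window actually used is serialized into every report. Requiring the
  windows to be disjoint and ordered is a validity rule of the class.
- **Reference window** (`refWindowS`, seconds, default 1). The reference
  color is the mean over the frames with `t < refWindowS` rather than the
  single first frame: at 25 fps that averages 25 frames and suppresses
  pixel noise in the denominator of every later percentage. Set it to one
  frame interval (`1/25`) to reproduce a strict single-frame "time zero"
  — the tests do exactly that when they need bit-exact recovery, because
  averaging over a rising ramp shifts the reference by ~0.1 % and
  rescales all slopes by the same factor.
- **Guard interval** (`guardS`, seconds, default 0). Optionally excludes
  the first moments after switch-on from the ultrasonic fit, in case the
  switching transient (surface ripple, bubbles flooding the ROI) should
  not count. The default is zero because the reference analysis uses the
  whole window.
- **Sign convention.** The reported speed is the raw OLS slope, positive
  when in-ROI intensity grows (dye and white sugar spreading through the
  ROI). No absolute value is taken; published speed tables are read as
  magnitudes of this slope.

## What the synthetic generator emulates — and what it does not

`generateVideo()` renders a disk of the sample color on a near-black
background (the black-painted holder) whose in-ROI mean follows the exact
piecewise-linear ramp `100 + r₁t` (then slope `r₂` after the switch) in
percent of its time-zero value, with three optional confounders layered on
top, each modelled after something visible in real footage:

- **Pixel noise** — zero-mean Gaussian per pixel per frame, clipped to
  `[0, 255]`: a truncated-Gaussian sensor model, the simplest one
  consistent with an 8-bit camera.
- **Illumination flicker** — a global sinusoidal gain
  `1 + A·sin(2πft)`. Unlike a *constant* gain it does **not** cancel in
  the normalization, which is the point: the flicker fixture quantifies
  exactly how large the residual slope artifact is.
- **Speckle** — single-frame bright disks placed inside the ROI during
  the ultrasonic phase only, mimicking cavitation bubbles and streaming
  glints. They leave the conventional fit untouched by construction.

Frames are kept as doubles end to end; quantization to 8 bits happens only
when frames are written to PNG/MP4. That choice is what makes the
noiseless round-trip test meaningful at `1e−6` %/s — and writing a
noiseless slow ramp to PNG is correspondingly *not* faithful: with
perfectly uniform disk pixels, a ramp slower than one quantization step
per window simply disappears (the tests dither such fixtures with a small
noise sigma, which is also what a real sensor does).

What the generator does **not** model: actual cavitation physics, bubble
clouds, acoustic streaming flow fields, the dye plume's spatial structure,
motion of the sample, rolling-shutter or compression artifacts, and —
importantly — channel saturation dynamics. Real footage of a fast
extraction saturates its dominant channel mid-window and the evolution
flattens; the generator instead refuses such parameterizations with a
range warning, because its contract is exact linear ground truth. Passing
tests therefore demonstrate that the *pipeline* is unbiased and
noise-stable under controlled conditions, not that any real video is
linear.

For the three reference experiments, `candyExperimentSpec()` builds
stand-ins carrying the published intact colors and speeds: red
`[145 35 22]` at 0.15 / 8.9 %/s, green `[76 178 71]` at 0.22 / 16.5 %/s,
blue `[37 142 192]` at 0.022 / 21.7 %/s, each on its dominant channel. The
base colors are scaled down (×0.25, ×0.2, ×0.15) so the dominant channel
completes the whole ultrasonic ramp inside 8 bits — with the unscaled blue
coating, +21.7 %/s could be sustained for barely 1.5 s before hitting 255.
Since speeds are percentages of the intact color, the scaling provably
changes nothing about them (that invariance is itself under test).

## Numerical choices

- **OLS** is delegated to `stats::lm()`; the test suite holds it against
  the closed-form two-pass formulas at `1e−9` relative, on randomized
  series. A window with fewer than 2 frames is an error, as is zero time
  variance. An exactly constant response short-circuits to slope 0 — the
  QR path would return an O(1e−17) slope whose *sign* is numerical noise,
  and the enhancement ratio divides by this number. R² is reported as 1
  for an exact constant fit (total and residual sums of squares both
  zero), and clamped into `[0, 1]` against floating-point spill.
- **Enhancement ratio** is `NA` (an undefined marker, not an error) when
  the conventional slope is exactly zero.
- **Masked means** are computed by subsetting the flattened frame with the
  mask index and `colMeans`; equivalence with an explicit per-pixel loop
  is a test invariant.
- **Determinism**: the generator seeds R's RNG locally and restores the
  caller's state, so a spec is bit-reproducible regardless of surrounding
  code.
- **Frame-directory round trips** are exact for 8-bit content (values are
  re-scaled by 255 and rounded on read); MP4 round trips are lossy and are
  treated as such (`≤ 2/255` mean absolute error is the contract when a
  codec is involved).

## Study sizes used by the tests

The validation battery runs on 48×48 px frames with a disk of radius 15 px
(≈ 700 mask pixels), 25 fps, 60 s runs switching at 25 s — a miniature of
the reference geometry that keeps per-pixel statistics honest. The noisy
recovery study uses 100 seeded replicates with per-pixel noise drawn
between 1 and 2 channel units, cycling through the three candy stand-ins,
and requires both slopes within `max(0.05 %/s, 5 %)` of truth in at least
95 of them, with the enhancement ratio above 1 in every replicate whose
true ratio is at least 10.

## Known limitations

- No variable-frame-rate support; such input must be resampled upstream.
- One static ROI per run; a drifting sample violates the model silently
  (visible as a drifting baseline in the evolution plot).
- Saturated (255) pixels are included in the mean as-is; near saturation
  the percentage series flattens and the fitted "speed" underestimates the
  true rate. Inspect the R² and the evolution plot.
- Illumination flicker is only *bounded*, not removed; the flicker fixture
  quantifies the size of the artifact for a 5 % sinusoidal gain.
- MP4 support requires an external ffmpeg binary; everything else,
  including the whole test battery, runs on lossless frame directories.

## A compact end-to-end run

```{r example, eval = FALSE}
spec <- candyExperimentSpec("green", noiseSigma = 1.5, seed = 7)
video <- generateVideo(spec)
series <- extractSeries(video, circularROI(23.5, 23.5, 15))
fit <- analyzeExtraction(series, phaseWindows(c(0, 25), c(25, 60)),
                         channel = "G")
speeds(fit)
enhancementRatio(fit)
```
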
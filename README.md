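# sonoKinetics

Video colorimetry of ultrasound-assisted extraction kinetics.

## The problem

Ultrasound-assisted extraction (UAE) pulls compounds out of a matrix far
faster than solvent alone: cavitation and acoustic streaming disrupt the
material, and the change of regime is dramatic enough to watch on camera. A
classic demonstration films a sugar-coated candy fixed in a water-filled
holder: for the first ~25 s only water acts and the colored coating
dissolves slowly; then a power-ultrasound transducer is switched on and the
coating strips away within seconds.

`sonoKinetics` turns such footage into numbers. For every frame it computes
the mean RGB color inside a circular region of interest (ROI) around the
sample, normalizes each channel to the intact-sample color at time zero,
and fits the normalized percentage against time by ordinary least squares
separately within each regime's window. The slope of each fit is the
**extraction speed** in percent per second:

```
c_pct(t) = 100 · mean_ROI(c, t) / mean_ROI(c, 0)        c ∈ {R, G, B}
v_phase  = argmin_b Σ_{t ∈ window} (c_pct(t) − a − b·t)²     [%/s]
```

with the **enhancement ratio** `v_ultrasonic / v_conventional` summarizing
how much the ultrasound accelerates the process. The headline speed is
fitted on the candy's dominant channel (red candy → R, green → G,
blue → B); all three channels are always extracted and exported.

The package is aimed at anyone quantifying extraction, dissolution or
color-release kinetics from fixed-camera footage — including classroom use,
where the included synthetic generator stands in for lab equipment.

## What is in the box

- **Video I/O** — `readVideo()` (MP4 via an external ffmpeg binary),
  `readFrameDir()` / `writeFrameDir()` (lossless numbered-PNG dialect),
  `writeMaskedVideo()` (ROI check view) and `writeEvolutionVideo()`
  (percentage overlay).
- **Colorimetry** — `makeMask()`, `extractSeries()`, `exportSeriesCSV()`,
  plus a convenience `autoDetectROI()`.
- **Kinetics** — `referenceColor()`, `normalizeSeries()`, `fitPhase()`,
  `analyzeExtraction()`, `channelForCandy()`.
- **Synthetic experiments** — `syntheticSpec()`, `generateVideo()`,
  `candyExperimentSpec()`, `fixtureSuite()`: videos with known
  piecewise-linear ground truth, pixel noise, illumination flicker and
  cavitation-like speckles.
- **Reporting** — `runConfig()` / `runAnalysis()` (CSV + JSON report +
  figure + annotated videos in one call), `runSimulate()`, and a thin CLI
  at `inst/scripts/sonokin`.

## Worked example

Emulate the blue-candy experiment (true speeds 0.022 and 21.7 %/s on the B
channel), then measure it back:

```r
library(sonoKinetics)

spec   <- candyExperimentSpec("blue", noiseSigma = 1, seed = 42)
video  <- generateVideo(spec)
series <- extractSeries(video, circularROI(23.5, 23.5, 15))
fit    <- analyzeExtraction(series, phaseWindows(c(0, 25), c(25, 60)),
                            channel = channelForCandy("blue"))
fit
#> ExtractionFit (channel B)
#>   conventional [0, 25) s: 0.02201 %/s  (R2 = 0.6242, n = 625)
#>   ultrasonic   [25, 60) s: 21.7 %/s  (R2 = 1.0000, n = 875)
#>   enhancement ratio: 986
```

The conventional (water-only) phase loses color at 0.022 %/s — barely above
the noise, hence the modest R² — while the ultrasonic phase strips it at
21.7 %/s, an enhancement of nearly three orders of magnitude. Both
estimates sit on top of the generator's ground truth.

The same analysis on real footage, writing all report files:

```r
cfg <- runConfig("candyblue_frames/", centerX = 321, centerY = 242,
                 radius = 88, windows = c(0, 25, 25, 60), candy = "blue",
                 outDir = "results")
runAnalysis(cfg)
```

or from a shell:

```sh
Rscript inst/scripts/sonokin analyze --input candyblue_frames/ \
    --center 321,242 --radius 88 --windows 0:25,25:60 --candy blue \
    --out results
```

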
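# Synthetic experiment videos with known ground-truth kinetics.
#
# The generator emulates what the camera sees in the extraction experiment:
# a colored disk (candy + dye halo filling the sample holder) on a
# near-black background, whose in-ROI mean color drifts piecewise-linearly
# in time — slowly while only water acts, fast once the ultrasound is on —
# with optional pixel noise, illumination flicker and cavitation-like
# speckles layered on top.

#' @rdname SyntheticSpec-class
#'
#' @details
#' The default spec is a 48x48 px, 60 s, 25 fps experiment switching from
#' the conventional to the ultrasonic regime at 25 s, with rates 0.15 and
#' 8.9 %/s on the red channel and 1 channel unit of pixel noise — a
#' miniature of a red-candy run. The default base color keeps the full
#' ultrasonic ramp inside the 8-bit range so the expected means stay exactly
#' linear (no clipping).
#'
#' @param height,width,frameRate,duration,diskCenter,diskRadius,baseColor,backgroundColor,phase1Rate,phase2Rate,switchTime,channel,channelGain,noiseSigma,flickerAmplitude,flickerFrequency,speckleDensity,seed
#'   see the class slots.
#' @export
syntheticSpec <- function(height = 48, width = 48, frameRate = 25,
                          duration = 60, diskCenter = c(23.5, 23.5),
                          diskRadius = 15, baseColor = c(36, 9, 6),
                          backgroundColor = c(6, 6, 6),
                          phase1Rate = 0.15, phase2Rate = 8.9,
                          switchTime = 25, channel = "R",
                          channelGain = c(1, 1, 1), noiseSigma = 1,
                          flickerAmplitude = 0, flickerFrequency = 1.3,
                          speckleDensity = 0, seed = 1L) {
  new("SyntheticSpec", height = height, width = width, frameRate = frameRate,
      duration = duration, diskCenter = as.numeric(diskCenter),
      diskRadius = diskRadius, baseColor = as.numeric(baseColor),
      backgroundColor = as.numeric(backgroundColor),
      phase1Rate = phase1Rate, phase2Rate = phase2Rate,
      switchTime = switchTime, channel = channel,
      channelGain = as.numeric(channelGain), noiseSigma = noiseSigma,
      flickerAmplitude = flickerAmplitude,
      flickerFrequency = flickerFrequency, speckleDensity = speckleDensity,
      seed = as.integer(seed))
}

# Evaluate code with a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Ground-truth percentage ramp of a synthetic spec
#'
#' The expected in-ROI mean of the designated channel, as a percent of its
#' time-zero value: `100 + phase1Rate * t` before the switch, continuing
#' with slope `phase2Rate` after it.
#'
#' @param spec a [SyntheticSpec-class].
#' @param times seconds.
#' @return numeric vector of percentages.
#' @export
expectedPercent <- function(spec, times) {
  atSwitch <- 100 + spec@phase1Rate * spec@switchTime
  ifelse(times < spec@switchTime,
         100 + spec@phase1Rate * times,
         atSwitch + spec@phase2Rate * (times - spec@switchTime))
}

#' @rdname expectedPercent
#' @return `expectedSpeeds()` returns the ground-truth
#'   `c(conventional, ultrasonic)` rates in %/s.
#' @export
expectedSpeeds <- function(spec) {
  c(conventional = spec@phase1Rate, ultrasonic = spec@phase2Rate)
}

#' Generate a synthetic experiment video
#'
#' Renders the spec into a [VideoSequence-class]. Inside the disk every
#' pixel of channel `ch` follows
#' `baseColor[ch] * (100 + channelGain[ch] * (pct(t) - 100)) / 100`, where
#' `pct(t)` is the ground-truth ramp of [expectedPercent()], so the in-ROI
#' mean of the designated channel follows the ramp exactly. Illumination
#' flicker multiplies whole frames by
#' `1 + flickerAmplitude * sin(2 * pi * flickerFrequency * t)`; speckles are
#' single-frame bright disks placed inside the ROI during the ultrasonic
#' phase; pixel noise is zero-mean Gaussian, added last, and the result is
#' clipped to `[0, 255]` (truncated-Gaussian noise, the simplest model
#' consistent with an 8-bit sensor). Frames are kept as doubles: values are
#' only quantized when written to disk, so noiseless specs round-trip
#' through the analysis at full floating-point precision.
#'
#' If the expected (pre-noise) values of any channel leave `[0, 255]` before
#' `duration`, a range warning is raised: clipping breaks the linearity that
#' the ground truth promises, and tests must choose safe rates.
#'
#' A fixed `seed` makes the output bit-identical across runs; the caller's
#' RNG state is left untouched.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A [VideoSequence-class].
#' @examples
#' v <- generateVideo(syntheticSpec(duration = 4, noiseSigma = 0))
#' nFrames(v)
#' @export
generateVideo <- function(spec) {
  validObject(spec)
  h <- as.integer(spec@height); w <- as.integer(spec@width)
  n <- as.integer(round(spec@duration * spec@frameRate))
  if (n < 1L) stop("duration shorter than one frame")
  times <- (seq_len(n) - 1) / spec@frameRate
  pct <- expectedPercent(spec, times)
  roi <- circularROI(spec@diskCenter[1], spec@diskCenter[2], spec@diskRadius)
  mask <- makeMask(roi, h, w)
  idx <- which(mask@grid == 1L)
  npx <- length(idx)

  ramps <- vapply(1:3, function(ch)
    spec@baseColor[ch] * (100 + spec@channelGain[ch] * (pct - 100)) / 100,
    numeric(n))
  ramps <- matrix(ramps, nrow = n)
  if (min(ramps) < 0 || max(ramps) > 255)
    warning("range warning: expected channel values leave [0, 255] before ",
            "duration; clipping will break the ground-truth linearity")

  flick <- if (spec@flickerAmplitude != 0)
    1 + spec@flickerAmplitude * sin(2 * pi * spec@flickerFrequency * times)
  else rep(1, n)

  .withSeed(spec@seed, {
    # assemble in a (pixel, channel, frame) layout that shares memory with
    # the final height x width x 3 x frame array
    vid <- array(0, dim = c(h * w, 3L, n))
    for (ch in 1:3) {
      mat <- matrix(spec@backgroundColor[ch], h * w, n)
      mat[idx, ] <- rep(ramps[, ch], each = npx)
      if (spec@flickerAmplitude != 0)
        mat <- mat * rep(flick, each = h * w)
      vid[, ch, ] <- mat
    }
    # speckles: short-lived bright disks inside the ROI, ultrasonic phase
    # only (they mimic cavitation bubbles / streaming glints)
    u <- stats::runif(n)
    hit <- which(u < spec@speckleDensity & times >= spec@switchTime)
    if (length(hit)) {
      sr <- max(1, spec@diskRadius / 6)
      for (k in hit) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, max(0, spec@diskRadius - sr))
        sx <- spec@diskCenter[1] + rad * cos(ang)
        sy <- spec@diskCenter[2] + rad * sin(ang)
        dy2 <- ((0:(h - 1)) - sy)^2
        dx2 <- ((0:(w - 1)) - sx)^2
        sp <- which(outer(dy2, dx2, "+") <= sr^2)
        vid[sp, , k] <- 255
      }
    }
    if (spec@noiseSigma > 0)
      vid <- vid + stats::rnorm(length(vid), 0, spec@noiseSigma)
    vid[vid < 0] <- 0
    vid[vid > 255] <- 255
    dim(vid) <- c(h, w, 3L, n)
    videoSequence(vid, spec@frameRate,
                  source = sprintf("synthetic(seed=%d)", spec@seed))
  })
}

#' Standard battery of synthetic fixtures with ground truth
#'
#' A named list of test scenarios, each a list with the `spec`, the
#' `expected` conventional/ultrasonic speeds, an absolute `tolerance` in
#' %/s within which an analysis of the generated video should recover them,
#' and a `note`. The battery covers: a noiseless run (recovery is exact to
#' floating point), a noisy run, pure illumination flicker (zero true rate;
#' the tolerance bounds the flicker-induced slope artifact), cavitation-like
#' speckles (which perturb only the ultrasonic phase), a zero-rate control,
#' and a clipping-edge spec whose generation raises a range warning
#' (`expected` is `NA`: the ground truth is no longer linear).
#'
#' @param seed base RNG seed for the battery.
#' @return Named list of fixture scenarios.
#' @export
fixtureSuite <- function(seed = 101L) {
  seed <- as.integer(seed)
  list(
    noiseless = list(
      spec = syntheticSpec(phase1Rate = 0.2, phase2Rate = 15,
                           baseColor = c(38, 10, 6), noiseSigma = 0,
                           seed = seed),
      expected = c(conventional = 0.2, ultrasonic = 15),
      tolerance = 1e-6,
      note = "exact construction; recovery limited only by float roundoff"),
    noisy = list(
      spec = syntheticSpec(phase1Rate = 0.2, phase2Rate = 15,
                           baseColor = c(38, 10, 6), noiseSigma = 1.5,
                           seed = seed + 1L),
      expected = c(conventional = 0.2, ultrasonic = 15),
      tolerance = 0.05,
      note = "pixel noise averaged over the mask; slopes stay accurate"),
    flicker = list(
      spec = syntheticSpec(phase1Rate = 0, phase2Rate = 0,
                           baseColor = c(38, 10, 6), noiseSigma = 0,
                           flickerAmplitude = 0.05, seed = seed + 2L),
      expected = c(conventional = 0, ultrasonic = 0),
      tolerance = 0.25,
      note = "global gain flicker is not removed by normalization; the
              tolerance bounds the residual slope artifact"),
    speckled = list(
      spec = syntheticSpec(phase1Rate = 0.2, phase2Rate = 15,
                           baseColor = c(38, 10, 6), noiseSigma = 0,
                           speckleDensity = 0.1, seed = seed + 3L),
      expected = c(conventional = 0.2, ultrasonic = 15),
      tolerance = 1.0,
      note = "speckles live only in the ultrasonic phase; the conventional
              fit equals the noiseless one exactly"),
    zeroRate = list(
      spec = syntheticSpec(phase1Rate = 0, phase2Rate = 0,
                           baseColor = c(38, 10, 6), noiseSigma = 1,
                           seed = seed + 4L),
      expected = c(conventional = 0, ultrasonic = 0),
      tolerance = 0.05,
      note = "control: nothing is extracted, both speeds are zero"),
    clippingEdge = list(
      spec = syntheticSpec(phase1Rate = 0.2, phase2Rate = 15,
                           baseColor = c(160, 40, 20), noiseSigma = 0,
                           seed = seed + 5L),
      expected = c(conventional = NA_real_, ultrasonic = NA_real_),
      tolerance = NA_real_,
      note = "designated channel saturates mid-ramp; generation raises a
              range warning and the linear ground truth no longer holds")
  )
}

#' Synthetic stand-ins for the three reference candy experiments
#'
#' Specs that emulate the red, green and blue candy experiments: the
#' ground-truth rates are the measured conventional/ultrasonic extraction
#' speeds of each experiment (0.15/8.9, 0.22/16.5 and 0.022/21.7 %/s on the
#' candy's dominant channel), and the base color is the intact-candy RGB
#' triple — red `[145 35 22]`, green `[76 178 71]`, blue `[37 142 192]` —
#' scaled down by `scale` so the dominant channel keeps the whole ultrasonic
#' ramp inside the 8-bit range (with the unscaled colors the fast ramps
#' would saturate mid-window and the linear ground truth would not hold).
#' Because extraction speeds are percentages of the intact color, they are
#' invariant to this scaling. These are synthetic stand-ins, not
#' re-creations of the experimental footage.
#'
#' @param candy `"red"`, `"green"` or `"blue"`.
#' @param noiseSigma pixel noise, channel units.
#' @param seed RNG seed.
#' @param scale factor on the intact color; defaults keep the ramp
#'   clip-free (0.25, 0.2, 0.15 for red, green, blue).
#' @return A [SyntheticSpec-class] with 48x48 px frames, 25 fps, 60 s
#'   duration and the ultrasound switch at 25 s.
#' @export
candyExperimentSpec <- function(candy = c("red", "green", "blue"),
                                noiseSigma = 1, seed = 1L, scale = NULL) {
  candy <- match.arg(candy)
  p <- switch(candy,
    red   = list(base = c(145, 35, 22),  rates = c(0.15, 8.9),  scale = 0.25),
    green = list(base = c(76, 178, 71),  rates = c(0.22, 16.5), scale = 0.2),
    blue  = list(base = c(37, 142, 192), rates = c(0.022, 21.7), scale = 0.15))
  if (is.null(scale)) scale <- p$scale
  syntheticSpec(baseColor = p$base * scale, phase1Rate = p$rates[1],
                phase2Rate = p$rates[2], channel = channelForCandy(candy),
                noiseSigma = noiseSigma, seed = seed)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %gx%g px, %g fps, %g s (switch at %g s)\n",
              object@width, object@height, object@frameRate,
              object@duration, object@switchTime))
  cat(sprintf("  rates (%s channel): %g then %g %%/s\n", object@channel,
              object@phase1Rate, object@phase2Rate))
  cat(sprintf("  base [%s] on background [%s]\n",
              paste(object@baseColor, collapse = " "),
              paste(object@backgroundColor, collapse = " ")))
  cat(sprintf("  noise sd %g, flicker %g @ %g Hz, speckle density %g, seed %d\n",
              object@noiseSigma, object@flickerAmplitude,
              object@flickerFrequency, object@speckleDensity, object@seed))
})
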
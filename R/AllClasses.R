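#' @import methods
NULL

#' Ordered video frames with a uniform frame rate
#'
#' A decoded video held in memory as a single numeric array with dimensions
#' height x width x channel x frame. Channel values live on the 8-bit scale
#' `[0, 255]` but are stored as doubles, so synthetic, unquantized frames keep
#' full precision through the pipeline. The timestamp of frame `i` (1-based)
#' is `(i - 1) / frameRate(x)` seconds; a constant frame rate is assumed and
#' variable-frame-rate material is rejected at read time.
#'
#' @slot frames numeric array, `height x width x 3 x nFrames`, values in
#'   `[0, 255]`.
#' @slot frameRate frames per second (positive scalar).
#' @slot source provenance string (file path, directory, or generator tag).
#'
#' @seealso [readFrameDir()], [readVideo()], [generateVideo()],
#'   [extractSeries()]
#' @export
setClass("VideoSequence",
  slots = c(frames = "array", frameRate = "numeric", source = "character"))

setValidity("VideoSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 4L)
    return("frames must be a height x width x 3 x nFrames array")
  if (d[3] != 3L)
    return("frames must carry exactly 3 color channels")
  if (any(d < 1L))
    return("frames array has a zero-length dimension")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    return("frameRate must be a single positive number")
  rng <- range(object@frames)
  if (!all(is.finite(rng)))
    return("frames contain non-finite pixel values")
  if (rng[1] < 0 || rng[2] > 255)
    return("pixel values must lie in [0, 255]")
  TRUE
})

#' Construct a VideoSequence
#'
#' @param frames either a `height x width x 3 x n` numeric array or a list of
#'   `height x width x 3` arrays (all the same shape), values in `[0, 255]`.
#' @param frameRate frames per second.
#' @param source provenance string recorded with the object.
#' @return A [VideoSequence-class] object.
#' @examples
#' f <- array(128, dim = c(4, 4, 3, 2))
#' videoSequence(f, frameRate = 25)
#' @export
videoSequence <- function(frames, frameRate, source = "in-memory") {
  if (is.list(frames)) {
    if (length(frames) == 0L)
      stop("empty input: no frames supplied")
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
    if (!all(ok))
      stop("shape mismatch: all frames must share the same dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(d, length(frames)))
  }
  new("VideoSequence", frames = frames, frameRate = as.numeric(frameRate),
      source = source)
}

#' Circular region of interest
#'
#' The analysis disk around the sample. Coordinates are 0-based pixel-center
#' coordinates with `x` the column, `y` the row and the origin at the
#' top-left; sub-pixel centers and radii are allowed. A pixel belongs to the
#' ROI when its center satisfies
#' `(x - centerX)^2 + (y - centerY)^2 <= radius^2` (closed disk, so a radius
#' of 0 at an integer center still covers one pixel). The disk must lie fully
#' inside the frame: in the experiment the radius is chosen slightly smaller
#' than the sample holder to avoid edge reflections, and a disk crossing the
#' frame edge is rejected rather than clipped.
#'
#' @slot centerX disk center column, pixels.
#' @slot centerY disk center row, pixels.
#' @slot radius disk radius, pixels (non-negative).
#' @seealso [circularROI()], [makeMask()]
#' @export
setClass("CircularROI",
  slots = c(centerX = "numeric", centerY = "numeric", radius = "numeric"))

setValidity("CircularROI", function(object) {
  v <- c(object@centerX, object@centerY, object@radius)
  if (length(v) != 3L || !all(is.finite(v)))
    return("centerX, centerY and radius must be finite scalars")
  if (object@radius < 0)
    return("radius must be non-negative")
  TRUE
})

#' @rdname CircularROI-class
#' @param centerX,centerY disk center, 0-based pixel coordinates
#'   (x = column, y = row).
#' @param radius disk radius in pixels.
#' @export
circularROI <- function(centerX, centerY, radius) {
  new("CircularROI", centerX = as.numeric(centerX),
      centerY = as.numeric(centerY), radius = as.numeric(radius))
}

#' Binary analysis mask
#'
#' The rasterized ROI: 1 inside the disk, 0 outside, so that masked
#' statistics reduce to a multiply-and-average.
#'
#' @slot grid integer matrix of 0/1, dimensions height x width.
#' @slot area number of 1-pixels.
#' @seealso [makeMask()]
#' @export
setClass("BinaryMask", slots = c(grid = "matrix", area = "integer"))

setValidity("BinaryMask", function(object) {
  if (!all(object@grid %in% c(0L, 1L)))
    return("mask grid must contain only 0 and 1")
  if (object@area != sum(object@grid == 1L))
    return("area must equal the number of 1-pixels")
  if (object@area < 1L)
    return("mask must cover at least one pixel")
  TRUE
})

#' Per-frame mean channel values inside the ROI
#'
#' The raw colorimetric signal: for every frame, the mean of each RGB channel
#' over the mask pixels, computed in floating point (no 8-bit truncation),
#' with timestamps from the frame index and frame rate.
#'
#' @slot times seconds per frame, strictly increasing, starting at 0.
#' @slot rMean,gMean,bMean per-frame in-mask channel means, `[0, 255]`.
#' @slot roi the [CircularROI-class] used.
#' @slot nPixels mask area in pixels.
#' @slot source provenance string of the video analysed.
#' @seealso [extractSeries()], [referenceColor()], [normalizeSeries()]
#' @export
setClass("ChannelTimeSeries",
  slots = c(times = "numeric", rMean = "numeric", gMean = "numeric",
            bMean = "numeric", roi = "CircularROI", nPixels = "integer",
            source = "character"))

setValidity("ChannelTimeSeries", function(object) {
  n <- length(object@times)
  if (length(object@rMean) != n || length(object@gMean) != n ||
      length(object@bMean) != n)
    return("times and channel means must have equal lengths")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  ch <- c(object@rMean, object@gMean, object@bMean)
  if (length(ch) && (min(ch) < 0 || max(ch) > 255))
    return("channel means must lie in [0, 255]")
  TRUE
})

#' Intact-sample reference color
#'
#' Mean RGB of the sample at time zero, used to express later frames as
#' percentages. Every component must be strictly positive or the percentage
#' normalization is undefined.
#'
#' @slot r0,g0,b0 reference channel means, each in `(0, 255]`.
#' @seealso [referenceColor()], [normalizeSeries()]
#' @export
setClass("ReferenceColor",
  slots = c(r0 = "numeric", g0 = "numeric", b0 = "numeric"))

setValidity("ReferenceColor", function(object) {
  v <- c(object@r0, object@g0, object@b0)
  if (!all(is.finite(v)))
    return("reference components must be finite")
  if (any(v <= 0))
    return("degenerate reference: every component must be > 0")
  if (any(v > 255))
    return("reference components must be <= 255")
  TRUE
})

#' @rdname ReferenceColor-class
#' @param r,g,b reference channel means in `(0, 255]`.
#' @export
referenceRGB <- function(r, g, b) {
  new("ReferenceColor", r0 = as.numeric(r), g0 = as.numeric(g),
      b0 = as.numeric(b))
}

#' Channel series normalized to the reference color
#'
#' Each channel expressed as a percent of the intact-sample reference, so the
#' time-zero window averages to 100 by construction and a global illumination
#' gain cancels exactly.
#'
#' @slot times seconds per frame.
#' @slot rPct,gPct,bPct per-frame percentages of the reference.
#' @slot reference the [ReferenceColor-class] used.
#' @seealso [normalizeSeries()], [fitPhase()]
#' @export
setClass("NormalizedSeries",
  slots = c(times = "numeric", rPct = "numeric", gPct = "numeric",
            bPct = "numeric", reference = "ReferenceColor"))

setValidity("NormalizedSeries", function(object) {
  n <- length(object@times)
  if (length(object@rPct) != n || length(object@gPct) != n ||
      length(object@bPct) != n)
    return("times and channel percentages must have equal lengths")
  ch <- c(object@rPct, object@gPct, object@bPct)
  if (length(ch) && min(ch) < -1e-9)
    return("percentages must be non-negative")
  TRUE
})

#' Phase windows of the two extraction regimes
#'
#' Half-open intervals `[start, end)` in seconds: the conventional
#' (water-only) phase and the ultrasonic phase. The defaults reflect the
#' protocol in which water acts alone for the first 25 s and ultrasound for
#' the remainder of a one-minute recording. Windows must be disjoint and the
#' conventional window must precede the ultrasonic one.
#'
#' @slot conventional `c(start, end)` seconds of the water-only phase.
#' @slot ultrasonic `c(start, end)` seconds of the ultrasound-on phase.
#' @seealso [phaseWindows()], [analyzeExtraction()]
#' @export
setClass("PhaseWindows",
  slots = c(conventional = "numeric", ultrasonic = "numeric"))

setValidity("PhaseWindows", function(object) {
  w1 <- object@conventional; w2 <- object@ultrasonic
  if (length(w1) != 2L || length(w2) != 2L || !all(is.finite(c(w1, w2))))
    return("each window must be c(start, end) with finite endpoints")
  if (w1[2] <= w1[1] || w2[2] <= w2[1])
    return("window end must exceed window start")
  if (w1[2] > w2[1])
    return("windows must be disjoint with the conventional phase first")
  TRUE
})

#' @rdname PhaseWindows-class
#' @param conventional,ultrasonic `c(start, end)` in seconds, half-open.
#' @export
phaseWindows <- function(conventional = c(0, 25), ultrasonic = c(25, 60)) {
  new("PhaseWindows", conventional = as.numeric(conventional),
      ultrasonic = as.numeric(ultrasonic))
}

#' Phase-wise extraction speed fit
#'
#' Result of fitting the normalized series of one channel by ordinary least
#' squares within each phase window. The slope is the extraction speed in
#' percent per second (raw signed slope; no absolute value is taken). The
#' enhancement ratio is `ultrasonicSpeed / conventionalSpeed`, or `NA` when
#' the conventional speed is zero.
#'
#' @slot channel fitted channel, one of `"R"`, `"G"`, `"B"`.
#' @slot conventionalSpeed,ultrasonicSpeed slopes in %/s.
#' @slot intercepts fitted percentage at `t = 0` for each window (named
#'   `conventional`, `ultrasonic`).
#' @slot rSquared coefficient of determination per window, in `[0, 1]`.
#' @slot residualStd residual standard deviation per window (`NA` with
#'   fewer than 3 points).
#' @slot nFrames frames used per window.
#' @slot enhancementRatio ultrasonic over conventional speed (dimensionless,
#'   `NA` when undefined).
#' @slot windows the [PhaseWindows-class] fitted.
#' @slot reference the [ReferenceColor-class] used for normalization.
#' @seealso [analyzeExtraction()], [fitPhase()]
#' @export
setClass("ExtractionFit",
  slots = c(channel = "character", conventionalSpeed = "numeric",
            ultrasonicSpeed = "numeric", intercepts = "numeric",
            rSquared = "numeric", residualStd = "numeric",
            nFrames = "integer", enhancementRatio = "numeric",
            windows = "PhaseWindows", reference = "ReferenceColor"))

setValidity("ExtractionFit", function(object) {
  if (!object@channel %in% c("R", "G", "B"))
    return("channel must be one of R, G, B")
  r2 <- object@rSquared
  if (any(!is.na(r2) & (r2 < -1e-12 | r2 > 1 + 1e-12)))
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' Specification of a synthetic extraction experiment
#'
#' Full parameterization of a simulated video with known ground-truth
#' kinetics: a colored disk (the candy plus its dye halo) on a near-black
#' background (the black-painted sample holder), whose in-ROI mean color
#' drifts piecewise-linearly — a slow conventional rate until `switchTime`,
#' then a fast ultrasonic rate — expressed in percent of the time-zero value
#' per second. Optional confounders emulate what real footage adds on top:
#' zero-mean Gaussian pixel noise (clipped to the 8-bit range), a global
#' sinusoidal illumination flicker, and short-lived bright speckles inside
#' the ROI during the ultrasonic phase that mimic cavitation/streaming
#' visuals. A fixed `seed` makes the output bit-identical across runs.
#'
#' `channelGain` scales how strongly each channel follows the percentage
#' ramp; the designated `channel` must have gain 1 so it carries exactly the
#' specified rates.
#'
#' @slot height,width frame size, pixels.
#' @slot frameRate frames per second.
#' @slot duration total length, seconds.
#' @slot diskCenter `c(x, y)` disk center, 0-based pixel coordinates.
#' @slot diskRadius disk radius, pixels.
#' @slot baseColor RGB triple of the intact sample, `[0, 255]`.
#' @slot backgroundColor RGB triple of the holder background (near-black).
#' @slot phase1Rate,phase2Rate ground-truth extraction speeds, %/s.
#' @slot switchTime ultrasound switch-on time, seconds, in
#'   `(0, duration)`.
#' @slot channel designated channel that carries the rates exactly.
#' @slot channelGain per-channel multiplier on the percentage ramp.
#' @slot noiseSigma pixel noise standard deviation, channel units.
#' @slot flickerAmplitude relative amplitude of the global gain flicker.
#' @slot flickerFrequency flicker frequency, Hz.
#' @slot speckleDensity fraction of ultrasonic-phase frames carrying a
#'   bright speckle.
#' @slot seed RNG seed (integer).
#' @seealso [syntheticSpec()], [generateVideo()], [fixtureSuite()]
#' @export
setClass("SyntheticSpec",
  slots = c(height = "numeric", width = "numeric", frameRate = "numeric",
            duration = "numeric", diskCenter = "numeric",
            diskRadius = "numeric", baseColor = "numeric",
            backgroundColor = "numeric", phase1Rate = "numeric",
            phase2Rate = "numeric", switchTime = "numeric",
            channel = "character", channelGain = "numeric",
            noiseSigma = "numeric", flickerAmplitude = "numeric",
            flickerFrequency = "numeric", speckleDensity = "numeric",
            seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@height < 1 || object@width < 1)
    return("frame size must be at least 1x1")
  if (object@frameRate <= 0) return("frameRate must be positive")
  if (object@duration <= 0) return("duration must be positive")
  if (!all(object@baseColor >= 0 & object@baseColor <= 255) ||
      length(object@baseColor) != 3L)
    return("baseColor must be an RGB triple in [0, 255]")
  if (!all(object@backgroundColor >= 0 & object@backgroundColor <= 255) ||
      length(object@backgroundColor) != 3L)
    return("backgroundColor must be an RGB triple in [0, 255]")
  if (!all(is.finite(c(object@phase1Rate, object@phase2Rate))))
    return("phase rates must be finite")
  if (object@switchTime <= 0 || object@switchTime >= object@duration)
    return("switchTime must lie strictly inside (0, duration)")
  if (!object@channel %in% c("R", "G", "B"))
    return("channel must be one of R, G, B")
  if (length(object@channelGain) != 3L)
    return("channelGain must have one entry per channel")
  i <- match(object@channel, c("R", "G", "B"))
  if (abs(object@channelGain[i] - 1) > 1e-12)
    return("the designated channel must have channelGain 1")
  if (object@noiseSigma < 0) return("noiseSigma must be non-negative")
  if (object@speckleDensity < 0 || object@speckleDensity > 1)
    return("speckleDensity must lie in [0, 1]")
  TRUE
})

#' Run configuration for a complete analysis
#'
#' Everything a reproducible run needs: the input video (MP4 file or frame
#' directory), the ROI, the phase windows, the channel to fit (directly or
#' via the candy color), the reference window, and the output directory. The
#' full configuration is serialized into the JSON report for provenance.
#'
#' @slot input path to an MP4 file or a frame directory.
#' @slot frameRate frames per second assumed for frame directories (and
#'   checked against MP4 metadata).
#' @slot roi the [CircularROI-class] to analyse.
#' @slot windows the [PhaseWindows-class] of the two regimes.
#' @slot channel channel fitted for the headline speed.
#' @slot refWindowS reference-color window length, seconds.
#' @slot guardS guard interval excluded after ultrasound switch-on, seconds.
#' @slot outDir output directory.
#' @slot writeVideos whether to write the masked and evolution videos.
#' @slot seed RNG seed recorded for provenance (synthetic runs).
#' @seealso [runConfig()], [runAnalysis()]
#' @export
setClass("RunConfig",
  slots = c(input = "character", frameRate = "numeric", roi = "CircularROI",
            windows = "PhaseWindows", channel = "character",
            refWindowS = "numeric", guardS = "numeric", outDir = "character",
            writeVideos = "logical", seed = "integer"))

setValidity("RunConfig", function(object) {
  if (!object@channel %in% c("R", "G", "B"))
    return("channel must be one of R, G, B")
  if (object@refWindowS <= 0)
    return("refWindowS must be positive")
  if (object@guardS < 0)
    return("guardS must be non-negative")
  if (object@frameRate <= 0)
    return("frameRate must be positive")
  TRUE
})
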
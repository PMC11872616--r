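#' Number of frames in a video sequence
#' @param x a [VideoSequence-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame rate of a video sequence
#' @param x a [VideoSequence-class].
#' @return frames per second.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Frame timestamps
#'
#' Timestamps are affine in the frame index with slope `1/frameRate(x)`:
#' frame `i` (1-based) is at `(i - 1) / frameRate(x)` seconds. No
#' dropped-frame handling is attempted.
#'
#' @param x a [VideoSequence-class] or [ChannelTimeSeries-class].
#' @return numeric vector of seconds.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Extract the in-ROI mean color time series from a video
#'
#' For every frame, each channel mean is the sum of that channel over the
#' mask pixels divided by the mask area, computed in floating point (no
#' 8-bit truncation).
#'
#' @param x a [VideoSequence-class].
#' @param roi a [CircularROI-class]; must lie fully inside the frame.
#' @return A [ChannelTimeSeries-class].
#' @examples
#' v <- generateVideo(syntheticSpec(duration = 2, noiseSigma = 0))
#' s <- extractSeries(v, circularROI(23.5, 23.5, 15))
#' head(as.data.frame(s))
#' @export
setGeneric("extractSeries", function(x, roi) standardGeneric("extractSeries"))

#' Run the full kinetics analysis on a channel series
#'
#' Composes [referenceColor()], [normalizeSeries()] and [fitPhase()] over
#' both phase windows and reports the two extraction speeds plus the
#' enhancement ratio.
#'
#' @param x a [ChannelTimeSeries-class].
#' @param windows a [PhaseWindows-class].
#' @param channel channel to fit: `"R"`, `"G"` or `"B"`.
#' @param refWindowS reference window length in seconds (default 1 s, i.e.
#'   25 frames at the standard 25 fps; use one frame interval to reproduce a
#'   single-frame reference).
#' @param guardS seconds excluded from the start of the ultrasonic window to
#'   skip the switch-on transient (default 0).
#' @return An [ExtractionFit-class].
#' @export
setGeneric("analyzeExtraction",
  function(x, windows = phaseWindows(), channel = "R", refWindowS = 1,
           guardS = 0)
    standardGeneric("analyzeExtraction"))

#' @rdname ExtractionFit-class
#' @param object an [ExtractionFit-class].
#' @return `speeds()` returns the two slopes as a named vector (%/s);
#'   `enhancementRatio()` the ultrasonic/conventional speed ratio.
#' @export
setGeneric("speeds", function(object) standardGeneric("speeds"))

#' @rdname ExtractionFit-class
#' @export
setGeneric("enhancementRatio",
  function(object) standardGeneric("enhancementRatio"))
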
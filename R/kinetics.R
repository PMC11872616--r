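# Normalization to the intact-sample reference color and phase-wise
# linear-rate estimation.

#' Intact-sample reference color at time zero
#'
#' Per-channel mean over the frames with `time < windowS`. Averaging over a
#' short window (default 1 s, i.e. 25 frames at the standard 25 fps) rather
#' than the single first frame makes the reference robust to pixel noise;
#' pass `windowS` equal to one frame interval for a single-frame reference.
#'
#' @param series a [ChannelTimeSeries-class].
#' @param windowS window length in seconds; must cover at least one frame.
#' @return A [ReferenceColor-class].
#' @examples
#' v <- generateVideo(syntheticSpec(duration = 2, noiseSigma = 0))
#' s <- extractSeries(v, circularROI(23.5, 23.5, 15))
#' referenceColor(s, 1)
#' @export
referenceColor <- function(series, windowS = 1) {
  if (length(series@times) == 0L)
    stop("empty input: series has no frames")
  if (windowS <= 0)
    stop("reference window must be positive")
  sel <- series@times < windowS
  if (!any(sel))
    stop("reference window shorter than one frame interval")
  v <- c(mean(series@rMean[sel]), mean(series@gMean[sel]),
         mean(series@bMean[sel]))
  if (any(v == 0))
    stop("degenerate reference: a channel mean at time zero is 0, ",
         "percentage normalization is undefined")
  referenceRGB(v[1], v[2], v[3])
}

#' Express a channel series as percent of the reference color
#'
#' `channel_pct(t) = 100 * channel_mean(t) / channel_ref`. When `ref` is the
#' series' own time-zero reference, the reference-window mean maps to 100
#' exactly, and any global multiplicative gain on the raw pixels cancels.
#'
#' @param series a [ChannelTimeSeries-class].
#' @param ref a [ReferenceColor-class] with strictly positive components.
#' @return A [NormalizedSeries-class].
#' @export
normalizeSeries <- function(series, ref) {
  validObject(ref)
  new("NormalizedSeries", times = series@times,
      rPct = 100 * series@rMean / ref@r0,
      gPct = 100 * series@gMean / ref@g0,
      bPct = 100 * series@bMean / ref@b0,
      reference = ref)
}

.channelPct <- function(norm, channel) {
  switch(match.arg(channel, c("R", "G", "B")),
         R = norm@rPct, G = norm@gPct, B = norm@bPct)
}

#' Fit the extraction speed within one phase window
#'
#' Ordinary least-squares regression of the normalized percentage of one
#' channel against time, over the frames with `start <= t < end` (half-open
#' window). The slope is the extraction speed in percent per second.
#'
#' @param norm a [NormalizedSeries-class].
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param window `c(start, end)` seconds, half-open.
#' @return A list with `slope` (%/s), `intercept` (% at t = 0), `rSquared`,
#'   `residualStd` (`NA` with fewer than 3 points) and `n` (frames used).
#' @examples
#' t <- (0:624) / 25
#' s <- new("NormalizedSeries", times = t, rPct = 100 + 2 * t,
#'          gPct = rep(100, 625), bPct = rep(100, 625),
#'          reference = referenceRGB(100, 100, 100))
#' fitPhase(s, "R", c(0, 25))$slope  # 2
#' @export
fitPhase <- function(norm, channel = "R", window) {
  sel <- norm@times >= window[1] & norm@times < window[2]
  n <- sum(sel)
  if (n < 2L)
    stop("insufficient data: fewer than 2 frames in window [",
         window[1], ", ", window[2], ")")
  t <- norm@times[sel]
  if (stats::var(t) == 0)
    stop("degenerate fit: zero time variance in window")
  y <- .channelPct(norm, channel)[sel]
  if (stats::var(y) == 0)  # exactly constant: slope is 0, not QR roundoff
    return(list(slope = 0, intercept = y[1], rSquared = 1,
                residualStd = if (n > 2L) 0 else NA_real_, n = n))
  fit <- stats::lm(y ~ t)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       # a constant series is fitted exactly; report R^2 = 1, not 0/0
       rSquared = if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1,
       residualStd = if (n > 2L) sqrt(rss / (n - 2)) else NA_real_,
       n = n)
}

#' @describeIn analyzeExtraction reference, normalization and both phase
#'   fits in one call.
setMethod("analyzeExtraction", "ChannelTimeSeries",
  function(x, windows = phaseWindows(), channel = "R", refWindowS = 1,
           guardS = 0) {
    validObject(windows)
    channel <- match.arg(channel, c("R", "G", "B"))
    ref <- referenceColor(x, refWindowS)
    norm <- normalizeSeries(x, ref)
    fitC <- fitPhase(norm, channel, windows@conventional)
    ultra <- c(windows@ultrasonic[1] + guardS, windows@ultrasonic[2])
    fitU <- fitPhase(norm, channel, ultra)
    ratio <- if (fitC$slope != 0) fitU$slope / fitC$slope else NA_real_
    new("ExtractionFit", channel = channel,
        conventionalSpeed = fitC$slope, ultrasonicSpeed = fitU$slope,
        intercepts = c(conventional = fitC$intercept,
                       ultrasonic = fitU$intercept),
        rSquared = c(conventional = fitC$rSquared,
                     ultrasonic = fitU$rSquared),
        residualStd = c(conventional = fitC$residualStd,
                        ultrasonic = fitU$residualStd),
        nFrames = c(conventional = fitC$n, ultrasonic = fitU$n),
        enhancementRatio = ratio, windows = windows, reference = ref)
  })

#' Dominant channel of a candy color
#'
#' The headline extraction speed is fitted on the channel matching the candy
#' color: red candies on R, green on G, blue on B.
#'
#' @param colorName `"red"`, `"green"` or `"blue"` (case-insensitive).
#' @return `"R"`, `"G"` or `"B"`.
#' @examples
#' channelForCandy("blue")
#' @export
channelForCandy <- function(colorName) {
  map <- c(red = "R", green = "G", blue = "B")
  key <- tolower(as.character(colorName)[1])
  if (!key %in% names(map))
    stop("unknown candy color '", colorName,
         "'; expected red, green or blue")
  unname(map[[key]])
}

setMethod("speeds", "ExtractionFit", function(object) {
  c(conventional = object@conventionalSpeed,
    ultrasonic = object@ultrasonicSpeed)
})

setMethod("enhancementRatio", "ExtractionFit",
  function(object) object@enhancementRatio)

setMethod("show", "ExtractionFit", function(object) {
  cat("ExtractionFit (channel ", object@channel, ")\n", sep = "")
  w <- object@windows
  cat(sprintf("  conventional [%g, %g) s: %.4g %%/s  (R2 = %.4f, n = %d)\n",
              w@conventional[1], w@conventional[2],
              object@conventionalSpeed, object@rSquared[["conventional"]],
              object@nFrames[["conventional"]]))
  cat(sprintf("  ultrasonic   [%g, %g) s: %.4g %%/s  (R2 = %.4f, n = %d)\n",
              w@ultrasonic[1], w@ultrasonic[2],
              object@ultrasonicSpeed, object@rSquared[["ultrasonic"]],
              object@nFrames[["ultrasonic"]]))
  cat("  enhancement ratio: ",
      if (is.na(object@enhancementRatio)) "undefined"
      else format(object@enhancementRatio, digits = 4), "\n", sep = "")
})

setMethod("show", "ReferenceColor", function(object) {
  cat("ReferenceColor: [",
      paste(format(c(object@r0, object@g0, object@b0), digits = 4),
            collapse = " "), "]\n", sep = "")
})

setMethod("show", "PhaseWindows", function(object) {
  cat(sprintf("PhaseWindows: conventional [%g, %g) s, ultrasonic [%g, %g) s\n",
              object@conventional[1], object@conventional[2],
              object@ultrasonic[1], object@ultrasonic[2]))
})

#' @describeIn NormalizedSeries-class coerce to a data frame with columns
#'   `frame`, `time_s`, `r_pct`, `g_pct`, `b_pct`.
#' @param x a `NormalizedSeries`.
#' @param row.names,optional,... S3 compatibility; unused.
#' @export
as.data.frame.NormalizedSeries <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(frame = seq_along(x@times) - 1L, time_s = x@times,
             r_pct = x@rPct, g_pct = x@gPct, b_pct = x@bPct)
}
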
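# Circular-ROI masking and per-frame RGB averaging.

.checkROI <- function(roi, height, width) {
  validObject(roi)
  cx <- roi@centerX; cy <- roi@centerY; r <- roi@radius
  if (cx < 0 || cx > width - 1 || cy < 0 || cy > height - 1)
    stop("roi error: disk center (", cx, ", ", cy,
         ") lies outside the ", width, "x", height, " frame")
  if (cx - r < 0 || cx + r > width - 1 || cy - r < 0 || cy + r > height - 1)
    stop("roi error: disk of radius ", r, " at (", cx, ", ", cy,
         ") extends past the frame edge; shrink the radius (do not clip)")
  invisible(TRUE)
}

#' Rasterize a circular ROI into a binary mask
#'
#' A pixel `(x, y)` (0-based, x = column, y = row, origin top-left) belongs
#' to the mask when `(x - centerX)^2 + (y - centerY)^2 <= radius^2`,
#' evaluated at integer pixel centers (closed disk, so radius 0 at an
#' integer center yields area 1). A disk that would cross a frame edge is an
#' error: the measurement protocol keeps the ROI strictly inside the holder
#' to avoid edge reflections, and silently clipping it would bias the mean.
#'
#' @param roi a [CircularROI-class].
#' @param height,width frame dimensions in pixels.
#' @return A [BinaryMask-class] with `grid` (height x width 0/1 matrix) and
#'   `area` (pixel count).
#' @examples
#' m <- makeMask(circularROI(100, 100, 50), 200, 200)
#' m@area / (pi * 50^2)  # close to 1
#' @export
makeMask <- function(roi, height, width) {
  .checkROI(roi, height, width)
  dy2 <- ((0:(height - 1)) - roi@centerY)^2
  dx2 <- ((0:(width - 1)) - roi@centerX)^2
  grid <- outer(dy2, dx2, "+") <= roi@radius^2
  storage.mode(grid) <- "integer"
  new("BinaryMask", grid = grid, area = sum(grid))
}

#' @describeIn extractSeries mean RGB inside the mask for every frame.
setMethod("extractSeries", "VideoSequence", function(x, roi) {
  d <- dim(x@frames)
  if (d[4] < 1L) stop("empty input: sequence has no frames")
  mask <- makeMask(roi, d[1], d[2])
  idx <- which(mask@grid == 1L)
  n <- d[4]
  perChannel <- function(ch) {
    mat <- matrix(x@frames[, , ch, ], d[1] * d[2], n)
    colMeans(mat[idx, , drop = FALSE])
  }
  new("ChannelTimeSeries",
      times = (seq_len(n) - 1) / x@frameRate,
      rMean = perChannel(1L), gMean = perChannel(2L), bMean = perChannel(3L),
      roi = roi, nPixels = mask@area, source = x@source)
})

#' @describeIn ChannelTimeSeries-class coerce to a data frame with columns
#'   `frame`, `time_s`, `r_mean`, `g_mean`, `b_mean`.
#' @param x a `ChannelTimeSeries`.
#' @param row.names,optional,... passed on for S3 compatibility; unused.
#' @export
as.data.frame.ChannelTimeSeries <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(frame = seq_along(x@times) - 1L, time_s = x@times,
             r_mean = x@rMean, g_mean = x@gMean, b_mean = x@bMean)
}

#' Write a channel time series to CSV
#'
#' Columns: `frame` (0-based), `time_s`, `r_mean`, `g_mean`, `b_mean`.
#'
#' @param series a [ChannelTimeSeries-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
exportSeriesCSV <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Convenience ROI auto-detection
#'
#' Locates the sample as the largest bright connected blob in a frame and
#' proposes a [CircularROI-class] at its centroid with a slightly shrunken
#' equivalent radius. This is a convenience for quickly setting up a run; it
#' is not part of the measurement method, which takes the ROI as explicit
#' input. Connected-component labelling uses EBImage when installed;
#' otherwise all bright pixels are treated as a single blob.
#'
#' @param x a [VideoSequence-class]; the first frame is used.
#' @param threshold brightness cut on the per-pixel channel maximum, in
#'   channel units. By default midway between the darkest and brightest
#'   pixel.
#' @param shrink factor applied to the equivalent radius so the ROI stays
#'   inside the sample (default 0.9).
#' @return A [CircularROI-class] proposal.
#' @export
autoDetectROI <- function(x, threshold = NULL, shrink = 0.9) {
  fr <- x@frames[, , , 1L, drop = FALSE]
  bright <- pmax(fr[, , 1L, 1L], fr[, , 2L, 1L], fr[, , 3L, 1L])
  if (is.null(threshold))
    threshold <- (min(bright) + max(bright)) / 2
  bin <- bright > threshold
  if (!any(bin))
    stop("auto-detect failed: no pixel exceeds the brightness threshold")
  if (requireNamespace("EBImage", quietly = TRUE)) {
    lab <- EBImage::bwlabel(t(bin))  # EBImage images are x-major
    lab <- t(lab)
    counts <- tabulate(lab[lab > 0])
    bin <- lab == which.max(counts)
  }
  rows <- row(bin)[bin]; cols <- col(bin)[bin]
  circularROI(mean(cols) - 1, mean(rows) - 1,
              shrink * sqrt(length(rows) / pi))
}

setMethod("show", "ChannelTimeSeries", function(object) {
  n <- length(object@times)
  cat("ChannelTimeSeries: ", n, " frames over ",
      format(if (n) max(object@times) else 0, digits = 4), " s\n", sep = "")
  cat("  ROI: center (", object@roi@centerX, ", ", object@roi@centerY,
      "), radius ", object@roi@radius, " (", object@nPixels, " px)\n",
      sep = "")
  if (n)
    cat("  first-frame mean RGB: [",
        paste(format(c(object@rMean[1], object@gMean[1], object@bMean[1]),
                     digits = 4), collapse = " "), "]\n", sep = "")
  cat("  source: ", object@source, "\n", sep = "")
})

setMethod("show", "CircularROI", function(object) {
  cat("CircularROI: center (", object@centerX, ", ", object@centerY,
      "), radius ", object@radius, " px\n", sep = "")
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask: ", nrow(object@grid), "x", ncol(object@grid),
      ", area ", object@area, " px\n", sep = "")
})
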
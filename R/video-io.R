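# Reading and writing videos.
#
# Two dialects: MP4 (decoded/encoded through an external ffmpeg binary when
# one is on the PATH) and frame directories of numbered PNG/TIFF images.
# The frame directory is the canonical lossless dialect — codec round-trips
# are lossy by nature — and is what the test suite exercises.

.readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF frames")
    tiff::readTIFF(path)
  } else stop("unsupported frame format: ", ext)
  if (is.matrix(img))                       # grayscale -> 3 equal channels
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L)                     # drop alpha
    img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Read a directory of numbered frame images
#'
#' Frames are PNG (or TIFF) files whose names contain a zero-padded integer
#' stem; they are ordered by that number, not lexically. Grayscale images
#' are broadcast to three identical channels; 8-bit values round-trip
#' exactly through [writeFrameDir()].
#'
#' @param path directory of frame images.
#' @param frameRate frames per second to attach (a bare directory carries no
#'   timing metadata).
#' @return A [VideoSequence-class].
#' @seealso [readVideo()] for MP4 containers.
#' @export
readFrameDir <- function(path, frameRate) {
  if (!dir.exists(path))
    stop("decode error: '", path, "' is not a directory")
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop("empty input: no frame images found in '", path, "'")
  stems <- regmatches(basename(files), regexpr("[0-9]+", basename(files)))
  if (length(stems) != length(files))
    stop("frame filenames must contain a numeric stem")
  files <- files[order(as.numeric(stems))]
  frames <- lapply(files, .readImageFile)
  d1 <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d1), logical(1))
  if (!all(same))
    stop("shape mismatch: frames ",
         paste(basename(files[!same]), collapse = ", "),
         " differ in size from the first frame")
  videoSequence(frames, frameRate, source = path)
}

#' Write a video sequence as a directory of PNG frames
#'
#' Frames are quantized to 8 bits and written as `00001.png`,
#' `00002.png`, ... so that [readFrameDir()] restores them in order.
#'
#' @param x a [VideoSequence-class].
#' @param path output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
writeFrameDir <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- dim(x@frames)[4]
  for (i in seq_len(n))
    png::writePNG(x@frames[, , , i] / 255,
                  file.path(path, sprintf("%05d.png", i)))
  invisible(path)
}

.findFFmpeg <- function() {
  ff <- Sys.which("ffmpeg")
  if (!nzchar(ff)) NULL else ff
}

#' Read an MP4 (or any ffmpeg-decodable) video
#'
#' Decodes the container through an external `ffmpeg` binary, which must be
#' on the PATH; without one, convert the video to a frame directory and use
#' [readFrameDir()]. The frame rate is taken from container metadata and
#' overridden by `expectedFps` when given; a disagreement beyond 1% raises
#' a warning. Variable frame rates are not modelled: timestamps are always
#' `index / frameRate`.
#'
#' @param path path to a video file.
#' @param expectedFps optional frames per second to enforce (e.g. 25 for
#'   footage acquired at 25 fps).
#' @return A [VideoSequence-class].
#' @export
readVideo <- function(path, expectedFps = NULL) {
  if (dir.exists(path))
    stop("dispatch error: '", path,
         "' is a directory; use readFrameDir() for frame directories")
  if (!file.exists(path))
    stop("decode error: file '", path, "' does not exist")
  ff <- .findFFmpeg()
  if (is.null(ff))
    stop("decode error: no ffmpeg binary on the PATH to decode '", path,
         "'; extract the frames to a directory and use readFrameDir()")
  tmp <- tempfile("frames")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  log <- suppressWarnings(system2(
    ff, c("-i", shQuote(path), "-vsync", "0",
          shQuote(file.path(tmp, "%06d.png"))),
    stdout = TRUE, stderr = TRUE))
  m <- regmatches(log, regexpr("[0-9]+(\\.[0-9]+)? fps", log))
  metaFps <- if (length(m)) as.numeric(sub(" fps", "", m[1])) else NA_real_
  fps <- if (!is.null(expectedFps)) expectedFps else metaFps
  if (is.na(fps))
    stop("decode error: no frame rate in container metadata; pass ",
         "expectedFps")
  if (!is.null(expectedFps) && !is.na(metaFps) &&
      abs(metaFps - expectedFps) / expectedFps > 0.01)
    warning("container reports ", metaFps, " fps but expectedFps is ",
            expectedFps, "; using expectedFps")
  out <- readFrameDir(tmp, fps)
  out@source <- path
  out
}

.writeSequence <- function(x, path) {
  if (grepl("\\.mp4$", path, ignore.case = TRUE)) {
    ff <- .findFFmpeg()
    if (is.null(ff))
      stop("encode error: no ffmpeg binary on the PATH to write '", path,
           "'; give a directory path to write lossless PNG frames instead")
    tmp <- tempfile("enc")
    writeFrameDir(x, tmp)
    on.exit(unlink(tmp, recursive = TRUE))
    status <- system2(ff, c("-y", "-framerate", x@frameRate, "-i",
                            shQuote(file.path(tmp, "%05d.png")),
                            "-pix_fmt", "yuv420p", shQuote(path)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0) stop("encode error: ffmpeg exited with status ", status)
  } else {
    writeFrameDir(x, path)
  }
  invisible(path)
}

#' Write the masked view of a video
#'
#' Pixels outside the circular ROI are set to black and pixels inside are
#' left unchanged, reproducing the mask-check videos used to verify the ROI
#' placement. Frame count and rate are preserved. With an `.mp4` path the
#' output is encoded through ffmpeg; any other path is treated as a
#' directory of lossless PNG frames.
#'
#' @param x a [VideoSequence-class].
#' @param roi a [CircularROI-class] inside the frame bounds.
#' @param path output path (`.mp4` file or frame directory).
#' @return The output path, invisibly.
#' @export
writeMaskedVideo <- function(x, roi, path) {
  d <- dim(x@frames)
  mask <- makeMask(roi, d[1], d[2])
  keep <- as.numeric(mask@grid)
  out <- x@frames
  for (ch in 1:3)
    out[, , ch, ] <- out[, , ch, , drop = FALSE] *
      array(keep, dim = c(d[1], d[2], 1, d[4]))
  .writeSequence(videoSequence(out, x@frameRate,
                               source = paste0(x@source, " [masked]")),
                 path)
}

# --- tiny 3x5 bitmap font for frame annotation -----------------------------

.glyphs <- local({
  rows <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "001", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"),
    "." = c("000", "000", "000", "000", "010"),
    "-" = c("000", "000", "111", "000", "000"))
  lapply(rows, function(r)
    do.call(rbind, lapply(strsplit(r, ""), function(b) as.integer(b))))
})

# Render a numeric label into a 0/1 matrix (scale-replicated 3x5 glyphs
# separated by one blank column).
.renderLabel <- function(text, scale = 2L) {
  chars <- strsplit(text, "")[[1]]
  bad <- setdiff(chars, names(.glyphs))
  if (length(bad)) stop("no glyph for: ", paste(bad, collapse = " "))
  gap <- matrix(0L, 5L, 1L)
  mats <- list()
  for (i in seq_along(chars)) {
    mats[[length(mats) + 1L]] <- .glyphs[[chars[i]]]
    if (i < length(chars)) mats[[length(mats) + 1L]] <- gap
  }
  lab <- do.call(cbind, mats)
  kronecker(lab, matrix(1L, scale, scale))
}

.stampLabel <- function(frame, label, scale = 2L) {
  lab <- .renderLabel(label, scale)
  lh <- nrow(lab); lw <- ncol(lab)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  r0 <- 2L; c0 <- 2L                       # 1 px black border around text
  rs <- r0:min(h, r0 + lh + 1L)
  cs <- c0:min(w, c0 + lw + 1L)
  frame[rs, cs, ] <- 0
  rr <- (r0 + 1L):min(h, r0 + lh)
  cc <- (c0 + 1L):min(w, c0 + lw)
  block <- lab[seq_along(rr), seq_along(cc), drop = FALSE] * 255
  for (ch in 1:3) {
    pl <- frame[rr, cc, ch]
    frame[rr, cc, ch] <- pmax(pl, block)
  }
  frame
}

#' Write the extraction-evolution video
#'
#' Annotates every frame with the running extraction percentage of one
#' channel (one decimal place, stamped as white text on a black box in the
#' top-left corner). Because the series is normalized to the intact-sample
#' reference, the first annotated value reads 100. The series must have
#' exactly one value per frame.
#'
#' @param x a [VideoSequence-class].
#' @param series a [NormalizedSeries-class] aligned with `x`.
#' @param path output path (`.mp4` file or frame directory).
#' @param channel channel whose percentage is displayed.
#' @return The output path, invisibly; the annotated percentage values are
#'   attached as the `"values"` attribute.
#' @export
writeEvolutionVideo <- function(x, series, path, channel = "R") {
  pct <- .channelPct(series, channel)
  n <- dim(x@frames)[4]
  if (length(pct) != n)
    stop("alignment error: series has ", length(pct),
         " values for ", n, " frames")
  out <- x@frames
  labels <- sprintf("%.1f", pct)
  for (i in seq_len(n))
    out[, , , i] <- .stampLabel(out[, , , i], labels[i])
  p <- .writeSequence(videoSequence(out, x@frameRate,
                                    source = paste0(x@source,
                                                    " [evolution]")),
                      path)
  attr(p, "values") <- pct
  invisible(p)
}

# --- accessors -------------------------------------------------------------

#' @describeIn nFrames frame count of a video sequence.
setMethod("nFrames", "VideoSequence", function(x) dim(x@frames)[4])

#' @describeIn frameRate frames per second of a video sequence.
setMethod("frameRate", "VideoSequence", function(x) x@frameRate)

#' @describeIn frameTimes timestamps of a video sequence.
setMethod("frameTimes", "VideoSequence",
  function(x) (seq_len(dim(x@frames)[4]) - 1) / x@frameRate)

#' @describeIn frameTimes timestamps of a channel time series.
setMethod("frameTimes", "ChannelTimeSeries", function(x) x@times)

#' Extract one frame from a video sequence
#' @param x a [VideoSequence-class].
#' @param i 1-based frame index.
#' @return A `height x width x 3` numeric array.
#' @export
getFrame <- function(x, i) {
  n <- dim(x@frames)[4]
  if (i < 1L || i > n) stop("frame index out of range")
  x@frames[, , , i]
}

setMethod("show", "VideoSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VideoSequence: %d frames of %dx%d px at %g fps (%.3g s)\n",
              d[4], d[2], d[1], object@frameRate, d[4] / object@frameRate))
  cat("  source: ", object@source, "\n", sep = "")
})
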
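# Run configuration, report writing and figure generation: the glue that
# turns a video plus an ROI and phase windows into CSV/JSON/plot outputs.

#' Parse a decimal number that may use a comma separator
#'
#' Configuration values copied from tables typeset with decimal commas
#' (`"0,15"`) are accepted alongside dotted decimals (`"0.15"`); all output
#' uses dots.
#'
#' @param x character or numeric vector.
#' @return numeric vector.
#' @examples
#' parseNumber(c("0,15", "8.9"))
#' @export
parseNumber <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(gsub(",", ".", trimws(x), fixed = TRUE)))
  if (any(is.na(out) & !is.na(x)))
    stop("cannot parse '", paste(x[is.na(out)], collapse = "', '"),
         "' as a number")
  out
}

#' @rdname RunConfig-class
#'
#' @param input path to an MP4 file or a frame directory.
#' @param centerX,centerY,radius the circular ROI (0-based pixel
#'   coordinates; decimal commas accepted in character input).
#' @param windows a [PhaseWindows-class], or a list/vector interpretable as
#'   `c(conv_start, conv_end, ultra_start, ultra_end)`.
#' @param candy optional candy color (`"red"`, `"green"`, `"blue"`); sets
#'   `channel` via [channelForCandy()] when `channel` is missing.
#' @param channel channel fitted for the headline speed.
#' @param frameRate frames per second for frame-directory input (default 25,
#'   the acquisition rate of the experiment footage).
#' @param refWindowS reference window, seconds.
#' @param guardS guard interval after ultrasound switch-on, seconds.
#' @param outDir output directory.
#' @param writeVideos write the masked and evolution videos too.
#' @param seed seed recorded for provenance.
#' @export
runConfig <- function(input, centerX, centerY, radius,
                      windows = phaseWindows(), candy = NULL,
                      channel = NULL, frameRate = 25, refWindowS = 1,
                      guardS = 0, outDir = "results", writeVideos = TRUE,
                      seed = NA_integer_) {
  if (is.null(channel)) {
    if (is.null(candy))
      stop("give either a candy color or an explicit channel")
    channel <- channelForCandy(candy)
  }
  if (!is(windows, "PhaseWindows")) {
    w <- parseNumber(unlist(windows, use.names = FALSE))
    if (length(w) != 4L)
      stop("windows must supply four numbers: conv start/end, ultra start/end")
    windows <- phaseWindows(w[1:2], w[3:4])
  }
  new("RunConfig", input = input, frameRate = parseNumber(frameRate),
      roi = circularROI(parseNumber(centerX), parseNumber(centerY),
                        parseNumber(radius)),
      windows = windows, channel = channel,
      refWindowS = parseNumber(refWindowS), guardS = parseNumber(guardS),
      outDir = outDir, writeVideos = isTRUE(writeVideos),
      seed = as.integer(seed))
}

#' Read a run configuration from a JSON file
#'
#' Keys mirror the [runConfig()] arguments: `input`, `center_x`, `center_y`,
#' `radius`, `windows` (four numbers), `candy` or `channel`, `frame_rate`,
#' `ref_window_s`, `guard_s`, `out_dir`, `write_videos`, `seed`. Numeric
#' fields may be strings with decimal commas.
#'
#' @param path JSON file path.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  get0 <- function(key, default = NULL)
    if (!is.null(cfg[[key]])) cfg[[key]] else default
  runConfig(input = get0("input", stop("config needs 'input'")),
            centerX = get0("center_x", stop("config needs 'center_x'")),
            centerY = get0("center_y", stop("config needs 'center_y'")),
            radius = get0("radius", stop("config needs 'radius'")),
            windows = get0("windows", c(0, 25, 25, 60)),
            candy = get0("candy"), channel = get0("channel"),
            frameRate = get0("frame_rate", 25),
            refWindowS = get0("ref_window_s", 1),
            guardS = get0("guard_s", 0),
            outDir = get0("out_dir", "results"),
            writeVideos = get0("write_videos", TRUE),
            seed = get0("seed", NA_integer_))
}

.configAsList <- function(config) {
  list(input = config@input, frame_rate = config@frameRate,
       center_x = config@roi@centerX, center_y = config@roi@centerY,
       radius = config@roi@radius,
       windows = list(conventional = config@windows@conventional,
                      ultrasonic = config@windows@ultrasonic),
       channel = config@channel, ref_window_s = config@refWindowS,
       guard_s = config@guardS, out_dir = config@outDir,
       write_videos = config@writeVideos,
       seed = if (is.na(config@seed)) NULL else config@seed)
}

.fitAsList <- function(fit) {
  num <- function(x) if (is.na(x)) NULL else x
  list(channel = fit@channel,
       conventional = list(
         speed_pct_per_s = fit@conventionalSpeed,
         intercept_pct = fit@intercepts[["conventional"]],
         r_squared = fit@rSquared[["conventional"]],
         residual_std = num(fit@residualStd[["conventional"]]),
         n_frames = fit@nFrames[["conventional"]]),
       ultrasonic = list(
         speed_pct_per_s = fit@ultrasonicSpeed,
         intercept_pct = fit@intercepts[["ultrasonic"]],
         r_squared = fit@rSquared[["ultrasonic"]],
         residual_std = num(fit@residualStd[["ultrasonic"]]),
         n_frames = fit@nFrames[["ultrasonic"]]),
       enhancement_ratio = num(fit@enhancementRatio),
       reference_rgb = c(fit@reference@r0, fit@reference@g0,
                         fit@reference@b0))
}

#' Plot the extraction evolution with the per-window linear fits
#'
#' Reproduces the standard report figure: the full three-channel evolution
#' on top, and below it the designated channel inside each phase window
#' with its fitted line — conventional on the left, ultrasonic on the
#' right.
#'
#' @param norm a [NormalizedSeries-class].
#' @param fit an [ExtractionFit-class] from the same series.
#' @param path output PNG path; `NULL` draws on the current device.
#' @return The path, invisibly.
#' @export
plotExtraction <- function(norm, fit, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::layout(matrix(c(1, 1, 2, 3), 2, 2, byrow = TRUE))
  t <- norm@times
  rng <- range(norm@rPct, norm@gPct, norm@bPct)
  graphics::plot(t, norm@rPct, type = "l", col = "red3", ylim = rng,
                 xlab = "time [s]", ylab = "color [% of intact]",
                 main = "Extraction evolution")
  graphics::lines(t, norm@gPct, col = "green4")
  graphics::lines(t, norm@bPct, col = "blue3")
  graphics::abline(v = fit@windows@ultrasonic[1], lty = 2, col = "grey40")
  graphics::legend("topleft", c("R", "G", "B"), lty = 1, bty = "n",
                   col = c("red3", "green4", "blue3"))
  y <- .channelPct(norm, fit@channel)
  panel <- function(win, slope, icept, label) {
    sel <- t >= win[1] & t < win[2]
    graphics::plot(t[sel], y[sel], pch = ".", cex = 2, col = "grey30",
                   xlab = "time [s]",
                   ylab = sprintf("%s [%% of intact]", fit@channel),
                   main = label)
    graphics::abline(icept, slope, col = "red3", lwd = 2)
    graphics::mtext(sprintf("%.3g %%/s", slope), side = 3, line = -1.5,
                    adj = 0.05, cex = 0.8)
  }
  panel(fit@windows@conventional, fit@conventionalSpeed,
        fit@intercepts[["conventional"]], "Conventional (water only)")
  panel(c(fit@windows@ultrasonic[1] + 0, fit@windows@ultrasonic[2]),
        fit@ultrasonicSpeed, fit@intercepts[["ultrasonic"]],
        "Ultrasound assisted")
  invisible(path)
}

#' Run the complete analysis described by a configuration
#'
#' Reads the input video (frame directory or MP4 by extension), extracts the
#' in-ROI channel series, runs the kinetics analysis, and writes into the
#' output directory: `series.csv` (raw means), `normalized.csv`,
#' `report.json` (fit results plus the full configuration and package
#' version for provenance), `extraction_plot.png`, and — when
#' `writeVideos` — the masked video under `masked/` and the annotated
#' evolution video under `evolution/`. The pipeline is deterministic:
#' re-running the same configuration on the same input reproduces identical
#' numbers.
#'
#' @param config a [RunConfig-class].
#' @return Invisibly, a list with the [ExtractionFit-class], the
#'   [ChannelTimeSeries-class] and the written file paths.
#' @export
runAnalysis <- function(config) {
  validObject(config)
  seq <- if (dir.exists(config@input))
    readFrameDir(config@input, config@frameRate)
  else readVideo(config@input, expectedFps = config@frameRate)
  d <- dim(seq@frames)
  .checkROI(config@roi, d[1], d[2])
  series <- extractSeries(seq, config@roi)
  fit <- analyzeExtraction(series, windows = config@windows,
                           channel = config@channel,
                           refWindowS = config@refWindowS,
                           guardS = config@guardS)
  norm <- normalizeSeries(series, fit@reference)
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(series = file.path(config@outDir, "series.csv"),
                normalized = file.path(config@outDir, "normalized.csv"),
                report = file.path(config@outDir, "report.json"),
                plot = file.path(config@outDir, "extraction_plot.png"))
  exportSeriesCSV(series, paths$series)
  utils::write.csv(as.data.frame(norm), paths$normalized, row.names = FALSE)
  report <- list(
    package = "sonoKinetics",
    version = as.character(utils::packageVersion("sonoKinetics")),
    config = .configAsList(config),
    n_frames = length(series@times),
    n_mask_pixels = series@nPixels,
    fit = .fitAsList(fit))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  plotExtraction(norm, fit, paths$plot)
  if (config@writeVideos) {
    paths$masked <- writeMaskedVideo(seq, config@roi,
                                     file.path(config@outDir, "masked"))
    paths$evolution <- writeEvolutionVideo(
      seq, norm, file.path(config@outDir, "evolution"),
      channel = config@channel)
  }
  invisible(list(fit = fit, series = series, paths = paths))
}

# --- synthetic-spec serialization and simulation runs ----------------------

#' Serialize / deserialize a synthetic spec as JSON
#'
#' @param spec a [SyntheticSpec-class].
#' @param path JSON file path.
#' @return `writeSyntheticSpec()` the path invisibly; `readSyntheticSpec()`
#'   a validated [SyntheticSpec-class].
#' @export
writeSyntheticSpec <- function(spec, path) {
  jsonlite::write_json(
    list(height = spec@height, width = spec@width,
         frame_rate = spec@frameRate, duration = spec@duration,
         disk_center = spec@diskCenter, disk_radius = spec@diskRadius,
         base_color = spec@baseColor,
         background_color = spec@backgroundColor,
         phase1_rate = spec@phase1Rate, phase2_rate = spec@phase2Rate,
         switch_time = spec@switchTime, channel = spec@channel,
         channel_gain = spec@channelGain, noise_sigma = spec@noiseSigma,
         flicker_amplitude = spec@flickerAmplitude,
         flicker_frequency = spec@flickerFrequency,
         speckle_density = spec@speckleDensity, seed = spec@seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSyntheticSpec
#' @export
readSyntheticSpec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- function(key) {
    if (is.null(s[[key]])) stop("spec is missing '", key, "'")
    s[[key]]
  }
  opt <- function(key, default) if (is.null(s[[key]])) default else s[[key]]
  syntheticSpec(
    height = parseNumber(opt("height", 48)),
    width = parseNumber(opt("width", 48)),
    frameRate = parseNumber(opt("frame_rate", 25)),
    duration = parseNumber(need("duration")),
    diskCenter = parseNumber(opt("disk_center", c(23.5, 23.5))),
    diskRadius = parseNumber(opt("disk_radius", 15)),
    baseColor = parseNumber(opt("base_color", c(36, 9, 6))),
    backgroundColor = parseNumber(opt("background_color", c(6, 6, 6))),
    phase1Rate = parseNumber(need("phase1_rate")),
    phase2Rate = parseNumber(need("phase2_rate")),
    switchTime = parseNumber(need("switch_time")),
    channel = opt("channel", "R"),
    channelGain = parseNumber(opt("channel_gain", c(1, 1, 1))),
    noiseSigma = parseNumber(opt("noise_sigma", 0)),
    flickerAmplitude = parseNumber(opt("flicker_amplitude", 0)),
    flickerFrequency = parseNumber(opt("flicker_frequency", 1.3)),
    speckleDensity = parseNumber(opt("speckle_density", 0)),
    seed = as.integer(parseNumber(opt("seed", 1))))
}

#' Simulate a synthetic experiment and write it with its ground truth
#'
#' Generates the video described by a spec (object or JSON file), writes it
#' as a lossless frame directory under `outDir/frames/` (and MP4 when
#' requested and ffmpeg is available), and writes `truth.json` holding the
#' spec plus the ground-truth speeds — ready to be compared against a
#' subsequent [runAnalysis()] on the written frames.
#'
#' @param spec a [SyntheticSpec-class] or the path to a spec JSON file.
#' @param outDir output directory.
#' @param mp4 also encode an MP4 (requires ffmpeg on the PATH).
#' @return Invisibly, a list with the frames directory, the truth file and
#'   the generated [VideoSequence-class].
#' @export
runSimulate <- function(spec, outDir, mp4 = FALSE) {
  if (is.character(spec)) spec <- readSyntheticSpec(spec)
  validObject(spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  video <- generateVideo(spec)
  framesDir <- file.path(outDir, "frames")
  writeFrameDir(video, framesDir)
  specPath <- file.path(outDir, "spec.json")
  writeSyntheticSpec(spec, specPath)
  truth <- list(
    spec = jsonlite::read_json(specPath, simplifyVector = TRUE),
    expected = list(
      conventional_speed_pct_per_s = spec@phase1Rate,
      ultrasonic_speed_pct_per_s = spec@phase2Rate,
      enhancement_ratio = if (spec@phase1Rate != 0)
        spec@phase2Rate / spec@phase1Rate else NULL),
    roi = list(center_x = spec@diskCenter[1], center_y = spec@diskCenter[2],
               radius = spec@diskRadius))
  truthPath <- file.path(outDir, "truth.json")
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (mp4)
    .writeSequence(video, file.path(outDir, "synthetic.mp4"))
  invisible(list(frames = framesDir, truth = truthPath, video = video))
}
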
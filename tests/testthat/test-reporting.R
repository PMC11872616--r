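writeFixtureRun <- function(dir, spec) {
  framesDir <- file.path(dir, "frames")
  writeFrameDir(generateVideo(spec), framesDir)
  framesDir
}

test_that("numbers with decimal commas parse like dotted decimals", {
  expect_equal(parseNumber("0,15"), 0.15)
  expect_equal(parseNumber(c("8,9", "21.7", " 16,5 ")), c(8.9, 21.7, 16.5))
  expect_equal(parseNumber(0.022), 0.022)
  expect_error(parseNumber("abc"), "cannot parse")
})

test_that("run configurations resolve the candy channel and validate", {
  cfg <- runConfig("in", centerX = "23,5", centerY = 23.5, radius = 15,
                   candy = "green", outDir = "out")
  expect_identical(cfg@channel, "G")
  expect_equal(cfg@roi@centerX, 23.5)
  expect_error(runConfig("in", 1, 1, 1), "candy color or an explicit")
  expect_error(runConfig("in", 1, 1, 1, channel = "G", refWindowS = 0),
               "refWindowS")
  expect_error(runConfig("in", 1, 1, 1, channel = "G",
                         windows = c(0, 25, 20, 60)),
               "disjoint")
})

test_that("JSON run configurations round-trip, commas included", {
  dir <- withr::local_tempdir()
  cfgPath <- file.path(dir, "run.json")
  jsonlite::write_json(
    list(input = "frames", center_x = "23,5", center_y = 23.5,
         radius = 15, windows = c(0, 25, 25, 60), candy = "blue",
         ref_window_s = "0,04"),
    cfgPath, auto_unbox = TRUE)
  cfg <- readRunConfig(cfgPath)
  expect_identical(cfg@channel, "B")
  expect_equal(cfg@roi@centerX, 23.5)
  expect_equal(cfg@refWindowS, 0.04)
})

test_that("the analysis run writes its full report and reproduces truth", {
  dir <- withr::local_tempdir()
  # noiseSigma dithers the 8-bit PNG quantization: with perfectly uniform
  # disk pixels the slow ramp would be smaller than one quantization step
  spec <- syntheticSpec(phase1Rate = 0.2, phase2Rate = 15,
                        baseColor = c(38, 10, 6), noiseSigma = 0.5,
                        duration = 8, switchTime = 4)
  framesDir <- writeFixtureRun(dir, spec)
  cfg <- runConfig(framesDir, centerX = 23.5, centerY = 23.5, radius = 15,
                   windows = c(0, 4, 4, 8), channel = "R",
                   refWindowS = 1 / 25, outDir = file.path(dir, "out"))
  res <- runAnalysis(cfg)

  expect_true(file.exists(res$paths$series))
  expect_true(file.exists(res$paths$normalized))
  expect_true(file.exists(res$paths$report))
  expect_true(file.exists(res$paths$plot))
  expect_true(dir.exists(res$paths$masked))
  expect_true(dir.exists(res$paths$evolution))

  report <- jsonlite::read_json(res$paths$report, simplifyVector = TRUE)
  expect_equal(report$fit$conventional$speed_pct_per_s, 0.2,
               tolerance = 0.25)
  expect_equal(report$fit$ultrasonic$speed_pct_per_s, 15, tolerance = 0.01)
  expect_identical(report$fit$channel, "R")
  # the full configuration is embedded for provenance
  expect_equal(report$config$center_x, 23.5)
  expect_equal(report$config$windows$ultrasonic, c(4, 8))
  expect_identical(report$package, "sonoKinetics")

  # deterministic pipeline: a re-run reproduces identical numbers
  cfg2 <- runConfig(framesDir, centerX = 23.5, centerY = 23.5, radius = 15,
                    windows = c(0, 4, 4, 8), channel = "R",
                    refWindowS = 1 / 25, outDir = file.path(dir, "out2"),
                    writeVideos = FALSE)
  res2 <- runAnalysis(cfg2)
  expect_identical(speeds(res2$fit), speeds(res$fit))
  expect_false("masked" %in% names(res2$paths))
})

test_that("an ROI outside the frame aborts the run with a roi error", {
  dir <- withr::local_tempdir()
  framesDir <- writeFixtureRun(dir, syntheticSpec(duration = 0.2,
                                                  switchTime = 0.1,
                                                  noiseSigma = 0))
  cfg <- runConfig(framesDir, centerX = 45, centerY = 45, radius = 15,
                   windows = c(0, 0.08, 0.08, 0.2), channel = "R",
                   outDir = file.path(dir, "out"))
  expect_error(runAnalysis(cfg), "roi error")
})

test_that("simulation runs write frames plus ground truth that analyze
           recovers", {
  dir <- withr::local_tempdir()
  specPath <- file.path(dir, "spec.json")
  writeSyntheticSpec(syntheticSpec(phase1Rate = 0.2, phase2Rate = 15,
                                   baseColor = c(38, 10, 6),
                                   noiseSigma = 0.5, duration = 8,
                                   switchTime = 4, seed = 9L),
                     specPath)
  sim <- runSimulate(specPath, file.path(dir, "sim"))
  truth <- jsonlite::read_json(sim$truth, simplifyVector = TRUE)
  expect_equal(truth$expected$conventional_speed_pct_per_s, 0.2)
  expect_equal(truth$expected$enhancement_ratio, 75)

  cfg <- runConfig(sim$frames, centerX = truth$roi$center_x,
                   centerY = truth$roi$center_y, radius = truth$roi$radius,
                   windows = c(0, 4, 4, 8), channel = truth$spec$channel,
                   refWindowS = 1 / 25, outDir = file.path(dir, "out"),
                   writeVideos = FALSE)
  res <- runAnalysis(cfg)
  expect_equal(unname(speeds(res$fit)), c(0.2, 15), tolerance = 0.05)
})

test_that("malformed or inconsistent simulation specs are rejected", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.json")
  writeLines("{not json", bad)
  expect_error(runSimulate(bad, file.path(dir, "out")))

  incomplete <- file.path(dir, "incomplete.json")
  jsonlite::write_json(list(duration = 10), incomplete, auto_unbox = TRUE)
  expect_error(runSimulate(incomplete, file.path(dir, "out")), "missing")

  inconsistent <- file.path(dir, "inconsistent.json")
  jsonlite::write_json(list(duration = 10, phase1_rate = 0,
                            phase2_rate = 1, switch_time = 10),
                       inconsistent, auto_unbox = TRUE)
  expect_error(runSimulate(inconsistent, file.path(dir, "out")),
               "switchTime")
})

test_that("synthetic specs serialize to JSON and back unchanged", {
  spec <- syntheticSpec(phase1Rate = 0.022, phase2Rate = 21.7,
                        baseColor = c(5.55, 21.3, 28.8), channel = "B",
                        noiseSigma = 1.5, speckleDensity = 0.05,
                        seed = 77L)
  path <- withr::local_tempfile(fileext = ".json")
  writeSyntheticSpec(spec, path)
  back <- readSyntheticSpec(path)
  for (sl in slotNames("SyntheticSpec"))
    expect_equal(slot(back, sl), slot(spec, sl), label = sl)
})
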
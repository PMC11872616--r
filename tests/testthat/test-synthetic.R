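stdROI <- circularROI(23.5, 23.5, 15)  # the default spec's disk

analyzeSpec <- function(spec, roi = stdROI,
                        windows = phaseWindows(c(0, spec@switchTime),
                                               c(spec@switchTime,
                                                 spec@duration))) {
  v <- generateVideo(spec)
  s <- extractSeries(v, roi)
  analyzeExtraction(s, windows, channel = spec@channel,
                    refWindowS = 1 / spec@frameRate)
}

test_that("the ground-truth ramp is piecewise linear through the switch", {
  spec <- syntheticSpec(phase1Rate = 0.5, phase2Rate = 10, switchTime = 20,
                        duration = 30)
  expect_equal(expectedPercent(spec, 0), 100)
  expect_equal(expectedPercent(spec, 10), 105)
  expect_equal(expectedPercent(spec, 20), 110)            # continuous
  expect_equal(expectedPercent(spec, 25), 110 + 50)
  expect_equal(unname(expectedSpeeds(spec)), c(0.5, 10))
})

test_that("noiseless specs round-trip through the pipeline exactly", {
  spec <- syntheticSpec(phase1Rate = 0.2, phase2Rate = 15,
                        baseColor = c(38, 10, 6), noiseSigma = 0,
                        duration = 35)
  fit <- analyzeSpec(spec)
  expect_equal(fit@conventionalSpeed, 0.2, tolerance = 1e-9)
  expect_equal(fit@ultrasonicSpeed, 15, tolerance = 1e-9)
  # the in-ROI mean itself follows the ramp exactly
  v <- generateVideo(spec)
  s <- extractSeries(v, stdROI)
  pct <- 100 * s@rMean / s@rMean[1]
  expect_equal(pct, expectedPercent(spec, s@times), tolerance = 1e-9)
})

test_that("generation is bit-identical under a fixed seed and leaves the
           caller's RNG alone", {
  spec <- syntheticSpec(duration = 2, noiseSigma = 1.5,
                        speckleDensity = 0.3, switchTime = 1)
  set.seed(123)
  before <- .Random.seed
  v1 <- generateVideo(spec)
  expect_identical(.Random.seed, before)  # RNG state restored
  v2 <- generateVideo(spec)
  expect_identical(v1@frames, v2@frames)
  v3 <- generateVideo(syntheticSpec(duration = 2, noiseSigma = 1.5,
                                    speckleDensity = 0.3, switchTime = 1,
                                    seed = 2L))
  expect_false(identical(v1@frames, v3@frames))
})

test_that("rates that leave the 8-bit range raise a range warning", {
  spec <- syntheticSpec(phase1Rate = 0.2, phase2Rate = 15,
                        baseColor = c(160, 40, 20), noiseSigma = 0,
                        duration = 35)
  expect_warning(generateVideo(spec), "range warning")
  expect_silent(generateVideo(syntheticSpec(duration = 2, switchTime = 1,
                                            noiseSigma = 0)))
})

test_that("spec invariants are enforced", {
  expect_error(syntheticSpec(switchTime = 60, duration = 60),
               "switchTime")
  expect_error(syntheticSpec(switchTime = 0), "switchTime")
  expect_error(syntheticSpec(duration = 10), "switchTime")  # switch at 25
  expect_error(syntheticSpec(baseColor = c(300, 0, 0)), "baseColor")
  expect_error(syntheticSpec(noiseSigma = -1), "noiseSigma")
  expect_error(syntheticSpec(channel = "R", channelGain = c(0.5, 1, 1)),
               "designated channel")
})

test_that("a global illumination gain changes no reported speed", {
  spec <- syntheticSpec(phase1Rate = 0.2, phase2Rate = 15,
                        baseColor = c(38, 10, 6), noiseSigma = 0,
                        duration = 35)
  v <- generateVideo(spec)
  fit1 <- analyzeExtraction(extractSeries(v, stdROI),
                            phaseWindows(c(0, 25), c(25, 35)),
                            refWindowS = oneFrame())
  vg <- videoSequence(v@frames * 1.3, v@frameRate)  # clip-free by design
  fit2 <- analyzeExtraction(extractSeries(vg, stdROI),
                            phaseWindows(c(0, 25), c(25, 35)),
                            refWindowS = oneFrame())
  expect_lt(abs(fit1@conventionalSpeed - fit2@conventionalSpeed), 1e-9)
  expect_lt(abs(fit1@ultrasonicSpeed - fit2@ultrasonicSpeed), 1e-9)
})

test_that("the fixture battery carries usable ground truth", {
  suite <- fixtureSuite(101L)
  expect_setequal(names(suite), c("noiseless", "noisy", "flicker",
                                  "speckled", "zeroRate", "clippingEdge"))

  fitN <- analyzeSpec(suite$noiseless$spec)
  expect_lt(abs(fitN@conventionalSpeed - 0.2), suite$noiseless$tolerance)
  expect_lt(abs(fitN@ultrasonicSpeed - 15), suite$noiseless$tolerance)

  fitY <- analyzeSpec(suite$noisy$spec)
  expect_lt(abs(fitY@conventionalSpeed - 0.2), suite$noisy$tolerance)
  expect_lt(abs(fitY@ultrasonicSpeed - 15), suite$noisy$tolerance)

  fitZ <- analyzeSpec(suite$zeroRate$spec)
  expect_lt(abs(fitZ@conventionalSpeed), suite$zeroRate$tolerance)
  expect_lt(abs(fitZ@ultrasonicSpeed), suite$zeroRate$tolerance)

  expect_warning(generateVideo(suite$clippingEdge$spec), "range warning")
})

test_that("flicker with zero true rate leaves only a bounded artifact", {
  suite <- fixtureSuite(101L)
  spec <- suite$flicker$spec
  fit <- analyzeSpec(spec)
  expect_lt(abs(fit@conventionalSpeed), suite$flicker$tolerance)
  expect_lt(abs(fit@ultrasonicSpeed), suite$flicker$tolerance)

  # deterministic oracle: with zero rate and no noise the normalized series
  # is exactly 100 * flick(t) / flick(0), so the fitted slope must equal
  # the OLS slope of that known gain curve
  t <- (0:(25 * 60 - 1)) / 25
  flick <- 1 + spec@flickerAmplitude *
    sin(2 * pi * spec@flickerFrequency * t)
  pct <- 100 * flick / flick[1]
  sel <- t < 25
  want <- olsOracle(t[sel], pct[sel])
  expect_equal(fit@conventionalSpeed, want[["slope"]], tolerance = 1e-9)
})

test_that("speckles perturb only the ultrasonic phase", {
  suite <- fixtureSuite(101L)
  spS <- suite$speckled$spec
  spClean <- suite$noiseless$spec  # same rates, no speckle
  fitS <- analyzeSpec(spS)
  fitC <- analyzeSpec(spClean)
  # conventional frames carry no speckle and no noise: identical fit
  expect_equal(fitS@conventionalSpeed, fitC@conventionalSpeed,
               tolerance = 1e-12)
  # ultrasonic estimate survives the bright-speckle confounder
  expect_lt(abs(fitS@ultrasonicSpeed - 15), suite$speckled$tolerance)
})

test_that("candy stand-in specs encode the reference experiments", {
  for (candy in c("red", "green", "blue")) {
    spec <- candyExperimentSpec(candy, seed = 5L)
    expect_identical(spec@channel, channelForCandy(candy))
    # the designated channel stays inside 8 bits over the whole ramp
    i <- match(spec@channel, c("R", "G", "B"))
    maxPct <- expectedPercent(spec, spec@duration)
    expect_lt(spec@baseColor[i] * maxPct / 100, 255)
    expect_silent(generateVideo(candyExperimentSpec(candy, noiseSigma = 0,
                                                    seed = 5L)))
  }
  expect_equal(unname(expectedSpeeds(candyExperimentSpec("blue"))),
               c(0.022, 21.7))
})
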
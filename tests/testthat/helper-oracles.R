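# Independent oracles and small fixture builders used across the suite.

# A video of n identical frames of one uniform color.
uniformVideo <- function(color, n = 3, h = 16, w = 16, fps = 25) {
  fr <- array(rep(rep(color, each = h * w), n), dim = c(h, w, 3, n))
  videoSequence(fr, fps, source = "uniform-fixture")
}

# Closed-form two-pass OLS (the textbook formulas), independent of lm().
olsOracle <- function(t, y) {
  tb <- mean(t); yb <- mean(y)
  slope <- sum((t - tb) * (y - yb)) / sum((t - tb)^2)
  c(slope = slope, intercept = yb - slope * tb)
}

# Naive per-pixel loop average of one channel inside a mask grid.
loopMaskMean <- function(frame, grid, channel) {
  total <- 0; count <- 0
  for (r in seq_len(nrow(grid)))
    for (c in seq_len(ncol(grid)))
      if (grid[r, c] == 1L) {
        total <- total + frame[r, c, channel]
        count <- count + 1
      }
  total / count
}

# Brute-force disk membership count at integer pixel centers.
loopDiskArea <- function(cx, cy, radius, h, w) {
  count <- 0L
  for (y in 0:(h - 1))
    for (x in 0:(w - 1))
      if ((x - cx)^2 + (y - cy)^2 <= radius^2) count <- count + 1L
  count
}

# Assemble a ChannelTimeSeries directly from per-channel vectors.
makeSeries <- function(times, r, g, b) {
  new("ChannelTimeSeries", times = times, rMean = r, gMean = g, bMean = b,
      roi = circularROI(5, 5, 2), nPixels = 13L, source = "direct-fixture")
}

# Assemble a NormalizedSeries directly (reference is irrelevant to fits).
makeNorm <- function(times, r, g = rep(100, length(times)),
                     b = rep(100, length(times))) {
  new("NormalizedSeries", times = times, rPct = r, gPct = g, bPct = b,
      reference = referenceRGB(100, 100, 100))
}

# One frame interval: the reference window that reproduces a single-frame,
# exact time-zero reference.
oneFrame <- function(fps = 25) 1 / fps
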
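## Independent oracles and small fixture builders shared across tests.

## OLS slope via lm(), independent of the package's closed-form implementation
oracleSlope <- function(y) {
  x <- seq_along(y)
  unname(coef(lm(y ~ x))[2])
}

## brute-force max-slope window search: enumerate every admissible start with
## the lm() oracle; earliest start wins ties (within floating tolerance)
oracleBestStart <- function(values, windowLen, from = 1,
                            to = length(values) - windowLen + 1) {
  starts <- from:to
  slopes <- vapply(starts, function(s)
    oracleSlope(values[s:(s + windowLen - 1)]), numeric(1))
  starts[which(slopes >= max(slopes) - 1e-12)][1]
}

## TIC with a unique steepest 6-frame segment at a known start; the half-step
## entry keeps every window overlapping the plateau strictly shallower
rampTic <- function(n, rampStart, rampSlope = 2, base = 1, fps = 30) {
  v <- rep(base, n)
  idx <- rampStart:min(n, rampStart + 5)
  v[idx] <- base + rampSlope * (seq_along(idx) - 0.5)
  if (max(idx) < n) v[(max(idx) + 1):n] <- v[max(idx)]
  TIC(v, "combined", fps)
}

workedExamplePath <- function() {
  system.file("extdata", "worked_example_tic_synthetic.csv",
              package = "pulmoflow")
}

cohortPath <- function() {
  system.file("extdata", "flow_split_comparison.csv", package = "pulmoflow")
}

## small raw sequence: mask frame + per-frame pattern scaling
patternSequence <- function(nFrames = 12, h = 24, w = 24, fps = 30,
                            maskLevel = 100) {
  arr <- array(maskLevel, c(nFrames, h, w))
  FrameSequence(arr, frameRate = fps)
}
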
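test_that("gamma-variate curve: onset zero, normalized peak, smooth mass", {
  expect_equal(gammaVariate(0.5, 0.5, 3, 0.15, 10), 0)
  expect_equal(gammaVariate(0.2, 0.5, 3, 0.15, 10), 0)      # before onset
  expect_equal(gammaVariate(0.5 + 3 * 0.15, 0.5, 3, 0.15, 10), 10)
  # the peak is a maximum
  tt <- seq(0.5, 3, by = 1e-3)
  expect_lte(max(gammaVariate(tt, 0.5, 3, 0.15, 10)), 10 + 1e-9)
  expect_error(gammaVariate(1, 0, -1, 0.15, 1), class = "pulmoflow_input_error")

  # trapezoid integral on the analysis grid agrees with a 100x finer grid
  t1 <- seq(0, 4, by = 1 / 30)
  t2 <- seq(0, 4, by = 1 / 3000)
  trap <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  a1 <- trap(t1, gammaVariate(t1, 0.5, 3, 0.15, 10))
  a2 <- trap(t2, gammaVariate(t2, 0.5, 3, 0.15, 10))
  expect_lt(abs(a1 - a2) / a2, 1e-3)
})

test_that("TIC generation is deterministic under a seed", {
  sp <- syntheticSpec(trueRightPercent = 45, noiseSigma = 4, seed = 77)
  t1 <- generateTics(sp)
  t2 <- generateTics(sp)
  expect_identical(as.data.frame(t1$table), as.data.frame(t2$table))
  t3 <- generateTics(syntheticSpec(trueRightPercent = 45, noiseSigma = 4,
                                   seed = 78))
  expect_false(identical(as.data.frame(t1$table), as.data.frame(t3$table)))
  # generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(generateTics(sp)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("50:50 with zero delay and noise gives identical sides", {
  sim <- generateTics(syntheticSpec(trueRightPercent = 50, sideDelay = 0,
                                    noiseSigma = 0))
  df <- as.data.frame(sim$table)
  expect_identical(df$right, df$left)
})

test_that("noise-free closed-loop recovery matches the truth within 1 point", {
  for (p in c(30, 45, 60, 70)) {
    sim <- generateTics(syntheticSpec(trueRightPercent = p, nFrames = 45,
                                      noiseSigma = 0))
    res <- analyzeFlowSplit(sim$table)
    expect_lte(abs(ratioPercent(res)["right"] - p), 1)
    expect_equal(sim$truth$true_right_percent, p)
  }
})

test_that("recovered split is invariant to amplitude, baseline and phase", {
  base <- analyzeFlowSplit(generateTics(syntheticSpec(
    trueRightPercent = 65, nFrames = 45, noiseSigma = 0))$table)
  amp <- analyzeFlowSplit(generateTics(syntheticSpec(
    trueRightPercent = 65, nFrames = 45, noiseSigma = 0,
    amplitude = 1000))$table)
  expect_equal(ratioPercent(amp), ratioPercent(base))

  # with synchronous sides the cardiac modulation scales both curves alike,
  # so the recovered split is unchanged by it
  puls <- analyzeFlowSplit(generateTics(syntheticSpec(
    trueRightPercent = 65, nFrames = 45, noiseSigma = 0, sideDelay = 0,
    pulsatilityDepth = 0.2))$table)
  noPuls <- analyzeFlowSplit(generateTics(syntheticSpec(
    trueRightPercent = 65, nFrames = 45, noiseSigma = 0, sideDelay = 0))$table)
  expect_equal(ratioPercent(puls), ratioPercent(noPuls))

  hiBase <- renderFrames(syntheticSpec(trueRightPercent = 65, imageSize = 64,
                                       nFrames = 45, noiseSigma = 0,
                                       baselineLevel = 2000))
  loBase <- renderFrames(syntheticSpec(trueRightPercent = 65, imageSize = 64,
                                       nFrames = 45, noiseSigma = 0,
                                       baselineLevel = 400))
  expect_equal(ratioPercent(analyzeFlowSplit(hiBase$sequence)),
               ratioPercent(analyzeFlowSplit(loBase$sequence)))
})

test_that("rendered frames keep the central gap at baseline", {
  sim <- renderFrames(syntheticSpec(trueRightPercent = 60, imageSize = 64,
                                    nFrames = 40, noiseSigma = 0))
  arr <- frames(sim$sequence)
  rois <- defaultRois(64, 64)
  gapCols <- (rois$right@x2 + 1):(rois$left@x1 - 1)
  gap <- arr[, , gapCols]
  expect_equal(max(gap), min(gap))        # constant over time and space
})

test_that("rendered frames drive the full pipeline back to the truth", {
  sim <- renderFrames(syntheticSpec(trueRightPercent = 60, imageSize = 96,
                                    nFrames = 45, noiseSigma = 0))
  res <- analyzeFlowSplit(sim$sequence)
  expect_equal(unname(ratioRounded(res)), c(60L, 40L))
})
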
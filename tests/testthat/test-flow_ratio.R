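test_that("ratio arithmetic: shares, rounding, scale invariance, guards", {
  r <- computeRatio(0.009824, 0.014666)
  expect_equal(r$right, 100 * 0.009824 / (0.009824 + 0.014666))
  expect_equal(r$rightRounded, 40L)
  expect_equal(r$leftRounded, 60L)

  expect_equal(computeRatio(1, 1)$right, 50)
  expect_equal(computeRatio(7.3, 7.3)$rightRounded, 50L)
  expect_equal(computeRatio(3, 1)$right, 75)
  expect_equal(computeRatio(3, 1)$left, 25)

  base <- computeRatio(0.4, 0.6)
  for (k in c(1e-6, 0.5, 3, 1e6)) {
    scaled <- computeRatio(k * 0.4, k * 0.6)
    expect_equal(scaled$right, base$right)
    expect_equal(scaled$rightRounded, base$rightRounded)
  }

  expect_error(computeRatio(-0.1, 0.2), class = "pulmoflow_algorithm_error")
  expect_error(computeRatio(0.1, 0), class = "pulmoflow_algorithm_error")

  # rounded pair always sums to 100, with round-half-up on the right share
  expect_equal(computeRatio(40.5, 59.5)$rightRounded, 41L)  # 40.5 rounds up
  expect_equal(computeRatio(40.5, 59.5)$leftRounded, 59L)
})

test_that("end-to-end recovery of a 60:40 split at zero noise", {
  sim <- renderFrames(syntheticSpec(trueRightPercent = 60, imageSize = 96,
                                    nFrames = 45, noiseSigma = 0))
  res <- analyzeFlowSplit(sim$sequence)
  expect_lte(abs(ratioPercent(res)["right"] - 60), 1)
  expect_equal(sum(ratioRounded(res)), 100L)
})

test_that("a perfectly symmetric sequence yields exactly 50:50", {
  sim <- renderFrames(syntheticSpec(trueRightPercent = 50, sideDelay = 0,
                                    imageSize = 96, nFrames = 45,
                                    noiseSigma = 0))
  res <- analyzeFlowSplit(sim$sequence)
  expect_equal(unname(ratioPercent(res)["right"]), 50)
  expect_equal(unname(ratioRounded(res)), c(50L, 50L))
})

test_that("contrast in one lung only errors, or warns when configured", {
  sim <- generateTics(syntheticSpec(trueRightPercent = 50, nFrames = 45,
                                    noiseSigma = 0, sideDelay = 0))
  tab <- sim$table
  silent <- TICTable(tab@frameNumbers, rep(0, nFrames(tab)),
                     as.data.frame(tab)$left, frameRate(tab))
  expect_error(analyzeFlowSplit(silent), class = "pulmoflow_algorithm_error")
  res <- analyzeFlowSplit(silent, nonpositiveSlope = "warn")
  expect_true(any(grepl("non-positive slope", res@warnings)))
  expect_true(is.na(res@rightPercent))
})

test_that("identical right/left columns give 50:50 with identical windows", {
  v <- ticValues(rampTic(30, 15))
  tab <- TICTable(1:30, v, v, 30)
  res <- analyzeFlowSplit(tab)
  expect_equal(unname(ratioPercent(res)), c(50, 50))
  expect_equal(windowStart(res@rightWindow), windowStart(res@leftWindow))
})

test_that("a 6-frame table admits exactly one window everywhere", {
  tab <- TICTable(1:6, c(0, 1, 3, 6, 10, 15), c(0, 2, 4, 6, 8, 10), 30)
  res <- analyzeFlowSplit(tab)
  expect_equal(windowStart(res@representativeWindow), 1L)
  expect_equal(windowStart(res@rightWindow), 1L)
  expect_equal(windowStart(res@leftWindow), 1L)
  expect_error(analyzeFlowSplit(TICTable(1:5, 1:5, 1:5, 30)),
               class = "pulmoflow_input_error")
})

test_that("same input and config give bit-identical result JSON", {
  tab <- loadTicTable(workedExamplePath(), frameRate = 30)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeResult(analyzeFlowSplit(tab), f1)
  writeResult(analyzeFlowSplit(tab), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pipeline errors identify the failing stage", {
  seq <- patternSequence()      # mask equals every frame
  err <- tryCatch(analyzeFlowSplit(seq), error = function(e) e)
  expect_match(conditionMessage(err), "^\\[tic_extraction\\]")
})
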
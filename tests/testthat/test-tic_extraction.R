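test_that("default ROIs are exact at the 1024 reference scale", {
  rois <- defaultRois(1024, 1024)
  expect_equal(c(rois$right@x1, rois$right@y1, rois$right@x2, rois$right@y2),
               c(9L, 103L, 358L, 922L))
  expect_equal(c(rois$left@x1, rois$left@y1, rois$left@x2, rois$left@y2),
               c(665L, 103L, 1014L, 922L))
  expect_equal(roiWidth(rois$right), 350L)
  expect_equal(roiHeight(rois$right), 820L)
  expect_equal(roiWidth(rois$left), 350L)
  # central gap excludes the pulmonary trunk: 665 - 358 - 1 columns
  expect_gte(rois$left@x1 - rois$right@x2 - 1L, 306L)
})

test_that("ROIs scale proportionally with round-half-up at other sizes", {
  rois <- defaultRois(512, 512)
  expect_equal(c(rois$right@x1, rois$right@y1, rois$right@x2, rois$right@y2),
               c(5L, 52L, 179L, 461L))
  expect_equal(c(rois$left@x1, rois$left@y1, rois$left@x2, rois$left@y2),
               c(333L, 52L, 507L, 461L))
  expect_error(defaultRois(8, 8), class = "pulmoflow_input_error")
  # never overlap after rounding, over a spread of sizes
  for (s in c(17, 31, 64, 100, 256, 640, 1000, 2048)) {
    r <- defaultRois(s, s)
    expect_gt(r$left@x1, r$right@x2)
  }
})

test_that("mask subtraction is linear and zeroes the mask frame", {
  h <- 24; w <- 24
  mask <- matrix(100, h, w)
  pattern <- matrix(runif(h * w), h, w)
  arr <- array(NA_real_, c(10, h, w))
  for (t in 1:10) arr[t, , ] <- mask + (t - 1) * pattern
  seq <- FrameSequence(arr, frameRate = 30)
  sub <- subtractMask(seq, "contrast_positive")
  expect_equal(frames(sub)[1, , ], matrix(0, h, w))
  for (t in c(2, 5, 10))
    expect_equal(frames(sub)[t, , ], (t - 1) * pattern)
})

test_that("subtracting a constant sequence is rejected", {
  seq <- patternSequence()
  expect_error(subtractMask(seq), class = "pulmoflow_input_error")
})

test_that("auto polarity flips attenuation-style input so the TIC rises", {
  # X-ray transmission falls where contrast arrives
  sim <- renderFrames(syntheticSpec(trueRightPercent = 55, imageSize = 64,
                                    nFrames = 40, noiseSigma = 0))
  sub <- subtractMask(sim$sequence, "auto")
  expect_equal(sub@polarity, "contrast_negative")
  rois <- defaultRois(64, 64)
  comb <- combineTics(extractTic(sub, rois$right, "right"),
                      extractTic(sub, rois$left, "left"))
  v <- ticValues(comb)
  expect_gt(max(v), 0)                     # enhancement is positive
  expect_gt(v[which.max(abs(v))], 0)       # net change at extremum positive
})

test_that("extractTic averages the ROI and is linear in pixel values", {
  h <- 20; w <- 20
  arr <- array(0, c(6, h, w))
  arr[2, , ] <- 5                                 # constant subtracted frame
  seq <- FrameSequence(arr, frameRate = 30)
  seq@subtracted <- TRUE
  roi <- ROIRect(3, 3, 10, 12)
  tic <- extractTic(seq, roi, "right")
  expect_equal(ticValues(tic)[1], 5)              # frame #1 post injection
  expect_equal(ticValues(tic)[2:5], rep(0, 4))

  onePx <- ROIRect(4, 7, 4, 7)
  arr2 <- array(rnorm(6 * h * w), c(6, h, w))
  s2 <- FrameSequence(arr2, frameRate = 30); s2@subtracted <- TRUE
  expect_equal(ticValues(extractTic(s2, onePx, "left")),
               arr2[2:6, 7, 4])                   # that pixel's time course

  # linearity: extract(a*S1 + b*S2) = a*extract(S1) + b*extract(S2)
  arr3 <- array(rnorm(6 * h * w), c(6, h, w))
  s3 <- FrameSequence(arr3, frameRate = 30); s3@subtracted <- TRUE
  sMix <- FrameSequence(2 * arr2 - 3 * arr3, frameRate = 30)
  sMix@subtracted <- TRUE
  expect_equal(ticValues(extractTic(sMix, roi, "combined")),
               2 * ticValues(extractTic(s2, roi, "combined")) -
               3 * ticValues(extractTic(s3, roi, "combined")))
})

test_that("combined TIC is the frame-wise mean and equals the pooled mean", {
  r <- TIC(c(0, 2), "right", 30)
  l <- TIC(c(2, 0), "left", 30)
  expect_equal(ticValues(combineTics(r, l)), c(1, 1))
  expect_equal(ticValues(combineTics(r, r)), ticValues(r))
  expect_error(combineTics(r, TIC(c(1, 2, 3), "left", 30)),
               class = "pulmoflow_input_error")

  # equal-area ROIs: mean of the two ROI means = pooled-pixel mean
  sim <- renderFrames(syntheticSpec(trueRightPercent = 65, imageSize = 64,
                                    nFrames = 40, noiseSigma = 2, seed = 11))
  sub <- subtractMask(sim$sequence, "auto")
  rois <- defaultRois(64, 64)
  expect_equal(roiWidth(rois$right) * roiHeight(rois$right),
               roiWidth(rois$left) * roiHeight(rois$left))
  comb <- combineTics(extractTic(sub, rois$right, "right"),
                      extractTic(sub, rois$left, "left"))
  nPost <- dim(frames(sub))[1] - injectionFrame(sub)
  pool <- vapply(seq_len(nPost), function(k) {
    fr <- frames(sub)[injectionFrame(sub) + k, , ]
    mean(c(fr[rois$right@y1:rois$right@y2, rois$right@x1:rois$right@x2],
           fr[rois$left@y1:rois$left@y2, rois$left@x1:rois$left@x2]))
  }, numeric(1))
  expect_equal(ticValues(comb), pool)
})

test_that("extracted TIC tracks the true kinetics on noise-free frames", {
  sp <- syntheticSpec(trueRightPercent = 60, imageSize = 96, nFrames = 40,
                      noiseSigma = 0, sideDelay = 0)
  sim <- renderFrames(sp)
  truthTab <- generateTics(sp)$table
  sub <- subtractMask(sim$sequence, "auto")
  rois <- defaultRois(96, 96)
  ticR <- extractTic(sub, rois$right, "right")
  expect_gt(cor(ticValues(ticR), as.data.frame(truthTab)$right), 0.99)
})
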
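test_that("window slope matches the closed form and the lm oracle", {
  tic <- TIC(c(0, 1, 2, 3, 4, 5), "combined", 30)
  expect_equal(windowSlope(tic, 1, 6), 1.0)
  expect_equal(windowSlope(TIC(rep(3.2, 10), "right", 30), 2, 6), 0)
  # hand case: y = 0,0,0,1,2,3 -> Sum(x-xbar)(y-ybar)/Sum(x-xbar)^2 = 11/17.5
  expect_equal(windowSlope(TIC(c(0, 0, 0, 1, 2, 3), "left", 30), 1, 6),
               11 / 17.5)
  set.seed(42)
  for (i in 1:20) {
    v <- cumsum(rnorm(30))
    s <- sample(1:25, 1)
    expect_equal(windowSlope(TIC(v, "combined", 30), s, 6),
                 oracleSlope(v[s:(s + 5)]), tolerance = 1e-12)
  }
  expect_error(windowSlope(tic, 3, 6), class = "pulmoflow_input_error")
})

test_that("two-point slope variant is the endpoint net increase", {
  v <- c(1, 9, 2, 8, 3, 11)
  expect_equal(windowSlope(TIC(v, "right", 30), 1, 6, method = "two_point"),
               (11 - 1) / 5)
})

test_that("representative window finds the unique steepest segment", {
  tic <- rampTic(40, rampStart = 18, rampSlope = 3)
  w <- findRepresentativeWindow(tic)
  expect_equal(windowStart(w), 18L)
  expect_equal(windowLength(w), 6L)
  expect_equal(fittedSlope(w), 3)
  expect_equal(side(w), "combined")
})

test_that("ties break to the earliest window", {
  # two identical slope-1 ramps (entry step 0.5 keeps neighbours shallower)
  v <- rep(0, 40)
  v[5] <- 0.5; v[6:10] <- v[5] + 1:5
  v[11:19] <- v[10]
  v[20] <- v[19] + 0.5; v[21:25] <- v[20] + 1:5
  v[26:40] <- v[25]
  tic <- TIC(v, "combined", 30)
  expect_equal(fittedSlope(findRepresentativeWindow(tic)), 1)
  expect_equal(windowStart(findRepresentativeWindow(tic)), 5L)

  lin <- TIC(seq(0, 39), "right", 30)       # equal slope everywhere
  w <- optimizeSideWindow(lin, c(17L, 30L))
  expect_equal(windowStart(w), 17L)
})

test_that("candidate range extends by 4 frames each side and clamps", {
  cfg <- windowConfig(30)
  rep21 <- new("TimeWindow", start = 21L, len = 6L, slope = 1, side = "combined")
  r <- candidateRange(rep21, cfg, 40)
  expect_equal(as.integer(r), c(17L, 30L))
  expect_false(attr(r, "clamped"))

  rep3 <- new("TimeWindow", start = 3L, len = 6L, slope = 1, side = "combined")
  r2 <- candidateRange(rep3, cfg, 40)
  expect_equal(as.integer(r2), c(1L, 12L))
  expect_true(attr(r2, "clamped"))

  cfg0 <- windowConfig(30, extension = 0)
  r3 <- candidateRange(rep21, cfg0, 40)
  expect_equal(as.integer(r3), c(21L, 26L))
})

test_that("both searches agree with brute-force enumeration", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(8:60, 1)
    v <- cumsum(rnorm(n)) + rnorm(n)
    tic <- TIC(v, "combined", 30)
    w <- findRepresentativeWindow(tic)
    expect_equal(windowStart(w), oracleBestStart(v, 6))
    cand <- candidateRange(w, windowConfig(30), n)
    ws <- optimizeSideWindow(TIC(v, "right", 30), cand)
    expect_equal(windowStart(ws),
                 oracleBestStart(v, 6, from = cand[1], to = cand[2] - 5))
  }
})

test_that("window choice is shift-invariant; scaling scales slopes only", {
  set.seed(5)
  v <- cumsum(abs(rnorm(35)))
  base <- findRepresentativeWindow(TIC(v, "combined", 30))
  shifted <- findRepresentativeWindow(TIC(v + 123.4, "combined", 30))
  scaled <- findRepresentativeWindow(TIC(3.7 * v, "combined", 30))
  expect_equal(windowStart(shifted), windowStart(base))
  expect_equal(fittedSlope(shifted), fittedSlope(base))
  expect_equal(windowStart(scaled), windowStart(base))
  expect_equal(fittedSlope(scaled), 3.7 * fittedSlope(base))
})

test_that("a per-side onset delay shifts that side's window by about d", {
  for (d in 1:3) {
    sim <- generateTics(syntheticSpec(trueRightPercent = 50, nFrames = 45,
                                      sideDelay = d / 30, noiseSigma = 0))
    res <- analyzeFlowSplit(sim$table)
    shift <- windowStart(res@rightWindow) - windowStart(res@leftWindow)
    expect_lte(abs(shift - d), 1)
  }
})

test_that("window length and extension scale with frame rate", {
  cfg30 <- windowConfig(30)
  expect_equal(cfg30@windowLen, 6L)
  expect_equal(cfg30@extension, 4L)
  cfg15 <- windowConfig(15)
  expect_equal(cfg15@windowLen, 3L)
  expect_equal(cfg15@extension, 2L)
  cfg60 <- windowConfig(60)          # capped at 6 frames (200 ms)
  expect_equal(cfg60@windowLen, 6L)
  expect_equal(cfg60@extension, 8L)
})
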
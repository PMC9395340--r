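#' Gamma-variate first-pass enhancement curve
#'
#' The canonical indicator-dilution model of a contrast bolus: zero before
#' onset, a single peak after. Parameterized so the peak value is exactly
#' \code{A}, reached at \code{t = t0 + alpha * tau}:
#' \deqn{c(t) = A ((t - t0) / (\alpha\tau))^\alpha e^{\alpha - (t - t0)/\tau}}
#'
#' @param t time, seconds (vectorized).
#' @param t0 onset time, seconds.
#' @param alpha shape (> 0).
#' @param tau time scale, seconds (> 0).
#' @param A peak amplitude, intensity units (> 0).
#' @return Enhancement at \code{t} (same length as \code{t}).
#' @examples
#' gammaVariate(0.5, 0.5, 3, 0.15, 10)            # 0 at onset
#' gammaVariate(0.5 + 3 * 0.15, 0.5, 3, 0.15, 10) # 10 at the peak
#' @export
gammaVariate <- function(t, t0, alpha, tau, A) {
  if (alpha <= 0 || tau <= 0 || A <= 0)
    pfInputError("synthetic_angio", "alpha, tau and A must be positive")
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- A * (dt[pos] / (alpha * tau))^alpha * exp(alpha - dt[pos] / tau)
  out
}

.sideCurves <- function(spec) {
  t <- seq_len(spec@nFrames) / spec@frameRate       # frame k acquired k/fps after injection
  onR <- spec@onsetTime + if (spec@delayedSide == "right") spec@sideDelay else 0
  onL <- spec@onsetTime + if (spec@delayedSide == "left") spec@sideDelay else 0
  aR <- spec@amplitude * spec@trueRightPercent / 100
  aL <- spec@amplitude * (100 - spec@trueRightPercent) / 100
  r <- gammaVariate(t, onR, spec@gammaShape, spec@gammaScale, aR)
  l <- gammaVariate(t, onL, spec@gammaShape, spec@gammaScale, aL)
  if (spec@pulsatilityDepth > 0) {
    mod <- 1 + spec@pulsatilityDepth * sin(2 * pi * spec@heartRate / 60 * t)
    r <- r * mod
    l <- l * mod
  }
  list(t = t, right = r, left = l)
}

.truthRecord <- function(spec) {
  list(true_right_percent = spec@trueRightPercent,
       true_left_percent = 100 - spec@trueRightPercent,
       frame_rate = spec@frameRate, n_frames = spec@nFrames,
       onset_time_s = spec@onsetTime, side_delay_s = spec@sideDelay,
       delayed_side = spec@delayedSide, gamma_shape = spec@gammaShape,
       gamma_scale_s = spec@gammaScale, amplitude = spec@amplitude,
       pulsatility_depth = spec@pulsatilityDepth, heart_rate_bpm = spec@heartRate,
       noise_sigma = spec@noiseSigma, seed = spec@seed)
}

#' Simulate right/left TICs with known ground truth
#'
#' Per-side gamma-variate enhancement whose amplitudes carry the true split
#' (right amplitude proportional to \code{trueRightPercent}), one side delayed
#' by \code{sideDelay} seconds, optional multiplicative cardiac pulsatility,
#' and additive zero-mean Gaussian noise drawn from the spec's seed (the
#' caller's RNG state is untouched).
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return List with \code{table} (a \linkS4class{TICTable}) and \code{truth}
#'   (named list of all generating parameters).
#' @examples
#' sim <- generateTics(syntheticSpec(trueRightPercent = 60, noiseSigma = 0))
#' ratioRounded(analyzeFlowSplit(sim$table))
#' @export
generateTics <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  cur <- .sideCurves(spec)
  r <- cur$right
  l <- cur$left
  if (spec@noiseSigma > 0) {
    noise <- withSeed(spec@seed,
                      rnorm(2L * spec@nFrames, sd = spec@noiseSigma))
    r <- r + noise[seq_len(spec@nFrames)]
    l <- l + noise[spec@nFrames + seq_len(spec@nFrames)]
  }
  list(table = TICTable(seq_len(spec@nFrames), r, l, spec@frameRate),
       truth = .truthRecord(spec))
}

.ellipseMask <- function(size, roi) {
  cx <- (roi@x1 + roi@x2) / 2
  cy <- (roi@y1 + roi@y2) / 2
  ax <- 0.45 * roiWidth(roi)
  ay <- 0.45 * roiHeight(roi)
  x <- matrix(rep(seq_len(size), each = size), nrow = size)   # column index
  y <- matrix(rep(seq_len(size), times = size), nrow = size)  # row index
  ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
}

#' Render a synthetic two-lung angiography frame sequence
#'
#' Frames contain two elliptical lung fields centered in the default right and
#' left ROIs with a central band left at baseline (the pulmonary trunk /
#' catheter stand-in). Lung pixel intensities *decrease* with the side's
#' enhancement (X-ray attenuation convention), exercising the pipeline's
#' polarity auto-detection. \code{preFrames} baseline frames precede
#' injection; frame 0 is the mask. Pixels get additive Gaussian noise, then
#' are rounded to integers and clamped to [0, 65535] so the sequence
#' round-trips exactly through TIFF and DICOM.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return List with \code{sequence} (a \linkS4class{FrameSequence}) and
#'   \code{truth} (generating parameters).
#' @export
renderFrames <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  size <- spec@imageSize
  rois <- defaultRois(size, size)
  if (spec@baselineLevel < spec@amplitude)
    pfInputError("synthetic_angio",
      "baselineLevel must be >= amplitude so attenuated pixels stay non-negative")
  mR <- .ellipseMask(size, rois$right)
  mL <- .ellipseMask(size, rois$left)
  cur <- .sideCurves(spec)
  nTotal <- spec@preFrames + spec@nFrames
  arr <- array(spec@baselineLevel, c(nTotal, size, size))
  for (k in seq_len(spec@nFrames)) {
    fr <- matrix(spec@baselineLevel, size, size)
    fr[mR] <- fr[mR] - cur$right[k]
    fr[mL] <- fr[mL] - cur$left[k]
    arr[spec@preFrames + k, , ] <- fr
  }
  if (spec@noiseSigma > 0) {
    arr <- arr + withSeed(spec@seed,
                          array(rnorm(length(arr), sd = spec@noiseSigma),
                                dim(arr)))
  }
  arr <- pmin(pmax(round(arr), 0), 65535)
  seq <- FrameSequence(arr, frameRate = spec@frameRate,
                       injectionFrame = spec@preFrames, maskFrame = 0L,
                       sourceId = sprintf("synthetic[%g:%g,seed=%d]",
                                          spec@trueRightPercent,
                                          100 - spec@trueRightPercent,
                                          spec@seed))
  list(sequence = seq, truth = .truthRecord(spec))
}
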
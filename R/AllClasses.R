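#' FrameSequence: a time-ordered stack of grayscale angiography frames
#'
#' Container for a dynamic acquisition: a \code{time x height x width} array
#' of pixel intensities plus the acquisition metadata the analysis needs.
#' Frame indices are 0-based internally; all *reported* frame numbers are
#' 1-based relative to the injection frame, so that frame #1 is the first
#' frame acquired after contrast injection.
#'
#' @slot frames numeric array, \code{time x height x width}.
#' @slot frameRate frames per second (> 0).
#' @slot injectionFrame 0-based index of the first frame after contrast
#'   injection.
#' @slot maskFrame 0-based index of the pre-injection baseline (mask) frame;
#'   must precede \code{injectionFrame}.
#' @slot sourceId free-text provenance label.
#' @slot subtracted \code{TRUE} once the mask has been subtracted (values may
#'   then be signed).
#' @slot polarity \code{"none"} before subtraction, afterwards the sign
#'   convention applied (\code{"contrast_positive"} or
#'   \code{"contrast_negative"}).
#' @exportClass FrameSequence
setClass("FrameSequence",
  representation(
    frames = "array", frameRate = "numeric",
    injectionFrame = "integer", maskFrame = "integer",
    sourceId = "character", subtracted = "logical", polarity = "character"
  ),
  prototype(subtracted = FALSE, polarity = "none", sourceId = "")
)

setValidity("FrameSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-D array (time x height x width)")
  if (d[1] < 2L) return("sequence must contain at least 2 frames")
  if (!all(is.finite(object@frames))) return("frames contain non-finite values")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0) return("frameRate must be a single positive number")
  if (object@maskFrame < 0L || object@maskFrame >= d[1]) return("maskFrame out of range")
  if (object@injectionFrame <= object@maskFrame ||
      object@injectionFrame >= d[1]) {
    return("injectionFrame must lie after maskFrame and inside the sequence")
  }
  TRUE
})

#' Construct a FrameSequence
#'
#' @param frames numeric 3-D array, time x height x width.
#' @param frameRate frames per second.
#' @param injectionFrame 0-based index of the first post-injection frame;
#'   defaults to \code{maskFrame + 1}.
#' @param maskFrame 0-based index of the baseline frame (default 0).
#' @param sourceId provenance label.
#' @return A \linkS4class{FrameSequence}.
#' @examples
#' fs <- FrameSequence(array(0:23, c(4, 3, 2)), frameRate = 30)
#' nFrames(fs)
#' @export
FrameSequence <- function(frames, frameRate, injectionFrame = maskFrame + 1L,
                          maskFrame = 0L, sourceId = "") {
  new("FrameSequence",
      frames = frames, frameRate = as.numeric(frameRate),
      injectionFrame = as.integer(injectionFrame),
      maskFrame = as.integer(maskFrame), sourceId = sourceId)
}

#' TIC: time-signal intensity curve for one region
#'
#' Per-frame mean subtracted intensity of one region of interest, starting at
#' frame #1 (the first frame after contrast injection).
#'
#' @slot values numeric vector of per-frame mean subtracted intensities.
#' @slot side one of \code{"right"}, \code{"left"}, \code{"combined"}.
#' @slot frameRate frames per second.
#' @slot firstFrameNumber 1-based frame number of \code{values[1]} relative to
#'   injection (normally 1).
#' @exportClass TIC
setClass("TIC",
  representation(values = "numeric", side = "character",
                 frameRate = "numeric", firstFrameNumber = "integer"),
  prototype(firstFrameNumber = 1L)
)

setValidity("TIC", function(object) {
  if (!all(is.finite(object@values))) return("TIC values must be finite")
  if (!object@side %in% c("right", "left", "combined"))
    return("side must be right, left or combined")
  if (object@frameRate <= 0) return("frameRate must be positive")
  if (object@firstFrameNumber < 1L) return("firstFrameNumber must be >= 1")
  TRUE
})

#' Construct a TIC
#' @param values numeric vector of mean subtracted intensities per frame.
#' @param side \code{"right"}, \code{"left"} or \code{"combined"}.
#' @param frameRate frames per second.
#' @param firstFrameNumber 1-based frame number of the first value (default 1).
#' @return A \linkS4class{TIC}.
#' @export
TIC <- function(values, side, frameRate, firstFrameNumber = 1L) {
  new("TIC", values = as.numeric(values), side = side,
      frameRate = as.numeric(frameRate),
      firstFrameNumber = as.integer(firstFrameNumber))
}

#' TICTable: paired right/left time-signal intensity curves
#'
#' The tabular form of a two-lung acquisition: consecutive 1-based frame
#' numbers (frame #1 = first frame after injection) with the right- and
#' left-lung mean subtracted intensities.
#'
#' @slot frameNumbers strictly consecutive integers starting at 1.
#' @slot right,left numeric vectors of equal length.
#' @slot frameRate frames per second.
#' @exportClass TICTable
setClass("TICTable",
  representation(frameNumbers = "integer", right = "numeric",
                 left = "numeric", frameRate = "numeric")
)

setValidity("TICTable", function(object) {
  n <- length(object@frameNumbers)
  if (length(object@right) != n || length(object@left) != n)
    return("frame, right and left columns must have equal length")
  if (n == 0L) return("table is empty")
  if (object@frameNumbers[1] != 1L ||
      (n > 1L && any(diff(object@frameNumbers) != 1L)))
    return("frame numbers must be consecutive integers starting at 1")
  if (!all(is.finite(object@right)) || !all(is.finite(object@left)))
    return("intensity values must be finite numbers")
  if (object@frameRate <= 0) return("frameRate must be positive")
  TRUE
})

#' Construct a TICTable
#' @param frameNumbers consecutive 1-based frame numbers.
#' @param right,left per-frame mean intensities for each lung.
#' @param frameRate frames per second.
#' @return A \linkS4class{TICTable}.
#' @export
TICTable <- function(frameNumbers, right, left, frameRate) {
  new("TICTable", frameNumbers = as.integer(frameNumbers),
      right = as.numeric(right), left = as.numeric(left),
      frameRate = as.numeric(frameRate))
}

#' ROIRect: rectangular region of interest
#'
#' Pixel coordinates are 1-based and inclusive, origin at the top-left corner,
#' x rightward and y downward; a rectangle (9, 103, 358, 922) therefore has
#' width 358 - 9 + 1 = 350 and height 922 - 103 + 1 = 820.
#'
#' @slot x1,y1,x2,y2 integer corner coordinates with x1 <= x2, y1 <= y2.
#' @exportClass ROIRect
setClass("ROIRect",
  representation(x1 = "integer", y1 = "integer", x2 = "integer", y2 = "integer"))

setValidity("ROIRect", function(object) {
  if (object@x1 < 1L || object@y1 < 1L) return("coordinates are 1-based")
  if (object@x1 > object@x2 || object@y1 > object@y2)
    return("need x1 <= x2 and y1 <= y2")
  TRUE
})

#' Construct an ROIRect
#' @param x1,y1,x2,y2 1-based inclusive pixel coordinates.
#' @return An \linkS4class{ROIRect}.
#' @examples
#' roiWidth(ROIRect(9, 103, 358, 922))  # 350
#' @export
ROIRect <- function(x1, y1, x2, y2) {
  new("ROIRect", x1 = as.integer(x1), y1 = as.integer(y1),
      x2 = as.integer(x2), y2 = as.integer(y2))
}

#' TimeWindow: a contiguous frame window with its fitted slope
#'
#' @slot start 1-based frame number (relative to injection) of the first frame
#'   in the window.
#' @slot len window length in frames.
#' @slot slope ordinary least-squares slope over the window, in intensity
#'   units per frame.
#' @slot side \code{"right"}, \code{"left"} or \code{"combined"}.
#' @exportClass TimeWindow
setClass("TimeWindow",
  representation(start = "integer", len = "integer",
                 slope = "numeric", side = "character"))

setValidity("TimeWindow", function(object) {
  if (object@len < 2L) return("window length must be >= 2 frames")
  if (object@start < 1L) return("window start must be >= 1")
  TRUE
})

#' WindowConfig: parameters of the two-stage time-window search
#'
#' Defaults reproduce a 30 frames/s acquisition: a 6-frame (200 ms) window,
#' extended by 4 frames on each side into a 14-frame candidate range. At other
#' frame rates the defaults scale to keep the same durations:
#' \code{windowLen = min(6, max(2, round(0.2 * fps)))} and
#' \code{extension = round(4 * fps / 30)}.
#'
#' @slot windowLen window length in frames (>= 2).
#' @slot extension frames added on each side of the representative window.
#' @slot searchStart first frame number considered by the stage-1 search.
#' @slot slopeMethod \code{"ols"} (six-point linear fit, default) or
#'   \code{"two_point"} (net increase between window endpoints, the older
#'   manual-method variant).
#' @exportClass WindowConfig
setClass("WindowConfig",
  representation(windowLen = "integer", extension = "integer",
                 searchStart = "integer", slopeMethod = "character"))

setValidity("WindowConfig", function(object) {
  if (object@windowLen < 2L) return("windowLen must be >= 2")
  if (object@extension < 0L) return("extension must be >= 0")
  if (object@searchStart < 1L) return("searchStart must be >= 1")
  if (!object@slopeMethod %in% c("ols", "two_point"))
    return("slopeMethod must be 'ols' or 'two_point'")
  TRUE
})

#' Construct a WindowConfig
#'
#' @param frameRate frames per second; used only to derive defaults.
#' @param windowLen window length in frames; default derived from
#'   \code{frameRate} (6 at 30 fps).
#' @param extension frames added on each side of the representative window;
#'   default derived from \code{frameRate} (4 at 30 fps).
#' @param searchStart first frame number searched in stage 1 (default 1).
#' @param slopeMethod \code{"ols"} or \code{"two_point"}.
#' @return A \linkS4class{WindowConfig}.
#' @examples
#' windowConfig(30)   # 6-frame window, 4-frame extension
#' windowConfig(15)   # 3-frame window, 2-frame extension
#' @export
windowConfig <- function(frameRate = 30, windowLen = NULL, extension = NULL,
                         searchStart = 1L, slopeMethod = "ols") {
  if (is.null(windowLen))
    windowLen <- min(6, max(2, roundHalfUp(0.2 * frameRate)))
  if (is.null(extension))
    extension <- roundHalfUp(4 * frameRate / 30)
  new("WindowConfig", windowLen = as.integer(windowLen),
      extension = as.integer(extension), searchStart = as.integer(searchStart),
      slopeMethod = slopeMethod)
}

#' AnalysisResult: full output of the flow-split pipeline
#'
#' Carries every intermediate the operator may want to audit: the selected
#' windows, fitted slopes, the flow split (full precision and integer-rounded,
#' rounded halves summing to 100 by construction), the extracted curves, the
#' configuration echo and any warnings raised along the way.
#'
#' @slot representativeWindow,rightWindow,leftWindow \linkS4class{TimeWindow}.
#' @slot rightSlope,leftSlope fitted slopes, intensity units per frame.
#' @slot rightPercent,leftPercent flow split at full precision.
#' @slot rightPercentRounded,leftPercentRounded integer split (sums to 100).
#' @slot tics named list of the right, left and combined \linkS4class{TIC}s.
#' @slot config named list echoing the analysis configuration.
#' @slot warnings character vector of pipeline warnings.
#' @exportClass AnalysisResult
setClass("AnalysisResult",
  representation(
    representativeWindow = "TimeWindow", rightWindow = "TimeWindow",
    leftWindow = "TimeWindow", rightSlope = "numeric", leftSlope = "numeric",
    rightPercent = "numeric", leftPercent = "numeric",
    rightPercentRounded = "integer", leftPercentRounded = "integer",
    tics = "list", config = "list", warnings = "character"
  )
)

#' ComparisonResult: agreement statistics against a reference modality
#'
#' @slot fitSlope,fitIntercept OLS fit of the angiographic right share on the
#'   reference right share.
#' @slot pearsonR Pearson correlation coefficient.
#' @slot rmsePaired root-mean-square of the paired differences
#'   (angiography minus reference).
#' @slot rmseResidual root-mean-square of the regression residuals (divisor n).
#' @slot nPatients number of paired observations.
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(fitSlope = "numeric", fitIntercept = "numeric",
                 pearsonR = "numeric", rmsePaired = "numeric",
                 rmseResidual = "numeric", nPatients = "integer"))

#' WindowSummary: per-cohort timing summary of the selected windows
#'
#' @slot meanStartTime mean first-point time of all per-side windows, seconds
#'   after injection.
#' @slot meanSideDiffFrames,maxSideDiffFrames mean and maximum of the absolute
#'   right-left difference in window start, in frames.
#' @slot meanSideDiffSeconds the mean difference converted to seconds.
#' @exportClass WindowSummary
setClass("WindowSummary",
  representation(meanStartTime = "numeric", meanSideDiffFrames = "numeric",
                 maxSideDiffFrames = "numeric", meanSideDiffSeconds = "numeric"))

#' SyntheticSpec: parameters of the synthetic two-lung angiography simulator
#'
#' The simulator emulates first-pass contrast transit through both lungs:
#' per-side gamma-variate enhancement curves whose amplitudes carry the true
#' flow split, a small onset delay on one side, optional cardiac pulsatility,
#' additive Gaussian noise, and (for frame rendering) two elliptical lung
#' fields separated by a central band left at baseline.
#'
#' @slot trueRightPercent ground-truth right share of flow, percent
#'   (0 < p < 100).
#' @slot frameRate frames per second (default 30).
#' @slot nFrames number of post-injection frames.
#' @slot onsetTime seconds from injection to contrast arrival on the earlier
#'   side (default 0.5 s, the second cardiac cycle at a pediatric heart rate).
#' @slot sideDelay extra onset delay of \code{delayedSide}, seconds (0-0.2;
#'   observed inter-side differences are up to about 0.1 s).
#' @slot delayedSide \code{"right"} or \code{"left"}.
#' @slot gammaShape,gammaScale gamma-variate shape (alpha, default 3) and time
#'   scale (tau, seconds, default 0.15).
#' @slot amplitude total peak enhancement, intensity units (split between the
#'   sides according to \code{trueRightPercent}).
#' @slot pulsatilityDepth fractional depth of sinusoidal cardiac modulation
#'   (0-1, default 0).
#' @slot heartRate beats per minute for the modulation (default 120,
#'   pediatric).
#' @slot noiseSigma standard deviation of additive Gaussian noise, intensity
#'   units.
#' @slot imageSize rendered frame side length in pixels (default 256).
#' @slot baselineLevel pre-contrast pixel intensity of rendered frames.
#' @slot preFrames rendered pre-injection frames (the first is the mask).
#' @slot seed integer seed for all simulator randomness.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    trueRightPercent = "numeric", frameRate = "numeric", nFrames = "integer",
    onsetTime = "numeric", sideDelay = "numeric", delayedSide = "character",
    gammaShape = "numeric", gammaScale = "numeric", amplitude = "numeric",
    pulsatilityDepth = "numeric", heartRate = "numeric", noiseSigma = "numeric",
    imageSize = "integer", baselineLevel = "numeric", preFrames = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  if (object@trueRightPercent <= 0 || object@trueRightPercent >= 100)
    return("trueRightPercent must be strictly between 0 and 100")
  if (object@frameRate <= 0) return("frameRate must be positive")
  if (object@sideDelay < 0 || object@sideDelay > 0.2)
    return("sideDelay must be within [0, 0.2] seconds")
  if (!object@delayedSide %in% c("right", "left"))
    return("delayedSide must be 'right' or 'left'")
  if (object@gammaShape <= 0 || object@gammaScale <= 0 || object@amplitude <= 0)
    return("gammaShape, gammaScale and amplitude must be positive")
  if (object@pulsatilityDepth < 0 || object@pulsatilityDepth >= 1)
    return("pulsatilityDepth must be in [0, 1)")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  onsetFrames <- ceiling((object@onsetTime + object@sideDelay) * object@frameRate)
  if (object@nFrames < onsetFrames + 14L)
    return("nFrames must be at least the onset frame count + 14")
  if (object@imageSize < 32L) return("imageSize must be >= 32 pixels")
  if (object@baselineLevel < 0) return("baselineLevel must be >= 0")
  if (object@preFrames < 1L) return("preFrames must be >= 1 (mask frame)")
  TRUE
})

#' Construct a SyntheticSpec
#'
#' @param trueRightPercent ground-truth right share (percent).
#' @param frameRate,nFrames acquisition grid (default 30 fps, 60 frames).
#' @param onsetTime,sideDelay,delayedSide contrast arrival timing (seconds).
#' @param gammaShape,gammaScale,amplitude gamma-variate kinetics.
#' @param pulsatilityDepth,heartRate cardiac modulation.
#' @param noiseSigma additive Gaussian noise SD (intensity units).
#' @param imageSize,baselineLevel,preFrames frame-rendering geometry.
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @examples
#' sp <- syntheticSpec(trueRightPercent = 60, noiseSigma = 0)
#' @export
syntheticSpec <- function(trueRightPercent = 55, frameRate = 30, nFrames = 60,
                          onsetTime = 0.5, sideDelay = 0.1,
                          delayedSide = "right", gammaShape = 3,
                          gammaScale = 0.15, amplitude = 100,
                          pulsatilityDepth = 0, heartRate = 120,
                          noiseSigma = 0, imageSize = 256,
                          baselineLevel = 400, preFrames = 3, seed = 1) {
  new("SyntheticSpec",
      trueRightPercent = trueRightPercent, frameRate = frameRate,
      nFrames = as.integer(nFrames), onsetTime = onsetTime,
      sideDelay = sideDelay, delayedSide = delayedSide,
      gammaShape = gammaShape, gammaScale = gammaScale, amplitude = amplitude,
      pulsatilityDepth = pulsatilityDepth, heartRate = heartRate,
      noiseSigma = noiseSigma, imageSize = as.integer(imageSize),
      baselineLevel = baselineLevel, preFrames = as.integer(preFrames),
      seed = as.integer(seed))
}
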
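#' Accessors for pulmoflow classes
#'
#' Small accessor generics so user code never touches slots directly.
#' \code{frames} returns the pixel array of a \linkS4class{FrameSequence};
#' \code{frameRate}, \code{injectionFrame} (0-based), \code{maskFrame}
#' (0-based), \code{nFrames} and \code{sourceId} return its metadata.
#' \code{ticValues} and \code{side} read a \linkS4class{TIC};
#' \code{windowStart}, \code{windowLength}, \code{windowFrames} and
#' \code{fittedSlope} read a \linkS4class{TimeWindow}; \code{roiWidth} and
#' \code{roiHeight} read an \linkS4class{ROIRect}; \code{ratioPercent} and
#' \code{ratioRounded} return the named \code{c(right=, left=)} split of an
#' \linkS4class{AnalysisResult}.
#'
#' @param x the object.
#' @return The slot value (see above).
#' @name accessors
NULL

#' @rdname accessors
setMethod("frames", "FrameSequence", function(x) x@frames)
#' @rdname accessors
setMethod("frameRate", "FrameSequence", function(x) x@frameRate)
#' @rdname accessors
setMethod("frameRate", "TIC", function(x) x@frameRate)
#' @rdname accessors
setMethod("frameRate", "TICTable", function(x) x@frameRate)
#' @rdname accessors
setMethod("injectionFrame", "FrameSequence", function(x) x@injectionFrame)
#' @rdname accessors
setMethod("maskFrame", "FrameSequence", function(x) x@maskFrame)
#' @rdname accessors
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[1])
#' @rdname accessors
setMethod("nFrames", "TICTable", function(x) length(x@frameNumbers))
#' @rdname accessors
setMethod("sourceId", "FrameSequence", function(x) x@sourceId)
#' @rdname accessors
setMethod("ticValues", "TIC", function(x) x@values)
#' @rdname accessors
setMethod("side", "TIC", function(x) x@side)
#' @rdname accessors
setMethod("side", "TimeWindow", function(x) x@side)
#' @rdname accessors
setMethod("windowStart", "TimeWindow", function(x) x@start)
#' @rdname accessors
setMethod("windowLength", "TimeWindow", function(x) x@len)
#' @rdname accessors
setMethod("windowFrames", "TimeWindow",
          function(x) seq.int(x@start, x@start + x@len - 1L))
#' @rdname accessors
setMethod("fittedSlope", "TimeWindow", function(x) x@slope)
#' @rdname accessors
setMethod("roiWidth", "ROIRect", function(x) x@x2 - x@x1 + 1L)
#' @rdname accessors
setMethod("roiHeight", "ROIRect", function(x) x@y2 - x@y1 + 1L)
#' @rdname accessors
setMethod("ratioPercent", "AnalysisResult",
          function(x) c(right = x@rightPercent, left = x@leftPercent))
#' @rdname accessors
setMethod("ratioRounded", "AnalysisResult",
          function(x) c(right = x@rightPercentRounded, left = x@leftPercentRounded))

#' Coerce a TICTable to a data.frame
#' @param x a \linkS4class{TICTable}.
#' @param ... ignored.
#' @return data.frame with columns \code{frame}, \code{right}, \code{left}.
#' @export
setMethod("as.data.frame", "TICTable", function(x, ...) {
  data.frame(frame = x@frameNumbers, right = x@right, left = x@left)
})

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d @ %.3g fps\n",
              d[1], d[2], d[3], object@frameRate))
  cat(sprintf("  mask frame %d, injection frame %d (0-based)%s\n",
              object@maskFrame, object@injectionFrame,
              if (object@subtracted)
                sprintf(", mask-subtracted (%s)", object@polarity) else ""))
  if (nzchar(object@sourceId)) cat("  source:", object@sourceId, "\n")
})

setMethod("show", "TIC", function(object) {
  cat(sprintf("TIC (%s): %d frames @ %.3g fps, first frame #%d, range [%.4g, %.4g]\n",
              object@side, length(object@values), object@frameRate,
              object@firstFrameNumber, min(object@values), max(object@values)))
})

setMethod("show", "TICTable", function(object) {
  cat(sprintf("TICTable: frames 1-%d @ %.3g fps\n",
              length(object@frameNumbers), object@frameRate))
})

setMethod("show", "ROIRect", function(object) {
  cat(sprintf("ROIRect (%d, %d, %d, %d), %d x %d px\n",
              object@x1, object@y1, object@x2, object@y2,
              roiWidth(object), roiHeight(object)))
})

setMethod("show", "TimeWindow", function(object) {
  cat(sprintf("TimeWindow (%s): frames %d-%d, slope %.6g /frame\n",
              object@side, object@start, object@start + object@len - 1L,
              object@slope))
})

setMethod("show", "AnalysisResult", function(object) {
  cat("Flow-split analysis\n")
  cat(sprintf("  representative window: frames %d-%d (combined TIC)\n",
              object@representativeWindow@start,
              object@representativeWindow@start + object@representativeWindow@len - 1L))
  cat(sprintf("  right window: frames %d-%d, slope %.6g\n",
              object@rightWindow@start,
              object@rightWindow@start + object@rightWindow@len - 1L,
              object@rightSlope))
  cat(sprintf("  left  window: frames %d-%d, slope %.6g\n",
              object@leftWindow@start,
              object@leftWindow@start + object@leftWindow@len - 1L,
              object@leftSlope))
  cat(sprintf("  right:left = %d:%d  (%.4f : %.4f)\n",
              object@rightPercentRounded, object@leftPercentRounded,
              object@rightPercent, object@leftPercent))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("Agreement over %d patients: slope %.4f, intercept %.4f, r %.4f\n",
              object@nPatients, object@fitSlope, object@fitIntercept,
              object@pearsonR))
  cat(sprintf("  RMSE paired %.4f, regression-residual %.4f\n",
              object@rmsePaired, object@rmseResidual))
})

setMethod("show", "WindowSummary", function(object) {
  cat(sprintf("Window timing: mean start %.3f s; right-left start diff mean %.2f frames (%.3f s), max %g frames\n",
              object@meanStartTime, object@meanSideDiffFrames,
              object@meanSideDiffSeconds, object@maxSideDiffFrames))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: true split %g:%g, %d frames @ %g fps, onset %g s (+%g s %s), noise sd %g, seed %d\n",
              object@trueRightPercent, 100 - object@trueRightPercent,
              object@nFrames, object@frameRate, object@onsetTime,
              object@sideDelay, object@delayedSide, object@noiseSigma,
              object@seed))
})
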
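#' Analyze a sequence or TIC table into a flow split
#'
#' Runs the full pipeline: (for frame input) mask subtraction, fixed ROI
#' placement and TIC extraction; then the two-stage time-window optimization
#' and the slope-ratio flow split. See \code{\link{computeRatio}} for the
#' final step and \linkS4class{AnalysisResult} for the output.
#'
#' @param x a \linkS4class{FrameSequence} or \linkS4class{TICTable}.
#' @param config a \linkS4class{WindowConfig}; defaults to
#'   \code{windowConfig(frameRate(x))}.
#' @param ... method-specific arguments: for frame input, \code{polarity}
#'   (\code{"auto"}, \code{"contrast_positive"}, \code{"contrast_negative"}),
#'   \code{rois} (optional list with elements \code{right} and \code{left} of
#'   \linkS4class{ROIRect}, overriding \code{\link{defaultRois}}); for both,
#'   \code{nonpositiveSlope} (\code{"error"} or \code{"warn"}).
#' @return An \linkS4class{AnalysisResult}.
#' @examples
#' tab <- loadTicTable(system.file("extdata", "worked_example_tic_synthetic.csv",
#'                                 package = "pulmoflow"), frameRate = 30)
#' res <- analyzeFlowSplit(tab)
#' ratioRounded(res)
#' @export
setGeneric("analyzeFlowSplit", function(x, config = NULL, ...)
  standardGeneric("analyzeFlowSplit"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("injectionFrame", function(x) standardGeneric("injectionFrame"))
#' @rdname accessors
#' @export
setGeneric("maskFrame", function(x) standardGeneric("maskFrame"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("ticValues", function(x) standardGeneric("ticValues"))
#' @rdname accessors
#' @export
setGeneric("side", function(x) standardGeneric("side"))
#' @rdname accessors
#' @export
setGeneric("windowStart", function(x) standardGeneric("windowStart"))
#' @rdname accessors
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))
#' @rdname accessors
#' @export
setGeneric("windowFrames", function(x) standardGeneric("windowFrames"))
#' @rdname accessors
#' @export
setGeneric("fittedSlope", function(x) standardGeneric("fittedSlope"))
#' @rdname accessors
#' @export
setGeneric("roiWidth", function(x) standardGeneric("roiWidth"))
#' @rdname accessors
#' @export
setGeneric("roiHeight", function(x) standardGeneric("roiHeight"))
#' @rdname accessors
#' @export
setGeneric("ratioPercent", function(x) standardGeneric("ratioPercent"))
#' @rdname accessors
#' @export
setGeneric("ratioRounded", function(x) standardGeneric("ratioRounded"))
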
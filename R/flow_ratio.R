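#' Flow split from the two per-side slopes
#'
#' The right share of pulmonary blood flow is the right slope's share of the
#' slope sum, \code{100 * sR / (sR + sL)}; the left share is its complement.
#' The integer report rounds the right share half up and derives the left
#' share as \code{100 - right}, so the rounded pair always sums to 100.
#'
#' @param rightSlope,leftSlope fitted slopes over the optimized windows; both
#'   must be strictly positive (a non-positive slope signals failed contrast
#'   detection or wrong polarity, not zero flow).
#' @return Named list: \code{right}, \code{left} (full precision, percent),
#'   \code{rightRounded}, \code{leftRounded} (integers summing to 100).
#' @examples
#' computeRatio(0.009824, 0.014666)$rightRounded   # 40
#' computeRatio(3, 1)$right                        # 75
#' @export
computeRatio <- function(rightSlope, leftSlope) {
  if (!is.finite(rightSlope) || !is.finite(leftSlope) ||
      rightSlope <= 0 || leftSlope <= 0)
    pfAlgorithmError("flow_ratio", sprintf(
      "non-positive slope (right %.6g, left %.6g): contrast not detected or wrong polarity",
      rightSlope, leftSlope))
  right <- 100 * rightSlope / (rightSlope + leftSlope)
  rr <- as.integer(roundHalfUp(right))
  list(right = right, left = 100 - right,
       rightRounded = rr, leftRounded = 100L - rr)
}

## shared tail of the pipeline: combined curve -> windows -> slopes -> ratio
.analyzeTics <- function(tics, config, nonpositiveSlope, extraConfig,
                         warnings = character()) {
  combined <- tics$combined
  n <- length(combined@values)
  if (n < config@windowLen)
    pfInputError("flow_ratio", sprintf(
      "only %d post-injection frames; need at least %d for one window",
      n, config@windowLen))

  rep <- findRepresentativeWindow(combined, config)
  cand <- candidateRange(rep, config, n)
  if (isTRUE(attr(cand, "clamped")))
    warnings <- c(warnings, sprintf(
      "candidate range clamped to frames %d-%d at the sequence edge",
      cand[1], cand[2]))

  wR <- optimizeSideWindow(tics$right, cand, config)
  wL <- optimizeSideWindow(tics$left, cand, config)

  for (w in list(right = wR, left = wL)) {
    starts <- seq.int(cand[1], cand[2] - config@windowLen + 1L)
    if (length(starts) > 1L) {
      tic <- tics[[w@side]]
      slopes <- vapply(starts, function(s)
        windowSlope(tic, s, config@windowLen, config@slopeMethod), numeric(1))
      top2 <- sort(slopes, decreasing = TRUE)[1:2]
      if (is.finite(top2[1]) && top2[1] > 0 &&
          (top2[1] - top2[2]) / abs(top2[1]) < 0.01)
        warnings <- c(warnings, sprintf(
          "near-tie window selection on the %s side (runner-up slope within 1%%)",
          w@side))
    }
  }

  if ((wR@slope <= 0 || wL@slope <= 0) && nonpositiveSlope == "warn") {
    warnings <- c(warnings, sprintf(
      "non-positive slope (right %.6g, left %.6g); ratio not computed",
      wR@slope, wL@slope))
    ratio <- list(right = NA_real_, left = NA_real_,
                  rightRounded = NA_integer_, leftRounded = NA_integer_)
  } else {
    ratio <- computeRatio(wR@slope, wL@slope)
  }

  cfg <- c(list(window_len = config@windowLen, extension = config@extension,
                search_start = config@searchStart,
                slope_method = config@slopeMethod,
                frame_rate = frameRate(combined)), extraConfig)
  new("AnalysisResult",
      representativeWindow = rep, rightWindow = wR, leftWindow = wL,
      rightSlope = wR@slope, leftSlope = wL@slope,
      rightPercent = ratio$right, leftPercent = ratio$left,
      rightPercentRounded = ratio$rightRounded,
      leftPercentRounded = ratio$leftRounded,
      tics = tics, config = cfg, warnings = warnings)
}

#' @describeIn analyzeFlowSplit Full pipeline on an image sequence: mask
#'   subtraction, default (or overridden) ROI placement, TIC extraction, then
#'   the window optimization and slope ratio.
#' @param polarity passed to \code{\link{subtractMask}} (default
#'   \code{"auto"}).
#' @param rois optional list(right=, left=) of \linkS4class{ROIRect} overriding
#'   \code{\link{defaultRois}}.
#' @param nonpositiveSlope \code{"error"} (default) or \code{"warn"}.
#' @export
setMethod("analyzeFlowSplit", "FrameSequence",
  function(x, config = NULL, polarity = "auto", rois = NULL,
           nonpositiveSlope = c("error", "warn")) {
    nonpositiveSlope <- match.arg(nonpositiveSlope)
    if (is.null(config)) config <- windowConfig(frameRate(x))
    d <- dim(frames(x))
    nPost <- d[1] - x@injectionFrame
    if (nPost < config@windowLen)
      pfInputError("flow_ratio", sprintf(
        "only %d post-injection frames; need at least %d", nPost,
        config@windowLen))
    warnings <- character()
    sub <- subtractMask(x, polarity)
    if (polarity == "auto" && sub@polarity == "contrast_negative")
      warnings <- c(warnings,
        "polarity auto-resolved to contrast_negative (attenuation input)")
    if (is.null(rois)) rois <- defaultRois(d[3], d[2])
    tics <- list(right = extractTic(sub, rois$right, "right"),
                 left = extractTic(sub, rois$left, "left"))
    tics$combined <- combineTics(tics$right, tics$left)
    extra <- list(
      input = "frames", source_id = sourceId(x), polarity = sub@polarity,
      roi_right = c(rois$right@x1, rois$right@y1, rois$right@x2, rois$right@y2),
      roi_left = c(rois$left@x1, rois$left@y1, rois$left@x2, rois$left@y2),
      mask_frame = maskFrame(x), injection_frame = injectionFrame(x))
    .analyzeTics(tics, config, nonpositiveSlope, extra, warnings)
  })

#' @describeIn analyzeFlowSplit Same pipeline starting from pre-extracted
#'   right/left TICs (the combined curve onward).
#' @export
setMethod("analyzeFlowSplit", "TICTable",
  function(x, config = NULL, nonpositiveSlope = c("error", "warn")) {
    nonpositiveSlope <- match.arg(nonpositiveSlope)
    if (is.null(config)) config <- windowConfig(frameRate(x))
    .analyzeTics(ticsFromTable(x), config, nonpositiveSlope,
                 list(input = "tic_table"))
  })
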
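## Reference ROI geometry, fixed for all cases at the 1024 x 1024 matrix:
## both rectangles are 350 x 820 px, flush with the lateral image borders,
## leaving a 306-column central gap that excludes the pulmonary trunk and
## catheter tip. On an AP projection the patient's right lung is on the
## image-left side.
.REF_DIM <- 1024L
.REF_RIGHT <- c(9L, 103L, 358L, 922L)
.REF_LEFT  <- c(665L, 103L, 1014L, 922L)

.scaleCoord <- function(coord, dimPx) {
  pmin(pmax(roundHalfUp(coord * dimPx / .REF_DIM), 1L), dimPx)
}

#' Default right/left lung ROIs for an image size
#'
#' At the reference 1024 x 1024 matrix the rectangles are exactly
#' right = (9, 103, 358, 922) and left = (665, 103, 1014, 922) in 1-based
#' inclusive coordinates. For other sizes every coordinate is scaled
#' proportionally (coordinate x dim / 1024, rounded half up, clamped to the
#' image); if rounding would make the rectangles touch or overlap, the left
#' ROI's x1 is raised.
#'
#' @param width,height image dimensions in pixels (>= 16 each).
#' @return A list with \linkS4class{ROIRect} elements \code{right} and
#'   \code{left}.
#' @examples
#' defaultRois(1024, 1024)$right   # (9, 103, 358, 922)
#' defaultRois(512, 512)$left      # (333, 52, 507, 461)
#' @export
defaultRois <- function(width, height) {
  if (width < 16L || height < 16L)
    pfInputError("tic_extraction", "image too small to place two lung ROIs")
  if (width == .REF_DIM && height == .REF_DIM) {
    return(list(right = do.call(ROIRect, as.list(.REF_RIGHT)),
                left  = do.call(ROIRect, as.list(.REF_LEFT))))
  }
  sx <- function(v) .scaleCoord(v, width)
  sy <- function(v) .scaleCoord(v, height)
  r <- c(sx(.REF_RIGHT[1]), sy(.REF_RIGHT[2]), sx(.REF_RIGHT[3]), sy(.REF_RIGHT[4]))
  l <- c(sx(.REF_LEFT[1]),  sy(.REF_LEFT[2]),  sx(.REF_LEFT[3]),  sy(.REF_LEFT[4]))
  if (l[1] <= r[3]) l[1] <- r[3] + 1L
  if (l[1] > l[3] || r[1] > r[3] || r[2] > r[4])
    pfInputError("tic_extraction",
      "image too small to host two non-overlapping scaled ROIs")
  list(right = do.call(ROIRect, as.list(r)), left = do.call(ROIRect, as.list(l)))
}

.roiMeanSeries <- function(arr, roi) {
  sub <- arr[, roi@y1:roi@y2, roi@x1:roi@x2, drop = FALSE]
  apply(sub, 1L, mean)
}

#' Subtract the pre-injection mask frame
#'
#' Replaces every frame by \code{sign * (frame - mask)}. With
#' \code{polarity = "auto"} the sign is chosen so that contrast arrival makes
#' the combined lung signal rise: the pooled right+left ROI difference curve is
#' examined post-injection and the sign of its largest-magnitude net change is
#' taken. Raw X-ray transmission falls where contrast arrives, so attenuation
#' inputs auto-resolve to \code{"contrast_negative"} (sign -1); pre-inverted
#' exports resolve to \code{"contrast_positive"}.
#'
#' @param seq a \linkS4class{FrameSequence} (not yet subtracted).
#' @param polarity \code{"auto"}, \code{"contrast_positive"} or
#'   \code{"contrast_negative"}.
#' @return A \linkS4class{FrameSequence} with signed subtracted values, the
#'   mask frame identically zero, and \code{polarity} recording the sign used.
#' @export
subtractMask <- function(seq, polarity = c("auto", "contrast_positive",
                                           "contrast_negative")) {
  stopifnot(is(seq, "FrameSequence"))
  polarity <- match.arg(polarity)
  arr <- frames(seq)
  mask <- arr[seq@maskFrame + 1L, , ]
  diffArr <- sweep(arr, c(2, 3), mask, "-")
  if (max(abs(diffArr)) == 0)
    pfInputError("tic_extraction",
      "mask equals every frame (all-zero difference); wrong input?")
  if (polarity == "auto") {
    rois <- defaultRois(dim(arr)[3], dim(arr)[2])
    post <- seq(seq@injectionFrame + 1L, dim(arr)[1])
    comb <- (.roiMeanSeries(diffArr[post, , , drop = FALSE], rois$right) +
             .roiMeanSeries(diffArr[post, , , drop = FALSE], rois$left)) / 2
    extremum <- comb[which.max(abs(comb))]
    if (extremum == 0)
      pfAlgorithmError("tic_extraction",
        "combined ROI difference is identically zero; cannot resolve polarity")
    polarity <- if (extremum > 0) "contrast_positive" else "contrast_negative"
  }
  sgn <- if (polarity == "contrast_positive") 1 else -1
  out <- seq
  out@frames <- sgn * diffArr
  out@subtracted <- TRUE
  out@polarity <- polarity
  out
}

#' Extract the time-signal intensity curve of one ROI
#'
#' Averages all pixels of the ROI in every post-injection frame of a
#' mask-subtracted sequence. \code{ticValues(tic)[k]} is the mean subtracted
#' intensity of frame #k (the k-th frame after injection).
#'
#' @param seq a mask-subtracted \linkS4class{FrameSequence}
#'   (see \code{\link{subtractMask}}).
#' @param roi an \linkS4class{ROIRect} inside the image.
#' @param side \code{"right"}, \code{"left"} or \code{"combined"}.
#' @return A \linkS4class{TIC} with \code{firstFrameNumber = 1}.
#' @export
extractTic <- function(seq, roi, side) {
  stopifnot(is(seq, "FrameSequence"), is(roi, "ROIRect"))
  if (!seq@subtracted)
    pfInputError("tic_extraction", "extractTic needs a mask-subtracted sequence")
  d <- dim(frames(seq))
  if (roi@x2 > d[3] || roi@y2 > d[2])
    pfInputError("tic_extraction", "ROI extends outside the image")
  post <- seq(seq@injectionFrame + 1L, d[1])
  TIC(.roiMeanSeries(frames(seq)[post, , , drop = FALSE], roi),
      side = side, frameRate = frameRate(seq), firstFrameNumber = 1L)
}

#' Average the right and left TICs into the combined curve
#'
#' The combined curve, \code{(right + left) / 2} frame by frame, anchors the
#' stage-1 window search: a steep combined slope requires simultaneous inflow
#' to both lungs, which skips the poorly mixed first cardiac cycle.
#'
#' @param right,left \linkS4class{TIC}s of equal length, frame rate and first
#'   frame number.
#' @return The combined \linkS4class{TIC}.
#' @export
combineTics <- function(right, left) {
  stopifnot(is(right, "TIC"), is(left, "TIC"))
  if (length(right@values) != length(left@values))
    pfInputError("tic_extraction", "right and left TIC lengths differ")
  if (right@frameRate != left@frameRate ||
      right@firstFrameNumber != left@firstFrameNumber)
    pfInputError("tic_extraction", "right and left TIC grids differ")
  TIC((right@values + left@values) / 2, side = "combined",
      frameRate = right@frameRate, firstFrameNumber = right@firstFrameNumber)
}

#' Split a TICTable into its right, left and combined TICs
#' @param table a \linkS4class{TICTable}.
#' @return A named list of \linkS4class{TIC}s: \code{right}, \code{left},
#'   \code{combined}.
#' @export
ticsFromTable <- function(table) {
  stopifnot(is(table, "TICTable"))
  r <- TIC(table@right, "right", table@frameRate)
  l <- TIC(table@left, "left", table@frameRate)
  list(right = r, left = l, combined = combineTics(r, l))
}
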
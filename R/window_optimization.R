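## Two-stage time-window optimization. Stage 1 finds the representative
## window of maximum slope on the combined curve; stage 2 extends it into a
## candidate range and re-optimizes each side independently, absorbing the
## small (up to ~100 ms) right-left difference in contrast arrival.

.olsSlope <- function(y) {
  x <- seq_along(y)
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc * xc)
}

.twoPointSlope <- function(y) (y[length(y)] - y[1]) / (length(y) - 1)

.slopeFun <- function(method) {
  if (method == "two_point") .twoPointSlope else .olsSlope
}

## exhaustive search over window starts; returns the earliest maximum and the
## gap to the runner-up (for near-tie warnings)
.searchWindow <- function(values, starts, windowLen, method = "ols") {
  f <- .slopeFun(method)
  slopes <- vapply(starts, function(s) f(values[s:(s + windowLen - 1L)]),
                   numeric(1))
  best <- which.max(slopes)              # earliest index on exact ties
  runnerGap <- if (length(slopes) > 1L) {
    top2 <- sort(slopes, decreasing = TRUE)[1:2]
    top2[1] - top2[2]
  } else Inf
  list(start = starts[best], slope = slopes[best], runnerGap = runnerGap,
       slopes = slopes)
}

#' Slope of a TIC over one time window
#'
#' Ordinary least-squares slope of intensity against frame index over all
#' points of the window, in intensity units per frame (the estimator used both
#' to rank windows and to compute the final flow split).
#'
#' @param tic a \linkS4class{TIC}.
#' @param startFrameNumber 1-based first frame of the window (relative to
#'   injection).
#' @param length window length in frames (>= 2).
#' @param method \code{"ols"} (default) or \code{"two_point"} (net increase
#'   between the endpoints divided by the span).
#' @return The slope (numeric scalar).
#' @examples
#' tic <- TIC(c(0, 1, 2, 3, 4, 5), "combined", 30)
#' windowSlope(tic, 1, 6)   # 1
#' @export
windowSlope <- function(tic, startFrameNumber, length, method = "ols") {
  stopifnot(is(tic, "TIC"))
  if (length < 2L)
    pfInputError("window_optimization", "window length must be >= 2")
  i0 <- startFrameNumber - tic@firstFrameNumber + 1L
  i1 <- i0 + length - 1L
  if (i0 < 1L || i1 > base::length(tic@values))
    pfInputError("window_optimization", sprintf(
      "window %d-%d outside the TIC range", startFrameNumber,
      startFrameNumber + length - 1L))
  .slopeFun(method)(tic@values[i0:i1])
}

#' Stage 1: representative window on the combined TIC
#'
#' Exhaustively evaluates every contiguous window of \code{config@windowLen}
#' frames starting at or after \code{config@searchStart} and returns the one
#' with maximum slope; exact ties go to the earliest start.
#'
#' @param combined the combined \linkS4class{TIC}.
#' @param config a \linkS4class{WindowConfig}.
#' @return A \linkS4class{TimeWindow} with side \code{"combined"}.
#' @export
findRepresentativeWindow <- function(combined, config = windowConfig(frameRate(combined))) {
  stopifnot(is(combined, "TIC"), is(config, "WindowConfig"))
  n <- length(combined@values)
  wl <- config@windowLen
  lastStart <- combined@firstFrameNumber + n - wl
  if (lastStart < config@searchStart)
    pfInputError("window_optimization", sprintf(
      "TIC too short (%d frames) for a %d-frame window", n, wl))
  starts <- seq.int(max(config@searchStart, combined@firstFrameNumber), lastStart)
  idx <- starts - combined@firstFrameNumber + 1L
  hit <- .searchWindow(combined@values, idx, wl, method = config@slopeMethod)
  new("TimeWindow", start = starts[match(hit$start, idx)], len = wl,
      slope = hit$slope, side = "combined")
}

#' Candidate range around the representative window
#'
#' Extends the representative window by \code{config@extension} frames on each
#' side (default 4, giving a 14-frame range at the 6-frame default), clamped
#' to the TIC's frame range. Clamping is reported via the \code{"clamped"}
#' attribute so the caller can surface it as a warning.
#'
#' @param rep the representative \linkS4class{TimeWindow}.
#' @param config a \linkS4class{WindowConfig}.
#' @param ticLength number of frames in the TIC.
#' @return Integer vector \code{c(first, last)} of 1-based frame numbers, with
#'   attribute \code{clamped} (logical).
#' @examples
#' w <- new("TimeWindow", start = 21L, len = 6L, slope = 1, side = "combined")
#' candidateRange(w, windowConfig(30), 40)   # 17 30
#' @export
candidateRange <- function(rep, config, ticLength) {
  stopifnot(is(rep, "TimeWindow"), is(config, "WindowConfig"))
  lo <- rep@start - config@extension
  hi <- rep@start + rep@len - 1L + config@extension
  clamped <- lo < 1L || hi > ticLength
  out <- c(max(lo, 1L), min(hi, as.integer(ticLength)))
  attr(out, "clamped") <- clamped
  out
}

#' Stage 2: per-side window within the candidate range
#'
#' Exhaustively evaluates every window of \code{config@windowLen} frames whose
#' span lies inside the candidate range and returns the one with maximum
#' slope (earliest on ties), with its fitted slope.
#'
#' @param tic the per-side \linkS4class{TIC}.
#' @param candidate integer \code{c(first, last)} frame numbers, e.g. from
#'   \code{\link{candidateRange}}.
#' @param config a \linkS4class{WindowConfig}.
#' @return A \linkS4class{TimeWindow} for \code{side(tic)}.
#' @export
optimizeSideWindow <- function(tic, candidate, config = windowConfig(frameRate(tic))) {
  stopifnot(is(tic, "TIC"), is(config, "WindowConfig"))
  wl <- config@windowLen
  first <- max(candidate[1], tic@firstFrameNumber)
  last <- min(candidate[2], tic@firstFrameNumber + length(tic@values) - 1L)
  if (last - first + 1L < wl)
    pfInputError("window_optimization", sprintf(
      "candidate range %d-%d shorter than the %d-frame window", first, last, wl))
  starts <- seq.int(first, last - wl + 1L)
  idx <- starts - tic@firstFrameNumber + 1L
  hit <- .searchWindow(tic@values, idx, wl, method = config@slopeMethod)
  new("TimeWindow", start = starts[match(hit$start, idx)], len = wl,
      slope = hit$slope, side = tic@side)
}
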
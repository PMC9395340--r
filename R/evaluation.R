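#' Agreement of angiographic flow splits with a reference modality
#'
#' Ordinary least-squares fit of the angiographic right share (response) on
#' the reference right share (predictor, e.g. perfusion scintigraphy), the
#' Pearson correlation, and two root-mean-square error variants: the RMS of
#' the paired differences and the RMS of the regression residuals (divisor n).
#' Both RMSEs are reported because "RMSE" is ambiguous between the two in
#' method-comparison summaries; they coincide when the fit is the identity
#' line.
#'
#' @param xaPercents angiographic right shares, percent.
#' @param refPercents reference right shares, percent (same length, >= 3).
#' @return A \linkS4class{ComparisonResult}.
#' @examples
#' compareToReference(c(82, 62, 84, 40, 38, 50, 49),
#'                    c(81, 59, 69, 43, 45, 55, 46))
#' @export
compareToReference <- function(xaPercents, refPercents) {
  n <- length(xaPercents)
  if (length(refPercents) != n)
    pfInputError("evaluation", "series must have equal length")
  if (n < 3L)
    pfInputError("evaluation", "need at least 3 paired observations for a fit")
  if (sd(xaPercents) == 0 || sd(refPercents) == 0)
    pfInputError("evaluation", "zero variance in one of the series")
  fit <- lm(xaPercents ~ refPercents)
  new("ComparisonResult",
      fitSlope = unname(coef(fit)[2]), fitIntercept = unname(coef(fit)[1]),
      pearsonR = cor(xaPercents, refPercents),
      rmsePaired = sqrt(mean((xaPercents - refPercents)^2)),
      rmseResidual = sqrt(mean(residuals(fit)^2)),
      nPatients = as.integer(n))
}

#' Timing summary of the selected per-side windows over a cohort
#'
#' Summarizes when the optimized windows start and how far the right and left
#' windows drift apart. The mean start time uses the supplied per-side elapsed
#' times when available (clinical exports may carry acquisition timestamps
#' that are not exact frame multiples); otherwise it is derived from the frame
#' numbers as \code{(start - 1 + offset) / fps}, where \code{offset = 1}
#' places frame #k at k/fps after injection (the simulator's clock).
#'
#' @param rightStart,leftStart per-patient 1-based window start frames.
#' @param fps frames per second (scalar or per patient).
#' @param elapsedRight,elapsedLeft optional per-patient start times, seconds
#'   after injection.
#' @param offset frame-to-time offset in frames (default 1), used only when
#'   elapsed times are absent.
#' @return A \linkS4class{WindowSummary}.
#' @examples
#' summarizeWindows(c(22, 26), c(22, 25), fps = 30)
#' @export
summarizeWindows <- function(rightStart, leftStart, fps,
                             elapsedRight = NULL, elapsedLeft = NULL,
                             offset = 1) {
  n <- length(rightStart)
  if (length(leftStart) != n || n < 1L)
    pfInputError("evaluation", "need equal-length, non-empty start vectors")
  fps <- rep_len(fps, n)
  meanStart <- if (!is.null(elapsedRight) && !is.null(elapsedLeft)) {
    mean(c(elapsedRight, elapsedLeft))
  } else {
    mean(c((rightStart - 1 + offset) / fps, (leftStart - 1 + offset) / fps))
  }
  d <- abs(rightStart - leftStart)
  new("WindowSummary",
      meanStartTime = meanStart,
      meanSideDiffFrames = mean(d),
      maxSideDiffFrames = max(d),
      meanSideDiffSeconds = mean(d / fps))
}

#' Evaluate a per-patient results CSV
#'
#' Convenience wrapper for cohort files with columns \code{patient_id},
#' \code{ls_right_percent} (reference), \code{xa_right_percent},
#' \code{right_start_frame}, \code{left_start_frame}, \code{elapsed_right_s},
#' \code{elapsed_left_s}, \code{fps}. A transcription of a seven-patient
#' clinical comparison ships with the package
#' (\code{system.file("extdata", "flow_split_comparison.csv",
#' package = "pulmoflow")}).
#'
#' @param path CSV file.
#' @return List with elements \code{comparison}
#'   (\linkS4class{ComparisonResult}) and \code{windows}
#'   (\linkS4class{WindowSummary}).
#' @export
evaluateCohort <- function(path) {
  df <- read.csv(path, strip.white = TRUE)
  need <- c("ls_right_percent", "xa_right_percent", "right_start_frame",
            "left_start_frame", "fps")
  if (!all(need %in% names(df)))
    pfInputError("evaluation", sprintf("CSV must have columns: %s",
                                       paste(need, collapse = ", ")))
  list(
    comparison = compareToReference(df$xa_right_percent, df$ls_right_percent),
    windows = summarizeWindows(df$right_start_frame, df$left_start_frame,
                               df$fps,
                               elapsedRight = df$elapsed_right_s,
                               elapsedLeft = df$elapsed_left_s)
  )
}
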
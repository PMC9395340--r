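#' Load a dynamic angiography frame sequence
#'
#' Reads a multi-page TIFF or an uncompressed multi-frame DICOM file into a
#' \linkS4class{FrameSequence}. Pixel values are never rescaled on load
#' (except when DICOM rescale tags demand it, which is reported); TIFF data
#' are read at their stored integer scale.
#'
#' @param path input file.
#' @param format \code{"dicom"} or \code{"tiff"}; inferred from the file
#'   extension when missing.
#' @param frameRate frames per second. Required for TIFF; for DICOM it
#'   defaults to the frame-rate metadata (CineRate, display rate, or
#'   1000/FrameTime) and an explicit value overrides it.
#' @param injectionFrame 0-based index of the first post-injection frame;
#'   defaults to \code{maskFrame + 1}.
#' @param maskFrame 0-based index of the baseline frame; defaults to 0.
#' @return A \linkS4class{FrameSequence}.
#' @examples
#' sim <- renderFrames(syntheticSpec(trueRightPercent = 60, imageSize = 64,
#'                                   nFrames = 40))
#' f <- tempfile(fileext = ".tif")
#' writeSequence(sim$sequence, f)
#' seq2 <- loadSequence(f, frameRate = 30)
#' @export
loadSequence <- function(path, format = NULL, frameRate = NULL,
                         injectionFrame = NULL, maskFrame = NULL) {
  if (!file.exists(path))
    pfInputError("image_io", sprintf("file '%s' does not exist", path))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tif = , tiff = "tiff",
                     dcm = , dicom = "dicom",
                     pfInputError("image_io",
                       sprintf("cannot infer format of '%s'; pass format=", path)))
  }
  format <- match.arg(format, c("tiff", "dicom"))

  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(!vapply(pages, function(p) length(dim(p)) == 2L, logical(1))))
      pfInputError("image_io", "only grayscale (single-channel) TIFF is supported")
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      pfInputError("image_io", "TIFF pages have inconsistent dimensions")
    arr <- array(NA_real_, c(length(pages), dims[1, 1], dims[2, 1]))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
    fps <- frameRate
  } else {
    dcm <- readDicomFrames(path)
    arr <- dcm$frames
    fps <- if (!is.null(frameRate)) frameRate else dcm$frameRate
  }
  if (dim(arr)[1] < 2L)
    pfInputError("image_io", "sequence must contain at least 2 frames")
  if (is.null(fps) || is.na(fps))
    pfInputError("image_io",
      "frame rate not present in metadata; pass frameRate explicitly")
  mf <- if (is.null(maskFrame)) 0L else as.integer(maskFrame)
  inj <- if (is.null(injectionFrame)) mf + 1L else as.integer(injectionFrame)
  FrameSequence(arr, frameRate = fps, injectionFrame = inj, maskFrame = mf,
                sourceId = basename(path))
}

#' Write a frame sequence to disk
#'
#' @param seq a \linkS4class{FrameSequence} with integer pixel values in
#'   [0, 2^bits - 1] (raw, not mask-subtracted).
#' @param path output file.
#' @param format \code{"tiff"} (default) or \code{"dicom"}.
#' @param bits bits per sample for TIFF output (8 or 16; DICOM always 16).
#' @return \code{path}, invisibly.
#' @export
writeSequence <- function(seq, path, format = c("tiff", "dicom"), bits = 16L) {
  stopifnot(is(seq, "FrameSequence"))
  format <- match.arg(format)
  fr <- frames(seq)
  if (seq@subtracted)
    pfInputError("image_io", "refusing to write a mask-subtracted sequence as image stack")
  if (format == "dicom") return(writeDicomFrames(fr, path, frameRate(seq)))
  if (!bits %in% c(8L, 16L)) pfInputError("image_io", "bits must be 8 or 16")
  top <- 2^bits - 1
  if (any(fr < 0 | fr > top) || max(abs(fr - round(fr))) > 1e-9)
    pfInputError("image_io",
      sprintf("TIFF writer needs integer pixel values in [0, %d]", top))
  pages <- lapply(seq_len(dim(fr)[1]), function(k) fr[k, , ] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Load a TIC table from CSV
#'
#' Expects a header row naming (case-insensitively) a frame, right and left
#' column; comma-separated, dot decimal. Frame numbers must be consecutive
#' integers starting at 1 (frame #1 = first frame after injection).
#'
#' @param path CSV file.
#' @param frameRate frames per second to attach (default 30).
#' @return A \linkS4class{TICTable}.
#' @export
loadTicTable <- function(path, frameRate = 30) {
  if (!file.exists(path))
    pfInputError("image_io", sprintf("file '%s' does not exist", path))
  df <- read.csv(path, strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- c("frame", "right", "left")
  if (!all(need %in% names(df)))
    pfInputError("image_io", sprintf(
      "CSV must have columns frame, right, left (found: %s)",
      paste(names(df), collapse = ", ")))
  for (col in need) {
    if (!is.numeric(df[[col]]))
      pfInputError("image_io", sprintf("column '%s' contains non-numeric cells", col))
  }
  if (nrow(df) == 0L) pfInputError("image_io", "TIC table is empty")
  fn <- df$frame
  if (any(fn != round(fn)) || fn[1] != 1L ||
      (nrow(df) > 1L && any(diff(fn) != 1)))
    pfInputError("image_io",
      "frame numbers must be consecutive integers starting at 1")
  TICTable(fn, df$right, df$left, frameRate)
}

#' Write a TIC table to CSV
#' @param table a \linkS4class{TICTable}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeTicTable <- function(table, path) {
  stopifnot(is(table, "TICTable"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.windowAsList <- function(w) {
  list(start_frame = w@start, end_frame = w@start + w@len - 1L,
       length = w@len, slope = w@slope, side = w@side)
}

#' Write an analysis result to JSON
#'
#' The JSON carries a schema version, the selected windows (1-based frame
#' numbers relative to injection), both slopes, the flow split at full
#' precision and integer-rounded, the configuration echo and any warnings, so
#' that a run can be audited and reproduced.
#'
#' @param result an \linkS4class{AnalysisResult}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeResult <- function(result, path) {
  stopifnot(is(result, "AnalysisResult"))
  out <- list(
    schema_version = "1.0",
    ratio = list(
      right_percent = result@rightPercent,
      left_percent = result@leftPercent,
      right_percent_rounded = result@rightPercentRounded,
      left_percent_rounded = result@leftPercentRounded
    ),
    slopes = list(right = result@rightSlope, left = result@leftSlope),
    windows = list(
      representative = .windowAsList(result@representativeWindow),
      right = .windowAsList(result@rightWindow),
      left = .windowAsList(result@leftWindow)
    ),
    config = result@config,
    warnings = as.list(result@warnings)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a result JSON written by \code{\link{writeResult}}
#' @param path JSON file.
#' @return A named list mirroring the JSON structure.
#' @export
readResult <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
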
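## Minimal DICOM Part-10 support: uncompressed multi-frame grayscale,
## explicit or implicit VR little endian. Covers only the tags the pipeline
## needs; anything fancier (sequences with undefined length, big endian,
## compressed transfer syntaxes) is rejected with a clear error.

.VR_SHORT <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT",
               "PN","SH","SL","SS","ST","TM","UI","UL","US")

## tag -> c(name, vr) for the implicit-VR dictionary subset we understand
.DICT <- list(
  "0008,2144" = c("RecommendedDisplayFrameRate", "IS"),
  "0018,0040" = c("CineRate", "IS"),
  "0018,1063" = c("FrameTime", "DS"),
  "0028,0002" = c("SamplesPerPixel", "US"),
  "0028,0004" = c("PhotometricInterpretation", "CS"),
  "0028,0008" = c("NumberOfFrames", "IS"),
  "0028,0010" = c("Rows", "US"),
  "0028,0011" = c("Columns", "US"),
  "0028,0100" = c("BitsAllocated", "US"),
  "0028,0101" = c("BitsStored", "US"),
  "0028,0103" = c("PixelRepresentation", "US"),
  "0028,1052" = c("RescaleIntercept", "DS"),
  "0028,1053" = c("RescaleSlope", "DS"),
  "7fe0,0010" = c("PixelData", "OW")
)

.u16 <- function(con) readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                              endian = "little")
.u32 <- function(con) {
  b <- readBin(con, "integer", 2L, size = 2L, signed = FALSE, endian = "little")
  b[1] + b[2] * 65536
}

## read one data element; returns list(tag, vr, bytes) or NULL at EOF
.readElement <- function(con, explicit) {
  g <- .u16(con)
  if (length(g) == 0L) return(NULL)
  e <- .u16(con)
  tag <- sprintf("%04x,%04x", g, e)
  if (explicit) {
    vr <- rawToChar(readBin(con, "raw", 2L))
    if (vr %in% .VR_SHORT) {
      len <- .u16(con)
    } else {
      readBin(con, "raw", 2L)               # reserved
      len <- .u32(con)
    }
  } else {
    vr <- if (tag %in% names(.DICT)) .DICT[[tag]][2] else "UN"
    len <- .u32(con)
  }
  if (len == 4294967295) {
    pfInputError("image_io", sprintf(
      "DICOM element %s has undefined length (sequences unsupported)", tag))
  }
  list(tag = tag, vr = vr, bytes = readBin(con, "raw", len))
}

.elementValue <- function(el) {
  switch(el$vr,
    US = readBin(el$bytes, "integer", length(el$bytes) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    UL = readBin(el$bytes, "integer", length(el$bytes) / 4L, size = 4L,
                 endian = "little"),
    IS = , DS = as.numeric(strsplit(trimws(rawToChar(el$bytes)), "\\\\")[[1]]),
    CS = , UI = , LO = , SH = trimws(rawToChar(el$bytes)),
    el$bytes)
}

#' Read a multi-frame DICOM file (minimal parser)
#'
#' Parses uncompressed explicit- or implicit-VR little-endian files. MONOCHROME1
#' pixel data are inverted so that larger value = brighter, and any
#' RescaleSlope/RescaleIntercept is applied; both adjustments are reported as
#' messages. Frame rate is resolved from CineRate, then
#' RecommendedDisplayFrameRate, then 1000/FrameTime.
#'
#' @param path file path.
#' @return list with \code{frames} (time x height x width array),
#'   \code{frameRate} (fps or \code{NA}), and the raw header fields.
#' @keywords internal
readDicomFrames <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 128L)
  if (!identical(rawToChar(readBin(con, "raw", 4L)), "DICM"))
    pfInputError("image_io", sprintf("'%s' is not a DICOM Part-10 file", path))

  ## file meta group is always explicit VR little endian
  ts <- "1.2.840.10008.1.2.1"
  repeat {
    pos <- seek(con)
    el <- .readElement(con, explicit = TRUE)
    if (is.null(el)) pfInputError("image_io", "truncated DICOM meta header")
    if (!startsWith(el$tag, "0002")) { seek(con, pos); break }
    if (el$tag == "0002,0010") ts <- .elementValue(el)
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2"   = FALSE,
    pfInputError("image_io", sprintf("unsupported transfer syntax '%s'", ts)))

  hdr <- list()
  pixelBytes <- NULL
  repeat {
    el <- .readElement(con, explicit)
    if (is.null(el)) break
    if (el$tag == "7fe0,0010") { pixelBytes <- el$bytes; break }
    if (el$tag %in% names(.DICT))
      hdr[[.DICT[[el$tag]][1]]] <- .elementValue(el)
  }
  if (is.null(pixelBytes)) pfInputError("image_io", "DICOM file has no PixelData")
  rows <- hdr$Rows; cols <- hdr$Columns
  if (is.null(rows) || is.null(cols))
    pfInputError("image_io", "DICOM file lacks Rows/Columns")
  nf <- if (!is.null(hdr$NumberOfFrames)) as.integer(hdr$NumberOfFrames) else 1L
  bits <- if (!is.null(hdr$BitsAllocated)) hdr$BitsAllocated else 16L
  if (!bits %in% c(8L, 16L))
    pfInputError("image_io", sprintf("unsupported BitsAllocated %d", bits))
  signed <- !is.null(hdr$PixelRepresentation) && hdr$PixelRepresentation == 1L
  npx <- as.numeric(rows) * cols * nf
  if (length(pixelBytes) < npx * bits / 8)
    pfInputError("image_io", "DICOM PixelData shorter than Rows*Columns*Frames")
  v <- if (bits == 8L) {
    readBin(pixelBytes, "integer", npx, size = 1L, signed = signed)
  } else {
    readBin(pixelBytes, "integer", npx, size = 2L, signed = signed,
            endian = "little")
  }
  if (!signed && bits == 16L) v <- ifelse(v < 0, v + 65536, v)

  if (identical(hdr$PhotometricInterpretation, "MONOCHROME1")) {
    bs <- if (!is.null(hdr$BitsStored)) hdr$BitsStored else bits
    v <- (2^bs - 1) - v
    message("pulmoflow: MONOCHROME1 input inverted to bright-is-high")
  }
  if (!is.null(hdr$RescaleSlope) || !is.null(hdr$RescaleIntercept)) {
    rs <- if (is.null(hdr$RescaleSlope)) 1 else hdr$RescaleSlope
    ri <- if (is.null(hdr$RescaleIntercept)) 0 else hdr$RescaleIntercept
    if (rs != 1 || ri != 0) {
      v <- v * rs + ri
      message(sprintf("pulmoflow: applied DICOM rescale %g * value + %g", rs, ri))
    }
  }

  ## pixel order is row-major within each frame
  arr <- array(NA_real_, c(nf, rows, cols))
  per <- rows * cols
  for (k in seq_len(nf)) {
    arr[k, , ] <- matrix(v[((k - 1) * per + 1):(k * per)],
                         nrow = rows, ncol = cols, byrow = TRUE)
  }

  fps <- NA_real_
  if (!is.null(hdr$CineRate)) fps <- hdr$CineRate
  else if (!is.null(hdr$RecommendedDisplayFrameRate)) fps <- hdr$RecommendedDisplayFrameRate
  else if (!is.null(hdr$FrameTime) && hdr$FrameTime > 0) fps <- 1000 / hdr$FrameTime

  list(frames = arr, frameRate = fps, header = hdr)
}

.wTag <- function(g, e) writeBin(as.integer(c(g, e)), raw(), size = 2L,
                                 endian = "little")
.padEven <- function(b, pad = as.raw(0L)) {
  if (length(b) %% 2L == 1L) c(b, pad) else b
}

.wElement <- function(g, e, vr, valueBytes) {
  valueBytes <- .padEven(valueBytes, if (vr %in% c("UI")) as.raw(0L) else
                         if (vr %in% c("OB", "OW")) as.raw(0L) else charToRaw(" "))
  hdr <- c(.wTag(g, e), charToRaw(vr))
  if (vr %in% .VR_SHORT) {
    c(hdr, writeBin(length(valueBytes), raw(), size = 2L, endian = "little")[1:2],
      valueBytes)
  } else {
    c(hdr, as.raw(c(0L, 0L)),
      writeBin(length(valueBytes), raw(), size = 4L, endian = "little"),
      valueBytes)
  }
}

.wUS <- function(g, e, x) .wElement(g, e, "US",
  writeBin(as.integer(x), raw(), size = 2L, endian = "little"))
.wStr <- function(g, e, vr, s) .wElement(g, e, vr, charToRaw(s))

#' Write a multi-frame DICOM file (minimal writer)
#'
#' Writes explicit-VR little-endian secondary-capture-style files with
#' MONOCHROME2 16-bit pixels and a CineRate tag carrying the frame rate. Pixel
#' values must be integers in [0, 65535].
#'
#' @param frames time x height x width integer-valued array.
#' @param path output path.
#' @param frameRate frames per second, stored as CineRate (rounded to an
#'   integer as the tag requires).
#' @return \code{path}, invisibly.
#' @keywords internal
writeDicomFrames <- function(frames, path, frameRate) {
  d <- dim(frames)
  if (length(d) != 3L) pfInputError("image_io", "frames must be a 3-D array")
  if (any(frames < 0 | frames > 65535) ||
      max(abs(frames - round(frames))) > 1e-9)
    pfInputError("image_io", "DICOM writer needs integer pixel values in [0, 65535]")

  sopClass <- "1.2.840.10008.5.1.4.1.1.12.1"     # X-Ray Angiographic Image
  uid <- paste0("1.2.826.0.1.3680043.9999.",
                paste(sample.int(9, 8, replace = TRUE), collapse = ""))
  meta <- c(
    .wElement(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .wStr(0x0002, 0x0002, "UI", sopClass),
    .wStr(0x0002, 0x0003, "UI", uid),
    .wStr(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  grpLen <- .wElement(0x0002, 0x0000, "UL",
                      writeBin(length(meta), raw(), size = 4L, endian = "little"))

  px <- integer(0)
  for (k in seq_len(d[1])) px <- c(px, as.integer(t(frames[k, , ])))
  pxBytes <- writeBin(px, raw(), size = 2L, endian = "little")

  body <- c(
    .wStr(0x0008, 0x0016, "UI", sopClass),
    .wStr(0x0008, 0x0018, "UI", uid),
    .wStr(0x0018, 0x0040, "IS", as.character(as.integer(round(frameRate)))),
    .wUS(0x0028, 0x0002, 1L),
    .wStr(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .wStr(0x0028, 0x0008, "IS", as.character(d[1])),
    .wUS(0x0028, 0x0010, d[2]),
    .wUS(0x0028, 0x0011, d[3]),
    .wUS(0x0028, 0x0100, 16L),
    .wUS(0x0028, 0x0101, 16L),
    .wUS(0x0028, 0x0102, 15L),
    .wUS(0x0028, 0x0103, 0L),
    .wElement(0x7fe0, 0x0010, "OW", pxBytes)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grpLen, meta, body), con)
  invisible(path)
}
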
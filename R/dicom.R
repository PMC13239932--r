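# Minimal DICOM CT reader/writer (Explicit VR Little Endian only).
#
# Phantom QA series use plain CT Image Storage with a linear rescale, so the
# reader covers exactly that: explicit-VR little-endian files, rescale
# slope/intercept HU conversion, position-based slice sorting. The writer
# exists to emit test fixtures and round-trip series.

.UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
.UID_ROOT <- "1.2.826.0.1.3680043.9999"

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(raw, i) {
  as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
}
.u32 <- function(raw, i) {
  as.integer(raw[i]) + 256 * as.integer(raw[i + 1L]) +
    65536 * as.integer(raw[i + 2L]) + 16777216 * as.integer(raw[i + 3L])
}

# Parse one explicit-VR-LE dataset starting at byte offset `pos` (1-based).
# Returns a list keyed "gggg,eeee" with fields vr and raw value.
.parseElements <- function(raw, pos) {
  n <- length(raw)
  out <- list()
  while (pos + 7L <= n) {
    group <- .u16(raw, pos); elem <- .u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("not an Explicit VR Little Endian DICOM dataset (bad VR at offset ",
           pos, ")")
    if (vr %in% .LONG_VRS) {
      len <- .u32(raw, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- .u16(raw, pos + 6L)
      vstart <- pos + 8L
    }
    if (vstart + len - 1L > n)
      stop("truncated DICOM file: element value exceeds file size")
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- list(vr = vr,
                       value = if (len > 0) raw[vstart:(vstart + len - 1L)]
                               else raw(0))
    pos <- vstart + len
  }
  out
}

.dcmString <- function(el) {
  if (is.null(el)) return(NULL)
  v <- el$value
  # strip trailing NUL/space padding (rawToChar rejects embedded NULs)
  while (length(v) && (v[length(v)] == as.raw(0) || v[length(v)] == as.raw(0x20)))
    v <- v[-length(v)]
  rawToChar(v)
}
.dcmNumeric <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(.dcmString(el), "\\\\")[[1L]])
}
.dcmUS <- function(el) {
  if (is.null(el)) return(NULL)
  .u16(el$value, 1L)
}

.readDicomFile <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L)
    stop("truncated or non-DICOM file: ", path)
  if (rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM marker): ", path)
  els <- .parseElements(raw, 133L)
  ts <- .dcmString(els[["0002,0010"]])
  if (!is.null(ts) && ts != .UID_EXPLICIT_LE)
    stop("unsupported transfer syntax ", ts, " in ", path,
         " (only Explicit VR Little Endian is supported)")
  rows <- .dcmUS(els[["0028,0010"]]); cols <- .dcmUS(els[["0028,0011"]])
  px <- els[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop("DICOM file lacks image pixel module: ", path)
  signed <- identical(.dcmUS(els[["0028,0103"]]), 1L)
  stored <- readBin(px$value, "integer", n = length(px$value) / 2L, size = 2L,
                    signed = signed, endian = "little")
  if (length(stored) != rows * cols)
    stop("pixel data size does not match Rows x Columns in ", path)
  slope <- .dcmNumeric(els[["0028,1053"]]); if (is.null(slope)) slope <- 1
  inter <- .dcmNumeric(els[["0028,1052"]]); if (is.null(inter)) inter <- 0
  ipp <- .dcmNumeric(els[["0020,0032"]])
  list(
    seriesUID = .dcmString(els[["0020,000e"]]),
    instanceNumber = .dcmNumeric(els[["0020,0013"]]),
    zPosition = if (length(ipp) >= 3) ipp[3] else NA_real_,
    pixelSpacing = .dcmNumeric(els[["0028,0030"]]),
    sliceThickness = .dcmNumeric(els[["0018,0050"]]),
    rows = rows, cols = cols,
    # DICOM pixel order is row-major
    hu = t(matrix(slope * stored + inter, nrow = cols, ncol = rows))
  )
}

#' Load a DICOM CT series as an ImageVolume
#'
#' Reads every file in \code{directoryPath}, converts stored values to HU
#' via the rescale slope/intercept, and stacks slices sorted by axial
#' position (Image Position (Patient) z; instance number as fallback), so
#' the result is invariant to file-name shuffling. Mixed series UIDs,
#' inconsistent pixel spacing across slices, and anisotropic in-plane
#' spacing are rejected. CT numbers below -1024 HU are clamped.
#'
#' @param directoryPath directory holding one DICOM CT series.
#' @return An \linkS4class{ImageVolume}.
#' @seealso \code{\link{writeDicomSeries}}, \code{\link{loadVolume}}
#' @export
loadDicomSeries <- function(directoryPath) {
  files <- list.files(directoryPath, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("no files found in ", directoryPath)
  slices <- lapply(files, .readDicomFile)
  uids <- vapply(slices, function(s) s$seriesUID %||% NA_character_,
                 character(1))
  if (length(unique(uids)) != 1L)
    stop("mixed series: directory contains ", length(unique(uids)),
         " distinct SeriesInstanceUIDs")
  sp <- t(vapply(slices, `[[`, numeric(2), "pixelSpacing"))
  if (any(abs(sweep(sp, 2, sp[1L, ])) > 1e-6))
    stop("inconsistent pixel spacing across slices")
  if (abs(sp[1L, 1L] - sp[1L, 2L]) > 1e-6)
    stop("anisotropic in-plane pixel spacing is not supported (",
         sp[1L, 1L], " x ", sp[1L, 2L], " mm)")
  dims <- vapply(slices, function(s) c(s$rows, s$cols), numeric(2))
  if (any(dims != dims[, 1L]))
    stop("inconsistent matrix size across slices")
  z <- vapply(slices, `[[`, numeric(1), "zPosition")
  ord <- if (all(is.finite(z))) order(z) else
    order(vapply(slices, function(s) s$instanceNumber %||% NA_real_,
                 numeric(1)))
  slices <- slices[ord]
  vox <- array(0, c(slices[[1L]]$rows, slices[[1L]]$cols, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  st <- slices[[1L]]$sliceThickness
  if (is.null(st) || !is.finite(st)) st <- 1
  imageVolume(vox, pixelSpacing = sp[1L, 1L], sliceThickness = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- writer -----------------------------------------------------------------

.evenPad <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2L == 1L) c(x, pad) else x
}

.dcmElement <- function(group, elem, vr, value) {
  if (is.character(value))
    value <- .evenPad(charToRaw(value),
                      pad = if (vr == "UI") as.raw(0) else as.raw(0x20))
  hdr <- writeBin(as.integer(c(group, elem)), raw(), size = 2L,
                  endian = "little")
  if (vr %in% .LONG_VRS) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4L, endian = "little"), value)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(value), raw(), size = 2L, endian = "little"), value)
  }
}

.dcmUSval <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                  endian = "little")

#' Write an ImageVolume as a DICOM CT series
#'
#' Minimal Explicit VR Little Endian CT Image Storage writer used to
#' materialize fixtures and round-trip series. Stored values are 16-bit
#' signed with rescale slope 1 and intercept -1024, so HU round-trip to
#' within the integer quantization (0.5 HU).
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param directoryPath output directory (created if missing).
#' @param seriesUID optional series UID; generated when NULL.
#' @return Invisibly, the vector of file paths written.
#' @export
writeDicomSeries <- function(volume, directoryPath, seriesUID = NULL) {
  stopifnot(is(volume, "ImageVolume"))
  dir.create(directoryPath, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seriesUID))
    seriesUID <- paste0(.UID_ROOT, ".",
                        paste(sample(0:9, 12, replace = TRUE), collapse = ""))
  vox <- volume@voxels
  d <- dim(vox)
  paths <- character(d[3L])
  for (k in seq_len(d[3L])) {
    sopUID <- paste0(seriesUID, ".", k)
    stored <- as.integer(pmax(pmin(round(vox[, , k] + 1024), 32767), -32768))
    # row-major pixel order
    pxRaw <- writeBin(as.vector(t(matrix(stored, d[1L], d[2L]))), raw(),
                      size = 2L, endian = "little")
    ds <- c(
      .dcmElement(0x0008, 0x0016, "UI", .UID_CT_STORAGE),
      .dcmElement(0x0008, 0x0018, "UI", sopUID),
      .dcmElement(0x0008, 0x0060, "CS", "CT"),
      .dcmElement(0x0020, 0x000d, "UI", paste0(seriesUID, ".0")),
      .dcmElement(0x0020, 0x000e, "UI", seriesUID),
      .dcmElement(0x0020, 0x0013, "IS", as.character(k)),
      .dcmElement(0x0020, 0x0032, "DS",
                  sprintf("0\\0\\%g", (k - 1) * volume@sliceThickness)),
      .dcmElement(0x0018, 0x0050, "DS", sprintf("%g", volume@sliceThickness)),
      .dcmElement(0x0028, 0x0002, "US", .dcmUSval(1L)),
      .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcmElement(0x0028, 0x0010, "US", .dcmUSval(d[1L])),
      .dcmElement(0x0028, 0x0011, "US", .dcmUSval(d[2L])),
      .dcmElement(0x0028, 0x0030, "DS",
                  sprintf("%g\\%g", volume@pixelSpacing, volume@pixelSpacing)),
      .dcmElement(0x0028, 0x0100, "US", .dcmUSval(16L)),
      .dcmElement(0x0028, 0x0101, "US", .dcmUSval(16L)),
      .dcmElement(0x0028, 0x0102, "US", .dcmUSval(15L)),
      .dcmElement(0x0028, 0x0103, "US", .dcmUSval(1L)),
      .dcmElement(0x0028, 0x1052, "DS", "-1024"),
      .dcmElement(0x0028, 0x1053, "DS", "1"),
      .dcmElement(0x7fe0, 0x0010, "OW", pxRaw)
    )
    metaBody <- c(
      .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcmElement(0x0002, 0x0002, "UI", .UID_CT_STORAGE),
      .dcmElement(0x0002, 0x0003, "UI", sopUID),
      .dcmElement(0x0002, 0x0010, "UI", .UID_EXPLICIT_LE),
      .dcmElement(0x0002, 0x0012, "UI", paste0(.UID_ROOT, ".1"))
    )
    meta <- c(.dcmElement(0x0002, 0x0000, "UL",
                          writeBin(length(metaBody), raw(), size = 4L,
                                   endian = "little")),
              metaBody)
    paths[k] <- file.path(directoryPath, sprintf("slice_%03d.dcm", k))
    con <- file(paths[k], "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(paths)
}
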
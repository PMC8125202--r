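# Minimal single-frame DICOM I/O (explicit VR little endian only).
#
# CBCT exports are plain single-frame CT series; only the tags the
# pipeline needs are read or written: series/instance UIDs, slice
# position and orientation, pixel spacing, rescale slope/intercept and
# the 16-bit pixel data. Multi-frame enhanced DICOM and implicit-VR
# files are rejected.

.UID_ROOT <- "1.2.826.0.1.3680043.10.1497"
.SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

.dcmPad <- function(s, pad = as.raw(0x20)) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, pad)
  r
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# One explicit-VR data element as raw bytes.
.dcmElement <- function(group, element, vr, value) {
  if (is.character(value))
    value <- .dcmPad(value, pad = if (vr == "UI") as.raw(0L) else as.raw(0x20))
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .u32(length(value)), value)
  } else if (vr == "US") {
    body <- .u16(value)
    c(head, .u16(length(body)), body)
  } else if (vr == "UL") {
    body <- .u32(value)
    c(head, .u16(length(body)), body)
  } else {
    c(head, .u16(length(value)), value)
  }
}

.dcmNumString <- function(x) paste(vapply(x, function(v)
  formatC(v, format = "g", digits = 10), ""), collapse = "\\")

# Write one axial slice as a DICOM file.
.writeDicomSlice <- function(path, pixels, nx, ny, spacing, position,
                             instance, seriesUID, studyUID,
                             slope = 1, intercept = -1024) {
  stored <- as.integer(round((pixels - intercept) / slope))
  stored <- pmin(pmax(stored, -32768L), 32767L)
  sopUID <- paste0(seriesUID, ".", instance)

  meta <- c(
    .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcmElement(0x0002, 0x0002, "UI", .SOP_CT),
    .dcmElement(0x0002, 0x0003, "UI", sopUID),
    .dcmElement(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .dcmElement(0x0002, 0x0012, "UI", paste0(.UID_ROOT, ".1")))
  meta <- c(.dcmElement(0x0002, 0x0000, "UL", length(meta)), meta)

  pix <- writeBin(stored, raw(), size = 2L, endian = "little")
  body <- c(
    .dcmElement(0x0008, 0x0016, "UI", .SOP_CT),
    .dcmElement(0x0008, 0x0018, "UI", sopUID),
    .dcmElement(0x0008, 0x0060, "CS", "CT"),
    .dcmElement(0x0018, 0x0050, "DS", .dcmNumString(spacing[3])),
    .dcmElement(0x0020, 0x000D, "UI", studyUID),
    .dcmElement(0x0020, 0x000E, "UI", seriesUID),
    .dcmElement(0x0020, 0x0013, "IS", .dcmNumString(instance)),
    .dcmElement(0x0020, 0x0032, "DS", .dcmNumString(position)),
    .dcmElement(0x0020, 0x0037, "DS", .dcmNumString(c(1, 0, 0, 0, 1, 0))),
    .dcmElement(0x0028, 0x0002, "US", 1L),
    .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcmElement(0x0028, 0x0010, "US", ny),
    .dcmElement(0x0028, 0x0011, "US", nx),
    # PixelSpacing is (row spacing, column spacing) = (dy, dx)
    .dcmElement(0x0028, 0x0030, "DS", .dcmNumString(spacing[c(2, 1)])),
    .dcmElement(0x0028, 0x0100, "US", 16L),
    .dcmElement(0x0028, 0x0101, "US", 16L),
    .dcmElement(0x0028, 0x0102, "US", 15L),
    .dcmElement(0x0028, 0x0103, "US", 1L),
    .dcmElement(0x0028, 0x1052, "DS", .dcmNumString(intercept)),
    .dcmElement(0x0028, 0x1053, "DS", .dcmNumString(slope)),
    .dcmElement(0x7FE0, 0x0010, "OW", pix))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Parse one DICOM file, returning the tags of interest.
.readDicomSlice <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM part-10 file", basename(path)))
  pos <- 133L
  n <- length(bytes)
  rd16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2L,
                               signed = FALSE, endian = "little")
  rd32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4L,
                               endian = "little")
  tags <- list()
  while (pos + 7L <= n) {
    group <- rd16(pos); element <- rd16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR transfer syntax is not supported")
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- rd32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- rd16(pos + 6L)
      vstart <- pos + 8L
    }
    if (len < 0L || vstart + len - 1L > n)
      stop("corrupt DICOM element length")
    val <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    tags[[key]] <- list(vr = vr, value = val)
    pos <- vstart + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  getStr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    v <- t$value
    trimws(rawToChar(v[v != as.raw(0L)]))
  }
  getNum <- function(key) {
    s <- getStr(key)
    if (is.null(s) || !nzchar(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  getU16 <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    readBin(t$value, "integer", size = 2L, signed = FALSE, endian = "little")
  }
  rows <- getU16("0028,0010"); cols <- getU16("0028,0011")
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns")
  bits <- getU16("0028,0100")
  if (!identical(bits, 16L)) stop("only 16-bit pixel data is supported")
  signed <- identical(getU16("0028,0103"), 1L)
  pix <- tags[["7FE0,0010"]]
  if (is.null(pix)) stop("missing PixelData")
  stored <- readBin(pix$value, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  list(
    seriesUID = getStr("0020,000E"),
    position = getNum("0020,0032"),
    instance = getNum("0020,0013"),
    pixelSpacing = getNum("0028,0030"),
    sliceThickness = getNum("0018,0050"),
    slope = getNum("0028,1053"),
    intercept = getNum("0028,1052"),
    nx = cols, ny = rows,
    stored = stored)
}
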
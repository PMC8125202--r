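#' Read a CBCT DICOM series into a calibrated volume
#'
#' Reads all single-frame DICOM files in a directory, checks that they
#' belong to one series with consistent pixel spacing, applies the rescale
#' slope/intercept so values are pseudo-HU, and sorts slices by physical
#' position into superior-to-inferior order (decreasing patient z).
#'
#' @param directory path containing one DICOM series (>= 2 files).
#' @return A [CBCTVolume-class].
#' @export
readDicomSeries <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L)
    stop("directory must contain at least 2 DICOM files")
  slices <- lapply(files, .readDicomSlice)

  uids <- vapply(slices, function(s) s$seriesUID %||% "", "")
  if (length(unique(uids)) != 1L)
    stop("mixed series UIDs in directory")
  ps <- t(vapply(slices, function(s) s$pixelSpacing, numeric(2)))
  if (any(abs(sweep(ps, 2, ps[1, ])) > 1e-6))
    stop("inconsistent pixel spacing across slices")
  dims <- t(vapply(slices, function(s) c(s$nx, s$ny), numeric(2)))
  if (any(dims[, 1] != dims[1, 1]) || any(dims[, 2] != dims[1, 2]))
    stop("inconsistent slice dimensions")

  noRescale <- vapply(slices, function(s)
    is.null(s$slope) || is.null(s$intercept), TRUE)
  if (any(noRescale))
    warning("missing rescale tags; assuming slope 1, intercept 0")

  z <- vapply(slices, function(s) s$position[3], 0)
  ord <- order(z, decreasing = TRUE)  # superior -> inferior
  slices <- slices[ord]
  z <- z[ord]
  dz <- if (length(z) > 1) abs(stats::median(diff(z))) else 1
  if (dz <= 0) stop("slices share identical positions")
  if (length(z) > 2 && diff(range(-diff(z))) > 1e-3 * dz)
    warning("non-uniform inter-slice distance; using the median")

  nx <- slices[[1]]$nx; ny <- slices[[1]]$ny; nz <- length(slices)
  vals <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    slope <- s$slope %||% 1
    intercept <- s$intercept %||% 0
    vals[, , k] <- matrix(s$stored * slope + intercept, nrow = nx)
  }
  CBCTVolume(vals,
             spacing = c(slices[[1]]$pixelSpacing[2],
                         slices[[1]]$pixelSpacing[1], dz),
             origin = slices[[1]]$position)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume as a single-frame DICOM series
#'
#' One file per axial slice, 16-bit explicit-VR little endian, with slice
#' positions decreasing in z so that the stored order is
#' superior-to-inferior. Values round-trip within integer storage
#' rounding.
#'
#' @param vol a [CBCTVolume-class].
#' @param directory output directory (created if needed).
#' @param intercept,slope rescale calibration used for storage.
#' @return The directory, invisibly.
#' @export
writeDicomSeries <- function(vol, directory, intercept = -1024, slope = 1) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol@values)
  serial <- sum(as.integer(charToRaw(basename(directory)))) %% 99991L
  seriesUID <- paste0(.UID_ROOT, ".2.", serial)
  studyUID <- paste0(.UID_ROOT, ".3.", serial)
  for (k in seq_len(d[3])) {
    pos <- c(vol@origin[1], vol@origin[2],
             vol@origin[3] - (k - 1) * vol@spacing[3])
    .writeDicomSlice(
      file.path(directory, sprintf("slice%04d.dcm", k)),
      pixels = as.vector(vol@values[, , k]),
      nx = d[1], ny = d[2], spacing = vol@spacing, position = pos,
      instance = k, seriesUID = seriesUID, studyUID = studyUID,
      slope = slope, intercept = intercept)
  }
  invisible(directory)
}

#' Crop a volume to a volume of interest
#'
#' @param vol a [CBCTVolume-class].
#' @param voi a [VOIBox-class] with 1-based inclusive index ranges.
#' @return The cropped [CBCTVolume-class]; spacing unchanged, origin
#'   shifted consistently.
#' @export
cropVolume <- function(vol, voi) {
  d <- dim(vol@values)
  rng <- list(x = voi@xRange, y = voi@yRange, z = voi@zRange)
  for (ax in 1:3) {
    r <- rng[[ax]]
    if (r[1] < 1L || r[2] > d[ax])
      stop(sprintf("VOI %s range [%d, %d] outside volume bounds [1, %d]",
                   names(rng)[ax], r[1], r[2], d[ax]))
  }
  vals <- vol@values[rng$x[1]:rng$x[2], rng$y[1]:rng$y[2],
                     rng$z[1]:rng$z[2], drop = FALSE]
  shift <- (vapply(rng, `[`, 0L, 1L) - 1L) * vol@spacing
  # z origin decreases inferiorly in scanner coordinates
  shift[3] <- -shift[3]
  CBCTVolume(vals, spacing = vol@spacing, origin = vol@origin + shift)
}

#' Write / read a mask stack as NIfTI
#'
#' Lossless binary round-trip of the per-slice condyle masks as one 3D
#' NIfTI image with the voxel spacing in its pixdim.
#'
#' @param stack a [MaskStack-class].
#' @param path output file (`.nii`).
#' @return `writeMaskStack()` returns the path invisibly;
#'   `readMaskStack()` returns the [MaskStack-class].
#' @export
writeMaskStack <- function(stack, path) {
  if (length(stack@mask) == 0L) stop("mask stack is empty")
  arr <- array(as.integer(stack@mask), dim(stack@mask))
  attr(arr, "pixdim") <- stack@spacing
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "uint8")
  invisible(path)
}

#' @rdname writeMaskStack
#' @export
readMaskStack <- function(path) {
  img <- RNifti::readNifti(path)
  MaskStack(array(as.vector(img) > 0.5, dim(img)),
            spacing = RNifti::pixdim(img)[1:3])
}
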
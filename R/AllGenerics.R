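#' Accessors for tmjgap objects
#'
#' `imageValues()` returns the raw scalar grid, `voxelSpacing()` the
#' spacing in mm, `maskArray()` the logical mask array, and `gapWidths()`
#' the named `(rC, rD, rF)` vector of a measurement.
#'
#' @param x a tmjgap object.
#' @return The slot contents (array, numeric vector or logical array).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("gapWidths", function(x) standardGeneric("gapWidths"))

#' @rdname accessors
#' @export
setMethod("imageValues", "CBCTVolume", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("imageValues", "ReferenceSlice", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CBCTVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "MaskStack", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ReferenceSlice", function(x) c(x@du, x@dv))
#' @rdname accessors
#' @export
setMethod("maskArray", "MaskStack", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("maskArray", "ReferenceSlice", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("gapWidths", "TMJMeasurement",
          function(x) c(rC = x@rC, rD = x@rD, rF = x@rF))

setMethod("show", "CBCTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CBCTVolume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  value range [%.1f, %.1f] pseudo-HU\n",
              min(object@values), max(object@values)))
})

setMethod("show", "MaskStack", function(object) {
  d <- dim(object@mask)
  cat(sprintf("MaskStack: %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@mask)))
  if (!is.na(object@firstSlice))
    cat(sprintf("  head on slices %d..%d\n", object@firstSlice,
                object@lastSlice))
})

setMethod("show", "GMMFit", function(object) {
  cat(sprintf("GMMFit: K = %d (converged in %d iterations)\n", object@K,
              object@iterations))
  for (k in seq_len(object@K))
    cat(sprintf("  component %d: mean %8.1f  sd %7.1f  weight %.3f\n", k,
                object@mean[k], sqrt(object@variance[k]), object@weight[k]))
})

setMethod("show", "ReferencePlane", function(object) {
  cat(sprintf("ReferencePlane: anchor (%.2f, %.2f) mm, azimuth %.2f deg\n",
              object@anchor[1], object@anchor[2], object@azimuthDeg))
})

setMethod("show", "ReferenceSlice", function(object) {
  d <- dim(object@values)
  cat(sprintf("ReferenceSlice (%s joint): %d x %d px, %.3g x %.3g mm/px\n",
              object@laterality, d[1], d[2], object@du, object@dv))
  cat(sprintf("  plane azimuth %.2f deg, dorsal = %s u\n", object@azimuthDeg,
              if (object@dorsalSign > 0) "+" else "-"))
})

setMethod("show", "TMJMeasurement", function(object) {
  cat(sprintf("TMJMeasurement (%s joint)\n", object@laterality))
  cat(sprintf("  rC = %.2f mm, rD = %.2f mm, rF = %.2f mm\n", object@rC,
              object@rD, object@rF))
  cat(sprintf("  tangent angles: dorsal %.2f deg, frontal %.2f deg\n",
              object@thetaTD, object@thetaTF))
  cat(sprintf("  plane azimuth %.2f deg, section length %.2f mm\n",
              object@planeAzimuthDeg, object@sectionLengthMm))
  if (length(object@degenerate))
    cat("  degenerate (contact) widths:",
        paste(object@degenerate, collapse = ", "), "\n")
})
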
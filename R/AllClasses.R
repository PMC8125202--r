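#' @import methods
NULL

#' CBCTVolume: a physically calibrated 3D CBCT image
#'
#' Holds a 3D scalar grid of pseudo-Hounsfield values together with its
#' voxel spacing and the physical position of the first voxel. The array is
#' indexed `values[ix, iy, iz]` where `ix` runs along the patient x axis
#' (columns of an axial slice), `iy` along y (rows) and `iz` enumerates
#' axial slices from superior to inferior. All in-package geometry uses the
#' index-derived millimetre coordinates `x = (ix - 1) * dx`,
#' `y = (iy - 1) * dy` and the depth-from-top coordinate
#' `v = (iz - 1) * dz`, which increases inferiorly (image convention).
#'
#' @slot values numeric 3D array of pseudo-HU values.
#' @slot spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm.
#' @slot origin numeric length-3, physical position (mm) of voxel
#'   `(1, 1, 1)` as reported by the scanner; bookkeeping only.
#'
#' @export
setClass("CBCTVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("CBCTVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3D array")
  if (any(d < 2L)) return("grid must span at least 2 voxels along every axis")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers")
  TRUE
})

#' Construct a CBCTVolume
#'
#' @param values numeric 3D array (pseudo-HU), indexed `[ix, iy, iz]`.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param origin physical position of voxel `(1, 1, 1)` in mm.
#' @return A [CBCTVolume-class] object.
#' @export
CBCTVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CBCTVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' VOIBox: a cuboid volume of interest
#'
#' Index ranges (1-based, inclusive) selecting a sub-volume of a
#' [CBCTVolume-class]. The z range must span at least 3 axial slices; its
#' first slice is expected to lie above the acetabular roof so that no part
#' of the condyle appears on it.
#'
#' @slot xRange,yRange,zRange integer length-2 inclusive index ranges.
#' @export
setClass("VOIBox",
  representation(xRange = "integer", yRange = "integer", zRange = "integer"))

setValidity("VOIBox", function(object) {
  for (nm in c("xRange", "yRange", "zRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(is.na(r))) return(sprintf("%s must be 2 integers", nm))
    if (r[1] < 1L || r[2] < r[1]) return(sprintf("%s must be a non-empty range", nm))
  }
  if (diff(object@zRange) + 1L < 3L) return("zRange must span at least 3 slices")
  TRUE
})

#' Construct a VOIBox
#' @param xRange,yRange,zRange integer length-2 inclusive index ranges
#'   (1-based) into a [CBCTVolume-class].
#' @return A [VOIBox-class] object.
#' @export
VOIBox <- function(xRange, yRange, zRange) {
  new("VOIBox", xRange = as.integer(xRange), yRange = as.integer(yRange),
      zRange = as.integer(zRange))
}

#' GMMFit: a univariate Gaussian mixture fitted to one axial slice
#'
#' @slot mean,variance,weight numeric length-K component parameters,
#'   ordered by ascending mean.
#' @slot K integer component count.
#' @slot logLik mean per-pixel log-likelihood at convergence.
#' @slot iterations EM iterations used.
#' @export
setClass("GMMFit",
  representation(mean = "numeric", variance = "numeric", weight = "numeric",
                 K = "integer", logLik = "numeric", iterations = "integer"))

setValidity("GMMFit", function(object) {
  K <- object@K
  if (length(object@mean) != K || length(object@variance) != K ||
      length(object@weight) != K)
    return("mean, variance, weight must all have length K")
  if (any(object@weight <= 0)) return("weights must be positive")
  if (abs(sum(object@weight) - 1) > 1e-9) return("weights must sum to 1")
  if (any(object@variance <= 0)) return("variances must be positive")
  if (is.unsorted(object@mean)) return("means must be sorted ascending")
  TRUE
})

#' MaskStack: per-slice binary condyle masks over a VOI
#'
#' Logical 3D array aligned with the (cropped) volume it was segmented
#' from, indexed like [CBCTVolume-class] values. After postprocessing the
#' slices containing foreground form one contiguous run, recorded in
#' `firstSlice`/`lastSlice` (NA when the stack is empty).
#'
#' @slot mask logical 3D array.
#' @slot spacing voxel spacing `(dx, dy, dz)` in mm.
#' @slot firstSlice,lastSlice indices of the first/last slice containing
#'   foreground.
#' @export
setClass("MaskStack",
  representation(mask = "array", spacing = "numeric",
                 firstSlice = "integer", lastSlice = "integer"))

setValidity("MaskStack", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    return("mask must be a logical 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers")
  counts <- apply(object@mask, 3L, any)
  if (any(counts)) {
    run <- range(which(counts))
    if (!identical(object@firstSlice, run[1]) ||
        !identical(object@lastSlice, run[2]))
      return("firstSlice/lastSlice inconsistent with mask content")
    if (!all(counts[run[1]:run[2]]))
      return("foreground slices must form one contiguous run")
  }
  TRUE
})

#' Construct a MaskStack
#' @param mask logical 3D array of per-slice condyle masks.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @return A [MaskStack-class] object.
#' @export
MaskStack <- function(mask, spacing) {
  counts <- apply(mask, 3L, any)
  if (any(counts)) {
    first <- as.integer(min(which(counts))); last <- as.integer(max(which(counts)))
  } else first <- last <- NA_integer_
  new("MaskStack", mask = mask, spacing = as.numeric(spacing),
      firstSlice = first, lastSlice = last)
}

#' MinAreaRect: minimum-area enclosing rectangle of a slice mask
#'
#' Corner coordinates are axial-plane millimetres (pixel centres). The two
#' shorter sides sit at the ends of the component's long axis; contact
#' points with the mask on those sides are the longest-section endpoint
#' candidates.
#'
#' @slot corners 4x2 numeric matrix of corner points (mm), consecutive
#'   corners adjacent.
#' @slot width,height side lengths (mm), `width >= height`.
#' @slot angleDeg orientation of the long side, degrees in `(-90, 90]`.
#' @slot shortSides list of two 2x2 matrices, each a shorter side's
#'   endpoints.
#' @slot isSquare TRUE when width and height are equal within tolerance.
#' @export
setClass("MinAreaRect",
  representation(corners = "matrix", width = "numeric", height = "numeric",
                 angleDeg = "numeric", shortSides = "list",
                 isSquare = "logical"))

setValidity("MinAreaRect", function(object) {
  if (!all(dim(object@corners) == c(4L, 2L))) return("corners must be 4x2")
  e1 <- object@corners[2, ] - object@corners[1, ]
  e2 <- object@corners[3, ] - object@corners[2, ]
  if (abs(sum(e1 * e2)) > 1e-6 * max(1, sqrt(sum(e1^2)) * sqrt(sum(e2^2))))
    return("adjacent edges must be orthogonal")
  if (object@height > object@width + 1e-9) return("height must not exceed width")
  TRUE
})

#' LongestSection: the condyle's longest axial-projection section
#'
#' @slot p0,p1 numeric length-2 endpoints (axial-plane mm).
#' @slot slice0,slice1 source slice index of each endpoint.
#' @slot lengthMm Euclidean endpoint distance (mm).
#' @export
setClass("LongestSection",
  representation(p0 = "numeric", p1 = "numeric", slice0 = "integer",
                 slice1 = "integer", lengthMm = "numeric"))

setValidity("LongestSection", function(object) {
  len <- sqrt(sum((object@p1 - object@p0)^2))
  if (abs(len - object@lengthMm) > 1e-9) return("lengthMm inconsistent with endpoints")
  if (object@lengthMm <= 0) return("section length must be positive")
  TRUE
})

#' ReferencePlane: the vertical measurement plane
#'
#' The plane passes through the midpoint of the longest section, is
#' vertical, and its in-axial-plane normal points along the section
#' (perpendicular-bisector construction).
#'
#' @slot anchor numeric length-2 axial-plane point (mm), midpoint of the
#'   longest section.
#' @slot azimuthDeg azimuth of the plane normal in the axial plane,
#'   degrees in `(-90, 90]` (modulo 180).
#' @export
setClass("ReferencePlane",
  representation(anchor = "numeric", azimuthDeg = "numeric"))

setValidity("ReferencePlane", function(object) {
  if (length(object@anchor) != 2L || any(!is.finite(object@anchor)))
    return("anchor must be a finite 2D point")
  if (!is.finite(object@azimuthDeg) ||
      object@azimuthDeg <= -90 || object@azimuthDeg > 90)
    return("azimuthDeg must lie in (-90, 90]")
  TRUE
})

#' ReferenceSlice: the 2D image resampled in the reference plane
#'
#' In-plane coordinates are `u` (horizontal, spacing `du`) and `v`
#' (vertical, spacing `dv = dz`, increasing downward). `values[iu, iv]`
#' maps to `u = (iu - 1) * du`, `v = (iv - 1) * dv`. `dorsalSign` records
#' which u direction is dorsal (posterior); `anchorU` is the u coordinate
#' of the reference-plane anchor.
#'
#' @slot values numeric matrix of pseudo-HU values.
#' @slot mask logical matrix, per-pixel bone classification (GMM, no hole
#'   filling, no largest-component restriction).
#' @slot du,dv in-plane spacing (mm).
#' @slot anchorU u coordinate (mm) of the plane anchor.
#' @slot dorsalSign +1 or -1: sign of the u direction pointing dorsally.
#' @slot laterality "left" or "right" joint.
#' @slot azimuthDeg azimuth of the source plane.
#' @export
setClass("ReferenceSlice",
  representation(values = "matrix", mask = "matrix", du = "numeric",
                 dv = "numeric", anchorU = "numeric", dorsalSign = "numeric",
                 laterality = "character", azimuthDeg = "numeric"))

setValidity("ReferenceSlice", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must have identical dimensions")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@du <= 0 || object@dv <= 0) return("spacings must be positive")
  if (!object@dorsalSign %in% c(-1, 1)) return("dorsalSign must be +1 or -1")
  if (!object@laterality %in% c("left", "right"))
    return("laterality must be 'left' or 'right'")
  TRUE
})

#' Profile: intensity samples along a half-line in the reference slice
#'
#' @slot positions strictly increasing sample positions (mm from origin).
#' @slot values sampled pseudo-HU values (bilinear interpolation).
#' @slot origin numeric length-2 slice point (u, v) in mm.
#' @slot direction unit vector (u, v) of the half-line.
#' @export
setClass("Profile",
  representation(positions = "numeric", values = "numeric",
                 origin = "numeric", direction = "numeric"))

setValidity("Profile", function(object) {
  n <- length(object@positions)
  if (length(object@values) != n) return("positions/values length mismatch")
  if (n >= 2) {
    st <- diff(object@positions)
    if (any(st <= 0)) return("positions must be strictly increasing")
    if (diff(range(st)) > 1e-9 * max(st)) return("positions must be uniform")
  }
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must be a unit vector")
  TRUE
})

#' TangentResult: outcome of the tangent sweep on one side
#'
#' @slot side "dorsal" or "frontal".
#' @slot thetaBelow,thetaAbove fine bracketing angles (degrees from the
#'   downward vertical).
#' @slot thetaT tangent angle, the mean of the bracketing pair.
#' @slot contact tangent contact point on the condyle boundary (slice mm).
#' @slot crossing head-entry point of the last crossing line (slice mm).
#' @slot dSeries data.frame with columns theta, d: distance-to-first-slope
#'   samples (coarse then fine), NA where no bone entry was found.
#' @export
setClass("TangentResult",
  representation(side = "character", thetaBelow = "numeric",
                 thetaAbove = "numeric", thetaT = "numeric",
                 contact = "numeric", crossing = "numeric",
                 dSeries = "data.frame"))

#' TMJMeasurement: landmarks, angles and the three gap widths
#'
#' Landmark coordinates are reference-slice (u, v) millimetres. Gap widths
#' `rC` (upper), `rD` (dorsal) and `rF` (frontal) are Euclidean distances
#' between the condyle-side and acetabulum-side landmarks.
#'
#' @slot landmarks named list of 2D points: pTMJh, pTMJa, pTMJD, pTMJF,
#'   pTMJaD, pTMJaF.
#' @slot rC,rD,rF gap widths in mm.
#' @slot thetaTD,thetaTF tangent angles (degrees) on the dorsal/frontal
#'   side.
#' @slot laterality "left" or "right".
#' @slot planeAzimuthDeg azimuth of the reference plane.
#' @slot sectionLengthMm length of the longest section (mm).
#' @slot degenerate character vector naming gap widths below one voxel
#'   (clinically meaningful contact cases), empty otherwise.
#' @export
setClass("TMJMeasurement",
  representation(landmarks = "list", rC = "numeric", rD = "numeric",
                 rF = "numeric", thetaTD = "numeric", thetaTF = "numeric",
                 laterality = "character", planeAzimuthDeg = "numeric",
                 sectionLengthMm = "numeric", degenerate = "character"))

setValidity("TMJMeasurement", function(object) {
  need <- c("pTMJh", "pTMJa", "pTMJD", "pTMJF", "pTMJaD", "pTMJaF")
  if (!all(need %in% names(object@landmarks)))
    return("landmarks must contain pTMJh, pTMJa, pTMJD, pTMJF, pTMJaD, pTMJaF")
  if (any(c(object@rC, object@rD, object@rF) < 0))
    return("gap widths must be non-negative")
  if (object@landmarks$pTMJa[2] >= object@landmarks$pTMJh[2])
    return("pTMJa must lie strictly above pTMJh (smaller v)")
  TRUE
})

#' PhantomSpec: parameters of the synthetic condyle/fossa phantom
#'
#' @slot spacing voxel spacing `(dx, dy, dz)` mm.
#' @slot dims grid dimensions `(nx, ny, nz)`.
#' @slot shape "sphere" or "ellipsoid".
#' @slot radius sphere radius (mm); ignored for ellipsoids.
#' @slot axes ellipsoid half-axes `(a, b, c)` mm with `a >= b`; `c` is the
#'   vertical half-axis.
#' @slot azimuthDeg long-axis azimuth (degrees) in the axial plane.
#' @slot gap uniform condyle-to-fossa gap (mm).
#' @slot fossaOffset `(x, y)` mm shift of the fossa inner surface centre
#'   (eccentric gap); `c(0, 0)` for concentric.
#' @slot shellThickness thickness of the fossa bone shell (mm).
#' @slot intensities named list bone/soft/air, each `c(mean, sd)`
#'   pseudo-HU.
#' @slot cavityRadius radius of an internal soft-intensity cavity in the
#'   condyle (mm, 0 = none); exercises convex-hull filling.
#' @slot distractor add a bone slab touching the VOI border (exercises
#'   border-component removal).
#' @slot seed integer noise seed.
#' @export
setClass("PhantomSpec",
  representation(spacing = "numeric", dims = "integer", shape = "character",
                 radius = "numeric", axes = "numeric", azimuthDeg = "numeric",
                 gap = "numeric", fossaOffset = "numeric",
                 shellThickness = "numeric", intensities = "list",
                 cavityRadius = "numeric", distractor = "logical",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (length(object@dims) != 3L || any(object@dims < 8L))
    return("dims must be 3 integers >= 8")
  if (!object@shape %in% c("sphere", "ellipsoid"))
    return("shape must be 'sphere' or 'ellipsoid'")
  if (object@gap <= 0) return("gap must be positive")
  ints <- object@intensities
  if (!all(c("bone", "soft", "air") %in% names(ints)))
    return("intensities must name bone, soft, air")
  if (!(ints$bone[1] > ints$soft[1] && ints$soft[1] > ints$air[1]))
    return("intensity means must satisfy bone > soft > air")
  ax <- .phantomAxes(object)
  if (ax[1] < ax[2]) return("long half-axis a must be >= b")
  ext <- ax[1:2] + object@gap
  halfx <- (object@dims[1] - 1) * object@spacing[1] / 2
  halfy <- (object@dims[2] - 1) * object@spacing[2] / 2
  if (ext[1] + 3 * object@spacing[1] > halfx ||
      ext[1] + 3 * object@spacing[2] > halfy)
    return("condyle (plus gap) must fit inside the grid with a 3-voxel margin")
  TRUE
})
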
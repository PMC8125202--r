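# Reference cross-section geometry: minimum-area rectangle per slice,
# longest-section search, perpendicular-bisector plane, and extraction of
# the reference slice by whole-volume rotation.

#' Minimum-area enclosing rectangle of a slice mask
#'
#' Rotating-calipers construction: the minimum-area rectangle of a convex
#' hull has one side collinear with a hull edge, so the rectangle is found
#' by scanning the hull edges. Operates on pixel centres in axial-plane
#' millimetres.
#'
#' @param mask logical matrix (slice mask), at least 3 non-collinear
#'   pixels.
#' @param spacing in-plane spacing `(dx, dy)` mm.
#' @return A [MinAreaRect-class].
#' @export
minAreaRect <- function(mask, spacing = c(1, 1)) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0L) stop("mask is empty")
  P <- cbind((pts[, 1] - 1) * spacing[1], (pts[, 2] - 1) * spacing[2])
  h <- grDevices::chull(P[, 1], P[, 2])
  H <- P[h, , drop = FALSE]
  if (nrow(H) < 3L || .polyArea(H) < 1e-12)
    stop("degenerate (collinear) component")
  best <- NULL
  for (i in seq_len(nrow(H))) {
    j <- if (i == nrow(H)) 1L else i + 1L
    e <- H[j, ] - H[i, ]
    ang <- atan2(e[2], e[1])
    ca <- cos(-ang); sa <- sin(-ang)
    rx <- H[, 1] * ca - H[, 2] * sa
    ry <- H[, 1] * sa + H[, 2] * ca
    w <- max(rx) - min(rx); hgt <- max(ry) - min(ry)
    if (is.null(best) || w * hgt < best$area - 1e-12) {
      best <- list(area = w * hgt, ang = ang,
                   xr = range(rx), yr = range(ry))
    }
  }
  ca <- cos(best$ang); sa <- sin(best$ang)
  back <- function(x, y) c(x * ca - y * sa, x * sa + y * ca)
  corners <- rbind(back(best$xr[1], best$yr[1]),
                   back(best$xr[2], best$yr[1]),
                   back(best$xr[2], best$yr[2]),
                   back(best$xr[1], best$yr[2]))
  w <- diff(best$xr); hgt <- diff(best$yr)
  if (w >= hgt) {
    width <- w; height <- hgt
    shortSides <- list(corners[c(2, 3), ], corners[c(4, 1), ])
    angleDeg <- best$ang * 180 / pi
  } else {
    width <- hgt; height <- w
    shortSides <- list(corners[c(1, 2), ], corners[c(3, 4), ])
    angleDeg <- best$ang * 180 / pi + 90
  }
  angleDeg <- ((angleDeg + 90) %% 180) - 90
  if (angleDeg <= -90) angleDeg <- angleDeg + 180
  new("MinAreaRect", corners = corners, width = width, height = height,
      angleDeg = angleDeg, shortSides = shortSides,
      isSquare = abs(width - height) < 1e-9)
}

.polyArea <- function(V) {
  n <- nrow(V)
  j <- c(2:n, 1)
  abs(sum(V[, 1] * V[j, 2] - V[j, 1] * V[, 2])) / 2
}

#' Contact point between a rectangle side and the mask
#'
#' Pixels of the component whose centres lie within `tol` of the side's
#' supporting line are averaged and the mean is projected onto the line.
#' The tolerance guards rasterization: an exact minimum rectangle touches
#' the hull, but pixel centres sit up to half a voxel diagonal away.
#'
#' @param mask logical matrix (slice mask).
#' @param side 2x2 matrix, the side's endpoints (mm).
#' @param spacing in-plane spacing `(dx, dy)` mm.
#' @param tol contact distance tolerance in mm; default 0.75 of the
#'   in-plane voxel diagonal.
#' @return Numeric length-2 contact point (mm).
#' @export
sideContactPoint <- function(mask, side, spacing = c(1, 1), tol = NULL) {
  if (is.null(tol)) tol <- 0.75 * sqrt(sum(spacing^2))
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0L) stop("mask is empty")
  P <- cbind((pts[, 1] - 1) * spacing[1], (pts[, 2] - 1) * spacing[2])
  A <- side[1, ]; B <- side[2, ]
  u <- B - A
  len <- sqrt(sum(u^2))
  if (len < 1e-12) stop("degenerate side")
  u <- u / len
  rel <- sweep(P, 2, A)
  dist <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
  sel <- dist <= tol
  if (!any(sel)) stop("no mask contact within tolerance of the side")
  m <- colMeans(P[sel, , drop = FALSE])
  t <- sum((m - A) * u)
  A + t * u
}

#' Longest axial-projection section through the condyle
#'
#' For every head-bearing slice the minimum-area rectangle of the mask is
#' built and the contact points of its two shorter sides collected; the
#' pair of collected candidates with the largest 2D distance is the
#' longest section. When a rectangle is square (no unique shorter pair)
#' the side pair whose contact points are farther apart is used. Slices
#' whose component is collinear fall back to the endpoints of the pixel
#' set's diameter.
#'
#' @param stack a [MaskStack-class] with at least one nonempty slice.
#' @param contactTolVoxels contact tolerance in units of the in-plane
#'   voxel diagonal.
#' @return A [LongestSection-class].
#' @export
longestSection <- function(stack, contactTolVoxels = 0.75) {
  sp <- stack@spacing[1:2]
  tol <- contactTolVoxels * sqrt(sum(sp^2))
  if (is.na(stack@firstSlice)) stop("empty mask stack")
  cand <- list()
  for (k in stack@firstSlice:stack@lastSlice) {
    m <- stack@mask[, , k]
    if (!any(m)) next
    pair <- tryCatch({
      rect <- minAreaRect(m, sp)
      sides <- list(rect@shortSides)
      if (rect@isSquare) {
        longSides <- list(rect@corners[c(1, 2), ], rect@corners[c(3, 4), ])
        if (identical(rect@shortSides[[1]], longSides[[1]]))
          longSides <- list(rect@corners[c(2, 3), ], rect@corners[c(4, 1), ])
        sides <- c(sides, list(longSides))
      }
      bestPair <- NULL
      for (s in sides) {
        p0 <- sideContactPoint(m, s[[1]], sp, tol)
        p1 <- sideContactPoint(m, s[[2]], sp, tol)
        if (is.null(bestPair) ||
            sum((p1 - p0)^2) > sum((bestPair[[2]] - bestPair[[1]])^2))
          bestPair <- list(p0, p1)
      }
      bestPair
    }, error = function(e) {
      if (!grepl("degenerate", conditionMessage(e))) stop(e)
      .diameterEndpoints(m, sp)
    })
    if (!is.null(pair))
      cand[[length(cand) + 1L]] <- list(p0 = pair[[1]], p1 = pair[[2]], k = k)
  }
  if (length(cand) == 0L) stop("all slices degenerate")
  pts <- do.call(rbind, lapply(cand, function(cc) rbind(cc$p0, cc$p1)))
  ks <- rep(vapply(cand, function(cc) cc$k, 0L), each = 2L)
  dd <- as.matrix(stats::dist(pts))
  idx <- arrayInd(which.max(dd), dim(dd))
  i <- idx[1]; j <- idx[2]
  if (dd[i, j] <= 0) stop("all slices degenerate")
  new("LongestSection", p0 = pts[i, ], p1 = pts[j, ],
      slice0 = ks[i], slice1 = ks[j], lengthMm = dd[i, j])
}

# Endpoints of the pixel set's diameter (fallback for collinear
# components).
.diameterEndpoints <- function(mask, spacing) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2L) return(NULL)
  P <- cbind((pts[, 1] - 1) * spacing[1], (pts[, 2] - 1) * spacing[2])
  dd <- as.matrix(stats::dist(P))
  idx <- arrayInd(which.max(dd), dim(dd))
  if (dd[idx[1], idx[2]] <= 0) return(NULL)
  list(P[idx[1], ], P[idx[2], ])
}

#' Reference plane from the longest section
#'
#' The vertical measurement plane is the perpendicular bisector of the
#' longest section: anchored at its midpoint, with in-plane normal along
#' the section direction. Swapping the endpoints yields the same plane
#' (azimuth modulo 180 degrees).
#'
#' @param sec a [LongestSection-class].
#' @return A [ReferencePlane-class].
#' @export
referencePlane <- function(sec) {
  d <- sec@p1 - sec@p0
  if (sqrt(sum(d^2)) < 1e-12) stop("zero-length section")
  az <- atan2(d[2], d[1]) * 180 / pi
  az <- ((az + 90) %% 180) - 90
  if (az <= -90) az <- az + 180
  new("ReferencePlane", anchor = (sec@p0 + sec@p1) / 2, azimuthDeg = az)
}

#' Rotate a volume about the vertical axis
#'
#' Resamples the volume on its own grid after an in-plane rotation about
#' a vertical axis through `center`, using bilinear interpolation within
#' each axial plane (exact in z, so the composite 3D resampling is
#' trilinear with degenerate vertical weights). Out-of-volume samples are
#' filled with `fill`.
#'
#' @param vol a [CBCTVolume-class].
#' @param angleDeg rotation angle in degrees (counter-clockwise in the
#'   axial x-y plane).
#' @param center numeric length-2 axial-plane rotation centre (mm).
#' @param fill fill value for samples outside the volume (default -1000,
#'   air).
#' @return The rotated [CBCTVolume-class].
#' @export
rotateVolumeZ <- function(vol, angleDeg, center, fill = -1000) {
  d <- dim(vol@values)
  dx <- vol@spacing[1]; dy <- vol@spacing[2]
  if (abs(angleDeg) < 1e-12) return(vol)
  th <- .deg2rad(angleDeg)
  # image content rotated CCW by angleDeg:
  # output(p) = input(center + R(-angleDeg) (p - center))
  gx <- ((seq_len(d[1]) - 1) * dx) - center[1]
  gy <- ((seq_len(d[2]) - 1) * dy) - center[2]
  X <- matrix(gx, d[1], d[2])
  Y <- matrix(gy, d[1], d[2], byrow = TRUE)
  sx <- center[1] + cos(th) * X + sin(th) * Y
  sy <- center[2] - sin(th) * X + cos(th) * Y
  px <- sx / dx + 1
  py <- sy / dy + 1
  ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2]
  i0 <- pmin(pmax(floor(px), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(py), 1), d[2] - 1)
  fx <- px - i0; fy <- py - j0
  nxy <- d[1] * d[2]
  Vmat <- matrix(vol@values, nxy, d[3])
  l00 <- as.vector((j0 - 1) * d[1] + i0)
  w00 <- as.vector((1 - fx) * (1 - fy))
  w10 <- as.vector(fx * (1 - fy))
  w01 <- as.vector((1 - fx) * fy)
  w11 <- as.vector(fx * fy)
  out <- Vmat[l00, , drop = FALSE] * w00 +
    Vmat[l00 + 1L, , drop = FALSE] * w10 +
    Vmat[l00 + d[1], , drop = FALSE] * w01 +
    Vmat[l00 + d[1] + 1L, , drop = FALSE] * w11
  out[!as.vector(ok), ] <- fill
  CBCTVolume(array(out, d), spacing = vol@spacing, origin = vol@origin)
}

#' Extract the reference slice in the measurement plane
#'
#' Rotates the whole volume about the vertical axis through the plane
#' anchor so that the measurement plane becomes parallel to a grid plane,
#' then takes the grid plane through the anchor. The slice's bone mask is
#' re-segmented with the per-slice Gaussian mixture classifier, without
#' hole filling and without largest-component restriction so that the
#' acetabulum survives. The in-plane axes are `u` (horizontal, spacing
#' `dy`) and `v` (vertical, spacing `dz`, increasing downward); with the
#' azimuth normalized to `(-90, 90]`, the +u direction points dorsally
#' (posteriorly).
#'
#' @param vol the (cropped, denoised) [CBCTVolume-class].
#' @param stack the [MaskStack-class] from [segmentTmjHead()] (carried for
#'   provenance; the slice mask itself is re-segmented).
#' @param plane a [ReferencePlane-class] with its anchor inside the
#'   volume.
#' @param laterality `"left"` or `"right"` joint (metadata; resolves label
#'   presentation, not the dorsal direction).
#' @param cfg configuration list, see [tmjConfig()].
#' @return A [ReferenceSlice-class].
#' @export
extractReferenceSlice <- function(vol, stack, plane,
                                  laterality = c("right", "left"),
                                  cfg = tmjConfig()) {
  laterality <- match.arg(laterality)
  d <- dim(vol@values)
  a <- plane@anchor
  lim <- (d[1:2] - 1) * vol@spacing[1:2]
  if (any(a < 0) || a[1] > lim[1] || a[2] > lim[2])
    stop("plane anchor outside volume")
  rot <- rotateVolumeZ(vol, -plane@azimuthDeg, center = a)
  ixa <- round(a[1] / vol@spacing[1]) + 1
  ixa <- min(max(ixa, 1L), d[1])
  vals <- rot@values[ixa, , ]  # (u = y index, v = z index)
  sc <- cfg$segmentation
  fit <- fitGmmSlice(vals, K = sc$components, seed = sc$seed, tol = sc$tol,
                     varFloor = sc$varFloor)
  mask <- classifyBone(vals, fit)
  new("ReferenceSlice", values = vals, mask = mask,
      du = vol@spacing[2], dv = vol@spacing[3],
      anchorU = a[2], dorsalSign = 1, laterality = laterality,
      azimuthDeg = plane@azimuthDeg)
}
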
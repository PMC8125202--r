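# Gap measurement on the reference slice: landmark location, line
# profiles, derivative-peak edge detection, tangent sweep, and the three
# gap widths.

#' Locate the top of the TMJ head (P_TMJh)
#'
#' On the uppermost head-bearing slice of the stack, the in-slice
#' projection line of the reference plane is intersected with the head
#' mask; the midpoint of the intersection run, mapped into
#' reference-slice coordinates, is the head-top landmark. With several
#' disjoint runs the longest is used (with a warning).
#'
#' @param stack the [MaskStack-class] from [segmentTmjHead()].
#' @param plane the [ReferencePlane-class].
#' @param ref the [ReferenceSlice-class] (supplies the coordinate frame).
#' @return Numeric length-2 slice point `(u, v)` in mm.
#' @export
locateHeadTop <- function(stack, plane, ref) {
  if (is.na(stack@firstSlice)) stop("empty mask stack")
  k0 <- stack@firstSlice
  m <- stack@mask[, , k0]
  sp <- stack@spacing
  phi <- .deg2rad(plane@azimuthDeg)
  dirv <- c(-sin(phi), cos(phi))  # in-slice direction of the plane
  a <- plane@anchor
  lim <- (dim(m) - 1) * sp[1:2]
  tmax <- sqrt(sum(lim^2))
  step <- 0.25 * min(sp[1:2])
  t <- seq(-tmax, tmax, by = step)
  px <- (a[1] + t * dirv[1]) / sp[1] + 1
  py <- (a[2] + t * dirv[2]) / sp[2] + 1
  ix <- round(px); iy <- round(py)
  ok <- ix >= 1 & ix <= nrow(m) & iy >= 1 & iy <= ncol(m)
  inside <- logical(length(t))
  inside[ok] <- m[cbind(ix[ok], iy[ok])]
  if (!any(inside))
    stop("reference plane does not intersect the head on its top slice")
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) > 1L)
    warning("multiple plane/head intersection runs on the top slice; ",
            "using the longest")
  best <- runs[which.max(r$lengths[runs])]
  tmid <- (t[starts[best]] + t[ends[best]]) / 2
  # u = anchor u + signed distance along the plane direction; the head
  # apex lies between this slice and the empty one above it, so the v
  # coordinate is taken half a slice up (half-sample boundary estimate)
  c(ref@anchorU + tmid, max((k0 - 1.5) * sp[3], 0))
}

#' Locate the acetabulum point (P_TMJa)
#'
#' Marches upward (decreasing v) from the head top along the vertical
#' line through it, skips the head's own bone run, requires at least one
#' non-bone sample (the joint gap), and returns the first bone pixel
#' encountered after that: the roof of the radiological fossa. The
#' reported v coordinate is the half-sample boundary between that bone
#' pixel and the gap, which is where the cortical surface lies on
#' average.
#'
#' @param ref the [ReferenceSlice-class] (its GMM bone mask is used).
#' @param pH head-top point `(u, v)` in mm from [locateHeadTop()].
#' @return Numeric length-2 slice point `(u, v)` in mm.
#' @export
locateAcetabulumPoint <- function(ref, pH) {
  iu <- round(pH[1] / ref@du) + 1
  iu <- min(max(iu, 1L), nrow(ref@mask))
  iv <- round(pH[2] / ref@dv) + 1
  iv <- min(max(iv, 1L), ncol(ref@mask))
  while (iv >= 1L && ref@mask[iu, iv]) iv <- iv - 1L  # skip head bone run
  gapSeen <- FALSE
  while (iv >= 1L && !ref@mask[iu, iv]) {
    gapSeen <- TRUE
    iv <- iv - 1L
  }
  if (iv < 1L || !gapSeen)
    stop("acetabulum not in VOI (no fossa bone above the head top)")
  # the fossa surface lies between this bone pixel and the non-bone
  # pixel below it: report the half-sample boundary, not the centre;
  # the u coordinate stays on the vertical line through the head top,
  # so r_C is purely vertical by construction
  c(pH[1], (iv - 0.5) * ref@dv)
}

#' Upper joint-space width r_C
#'
#' Euclidean distance between the acetabulum point and the head top; by
#' construction the segment is vertical, perpendicular to the Frankfurt
#' plane for a scan acquired in Natural Head Position.
#'
#' @param pH,pA slice points `(u, v)` in mm.
#' @return Length in mm (0 is a degenerate contact case, flagged by
#'   [measureTMJ()]).
#' @export
computeRc <- function(pH, pA) sqrt(sum((pA - pH)^2))

#' Intensity profile along a half-line of the reference slice
#'
#' Bilinear samples at a uniform step along the half-line from `origin`
#' in direction `direction`, truncated at the slice boundary.
#'
#' @param ref the [ReferenceSlice-class].
#' @param origin slice point `(u, v)` in mm.
#' @param direction length-2 direction vector (need not be unit).
#' @param step sample step in mm; default half the smaller in-plane
#'   spacing.
#' @param maxLen maximal profile length in mm; default the slice
#'   diagonal.
#' @return A [Profile-class].
#' @export
lineProfile <- function(ref, origin, direction, step = NULL, maxLen = NULL) {
  d <- dim(ref@values)
  if (is.null(step)) step <- 0.5 * min(ref@du, ref@dv)
  if (is.null(maxLen))
    maxLen <- sqrt(sum(((d - 1) * c(ref@du, ref@dv))^2))
  dirn <- direction / sqrt(sum(direction^2))
  pos <- seq(0, maxLen, by = step)
  pu <- (origin[1] + pos * dirn[1]) / ref@du + 1
  pv <- (origin[2] + pos * dirn[2]) / ref@dv + 1
  ok <- pu >= 1 & pu <= d[1] & pv >= 1 & pv <= d[2]
  keep <- if (any(!ok)) min(which(!ok)) - 1L else length(ok)
  if (keep < 2L) stop("profile leaves the slice immediately")
  pos <- pos[seq_len(keep)]
  vals <- .bilinear(ref@values, pu[seq_len(keep)], pv[seq_len(keep)])
  new("Profile", positions = pos, values = vals, origin = as.numeric(origin),
      direction = dirn)
}

#' Distance to the first bone entry along a profile
#'
#' Computes the central-difference derivative of the profile and returns
#' the position of the first positive local maximum that exceeds the peak
#' threshold and lies beyond a minimal offset from the origin (skipping
#' the origin's own bone-exit peak). The threshold is relative to the
#' profile's largest absolute derivative, with a small absolute floor
#' against numerical dust.
#'
#' When `boneMask` is supplied (the GMM bone classification sampled along
#' the same line), the entry must additionally coincide with a soft-to-
#' bone transition of the mask: the first bone run after leaving the
#' origin's own bone run anchors the search, and the derivative peak
#' nearest that transition gives the sub-voxel position. This gates out
#' correlated-noise bumps inside the joint gap, which can otherwise
#' exceed the derivative threshold on low-dose scans.
#'
#' @param profile a [Profile-class].
#' @param peakFrac threshold as a fraction of the maximum absolute
#'   derivative (default 0.25).
#' @param minOffsetSamples minimal peak offset in samples (default 2).
#' @param peakFloor absolute minimal derivative (pseudo-HU/mm).
#' @param boneMask optional logical vector, the bone mask sampled at the
#'   profile positions.
#' @return Distance in mm, or `NA_real_` when no bone entry is found.
#' @export
firstBoneEntry <- function(profile, peakFrac = 0.25, minOffsetSamples = 2L,
                           peakFloor = 0.5, boneMask = NULL) {
  v <- profile@values
  n <- length(v)
  if (n < 3L) return(NA_real_)
  h <- profile@positions[2] - profile@positions[1]
  der <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * h), NA)
  thr <- max(peakFrac * max(abs(der), na.rm = TRUE), peakFloor)
  idx <- 2:(n - 1)
  isMax <- der[idx] >= der[idx - 1] & der[idx] > der[idx + 1]
  isMax[is.na(isMax)] <- FALSE
  cand <- idx[isMax & der[idx] > thr & idx > minOffsetSamples]
  if (is.null(boneMask)) {
    if (length(cand) == 0L) return(NA_real_)
    return(profile@positions[cand[1]])
  }
  stopifnot(length(boneMask) == n)
  # leave the origin's own bone run, then find the first sustained bone
  # run of the mask
  j <- 1L
  while (j <= n && boneMask[j]) j <- j + 1L
  entry <- NA_integer_
  while (j < n) {
    if (boneMask[j] && boneMask[j + 1L] && j > minOffsetSamples) {
      entry <- j
      break
    }
    j <- j + 1L
  }
  if (is.na(entry)) return(NA_real_)
  # sub-voxel refinement: derivative peak nearest the mask transition
  near <- cand[abs(cand - entry) <= 3L]
  if (length(near) > 0L) return(profile@positions[near[which.min(abs(near - entry))]])
  profile@positions[entry] - h / 2
}

# The head's own connected component in the reference-slice bone mask:
# the first bone run straight below the acetabulum point. Lines in the
# tangent sweep are tested against this component, so that a line past
# the tangent which still hits the fossa farther out counts as "no
# longer crossing the head".
.headMask <- function(ref, pA) {
  d <- dim(ref@mask)
  iu <- min(max(round(pA[1] / ref@du) + 1, 1L), d[1])
  iv <- min(max(round(pA[2] / ref@dv) + 1, 1L), d[2])
  while (iv <= d[2] && ref@mask[iu, iv]) iv <- iv + 1L  # leave the fossa
  while (iv <= d[2] && !ref@mask[iu, iv]) iv <- iv + 1L  # cross the gap
  if (iv > d[2]) stop("no head bone below the acetabulum point")
  lab <- .labelComponents(ref@mask, 8L)
  lab == lab[iu, iv]
}

# A mask sampled (nearest pixel) at the positions of a profile.
.maskAlong <- function(ref, profile, mask = ref@mask) {
  d <- dim(mask)
  pu <- round((profile@origin[1] + profile@positions * profile@direction[1]) /
                ref@du) + 1
  pv <- round((profile@origin[2] + profile@positions * profile@direction[2]) /
                ref@dv) + 1
  out <- logical(length(pu))
  ok <- pu >= 1 & pu <= d[1] & pv >= 1 & pv <= d[2]
  out[ok] <- mask[cbind(pu[ok], pv[ok])]
  out
}

#' Tangent angle from a distance-to-first-slope series
#'
#' Finds the first consecutive angle pair across which the distance to
#' the first bone entry jumps (the line has passed the tangent to the
#' head, so the next bone crossing is much farther or absent) and returns
#' the mean of the bracketing pair. A transition from a finite distance
#' to none counts as a jump.
#'
#' @param theta increasing angle grid (degrees).
#' @param d distances (mm) at each angle, `NA` = no bone entry.
#' @param stepThreshold jump threshold in mm; `NULL` (default) uses
#'   `max(1, 3 * median increment of d before the jump)`.
#' @return List with `thetaBelow`, `thetaAbove`, `thetaT` (their mean) and
#'   the index `i` of the bracket, or `NULL` when no jump is found.
#' @export
tangentBracket <- function(theta, d, stepThreshold = NULL) {
  n <- length(theta)
  stopifnot(length(d) == n)
  for (i in seq_len(n - 1L)) {
    if (is.na(d[i])) next
    jump <- if (is.na(d[i + 1])) Inf else d[i + 1] - d[i]
    thr <- stepThreshold
    if (is.null(thr)) {
      incs <- diff(d[seq_len(i)])
      incs <- incs[is.finite(incs)]
      thr <- if (length(incs)) max(1, 3 * stats::median(incs)) else 1
    }
    if (jump > thr)
      return(list(thetaBelow = theta[i], thetaAbove = theta[i + 1],
                  thetaT = (theta[i] + theta[i + 1]) / 2, i = i,
                  threshold = thr))
  }
  NULL
}

#' Tangent sweep on one side of the TMJ head
#'
#' Half-lines from the acetabulum point are swept away from the downward
#' vertical in coarse steps; at each angle the distance to the first bone
#' entry is measured on the line profile. The first coarse pair across
#' which this distance jumps brackets the tangent; the bracket is
#' re-swept at the fine step and the tangent angle is the mean of the
#' fine bracketing pair. The contact point is the bone-entry point of the
#' last line still crossing the head (the fine angle below the jump).
#'
#' @param ref the [ReferenceSlice-class].
#' @param pA acetabulum point `(u, v)` in mm.
#' @param side `"dorsal"` or `"frontal"`.
#' @param cfg configuration list, see [tmjConfig()]; uses the `sweep` and
#'   `profile` entries.
#' @return A [TangentResult-class].
#' @export
tangentSweep <- function(ref, pA, side = c("dorsal", "frontal"),
                         cfg = tmjConfig()) {
  side <- match.arg(side)
  sw <- cfg$sweep
  uSign <- if (side == "dorsal") ref@dorsalSign else -ref@dorsalSign
  headM <- .headMask(ref, pA)
  evalD <- function(thetaDeg) {
    th <- .deg2rad(thetaDeg)
    dirv <- c(uSign * sin(th), cos(th))
    p <- lineProfile(ref, pA, dirv, step = cfg$profile$stepFactor *
                       min(ref@du, ref@dv))
    firstBoneEntry(p, peakFrac = cfg$profile$peakFrac,
                   minOffsetSamples = cfg$profile$minOffsetSamples,
                   peakFloor = cfg$profile$peakFloor,
                   boneMask = .maskAlong(ref, p, headM))
  }
  coarse <- seq(0, sw$thetaMaxDeg, by = sw$coarseStepDeg)
  dCoarse <- vapply(coarse, evalD, 0)
  if (is.na(dCoarse[1]))
    stop("d(0) undefined: no bone entry below the acetabulum point")
  # Scan coarse pairs for a step; refine each candidate bracket at the
  # fine step. A candidate whose fine sweep shows only smooth growth is
  # a false alarm (d(theta) accelerates towards the tangent), so the
  # scan continues with the next coarse pair.
  brf <- NULL
  from <- 1L
  dSer <- data.frame(theta = coarse, d = dCoarse)
  repeat {
    sel <- from:length(coarse)
    br <- tangentBracket(coarse[sel], dCoarse[sel], sw$stepThresholdMm)
    if (is.null(br)) break
    fine <- seq(br$thetaBelow, br$thetaAbove, by = sw$fineStepDeg)
    dFine <- vapply(fine, evalD, 0)
    dSer <- rbind(dSer, data.frame(theta = fine, d = dFine))
    brf <- tangentBracket(fine, dFine, br$threshold)
    if (!is.null(brf)) {
      brf$dBelow <- dFine[brf$i]
      break
    }
    from <- from + br$i
    if (from >= length(coarse)) break
  }
  if (is.null(brf)) {
    if (is.na(dCoarse[length(coarse)]))
      stop("tangent not found (degenerate head shape)")
    # the discretized head still intersects every line up to the sweep
    # limit (grazing lines pick up boundary pixels of the mask): the
    # tangent lies at or just beyond the range
    warning("tangent at or beyond the sweep range; using its upper limit")
    th <- coarse[length(coarse)]
    brf <- list(thetaBelow = th, thetaAbove = th, thetaT = th,
                dBelow = dCoarse[length(coarse)])
  }
  thB <- .deg2rad(brf$thetaBelow)
  dirB <- c(uSign * sin(thB), cos(thB))
  contact <- pA + brf$dBelow * dirB
  new("TangentResult", side = side, thetaBelow = brf$thetaBelow,
      thetaAbove = brf$thetaAbove, thetaT = brf$thetaT,
      contact = contact, crossing = contact, dSeries = dSer)
}

#' Gap width at the tangent contact point
#'
#' From the tangent contact point a profile is cast perpendicular to the
#' tangent line, directed towards the acetabulum; the distance to the
#' first bone entry on that profile is the gap width, and the entry point
#' is the acetabulum-side landmark (P_TMJaD / P_TMJaF).
#'
#' @param ref the [ReferenceSlice-class].
#' @param tr a [TangentResult-class].
#' @param pA acetabulum point `(u, v)` in mm (fixes the inward
#'   direction).
#' @param cfg configuration list, see [tmjConfig()].
#' @return List with `r` (mm) and `point`, the acetabulum-side landmark.
#' @export
gapWidthAtTangent <- function(ref, tr, pA, cfg = tmjConfig()) {
  uSign <- if (tr@side == "dorsal") ref@dorsalSign else -ref@dorsalSign
  th <- .deg2rad(tr@thetaBelow)
  e <- c(uSign * sin(th), cos(th))
  n1 <- c(-e[2], e[1])
  # towards the acetabulum: away from the head, i.e. upward (contact
  # lies on the line through pA, so pA itself cannot disambiguate)
  if (n1[2] > 0) n1 <- -n1
  p <- lineProfile(ref, tr@contact, n1,
                   step = cfg$profile$stepFactor * min(ref@du, ref@dv))
  r <- firstBoneEntry(p, peakFrac = cfg$profile$peakFrac,
                      minOffsetSamples = cfg$profile$minOffsetSamples,
                      peakFloor = cfg$profile$peakFloor,
                      boneMask = .maskAlong(ref, p))
  if (is.na(r))
    stop(sprintf("fossa not found on the perpendicular (%s side)", tr@side))
  list(r = r, point = tr@contact + r * n1)
}

#' Measure the TMJ joint-space widths on a CBCT volume
#'
#' Full orchestration: VOI crop, curvature-flow denoising, per-slice
#' condyle segmentation, longest-section search, reference-plane
#' construction, reference-slice extraction, landmark location and the
#' three gap widths r_C (upper), r_D (dorsal), r_F (frontal). Errors from
#' any stage are re-thrown with the stage name attached. Gap widths below
#' one voxel are flagged degenerate (contact cases), not errors.
#'
#' @param vol the full [CBCTVolume-class].
#' @param voi the manually chosen [VOIBox-class].
#' @param laterality `"right"` or `"left"` joint.
#' @param cfg configuration list, see [tmjConfig()].
#' @return A [TMJMeasurement-class].
#' @export
measureTMJ <- function(vol, voi, laterality = c("right", "left"),
                       cfg = tmjConfig()) {
  laterality <- match.arg(laterality)
  cropped <- .stage("crop_voi", cropVolume(vol, voi))
  den <- .stage("denoise", curvatureFlowDenoise(
    cropped, timeStep = cfg$denoise$timeStep,
    iterations = cfg$denoise$iterations))
  stack <- .stage("segmentation", segmentTmjHead(den, cfg))
  sec <- .stage("longest_section",
                longestSection(stack, cfg$geometry$contactTolVoxels))
  plane <- .stage("reference_plane", referencePlane(sec))
  ref <- .stage("reference_slice",
                extractReferenceSlice(den, stack, plane, laterality, cfg))
  pH <- .stage("head_top", locateHeadTop(stack, plane, ref))
  pA <- .stage("acetabulum", locateAcetabulumPoint(ref, pH))
  rC <- .stage("r_C", computeRc(pH, pA))
  trD <- .stage("tangent_dorsal", tangentSweep(ref, pA, "dorsal", cfg))
  trF <- .stage("tangent_frontal", tangentSweep(ref, pA, "frontal", cfg))
  gD <- .stage("r_D", gapWidthAtTangent(ref, trD, pA, cfg))
  gF <- .stage("r_F", gapWidthAtTangent(ref, trF, pA, cfg))
  voxel <- min(ref@du, ref@dv)
  deg <- c(rC = rC, rD = gD$r, rF = gF$r)
  new("TMJMeasurement",
      landmarks = list(pTMJh = pH, pTMJa = pA, pTMJD = trD@contact,
                       pTMJF = trF@contact, pTMJaD = gD$point,
                       pTMJaF = gF$point),
      rC = rC, rD = gD$r, rF = gF$r,
      thetaTD = trD@thetaT, thetaTF = trF@thetaT,
      laterality = laterality, planeAzimuthDeg = plane@azimuthDeg,
      sectionLengthMm = sec@lengthMm,
      degenerate = names(deg)[deg < voxel])
}
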
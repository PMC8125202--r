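# Synthetic condyle/fossa phantom with analytically known gap widths.
#
# The phantom emulates the intensity regime observed near the TMJ on
# CBCT: a dominant air background, soft tissue filling the joint gap and
# surrounding the bone, and bone values that barely exceed 200 pseudo-HU,
# so segmentation genuinely requires the mixture model rather than a
# fixed threshold. Voxels straddling a tissue boundary get
# fraction-weighted intensities (2x2x2 supersampling), mimicking the
# partial-volume effect of real scanners and keeping surface
# localization unbiased at the voxel scale.

.phantomAxes <- function(spec) {
  if (spec@shape == "sphere") rep(spec@radius, 3) else spec@axes
}

#' Specify a synthetic condyle/fossa phantom
#'
#' Geometry (in a frame whose x' axis is the condyle long axis, rotated
#' by `azimuthDeg` in the axial plane): the condyle is an ellipsoid with
#' half-axes `(a, b, c)` (a sphere when `shape = "sphere"`); the
#' acetabular cavity's inner surface is the concentric ellipsoid offset
#' outward by `gap` (optionally shifted by `fossaOffset = (along-axis,
#' dorsal)` mm for eccentric gaps); the fossa bone is an ellipsoidal
#' shell of thickness `shellThickness` over the upper part of the head,
#' with a narrow root strip running medially to the grid border, the way
#' the temporal bone reaches the edge of any clinical VOI; a condylar
#' neck continues below the head the way the mandibular ramus does. Soft
#' tissue fills the joint gap and an envelope around the bone;
#' everything else is air.
#'
#' @param spacing voxel spacing `(dx, dy, dz)` mm.
#' @param dims grid dimensions `(nx, ny, nz)`.
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param radius sphere radius (mm).
#' @param axes ellipsoid half-axes `(a, b, c)` mm, `a >= b`, `c`
#'   vertical.
#' @param azimuthDeg long-axis azimuth in the axial plane (degrees).
#' @param gap condyle-to-fossa gap (mm).
#' @param fossaOffset `(along-axis, dorsal)` mm shift of the fossa inner
#'   surface (eccentric gap).
#' @param shellThickness fossa shell thickness (mm).
#' @param intensities named list `bone`, `soft`, `air`, each
#'   `c(mean, sd)` in pseudo-HU.
#' @param cavityRadius internal soft cavity radius in the condyle (mm).
#' @param distractor add a bone slab touching the VOI border.
#' @param seed noise seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(spacing = c(0.3, 0.3, 0.3),
                        dims = c(128L, 128L, 128L),
                        shape = c("sphere", "ellipsoid"),
                        radius = 6,
                        axes = c(10, 6, 6),
                        azimuthDeg = 0,
                        gap = 2,
                        fossaOffset = c(0, 0),
                        shellThickness = 2,
                        intensities = list(bone = c(180, 25),
                                           soft = c(-60, 25),
                                           air = c(-950, 25)),
                        cavityRadius = 0,
                        distractor = FALSE,
                        seed = 1L) {
  new("PhantomSpec", spacing = as.numeric(spacing), dims = as.integer(dims),
      shape = match.arg(shape), radius = as.numeric(radius),
      axes = as.numeric(axes), azimuthDeg = as.numeric(azimuthDeg),
      gap = as.numeric(gap), fossaOffset = as.numeric(fossaOffset),
      shellThickness = as.numeric(shellThickness), intensities = intensities,
      cavityRadius = as.numeric(cavityRadius),
      distractor = isTRUE(distractor), seed = as.integer(seed))
}

#' Generate a phantom volume with ground truth
#'
#' Renders the phantom described by a [PhantomSpec-class] and returns the
#' volume, the analytic ground truth and a volume of interest whose
#' uppermost slice lies in the bone plate right above the acetabulum (so
#' the condyle is absent from it) and which leaves air, soft tissue and
#' bone visible on every slice.
#'
#' @param spec a [PhantomSpec-class].
#' @return List with elements `volume` ([CBCTVolume-class]), `truth`
#'   (list: `rC`, `rD`, `rF`, `thetaTD`, `thetaTF`, `azimuthDeg`,
#'   `sectionLengthMm`, `vHeadTop`, `vAcetabulum` — the last two are
#'   VOI-relative v coordinates in mm) and `voi` ([VOIBox-class]).
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  sp <- spec@spacing; d <- spec@dims
  ax <- .phantomAxes(spec)
  a <- ax[1]; b <- ax[2]; cc <- ax[3]
  g <- spec@gap
  phi <- .deg2rad(spec@azimuthDeg)
  ox <- spec@fossaOffset[1]; oy <- spec@fossaOffset[2]
  ints <- spec@intensities
  t <- spec@shellThickness  # fossa shell thickness
  softPad <- 4

  cx <- (d[1] - 1) * sp[1] / 2
  cy <- (d[2] - 1) * sp[2] / 2
  vc <- 2 + cc + g + t  # air margin 2 mm above the shell top

  # VOI: 1-2 shell-cap slices on top (bone right above the acetabulum,
  # no head), 2 mm below the condyle, lateral half-extent a+g+6 mm (air
  # remains visible at the VOI edges)
  vTopVOI <- vc - (cc + g) - min(1.2, t / 2)
  kTop <- max(1L, floor(vTopVOI / sp[3]) + 1L)
  kBot <- min(d[3], floor((vc + cc + 2) / sp[3]) + 1L)
  halfX <- a + g + 6; halfY <- a + g + 6
  ix1 <- max(1L, ceiling((cx - halfX) / sp[1]) + 1L)
  ix2 <- min(d[1], floor((cx + halfX) / sp[1]) + 1L)
  iy1 <- max(1L, ceiling((cy - halfY) / sp[2]) + 1L)
  iy2 <- min(d[2], floor((cy + halfY) / sp[2]) + 1L)
  voi <- VOIBox(c(ix1, ix2), c(iy1, iy2), c(kTop, kBot))
  yVoiMax <- (iy2 - 1) * sp[2]

  gx <- (seq_len(d[1]) - 1) * sp[1]
  gy <- (seq_len(d[2]) - 1) * sp[2]
  X <- matrix(gx, d[1], d[2])
  Y <- matrix(gy, d[1], d[2], byrow = TRUE)
  offs <- c(-0.25, 0.25)

  boneCnt <- softCnt <- array(0L, d)
  classify <- function(x, y, v) {
    xr <- (x - cx) * cos(phi) + (y - cy) * sin(phi)
    yr <- -(x - cx) * sin(phi) + (y - cy) * cos(phi)
    w <- v - vc
    condyle <- (xr / a)^2 + (yr / b)^2 + (w / cc)^2 <= 1
    if (spec@cavityRadius > 0)
      condyle <- condyle & (xr^2 + yr^2 + w^2 > spec@cavityRadius^2)
    xf <- xr - ox; yf <- yr - oy
    outsideInner <- (xf / (a + g))^2 + (yf / (b + g))^2 +
      (w / (cc + g))^2 > 1
    # Fossa: an ellipsoidal bone shell of thickness `t` over the upper
    # part of the head (within a 65-degree cone about the vertical, so
    # its lower rim slopes steeply and no axial slice cuts a wide flat
    # bone edge), plus a narrow vertical-walled root strip running
    # medially (x' >= 3 mm, clear of the reference plane) to the grid
    # border. The strip keeps every axial cross-section of the fossa
    # border-connected, the way the temporal bone reaches the edge of a
    # clinical VOI, so the border-removal step deletes it as in real
    # scans.
    insideOuter <- (xf / (a + g + t))^2 + (yf / (b + g + t))^2 +
      (w / (cc + g + t))^2 <= 1
    # 65-degree cone about an axis tilted 20 degrees towards the medial
    # root: the shell's lower rim is then slanted, so no axial slice
    # cuts it in a free-floating partial-volume ring, and every shell
    # arc stays connected to the root strip
    p1 <- xf / (a + g); p2 <- yf / (b + g); p3 <- w / (cc + g)
    nrm <- sqrt(p1^2 + p2^2 + p3^2)
    inCone <- w < 0 &
      (p1 * sin(20 * pi / 180) - p3 * cos(20 * pi / 180)) >=
        nrm * cos(65 * pi / 180)
    root <- xr >= 3 & abs(yf) <= 2 & w < 0
    fossa <- outsideInner & ((insideOuter & inCone) | root)
    # condylar neck: bone continues below the head, as the mandibular
    # ramus does on real slices
    neck <- v >= vc & xr^2 + yr^2 <= (0.55 * b)^2
    bone <- condyle | fossa | neck
    if (spec@distractor)
      bone <- bone | (y >= yVoiMax - 1.5 & abs(x - cx) <= 3 &
                        v >= vc + 1 & v <= vc + 5)
    soft <- !bone & ((xr / (a + g + softPad))^2 +
                       (yr / (b + g + softPad))^2 <= 1)
    list(bone = bone, soft = soft)
  }

  for (k in seq_len(d[3])) {
    v <- (k - 1) * sp[3]
    bAcc <- sAcc <- matrix(0L, d[1], d[2])
    for (ou in offs) for (ov in offs) for (ow in offs) {
      cl <- classify(X + ou * sp[1], Y + ov * sp[2], v + ow * sp[3])
      bAcc <- bAcc + cl$bone
      sAcc <- sAcc + cl$soft
    }
    boneCnt[, , k] <- bAcc
    softCnt[, , k] <- sAcc
  }
  airCnt <- 8L - boneCnt - softCnt
  mu <- (boneCnt * ints$bone[1] + softCnt * ints$soft[1] +
           airCnt * ints$air[1]) / 8
  sdv <- (boneCnt * ints$bone[2] + softCnt * ints$soft[2] +
            airCnt * ints$air[2]) / 8
  noise <- .withSeed(spec@seed, stats::rnorm(prod(d)))
  vals <- mu + array(noise, d) * sdv

  vol <- CBCTVolume(vals, spacing = sp, origin = c(0, 0, 0))
  truth <- .phantomTruth(spec, vTopVOI = (kTop - 1) * sp[3])
  list(volume = vol, truth = truth, voi = voi)
}

# Analytic ground truth in the reference plane x' = 0 through the
# condyle centre (2D in-plane coordinates: y' toward dorsal, w downward
# from the centre).
.phantomTruth <- function(spec, vTopVOI) {
  ax <- .phantomAxes(spec)
  a <- ax[1]; b <- ax[2]; cc <- ax[3]
  g <- spec@gap
  ox <- spec@fossaOffset[1]; oy <- spec@fossaOffset[2]
  B <- b + g; C <- cc + g
  s2 <- 1 - (ox / (a + g))^2
  if (s2 <= (oy / B)^2) stop("fossa offset too large for the gap")
  wA <- -C * sqrt(s2 - (oy / B)^2)  # acetabulum point on the axis
  rC <- -wA - cc

  vc <- 2 + spec@shellThickness + cc + g
  oneSide <- function(sgn) {
    intersects <- function(thetaDeg) {
      th <- .deg2rad(thetaDeg)
      ey <- sgn * sin(th); ew <- cos(th)
      A2 <- (ey / b)^2 + (ew / cc)^2
      B2 <- 2 * wA * ew / cc^2
      C2 <- (wA / cc)^2 - 1
      B2^2 - 4 * A2 * C2 >= 0
    }
    lo <- 0; hi <- 89.9
    if (!intersects(lo)) stop("phantom axis line misses the condyle")
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (intersects(mid)) lo <- mid else hi <- mid
    }
    thT <- lo
    th <- .deg2rad(thT)
    ey <- sgn * sin(th); ew <- cos(th)
    A2 <- (ey / b)^2 + (ew / cc)^2
    B2 <- 2 * wA * ew / cc^2
    t0 <- -B2 / (2 * A2)
    P <- c(ey, ew) * t0 + c(0, wA)  # tangency point (y', w)
    n <- c(-ew, ey)
    if (sum(n * (c(0, wA) - P)) < 0) n <- -n
    # ray P + t n against the fossa inner cross-section ellipse
    s <- sqrt(s2)
    Af <- (n[1] / (B * s))^2 + (n[2] / (C * s))^2
    Bf <- 2 * ((P[1] - oy) * n[1] / (B * s)^2 + P[2] * n[2] / (C * s)^2)
    Cf <- ((P[1] - oy) / (B * s))^2 + (P[2] / (C * s))^2 - 1
    disc <- Bf^2 - 4 * Af * Cf
    if (disc < 0) stop("tangent perpendicular misses the fossa")
    roots <- (-Bf + c(-1, 1) * sqrt(disc)) / (2 * Af)
    r <- min(roots[roots > 0])
    list(thetaT = thT, r = r)
  }
  dorsal <- oneSide(1)
  frontal <- oneSide(-1)
  az <- ((spec@azimuthDeg + 90) %% 180) - 90
  if (az <= -90) az <- az + 180
  list(rC = rC, rD = dorsal$r, rF = frontal$r,
       thetaTD = dorsal$thetaT, thetaTF = frontal$thetaT,
       azimuthDeg = if (spec@shape == "sphere") NA_real_ else az,
       sectionLengthMm = 2 * a,
       vHeadTop = (vc - cc) - vTopVOI,
       vAcetabulum = (vc + wA) - vTopVOI)
}

#' Write a phantom volume as a DICOM series
#'
#' Thin wrapper around [writeDicomSeries()] so phantoms exercise the
#' same input path as clinical data.
#'
#' @param vol a [CBCTVolume-class] (e.g. from [generatePhantom()]).
#' @param directory output directory.
#' @return The directory, invisibly.
#' @export
writePhantomDicom <- function(vol, directory) writeDicomSeries(vol, directory)

#' Analytic 2D reference-slice fixture
#'
#' Builds a [ReferenceSlice-class] directly: a bone disk (the condyle
#' cross-section) with a one-pixel antialiased rim on a soft-tissue
#' background, optionally with a concentric or shifted fossa arc above
#' it. Used for resolution-controlled tests of the tangent sweep and gap
#' measurement, where the analytic tangent angle from an external point
#' to a circle, `asin(R / (R + d))`, is known exactly.
#'
#' @param R disk radius (mm).
#' @param d distance of the acetabulum point above the disk top (mm).
#' @param spacing in-plane spacing (mm/px).
#' @param fossaGap radial gap of a fossa arc (mm), `NA` for no arc.
#' @param fossaOffsetU dorsal (+u) shift of the arc centre (mm).
#' @param arcThickness arc thickness (mm).
#' @param widthMm,heightMm slice extent (mm).
#' @param bone,soft class intensities (pseudo-HU).
#' @return List with `ref` (the [ReferenceSlice-class]), `pA` (the
#'   acetabulum point, slice mm), `center` (disk centre) and `thetaT`
#'   (the analytic tangent angle, degrees).
#' @export
phantomReferenceSlice <- function(R = 6, d = 2, spacing = 0.02,
                                  fossaGap = NA, fossaOffsetU = 0,
                                  arcThickness = 2,
                                  widthMm = 24, heightMm = 20,
                                  bone = 180, soft = -60) {
  nu <- round(widthMm / spacing) + 1L
  nv <- round(heightMm / spacing) + 1L
  uc <- widthMm / 2
  vcen <- d + R + 4  # 4 mm headroom above the acetabulum point
  u <- (seq_len(nu) - 1) * spacing
  v <- (seq_len(nv) - 1) * spacing
  U <- matrix(u, nu, nv)
  V <- matrix(v, nu, nv, byrow = TRUE)
  w <- spacing
  ramp <- function(x) pmin(pmax(x / w + 0.5, 0), 1)
  rho <- sqrt((U - uc)^2 + (V - vcen)^2)
  frac <- ramp(R - rho)
  if (!is.na(fossaGap)) {
    rf <- sqrt((U - uc - fossaOffsetU)^2 + (V - vcen)^2)
    arc <- ramp(rf - (R + fossaGap)) * ramp((R + fossaGap + arcThickness) - rf) *
      ramp(vcen - V)
    frac <- pmax(frac, arc)
  }
  vals <- soft + (bone - soft) * frac
  mask <- frac > 0.5
  ref <- new("ReferenceSlice", values = vals, mask = mask, du = spacing,
             dv = spacing, anchorU = uc, dorsalSign = 1,
             laterality = "right", azimuthDeg = 0)
  list(ref = ref, pA = c(uc, vcen - R - d), center = c(uc, vcen),
       thetaT = asin(R / (R + d)) * 180 / pi)
}

#' Mirror a reference slice horizontally
#'
#' Flips the slice in u while keeping the dorsal sign, so that a sweep on
#' the dorsal side of the mirrored slice samples what the frontal side of
#' the original did (used for symmetry checks).
#'
#' @param ref a [ReferenceSlice-class].
#' @return The mirrored [ReferenceSlice-class].
#' @export
mirrorReferenceSlice <- function(ref) {
  nu <- nrow(ref@values)
  new("ReferenceSlice", values = ref@values[nu:1, , drop = FALSE],
      mask = ref@mask[nu:1, , drop = FALSE], du = ref@du, dv = ref@dv,
      anchorU = (nu - 1) * ref@du - ref@anchorU,
      dorsalSign = ref@dorsalSign, laterality = ref@laterality,
      azimuthDeg = ref@azimuthDeg)
}
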
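test_that("minimum-area rectangle is exact for axis-aligned rectangles", {
  m <- matrix(FALSE, 16, 10)
  m[4:13, 4:7] <- TRUE  # 10 x 4 pixels => 9 x 3 over pixel centres
  r <- minAreaRect(m, c(1, 1))
  expect_equal(r@width, 9, tolerance = 1e-9)
  expect_equal(r@height, 3, tolerance = 1e-9)
  expect_equal(r@width * r@height, 27, tolerance = 1e-9)
  expect_equal(abs(r@angleDeg), 0, tolerance = 1e-6)
})

test_that("rotated rectangles recover angle and area against the grid oracle", {
  th <- 30 * pi / 180
  m <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    x <- (i - 20) * cos(-th) - (j - 20) * sin(-th)
    y <- (i - 20) * sin(-th) + (j - 20) * cos(-th)
    if (abs(x) <= 8 && abs(y) <= 3) m[i, j] <- TRUE
  }
  r <- minAreaRect(m, c(1, 1))
  expect_lt(abs(r@angleDeg - 30), 3)
  pts <- which(m, arr.ind = TRUE) - 1
  oracle <- gridMinRectOracle(pts, 0.1)
  expect_lt(abs(r@width * r@height - oracle) / oracle, 0.10)
})

test_that("circle masks match the grid oracle area within 1 percent", {
  n <- 41
  m <- outer(1:n, 1:n, function(i, j) (i - 21)^2 + (j - 21)^2 <= 15^2)
  r <- minAreaRect(m, c(1, 1))
  pts <- which(m, arr.ind = TRUE) - 1
  oracle <- gridMinRectOracle(pts, 0.1)
  expect_lt(abs(r@width * r@height - oracle) / oracle, 0.01)
})

test_that("collinear components are rejected as degenerate", {
  m <- matrix(FALSE, 10, 10); m[3:8, 5] <- TRUE
  expect_error(minAreaRect(m, c(1, 1)), "degenerate")
})

test_that("side contact points are means of touching pixels", {
  m <- matrix(FALSE, 16, 10); m[4:13, 4:7] <- TRUE
  r <- minAreaRect(m, c(1, 1))
  p <- sideContactPoint(m, r@shortSides[[1]], c(1, 1))
  # short side at one end of the long axis; contact is its midpoint
  expect_equal(p[2], 4.5, tolerance = 1e-6)
  expect_true(abs(p[1] - 3) < 1e-6 || abs(p[1] - 12) < 1e-6)
  single <- matrix(FALSE, 8, 8); single[3, 3] <- TRUE; single[6, 6] <- TRUE
  side <- matrix(c(2, 2, 2, 6), 2, 2)  # vertical line x = 2 near (3,3)
  p2 <- sideContactPoint(single, side, c(1, 1), tol = 1.5)
  expect_equal(p2, c(2, 2), tolerance = 1e-6)
})

test_that("longest section of an ellipse matches the brute-force oracle", {
  sp <- c(0.4, 0.4, 0.4)
  n <- 64
  m <- outer(1:n, 1:n, function(i, j)
    ((i - 32) * sp[1] / 10)^2 + ((j - 32) * sp[2] / 4)^2 <= 1)
  arr <- array(FALSE, c(n, n, 3)); arr[, , 2] <- m
  stack <- MaskStack(arr, spacing = sp)
  sec <- longestSection(stack)
  oracle <- bruteLongestOracle(m, sp)
  expect_lt(abs(sec@lengthMm - oracle$length), max(sp))
  expect_lt(abs(sec@lengthMm - 20), 2 * max(sp))
  dirSec <- (sec@p1 - sec@p0) / sec@lengthMm
  ang <- (atan2(dirSec[2], dirSec[1]) * 180 / pi) %% 180
  expect_lt(min(ang, 180 - ang), 2)
  # duplicated slices cannot change the result
  arr3 <- array(FALSE, c(n, n, 4))
  for (k in 1:4) arr3[, , k] <- m
  sec3 <- longestSection(MaskStack(arr3, spacing = sp))
  expect_equal(sec3@lengthMm, sec@lengthMm, tolerance = 1e-9)
})

test_that("reference plane is the perpendicular bisector, symmetric in endpoints", {
  mk <- function(p0, p1) new("LongestSection", p0 = p0, p1 = p1,
                             slice0 = 1L, slice1 = 1L,
                             lengthMm = sqrt(sum((p1 - p0)^2)))
  pl <- referencePlane(mk(c(0, 0), c(2, 0)))
  expect_equal(pl@anchor, c(1, 0))
  expect_equal(pl@azimuthDeg, 0)
  pl2 <- referencePlane(mk(c(0, 0), c(0, 2)))
  expect_equal(pl2@anchor, c(0, 1))
  expect_equal(pl2@azimuthDeg, 90)
  pl3 <- referencePlane(mk(c(0, 2), c(0, 0)))
  expect_equal(pl3@azimuthDeg, pl2@azimuthDeg)
  expect_equal(pl3@anchor, pl2@anchor)
})

test_that("volume rotation is exact at zero and self-inverse elsewhere", {
  set.seed(61)
  vol <- CBCTVolume(array(rnorm(32^3, 0, 100), c(32, 32, 32)),
                    spacing = c(0.4, 0.4, 0.4))
  ctr <- c(31 * 0.4 / 2, 31 * 0.4 / 2)
  expect_identical(rotateVolumeZ(vol, 0, ctr)@values, vol@values)
  core <- 9:24
  # smooth fields: self-inverse agreement within 2% of the dynamic range
  # away from the borders
  idx <- (1:32 - 16.5) * 0.4
  radial <- exp(-outer(outer(idx^2, idx^2, `+`), idx^2, `+`) / 20) * 100
  for (field in list(array(rep(seq(0, 100, length.out = 32), 32 * 32),
                           c(32, 32, 32)),
                     array(radial, c(32, 32, 32)))) {
    sm <- CBCTVolume(field, spacing = c(0.4, 0.4, 0.4))
    back2 <- rotateVolumeZ(rotateVolumeZ(sm, 23, ctr), -23, ctr)
    expect_lt(max(abs(back2@values[core, core, core] -
                        sm@values[core, core, core])), 0.02 * 100)
  }
})

test_that("the reference slice shows the condyle disk under the fossa arc", {
  fx <- smallSphereRun()
  ref <- fx$ref
  truth <- fx$ph$truth
  sp <- voxelSpacing(ref)
  iu <- round(ref@anchorU / sp[1]) + 1
  col <- ref@mask[iu, ]
  vHead <- truth$vHeadTop
  vAce <- truth$vAcetabulum
  # first bone below the gap (head top) and last bone above it (fossa)
  kHead <- which(col & (seq_along(col) - 1) * sp[2] >= vHead - sp[2])[1]
  expect_lt(abs((kHead - 1) * sp[2] - vHead), 1.5 * sp[2])
  fossaRows <- which(col & (seq_along(col) - 1) * sp[2] < vHead - 0.5)
  expect_gt(length(fossaRows), 0)
  vFossaBottom <- (max(fossaRows) - 1) * sp[2]
  expect_lt(abs(vFossaBottom - vAce), 1.5 * sp[2])
  # anchor must lie inside the volume
  plane <- fx$plane
  badPlane <- new("ReferencePlane", anchor = c(-50, -50), azimuthDeg = 0)
  expect_error(extractReferenceSlice(fx$den, fx$stack, badPlane, "right"),
               "anchor")
})

test_that("plane recovery is rotation-covariant and deterministic", {
  runSeg <- function(az) {
    ph <- generatePhantom(smallPhantomSpec(shape = "ellipsoid",
                                           azimuthDeg = az, seed = 44L))
    cropped <- cropVolume(ph$volume, ph$voi)
    den <- curvatureFlowDenoise(cropped)
    stack <- segmentTmjHead(den)
    sec <- longestSection(stack)
    list(sec = sec, plane = referencePlane(sec))
  }
  r0 <- runSeg(0)
  r25 <- runSeg(25)
  expect_lt(abs(r25$plane@azimuthDeg - r0$plane@azimuthDeg - 25), 2)
  expect_lt(abs(r25$sec@lengthMm - r0$sec@lengthMm), 0.4 + 1e-9)
  rAgain <- runSeg(25)
  expect_identical(rAgain$plane@anchor, r25$plane@anchor)
  expect_identical(rAgain$plane@azimuthDeg, r25$plane@azimuthDeg)
})
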
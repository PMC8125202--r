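test_that("the head top lands on the sphere pole within a voxel", {
  fx <- smallSphereRun()
  pH <- locateHeadTop(fx$stack, fx$plane, fx$ref)
  expect_lt(abs(pH[2] - fx$ph$truth$vHeadTop), fx$stack@spacing[3] + 1e-9)
  # the pole sits above the centre column of the condyle
  d <- dim(fx$stack@mask)
  expect_lt(abs(pH[1] - (d[2] - 1) * fx$stack@spacing[2] / 2), 1.0)
})

test_that("single-pixel and split plane intersections are handled", {
  arr <- array(FALSE, c(11, 11, 3))
  arr[6, 6, 1] <- TRUE
  stack <- MaskStack(arr, spacing = c(1, 1, 1))
  plane <- new("ReferencePlane", anchor = c(5, 5), azimuthDeg = 0)
  ref <- refSliceFromValues(matrix(-60, 11, 3), spacing = 1)
  pH <- locateHeadTop(stack, plane, ref)
  expect_equal(pH[1], ref@anchorU + 0, tolerance = 0.3)
  # two disjoint runs along the plane line: longest wins, with warning
  arr2 <- array(FALSE, c(11, 11, 3))
  arr2[6, 2:3, 1] <- TRUE   # short run
  arr2[6, 6:9, 1] <- TRUE   # long run
  stack2 <- MaskStack(arr2, spacing = c(1, 1, 1))
  expect_warning(pH2 <- locateHeadTop(stack2, plane, ref), "runs")
  expect_equal(pH2[1], ref@anchorU + 1.5, tolerance = 0.3)
  # plane missing the mask entirely
  arr3 <- array(FALSE, c(11, 11, 3)); arr3[2, 2, 1] <- TRUE
  plane3 <- new("ReferencePlane", anchor = c(5, 9), azimuthDeg = 90)
  expect_error(locateHeadTop(MaskStack(arr3, c(1, 1, 1)), plane3, ref),
               "intersect")
})

test_that("the acetabulum point is the fossa surface above the head", {
  fx <- smallSphereRun()
  pH <- locateHeadTop(fx$stack, fx$plane, fx$ref)
  pA <- locateAcetabulumPoint(fx$ref, pH)
  expect_lt(abs(pA[2] - fx$ph$truth$vAcetabulum), fx$ref@dv + 1e-9)
  expect_lt(pA[2], pH[2])
  rc <- computeRc(pH, pA)
  expect_lt(abs(rc - fx$ph$truth$rC), fx$ref@dv + 1e-9)
})

test_that("gap-less contact and missing fossa raise errors", {
  vals <- matrix(-60, 21, 30)
  vals[8:14, 10:25] <- 180  # bone column with no gap above reaching row 1
  vals[8:14, 1:9] <- 180
  ref <- refSliceFromValues(vals, spacing = 0.5)
  expect_error(locateAcetabulumPoint(ref, c(10 * 0.5, 15 * 0.5)),
               "acetabulum")
})

test_that("r_C is the Euclidean landmark distance", {
  expect_equal(computeRc(c(3, 10), c(3, 7)), 3)
  expect_equal(computeRc(c(3, 10), c(3, 10)), 0)
})

test_that("line profiles sample the slice correctly", {
  n <- 21
  ramp <- matrix(rep((0:(n - 1)) * 0.5, each = n), n, n)  # value = v mm
  ref <- refSliceFromValues(ramp, spacing = 0.5, mask = ramp > 1e9)
  p <- lineProfile(ref, c(5, 0), c(0, 1), step = 0.25)
  expect_equal(p@values, p@positions, tolerance = 1e-9)
  const <- refSliceFromValues(matrix(7, n, n), spacing = 0.5,
                              mask = matrix(FALSE, n, n))
  pc <- lineProfile(const, c(5, 0), c(0, 1), step = 0.25)
  expect_true(all(pc@values == 7))
  # a vertical profile stepping exactly on pixel centres reproduces the
  # column values without interpolation
  set.seed(71)
  img <- matrix(rnorm(n * n), n, n)
  refi <- refSliceFromValues(img, spacing = 0.5, mask = img > 1e9)
  pi2 <- lineProfile(refi, c(5, 0), c(0, 1), step = 0.5)
  expect_equal(pi2@values, img[11, ], tolerance = 1e-12)
})

test_that("first bone entry finds step edges and rejects monotone decay", {
  mkProfile <- function(v, step = 0.1)
    new("Profile", positions = seq(0, by = step, length.out = length(v)),
        values = v, origin = c(0, 0), direction = c(0, 1))
  step <- c(rep(-50, 40), rep(200, 30))  # edge at 4.0 mm
  expect_lt(abs(firstBoneEntry(mkProfile(step)) - 4.0), 0.05 + 1e-9)
  mono <- seq(200, -300, length.out = 60)
  expect_true(is.na(firstBoneEntry(mkProfile(mono))))
  # noisy step localized within 2 samples across 100 realizations
  set.seed(72)
  hits <- replicate(100, {
    noisy <- step + rnorm(70, sd = 10)
    firstBoneEntry(mkProfile(noisy))
  })
  expect_true(all(abs(hits - 4.0) <= 0.2 + 1e-9))
})

test_that("the bracketing rule averages the jump pair exactly", {
  theta <- seq(30, 33, by = 0.5)
  d <- c(4.1, 4.15, 4.2, NA, NA, NA, NA)  # jump between 31.0 and 31.5
  br <- tangentBracket(theta, d)
  expect_identical(br$thetaT, 31.25)
  expect_identical(c(br$thetaBelow, br$thetaAbove), c(31.0, 31.5))
  # finite-to-finite jump with explicit threshold
  d2 <- c(2.0, 2.1, 2.2, 6.0, 6.1, 6.2, 6.3)
  br2 <- tangentBracket(theta, d2, stepThreshold = 1)
  expect_identical(br2$thetaT, 31.25)
  # gentle growth is not a jump
  expect_null(tangentBracket(theta, seq(2, 2.6, by = 0.1)))
})

test_that("the tangent sweep matches the analytic circle tangent", {
  fx <- phantomReferenceSlice(R = 6, d = 2, spacing = 0.02)
  for (side in c("dorsal", "frontal")) {
    tr <- tangentSweep(fx$ref, fx$pA, side)
    expect_lt(abs(tr@thetaT - fx$thetaT), 0.5 + 1e-9)
    # d grows monotonically until the bracket
    dPre <- tr@dSeries$d[seq_len(which(tr@dSeries$theta == tr@thetaBelow)[1])]
    expect_true(all(diff(dPre[!is.na(dPre)]) >= -1e-9))
  }
})

test_that("mirroring the slice swaps dorsal and frontal results", {
  fx <- phantomReferenceSlice(R = 5, d = 2, spacing = 0.05,
                              fossaGap = 2)
  ref <- fx$ref
  mir <- mirrorReferenceSlice(ref)
  pAm <- c((nrow(ref@values) - 1) * ref@du - fx$pA[1], fx$pA[2])
  trD <- tangentSweep(ref, fx$pA, "dorsal")
  trF <- tangentSweep(ref, fx$pA, "frontal")
  trDm <- tangentSweep(mir, pAm, "dorsal")
  trFm <- tangentSweep(mir, pAm, "frontal")
  expect_equal(trDm@thetaT, trF@thetaT, tolerance = 1e-9)
  expect_equal(trFm@thetaT, trD@thetaT, tolerance = 1e-9)
  gD <- gapWidthAtTangent(ref, trD, fx$pA)
  gF <- gapWidthAtTangent(ref, trF, fx$pA)
  gDm <- gapWidthAtTangent(mir, trDm, pAm)
  gFm <- gapWidthAtTangent(mir, trFm, pAm)
  expect_equal(gDm$r, gF$r, tolerance = 1e-9)
  expect_equal(gFm$r, gD$r, tolerance = 1e-9)
})

test_that("concentric and eccentric fossa gaps match ray-cast truth", {
  # concentric: both sides equal the construction gap
  fx <- phantomReferenceSlice(R = 6, d = 2, spacing = 0.05, fossaGap = 2)
  for (side in c("dorsal", "frontal")) {
    tr <- tangentSweep(fx$ref, fx$pA, side)
    gw <- gapWidthAtTangent(fx$ref, tr, fx$pA)
    expect_lt(abs(gw$r - 2), 0.15)
  }
  # eccentric: fossa centre shifted dorsally; ray-cast oracle per side
  off <- 1
  fe <- phantomReferenceSlice(R = 6, d = 2, spacing = 0.05, fossaGap = 2,
                              fossaOffsetU = off)
  pA <- locateAcetabulumPoint(fe$ref, c(fe$center[1], fe$center[2] - 5))
  rs <- list()
  for (side in c("dorsal", "frontal")) {
    tr <- tangentSweep(fe$ref, pA, side)
    gw <- gapWidthAtTangent(fe$ref, tr, pA)
    th <- tr@thetaBelow * pi / 180
    sgn <- if (side == "dorsal") 1 else -1
    e <- c(sgn * sin(th), cos(th))
    n1 <- c(-e[2], e[1]); if (n1[2] > 0) n1 <- -n1
    oracle <- rayCastCircleOracle(tr@contact, n1,
                                  centre = fe$center + c(off, 0),
                                  radius = 6 + 2)
    expect_lt(abs(gw$r - oracle), 0.15)
    rs[[side]] <- gw$r
  }
  # dorsal shift of the fossa opens the dorsal gap and closes the frontal
  expect_gt(rs$dorsal, rs$frontal)
})

test_that("a missing fossa on one side fails only that side", {
  # arc only over the dorsal half: frontal perpendicular finds no bone
  fx <- phantomReferenceSlice(R = 6, d = 2, spacing = 0.05, fossaGap = 2)
  ref <- fx$ref
  uc <- fx$center[1]
  half <- ref@values
  cut <- seq_len(floor(uc / ref@du) - round(2 / ref@du)) # frontal side u < uc-2
  vcut <- seq_len(round((fx$center[2] - 6) / ref@dv))    # above the head only
  half[cut, vcut] <- -60
  refHalf <- new("ReferenceSlice", values = half, mask = half > 60,
                 du = ref@du, dv = ref@dv, anchorU = ref@anchorU,
                 dorsalSign = 1, laterality = "right", azimuthDeg = 0)
  trD <- tangentSweep(refHalf, fx$pA, "dorsal")
  expect_no_error(gapWidthAtTangent(refHalf, trD, fx$pA))
  trF <- tangentSweep(refHalf, fx$pA, "frontal")
  expect_error(gapWidthAtTangent(refHalf, trF, fx$pA), "fossa not found")
})

test_that("the full measurement is deterministic and correctly labelled", {
  ph <- generatePhantom(smallPhantomSpec(seed = 55L))
  m1 <- suppressWarnings(measureTMJ(ph$volume, ph$voi, "right"))
  m2 <- suppressWarnings(measureTMJ(ph$volume, ph$voi, "right"))
  j1 <- jsonlite::toJSON(measurementReport(m1), auto_unbox = TRUE, digits = NA)
  j2 <- jsonlite::toJSON(measurementReport(m2), auto_unbox = TRUE, digits = NA)
  expect_identical(as.character(j1), as.character(j2))
  expect_identical(m1@laterality, "right")
  truth <- ph$truth
  voxel <- 0.4
  expect_lte(abs(m1@rC - truth$rC), voxel + 1e-6)
  expect_lte(abs(m1@rD - truth$rD), voxel + 1e-6)
  expect_lte(abs(m1@rF - truth$rF), voxel + 1e-6)
})

test_that("larger true gaps yield larger measured widths", {
  rs <- vapply(c(1.6, 2.4, 3.2), function(g) {
    ph <- generatePhantom(smallPhantomSpec(gap = g, seed = 56L))
    m <- suppressWarnings(measureTMJ(ph$volume, ph$voi, "right"))
    unname(gapWidths(m))
  }, numeric(3))
  expect_true(all(rs[, 2] > rs[, 1]))
  expect_true(all(rs[, 3] > rs[, 2]))
})
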
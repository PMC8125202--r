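test_that("EM recovers a well-separated two-component mixture", {
  set.seed(21)
  n <- 12000
  x <- c(rnorm(n / 2, -800, 50), rnorm(n / 2, 150, 40))
  fit <- fitGmmSlice(matrix(x, 100), K = 2)
  expect_lt(abs(fit@mean[1] - (-800)), 15)
  expect_lt(abs(fit@mean[2] - 150), 15)
  expect_lt(max(abs(fit@weight - 0.5)), 0.05)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  set.seed(22)
  x <- c(rnorm(4000, -900, 30), rnorm(3000, -60, 30), rnorm(3000, 180, 30))
  fit <- fitGmmSlice(matrix(x, 100), K = 3)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(fit@mean, sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("single-component fit reduces to the sample moments", {
  set.seed(23)
  x <- 100 + rnorm(500, sd = 0.01)
  fit <- fitGmmSlice(x, K = 1)
  expect_equal(fit@mean, mean(x), tolerance = 1e-6)
  expect_equal(fit@weight, 1)
})

test_that("fits are deterministic and demand K distinct values", {
  set.seed(24)
  x <- matrix(rnorm(2000, c(-500, 100), 40), 50)
  f1 <- fitGmmSlice(x, K = 2, seed = 1)
  f2 <- fitGmmSlice(x, K = 2, seed = 1)
  expect_identical(f1@mean, f2@mean)
  expect_identical(f1@variance, f2@variance)
  expect_error(fitGmmSlice(matrix(1, 5, 5), K = 2), "distinct")
})

test_that("bone classification matches the analytic posterior crossing", {
  set.seed(25)
  x <- c(rnorm(6000, -100, 50), rnorm(4000, 200, 40))
  fit <- fitGmmSlice(x, K = 2)
  expect_true(all(classifyBone(fit@mean[2], fit)))
  expect_false(any(classifyBone(fit@mean[1], fit)))
  # closed-form crossing of two weighted normal densities
  crossing <- function(m1, s1, w1, m2, s2, w2) {
    a <- 1 / s1^2 - 1 / s2^2
    b <- -2 * (m1 / s1^2 - m2 / s2^2)
    cc <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log((w1 / s1) / (w2 / s2))
    r <- Re(polyroot(c(cc, b, a)))
    r[r > m1 & r < m2][1]
  }
  thr <- crossing(fit@mean[1], sqrt(fit@variance[1]), fit@weight[1],
                  fit@mean[2], sqrt(fit@variance[2]), fit@weight[2])
  grid <- seq(fit@mean[1], fit@mean[2], by = 0.05)
  cls <- as.vector(classifyBone(grid, fit))
  boundary <- grid[which(cls)[1]]
  expect_lt(abs(boundary - thr), 0.1)
})

test_that("classification threshold rises with the bone component mean", {
  base <- new("GMMFit", mean = c(-60, 180), variance = c(625, 625),
              weight = c(0.5, 0.5), K = 2L, logLik = 0, iterations = 1L)
  thrOf <- function(fit) {
    grid <- seq(fit@mean[1], fit@mean[2], by = 0.1)
    grid[which(as.vector(classifyBone(grid, fit)))[1]]
  }
  thrs <- vapply(c(120, 180, 260, 400), function(m2) {
    f <- base; f@mean[2] <- m2; thrOf(f)
  }, 0)
  expect_true(all(diff(thrs) > 0))
})

test_that("border-touching components are removed exactly as flood fill says", {
  centered <- matrix(FALSE, 15, 15); centered[6:9, 6:9] <- TRUE
  expect_identical(removeBorderComponents(centered), centered)
  touching <- centered; touching[1:3, 7] <- TRUE
  expect_identical(removeBorderComponents(touching), centered)
  for (s in 1:10) {
    set.seed(300 + s)
    m <- matrix(runif(400) > 0.55, 20, 20)
    expect_identical(removeBorderComponents(m), m & !floodBorderOracle(m))
  }
})

test_that("convex-hull filling matches the lattice point-in-hull oracle", {
  rect <- matrix(FALSE, 12, 12); rect[3:9, 4:8] <- TRUE
  expect_identical(fillConvexHulls(rect), rect)
  cshape <- matrix(FALSE, 14, 14)
  cshape[3:11, 3:5] <- TRUE; cshape[3:5, 3:11] <- TRUE
  cshape[9:11, 3:11] <- TRUE
  filled <- fillConvexHulls(cshape)
  expect_identical(filled, hullFillOracle(cshape))
  expect_identical(fillConvexHulls(filled), filled)
  for (s in 1:6) {
    set.seed(400 + s)
    m <- matrix(FALSE, 18, 18)
    pts <- cbind(sample(3:16, 10, TRUE), sample(3:16, 10, TRUE))
    m[pts] <- TRUE
    out <- fillConvexHulls(m)
    expect_identical(out, hullFillOracle(m))
    expect_identical(fillConvexHulls(out), out)
  }
})

test_that("largest 3D component selection is size-correct and tie-stable", {
  arr <- array(FALSE, c(10, 10, 6))
  arr[2:6, 2:6, 2:3] <- TRUE        # 50 voxels
  arr[8:9, 8:9, 5:6] <- TRUE        # 8 voxels
  kept <- keepLargestComponent(arr, spacing = c(1, 1, 1))
  expect_equal(sum(kept@mask), 50)
  expect_false(any(kept@mask[8:9, 8:9, ]))
  # exact tie: two 2x2x2 cubes, the one with the smaller (slice, row,
  # col) key wins, deterministically
  tie <- array(FALSE, c(8, 8, 6))
  tie[6:7, 6:7, 4:5] <- TRUE
  tie[2:3, 2:3, 2:3] <- TRUE
  k1 <- keepLargestComponent(tie)
  k2 <- keepLargestComponent(tie)
  expect_identical(k1@mask, k2@mask)
  expect_true(k1@mask[2, 2, 2])
  expect_false(any(k1@mask[6:7, 6:7, ]))
  expect_error(keepLargestComponent(array(FALSE, c(4, 4, 4))), "no bone")
})

test_that("head segmentation matches sphere geometry on the phantom", {
  fx <- smallSphereRun()
  stack <- fx$stack
  sp <- stack@spacing
  truth <- fx$ph$truth
  R <- 6
  # analytic slice range of the sphere (VOI-relative v)
  vTop <- truth$vHeadTop
  vBot <- vTop + 2 * R
  kTop <- round(vTop / sp[3]) + 1
  kBot <- round(vBot / sp[3]) + 1
  expect_lte(abs(stack@firstSlice - kTop), 1)
  expect_lte(abs(stack@lastSlice - dim(stack@mask)[3]), 1)  # neck continues
  # one 26-connected component
  lab <- tmjgap:::.labelComponents(stack@mask, 26L)
  expect_equal(max(lab), 1L)
  # per-slice area follows the circle area within 15% away from the pole
  vc <- vTop + R
  for (k in seq(stack@firstSlice + 3, floor(vc / sp[3]) - 1)) {
    dist <- abs((k - 1) * sp[3] - vc)
    areaTrue <- pi * (R^2 - dist^2)
    areaSeen <- sum(stack@mask[, , k]) * sp[1] * sp[2]
    expect_lt(abs(areaSeen - areaTrue) / areaTrue, 0.15)
  }
})

test_that("internal cavities are hull-filled and the fossa shell is removed", {
  ph <- generatePhantom(smallPhantomSpec(cavityRadius = 2.5, distractor = TRUE,
                                         seed = 31L))
  cropped <- cropVolume(ph$volume, ph$voi)
  den <- curvatureFlowDenoise(cropped)
  stack <- segmentTmjHead(den)
  sp <- stack@spacing
  # cavity centre voxel (condyle centre) is filled despite soft intensity
  vcRel <- ph$truth$vHeadTop + 6
  kc <- round(vcRel / sp[3]) + 1
  d <- dim(stack@mask)
  expect_true(stack@mask[round(d[1] / 2), round(d[2] / 2), kc])
  # no mask voxels above the head top (fossa + distractor removed)
  kHead <- floor(ph$truth$vHeadTop / sp[3])
  expect_false(any(stack@mask[, , seq_len(kHead - 1)]))
})

test_that("a head reaching the uppermost VOI slice triggers a warning", {
  ph <- generatePhantom(smallPhantomSpec(seed = 32L))
  voi <- ph$voi
  kHead <- floor(ph$truth$vHeadTop / 0.4) + 2L  # inside the head run
  badVoi <- VOIBox(voi@xRange, voi@yRange,
                   c(voi@zRange[1] + kHead, voi@zRange[2]))
  cropped <- cropVolume(ph$volume, badVoi)
  den <- curvatureFlowDenoise(cropped)
  expect_warning(segmentTmjHead(den), "uppermost")
})
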
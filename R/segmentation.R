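# TMJ head (condyle) segmentation: per-slice Gaussian mixture
# classification plus morphological postprocessing.

#' Fit a univariate Gaussian mixture to one axial slice
#'
#' EM on the slice's pseudo-HU values. Near the TMJ the histogram is
#' dominated by a large low-value (air) peak with faint soft-tissue and
#' bone peaks to its right, so by default three components are fitted and
#' the highest-mean one is taken as bone (see [classifyBone()]).
#' Initialization is deterministic: means at the 10th..90th percentiles of
#' the slice values (evenly spread), equal weights, common variance. EM
#' stops when the mean per-pixel log-likelihood changes by less than
#' `tol`. A variance floor guards degeneracy; if a component still
#' collapses the fit restarts once with a larger floor before failing.
#'
#' @param values numeric matrix (or vector) of slice pseudo-HU values with
#'   at least `K` distinct values.
#' @param K number of mixture components (default 3).
#' @param seed accepted for interface stability; the fit is deterministic,
#'   so the seed is not consumed.
#' @param tol convergence tolerance on the mean log-likelihood.
#' @param maxIter iteration cap.
#' @param varFloor minimal component variance (pseudo-HU squared).
#' @return A [GMMFit-class] with components sorted by ascending mean.
#' @export
fitGmmSlice <- function(values, K = 3L, seed = NULL, tol = 1e-4,
                        maxIter = 500L, varFloor = 1) {
  x <- as.numeric(values)
  x <- x[is.finite(x)]
  if (length(unique(x)) < K)
    stop(sprintf("slice needs at least %d distinct values", K))
  fit <- .emGauss1d(x, K, tol, maxIter, varFloor)
  if (is.null(fit)) fit <- .emGauss1d(x, K, tol, maxIter, varFloor * 100)
  if (is.null(fit)) stop("EM degenerate: vanishing component")
  ord <- order(fit$mu)
  new("GMMFit", mean = fit$mu[ord], variance = fit$s2[ord],
      weight = fit$w[ord] / sum(fit$w[ord]), K = as.integer(K),
      logLik = fit$ll, iterations = fit$iter)
}

# Deterministic multi-start EM: three fixed initializations (low/median/
# high quantiles, quantiles with the top component anchored in the upper
# tail, and means spread evenly over the value range); the fit with the
# best final log-likelihood wins. The upper-tail start matters on slices
# where bone is a small fraction of the pixels and the 90th percentile
# falls inside soft tissue.
.emGauss1d <- function(x, K, tol, maxIter, varFloor) {
  starts <- if (K == 1L) {
    list(unname(stats::quantile(x, 0.5)))
  } else {
    rng <- range(x)
    list(unname(stats::quantile(x, seq(0.1, 0.9, length.out = K))),
         unname(stats::quantile(x, c(seq(0.1, 0.6, length.out = K - 1),
                                     0.99))),
         rng[1] + (2 * seq_len(K) - 1) / (2 * K) * diff(rng))
  }
  fits <- list()
  for (mu0 in starts) {
    fit <- .emRun(x, mu0, K, tol, maxIter, varFloor)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0L) return(NULL)
  # Prefer fits suitable for bone classification: the top component
  # must be compact (not a wide catch-all for partial-volume pixels)
  # and clearly above its neighbour. Without this, slices with little
  # bone reward degenerate solutions whose top component swallows soft
  # tissue.
  suitable <- vapply(fits, function(f) {
    if (K == 1L) return(TRUE)
    ord <- order(f$mu)
    mu <- f$mu[ord]; s <- sqrt(f$s2[ord])
    (mu[K] - mu[K - 1]) > 4 * s[K] && s[K] <= 3 * min(s)
  }, TRUE)
  pool <- if (any(suitable)) fits[suitable] else fits
  pool[[which.max(vapply(pool, function(f) f$ll, 0))]]
}

.emRun <- function(x, mu, K, tol, maxIter, varFloor) {
  n <- length(x)
  if (anyDuplicated(mu)) mu <- mu + seq(0, K - 1) * 1e-6 * (1 + diff(range(x)))
  # k-means-style hard assignment refines the start: component scales
  # come from the assigned pixels, so a sparse class (bone on a
  # near-boneless slice) is not swallowed by an over-wide neighbour
  w <- rep(1 / K, K)
  s2 <- rep(max(stats::var(x), varFloor), K)
  for (it in 1:3) {
    cl <- max.col(-abs(outer(x, mu, `-`)), ties.method = "first")
    for (k in seq_len(K)) {
      xk <- x[cl == k]
      if (length(xk) >= 2L) {
        mu[k] <- mean(xk)
        s2[k] <- max(stats::var(xk), varFloor)
        w[k] <- length(xk) / n
      }
    }
    w <- pmax(w, 1e-4); w <- w / sum(w)
    ord <- order(mu); mu <- mu[ord]; s2 <- s2[ord]; w <- w[ord]
  }
  prevll <- -Inf
  logd <- matrix(0, n, K)
  for (iter in seq_len(maxIter)) {
    for (k in seq_len(K))
      logd[, k] <- stats::dnorm(x, mu[k], sqrt(s2[k]), log = TRUE) + log(w[k])
    m <- logd[, 1]
    if (K > 1) for (k in 2:K) m <- pmax(m, logd[, k])
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    Nk <- colSums(resp)
    if (any(!is.finite(Nk)) || any(Nk < 1e-8)) return(NULL)
    w <- Nk / n
    mu <- colSums(resp * x) / Nk
    for (k in seq_len(K))
      s2[k] <- max(sum(resp[, k] * (x - mu[k])^2) / Nk[k], varFloor)
    ll <- mean(lse)
    if (is.finite(prevll) && abs(ll - prevll) < tol) break
    prevll <- ll
  }
  if (any(!is.finite(mu)) || any(!is.finite(s2))) return(NULL)
  list(mu = mu, s2 = s2, w = w, ll = ll, iter = as.integer(iter))
}

#' Classify slice pixels as bone
#'
#' A pixel is bone iff its maximum-posterior component is the component
#' with the highest mean.
#'
#' @param values numeric matrix of slice pseudo-HU values.
#' @param fit a [GMMFit-class] for this slice.
#' @return Logical matrix the shape of `values`.
#' @export
classifyBone <- function(values, fit) {
  x <- as.numeric(values)
  K <- fit@K
  if (K == 1L) return(array(TRUE, dim(values) %||% length(values)))
  logd <- matrix(0, length(x), K)
  for (k in seq_len(K))
    logd[, k] <- stats::dnorm(x, fit@mean[k], sqrt(fit@variance[k]),
                              log = TRUE) + log(fit@weight[k])
  bone <- max.col(logd, ties.method = "last") == K
  dim(bone) <- dim(values)
  bone
}

#' Remove mask components touching the slice border
#'
#' Bone structures other than the condyle (temporal bone, fossa walls)
#' reach the edge of the region of interest; any 8-connected foreground
#' component touching the 2D border is deleted.
#'
#' @param mask logical matrix (slice mask).
#' @return Logical matrix without border-touching components.
#' @export
removeBorderComponents <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- .labelComponents(mask, 8L)
  nx <- nrow(lab); ny <- ncol(lab)
  borderLabs <- unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny]))
  borderLabs <- borderLabs[borderLabs > 0L]
  mask & !(lab %in% borderLabs)
}

#' Replace each mask component by its filled convex hull
#'
#' The condyle's shape is close to convex; filling each 8-connected
#' component's convex hull closes internal voids and broken contours. The
#' operation is idempotent. Components with collinear pixels are kept
#' unchanged.
#'
#' @param mask logical matrix (slice mask).
#' @return Logical matrix of filled hulls.
#' @export
fillConvexHulls <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- .labelComponents(mask, 8L)
  out <- mask
  for (l in seq_len(max(lab))) {
    pts <- which(lab == l, arr.ind = TRUE)
    if (nrow(pts) < 3L) next
    h <- grDevices::chull(pts[, 1], pts[, 2])
    if (length(h) < 3L) next
    V <- pts[h, , drop = FALSE]
    xr <- range(V[, 1]); yr <- range(V[, 2])
    cand <- as.matrix(expand.grid(x = xr[1]:xr[2], y = yr[1]:yr[2]))
    inside <- .inConvexPolygon(cand[, 1], cand[, 2], V)
    out[cand[inside, , drop = FALSE]] <- TRUE
  }
  out
}

# Points strictly inside or on a convex polygon (vertices ordered, as
# returned by chull). Sign test per edge with a small tolerance.
.inConvexPolygon <- function(px, py, V, eps = 1e-9) {
  nv <- nrow(V)
  pos <- rep(TRUE, length(px)); neg <- rep(TRUE, length(px))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cr <- (V[j, 1] - V[i, 1]) * (py - V[i, 2]) -
          (V[j, 2] - V[i, 2]) * (px - V[i, 1])
    pos <- pos & cr >= -eps
    neg <- neg & cr <= eps
  }
  pos | neg
}

#' Keep the largest 3D connected component of a mask stack
#'
#' Labels the stack with 26-connectivity and keeps only the component
#' with the most voxels (the condyle). Exact ties are broken
#' deterministically in favour of the component whose minimal
#' (slice, row, column) index is smallest.
#'
#' @param stack a [MaskStack-class] or logical 3D array.
#' @param spacing voxel spacing, used when `stack` is a plain array.
#' @return A [MaskStack-class] containing a single component.
#' @export
keepLargestComponent <- function(stack, spacing = c(1, 1, 1)) {
  arr <- if (is(stack, "MaskStack")) stack@mask else stack
  if (is(stack, "MaskStack")) spacing <- stack@spacing
  if (!any(arr)) stop("no bone found in VOI")
  lab <- .labelComponents(arr, 26L)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # lexicographic (slice, row, col) = (k, iy, ix) key per candidate
    d <- dim(arr)
    keys <- vapply(best, function(l) {
      co <- arrayInd(which(lab == l), d)
      min(((co[, 3] - 1) * d[2] + (co[, 2] - 1)) * d[1] + co[, 1])
    }, 0)
    best <- best[which.min(keys)]
  }
  MaskStack(array(lab == best, dim(arr)), spacing = spacing)
}

#' Segment the TMJ head on every axial VOI slice
#'
#' Full per-slice pipeline: Gaussian-mixture fit, bone classification,
#' border-component removal and convex-hull filling, followed by 3D
#' largest-component selection across the stack. A warning is issued if
#' the uppermost slice contains head voxels (the VOI should start above
#' the acetabular roof).
#'
#' @param vol a (cropped, denoised) [CBCTVolume-class].
#' @param cfg configuration list, see [tmjConfig()]; uses the
#'   `segmentation` entries.
#' @return A [MaskStack-class] holding one 26-connected component.
#' @export
segmentTmjHead <- function(vol, cfg = tmjConfig()) {
  sc <- cfg$segmentation
  d <- dim(vol@values)
  arr <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- vol@values[, , k]
    fit <- fitGmmSlice(sl, K = sc$components, seed = sc$seed,
                       tol = sc$tol, varFloor = sc$varFloor)
    m <- classifyBone(sl, fit)
    m <- removeBorderComponents(m)
    m <- fillConvexHulls(m)
    arr[, , k] <- m
  }
  stack <- keepLargestComponent(arr, spacing = vol@spacing)
  if (any(stack@mask[, , 1]))
    warning("TMJ head present on the uppermost VOI slice; ",
            "the VOI should start above the acetabular roof")
  stack
}
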
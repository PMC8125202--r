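# Independent oracles, implemented without reusing the package's code
# paths: scalar flood fill, gift-wrapping hull + integer sign test,
# exhaustive rotation-grid rectangle search, all-pairs section search,
# and a numeric ray-marcher for gap truths.

# Foreground pixels 8-connected to the image border (scalar BFS queue).
floodBorderOracle <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  seen <- matrix(FALSE, nx, ny)
  queue <- list()
  push <- function(i, j) queue[[length(queue) + 1L]] <<- c(i, j)
  for (i in seq_len(nx)) for (j in c(1L, ny))
    if (mask[i, j] && !seen[i, j]) { seen[i, j] <- TRUE; push(i, j) }
  for (j in seq_len(ny)) for (i in c(1L, nx))
    if (mask[i, j] && !seen[i, j]) { seen[i, j] <- TRUE; push(i, j) }
  while (length(queue) > 0L) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (di in -1:1) for (dj in -1:1) {
      i <- p[1] + di; j <- p[2] + dj
      if (i >= 1 && i <= nx && j >= 1 && j <= ny &&
          mask[i, j] && !seen[i, j]) {
        seen[i, j] <- TRUE
        push(i, j)
      }
    }
  }
  seen
}

# Convex hull by gift wrapping (Jarvis march) on integer points.
giftWrapHull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(pts[, 1] * 1e6 + pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (k in seq_len(n)) {
      if (k == cur) next
      cr <- cross(pts[cur, ], pts[cand, ], pts[k, ])
      if (cr < 0 ||
          (cr == 0 && sum((pts[k, ] - pts[cur, ])^2) >
             sum((pts[cand, ] - pts[cur, ])^2)))
        cand <- k
    }
    cur <- cand
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# Exact lattice point-in-convex-hull test (integer cross products).
hullFillOracle <- function(mask) {
  lab <- tmjgap:::.labelComponents(mask, 8L)
  out <- mask
  for (l in seq_len(max(lab, 0L))) {
    pts <- which(lab == l, arr.ind = TRUE)
    if (nrow(pts) < 3L) next
    V <- giftWrapHull(pts)
    if (nrow(V) < 3L) next
    xr <- range(V[, 1]); yr <- range(V[, 2])
    nv <- nrow(V)
    for (x in xr[1]:xr[2]) for (y in yr[1]:yr[2]) {
      signs <- integer(nv)
      for (i in seq_len(nv)) {
        j <- if (i == nv) 1L else i + 1L
        signs[i] <- sign((V[j, 1] - V[i, 1]) * (y - V[i, 2]) -
                           (V[j, 2] - V[i, 2]) * (x - V[i, 1]))
      }
      if (all(signs >= 0) || all(signs <= 0)) out[x, y] <- TRUE
    }
  }
  out
}

# Minimum bounding-rectangle area over an exhaustive angle grid.
gridMinRectOracle <- function(ptsMm, stepDeg = 0.1) {
  best <- Inf
  for (ang in seq(0, 180 - stepDeg, by = stepDeg)) {
    th <- ang * pi / 180
    rx <- ptsMm[, 1] * cos(th) - ptsMm[, 2] * sin(th)
    ry <- ptsMm[, 1] * sin(th) + ptsMm[, 2] * cos(th)
    area <- (max(rx) - min(rx)) * (max(ry) - min(ry))
    if (area < best) best <- area
  }
  best
}

# Longest section by brute force over all boundary-pixel pairs.
bruteLongestOracle <- function(mask, spacing) {
  nx <- nrow(mask); ny <- ncol(mask)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- mask
  inner <- pad[2:(nx + 1), 2:(ny + 1)] &
    pad[1:nx, 2:(ny + 1)] & pad[3:(nx + 2), 2:(ny + 1)] &
    pad[2:(nx + 1), 1:ny] & pad[2:(nx + 1), 3:(ny + 2)]
  boundary <- which(mask & !inner, arr.ind = TRUE)
  P <- cbind((boundary[, 1] - 1) * spacing[1], (boundary[, 2] - 1) * spacing[2])
  dd <- as.matrix(stats::dist(P))
  idx <- arrayInd(which.max(dd), dim(dd))
  list(length = dd[idx[1], idx[2]], p0 = P[idx[1], ], p1 = P[idx[2], ])
}

# March a ray from `origin` along `dir` until it first leaves the disc
# (centre, radius), i.e. reaches the fossa inner surface; 0.01 mm steps.
rayCastCircleOracle <- function(origin, dir, centre, radius, maxLen = 30) {
  dir <- dir / sqrt(sum(dir^2))
  for (t in seq(0.01, maxLen, by = 0.01)) {
    p <- origin + t * dir
    if (sum((p - centre)^2) >= radius^2) return(t)
  }
  NA_real_
}

# Random convex-ish blob mask for oracle comparisons.
randomConvexMask <- function(n = 40, seed) {
  set.seed(seed)
  npts <- sample(6:12, 1)
  ang <- sort(runif(npts, 0, 2 * pi))
  rad <- runif(npts, n / 6, n / 2 - 2)
  cx <- n / 2 + runif(1, -2, 2); cy <- n / 2 + runif(1, -2, 2)
  vx <- cx + rad * cos(ang); vy <- cy + rad * sin(ang)
  mask <- matrix(FALSE, n, n)
  V <- giftWrapHull(cbind(round(vx), round(vy)))
  if (nrow(V) < 3L) return(randomConvexMask(n, seed + 1000))
  nv <- nrow(V)
  for (x in 1:n) for (y in 1:n) {
    signs <- integer(nv)
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      signs[i] <- sign((V[j, 1] - V[i, 1]) * (y - V[i, 2]) -
                         (V[j, 2] - V[i, 2]) * (x - V[i, 1]))
    }
    if (all(signs >= 0) || all(signs <= 0)) mask[x, y] <- TRUE
  }
  mask
}
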
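# Shared low-level helpers: array shifts, connected components, bilinear
# sampling, RNG scoping.

# Shift an array along one axis by one voxel with replicate (Neumann)
# boundary handling.
.shift1 <- function(a, axis, by) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# Linear index from an m x nd coordinate matrix.
.linIndex <- function(coords, d) {
  strides <- cumprod(c(1, d[-length(d)]))
  as.integer(1 + (coords - 1) %*% strides)
}

# Label connected components of a logical array (2D or 3D).
# connectivity: 8 (2D default) or 4; 26 (3D default) or 6.
# Returns an integer array of labels (0 = background); labels are assigned
# in first-encounter order of the linear scan, so labelling is
# deterministic.
.labelComponents <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  nd <- length(d)
  if (is.null(connectivity)) connectivity <- if (nd == 2L) 8L else 26L
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity %in% c(4L, 6L))
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  maskv <- as.logical(mask)
  labv <- integer(length(maskv))
  fg <- which(maskv)
  nOff <- nrow(offs)
  cur <- 0L
  for (seed in fg) {
    if (labv[seed] != 0L) next
    cur <- cur + 1L
    labv[seed] <- cur
    frontier <- matrix(arrayInd(seed, d), nrow = 1L)
    while (nrow(frontier) > 0L) {
      m <- nrow(frontier)
      cand <- frontier[rep(seq_len(m), times = nOff), , drop = FALSE] +
        offs[rep(seq_len(nOff), each = m), , drop = FALSE]
      ok <- rep(TRUE, nrow(cand))
      for (ax in seq_len(nd))
        ok <- ok & cand[, ax] >= 1L & cand[, ax] <= d[ax]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0L) break
      lin <- .linIndex(cand, d)
      lin <- unique(lin[maskv[lin] & labv[lin] == 0L])
      if (length(lin) == 0L) break
      labv[lin] <- cur
      frontier <- arrayInd(lin, d)
    }
  }
  array(labv, d)
}

# Bilinear interpolation on a matrix at fractional 1-based pixel
# coordinates; coordinates outside the grid return `fill`.
.bilinear <- function(mat, px, py, fill = NA_real_) {
  nx <- nrow(mat); ny <- ncol(mat)
  out <- rep(fill, length(px))
  ok <- px >= 1 & px <= nx & py >= 1 & py <= ny &
    is.finite(px) & is.finite(py)
  if (!any(ok)) return(out)
  x <- px[ok]; y <- py[ok]
  i0 <- pmin(floor(x), nx - 1); j0 <- pmin(floor(y), ny - 1)
  fx <- x - i0; fy <- y - j0
  v00 <- mat[cbind(i0, j0)]
  v10 <- mat[cbind(i0 + 1, j0)]
  v01 <- mat[cbind(i0, j0 + 1)]
  v11 <- mat[cbind(i0 + 1, j0 + 1)]
  out[ok] <- (v00 * (1 - fx) + v10 * fx) * (1 - fy) +
    (v01 * (1 - fx) + v11 * fx) * fy
  out
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Wrap a pipeline stage so its errors carry the stage name.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.deg2rad <- function(x) x * pi / 180
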
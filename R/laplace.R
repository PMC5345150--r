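# Harmonic (Laplace) transmural depth and local cardiac frames.

#' Transmural depth by harmonic interpolation
#'
#' Solves the Laplace equation on the myocardial mask with Dirichlet
#' conditions depth = 0 on the epicardial boundary voxels and depth = 1 on
#' the endocardial boundary voxels, using a sparse direct solve of the
#' 6-neighbour finite-difference Laplacian (non-mask neighbours act as
#' zero-flux walls). Connected components of the mask that do not touch
#' both boundaries are left undefined. The maximum principle guarantees
#' the solution lies in [0, 1].
#'
#' A 2D problem can be posed as a single-slice 3D mask.
#'
#' @param mask logical 3D array: the myocardium including both boundary
#'   layers.
#' @param epi,endo logical 3D arrays marking the epicardial and endocardial
#'   boundary voxels (disjoint subsets of \code{mask}).
#' @return list with \code{depth} (numeric array, NA outside/undefined) and
#'   \code{gradient} (\code{c(dim, 3)} array of central-difference
#'   gradients in voxel units).
#' @export
laplaceDepth <- function(mask, epi, endo) {
  d <- dim(mask)
  stopifnot(identical(d, dim(epi)), identical(d, dim(endo)))
  if (any(epi & endo))
    stop("epicardial and endocardial boundaries must be disjoint",
         call. = FALSE)
  if (!any(epi & mask) || !any(endo & mask))
    stop("both boundaries must intersect the mask", call. = FALSE)
  epi <- epi & mask
  endo <- endo & mask
  # restrict to components reaching both boundaries
  lab <- .labelComponents(mask)
  good <- intersect(unique(lab[epi]), unique(lab[endo]))
  solvable <- mask & array(lab %in% good, d)

  depth <- array(NA_real_, d)
  depth[solvable & epi] <- 0
  depth[solvable & endo] <- 1
  interior <- solvable & !epi & !endo
  idx <- which(interior)
  if (length(idx)) {
    rank <- array(0L, d)
    rank[idx] <- seq_along(idx)
    strides <- c(1L, d[1], d[1] * d[2])
    coords <- arrayInd(idx, d)
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    rhs <- numeric(length(idx))
    deg <- numeric(length(idx))
    for (ax in 1:3) for (sgn in c(-1L, 1L)) {
      nc <- coords
      nc[, ax] <- nc[, ax] + sgn
      inb <- nc[, ax] >= 1L & nc[, ax] <= d[ax]
      nIdx <- idx[inb] + sgn * strides[ax]
      sel <- which(inb)[solvable[nc[inb, , drop = FALSE]]]
      nIdx <- idx[sel] + sgn * strides[ax]
      deg[sel] <- deg[sel] + 1
      isInt <- interior[nIdx]
      # interior neighbour -> off-diagonal entry; boundary -> RHS
      intSel <- sel[isInt]
      if (length(intSel)) {
        rows <- c(rows, rank[idx[intSel]])
        cols <- c(cols, rank[nIdx[isInt]])
        vals <- c(vals, rep(-1, length(intSel)))
      }
      bSel <- sel[!isInt]
      if (length(bSel)) rhs[bSel] <- rhs[bSel] + depth[nIdx[!isInt]]
    }
    A <- Matrix::sparseMatrix(i = c(rows, seq_along(idx)),
                              j = c(cols, seq_along(idx)),
                              x = c(vals, deg),
                              dims = c(length(idx), length(idx)))
    sol <- as.numeric(Matrix::solve(A, rhs))
    depth[idx] <- sol
  }
  grad <- array(NA_real_, c(d, 3))
  for (ax in 1:3) {
    up <- array(NA_real_, d); dn <- array(NA_real_, d)
    n <- d[ax]
    if (n > 1) {
      src <- function(shift) {
        i <- seq_len(n) + shift
        i[i < 1L] <- 1L; i[i > n] <- n
        switch(ax, depth[i, , , drop = FALSE], depth[, i, , drop = FALSE],
               depth[, , i, drop = FALSE])
      }
      fw <- array(src(1L), d); bw <- array(src(-1L), d)
      ctr <- depth
      fw[is.na(fw)] <- ctr[is.na(fw)]   # one-sided at walls
      bw[is.na(bw)] <- ctr[is.na(bw)]
      grad[, , , ax] <- (fw - bw) / 2
    } else grad[, , , ax] <- 0
  }
  for (ax in 1:3) grad[, , , ax][is.na(depth)] <- NA_real_
  list(depth = depth, gradient = grad)
}

#' Local cardiac coordinate frames from a depth field
#'
#' The radial axis is the normalised depth gradient (pointing from
#' epicardium to endocardium); the longitudinal axis is the component of
#' the global long axis orthogonal to it; the circumferential axis
#' completes the right-handed frame as \code{c = l x r} (so
#' \code{r x c = l}). Voxels with a degenerate gradient are undefined.
#'
#' @param depthField the list returned by [laplaceDepth()].
#' @param longAxis global long-axis unit vector (default +z).
#' @param voxelSize isotropic voxel size in micrometres.
#' @return A [FrameField-class].
#' @export
localFrames <- function(depthField, longAxis = c(0, 0, 1), voxelSize = 1) {
  g <- depthField$gradient
  d <- dim(g)[1:3]
  gc <- lapply(1:3, function(k) .comp4(g, k))
  gn <- sqrt(gc[[1]]^2 + gc[[2]]^2 + gc[[3]]^2)
  ok <- !is.na(gn) & gn > 1e-12
  r <- array(NA_real_, c(d, 3))
  for (ax in 1:3) r[, , , ax] <- ifelse(ok, gc[[ax]] / gn, NA_real_)
  L <- longAxis / sqrt(sum(longAxis^2))
  rc <- lapply(1:3, function(k) .comp4(r, k))
  dotRL <- rc[[1]] * L[1] + rc[[2]] * L[2] + rc[[3]] * L[3]
  l <- array(NA_real_, c(d, 3))
  for (ax in 1:3) l[, , , ax] <- L[ax] - dotRL * rc[[ax]]
  lc <- lapply(1:3, function(k) .comp4(l, k))
  ln <- sqrt(lc[[1]]^2 + lc[[2]]^2 + lc[[3]]^2)
  bad <- !is.na(ln) & ln < 1e-9
  for (ax in 1:3) {
    l[, , , ax] <- ifelse(bad, NA_real_, lc[[ax]] / ln)
  }
  lc <- lapply(1:3, function(k) .comp4(l, k))
  cc <- array(NA_real_, c(d, 3))
  cc[, , , 1] <- lc[[2]] * rc[[3]] - lc[[3]] * rc[[2]]
  cc[, , , 2] <- lc[[3]] * rc[[1]] - lc[[1]] * rc[[3]]
  cc[, , , 3] <- lc[[1]] * rc[[2]] - lc[[2]] * rc[[1]]
  new("FrameField", depth = depthField$depth, radial = r,
      circumferential = cc, longitudinal = l, voxelSize = voxelSize)
}

#' Constant slab frames
#'
#' The trivial frame field of a transmural slab: radial = +x,
#' circumferential = +y, longitudinal = +z, with depth linear in x. Used
#' for phantom analyses where the Laplace solution is exactly linear.
#'
#' @param dims integer(3) grid dimensions.
#' @param voxelSize isotropic voxel size in micrometres.
#' @return A [FrameField-class].
#' @export
slabFrames <- function(dims, voxelSize = 1) {
  d <- as.integer(dims)
  ax <- function(v) {
    a <- array(0, c(d, 3))
    for (k in 1:3) a[, , , k] <- v[k]
    a
  }
  depth <- array(rep((seq_len(d[1]) - 0.5) / d[1], prod(d[2:3])), d)
  new("FrameField", depth = depth, radial = ax(c(1, 0, 0)),
      circumferential = ax(c(0, 1, 0)), longitudinal = ax(c(0, 0, 1)),
      voxelSize = voxelSize)
}
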
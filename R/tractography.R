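# Deterministic streamline tracking of axial eigenvector fields.

# Interpolate an axial unit-vector field at a fractional voxel coordinate,
# sign-aligning each corner vector to `ref` before weighting (the field is
# axial: v and -v are the same orientation).
#' @noRd
.interpAxial <- function(vf, p, ref) {
  d <- dim(vf)[1:3]
  if (any(p < 1) || any(p > d)) return(NULL)
  p <- pmin(p, d - 1e-9)
  p0 <- floor(p); f <- p - p0
  acc <- c(0, 0, 0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    if (w == 0) next
    v <- vf[p0[1] + dx, p0[2] + dy, p0[3] + dz, ]
    if (anyNA(v)) return(NULL)
    if (sum(v * ref) < 0) v <- -v
    acc <- acc + w * v
  }
  n <- sqrt(sum(acc^2))
  if (n < 1e-9) return(NULL)
  acc / n
}

#' @noRd
.traceOne <- function(vf, mask, seedVox, dir0, stepVox, cosThresh,
                      maxSteps) {
  d <- dim(mask)
  pts <- matrix(NA_real_, maxSteps + 1L, 3)
  pts[1, ] <- seedVox
  p <- seedVox
  prev <- dir0
  nPts <- 1L
  for (s in seq_len(maxSteps)) {
    v1 <- .interpAxial(vf, p, prev)
    if (is.null(v1)) break
    vm <- .interpAxial(vf, p + 0.5 * stepVox * v1, v1)   # midpoint (RK2)
    if (is.null(vm)) break
    pNew <- p + stepVox * vm
    if (any(pNew < 1) || any(pNew > d)) break
    vox <- pmin(pmax(round(pNew), 1), d)
    if (!mask[vox[1], vox[2], vox[3]]) break
    if (sum(vm * prev) < cosThresh) break
    nPts <- nPts + 1L
    pts[nPts, ] <- pNew
    p <- pNew
    prev <- vm
  }
  pts[seq_len(nPts), , drop = FALSE]
}

#' Deterministic streamline tractography
#'
#' Seeds one bidirectional streamline at every mask voxel centre and
#' integrates the chosen axial eigenvector field with a second-order
#' (midpoint) Runge-Kutta scheme and trilinear interpolation. At every
#' evaluation the interpolated vector is sign-aligned to the previous
#' direction. A streamline terminates on leaving the mask or field, or when
#' the turning angle between consecutive steps exceeds the threshold.
#' Tracks shorter than the minimum length are discarded; an optional
#' 3-point moving-average pass smooths the retained polylines (a stand-in
#' for a spline filter).
#'
#' @param es an [EigenSystem-class] or a \code{c(dim, 3)} vector array.
#' @param mask logical 3D array of seed/tracking voxels.
#' @param selector eigenvector index when \code{es} is an eigensystem
#'   ("v1".."v3"; "v3" follows the structure-tensor cell axis, "v1" the
#'   diffusion-tensor cell axis).
#' @param voxelSizeMm isotropic voxel size in millimetres.
#' @param stepVox integration step in voxels (default 0.25).
#' @param angleThreshold per-step turning angle limit in degrees.
#' @param minLength minimum track length in millimetres.
#' @param smooth apply the 3-point moving-average pass.
#' @param maxSteps per-direction step cap.
#' @param seeds optional n x 3 matrix of seed voxel coordinates; defaults
#'   to every mask voxel centre.
#' @return A [TrackSet-class] with coordinates in millimetres.
#' @export
trackStreamlines <- function(es, mask, selector = "v3", voxelSizeMm = 0.1,
                             stepVox = 0.25, angleThreshold = 30,
                             minLength = 0.5, smooth = TRUE,
                             maxSteps = 2000L, seeds = NULL) {
  vf <- if (is(es, "EigenSystem"))
    eigenVectors(es, as.integer(substring(selector, 2))) else es
  d <- dim(vf)[1:3]
  stopifnot(identical(dim(mask), d))
  cosThresh <- cos(angleThreshold * pi / 180)
  if (is.null(seeds)) seeds <- which(mask, arr.ind = TRUE)
  tracks <- list()
  for (i in seq_len(nrow(seeds))) {
    seed <- as.numeric(seeds[i, ])
    # reference for the first sign alignment: the nearest voxel's vector
    nv <- pmin(pmax(round(seed), 1L), d)
    ref0 <- vf[nv[1], nv[2], nv[3], ]
    if (anyNA(ref0)) next
    v0 <- .interpAxial(vf, seed, ref0)
    if (is.null(v0)) next
    fwd <- .traceOne(vf, mask, seed, v0, stepVox, cosThresh, maxSteps)
    bwd <- .traceOne(vf, mask, seed, -v0, stepVox, cosThresh, maxSteps)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))[-1]), , drop = FALSE], fwd)
    if (nrow(pts) < 2L) next
    mm <- pts * voxelSizeMm
    len <- sum(sqrt(rowSums(diff(mm)^2)))
    if (len < minLength) next
    if (smooth && nrow(mm) >= 3L) {
      sm <- mm
      n <- nrow(mm)
      sm[2:(n - 1), ] <- (mm[1:(n - 2), ] + mm[2:(n - 1), ] + mm[3:n, ]) / 3
      mm <- sm
    }
    tracks[[length(tracks) + 1L]] <- mm
  }
  new("TrackSet", tracks = tracks,
      parameters = list(selector = selector, stepVox = stepVox,
                        angleThreshold = angleThreshold,
                        minLength = minLength, smooth = smooth,
                        voxelSizeMm = voxelSizeMm))
}

#' Write a TrackVis (.trk) file
#'
#' Emits the version-2 TrackVis dialect with a 1000-byte header; point
#' coordinates are stored in the "voxmm" convention (millimetres in voxel
#' space), matching [trackStreamlines()] output.
#'
#' @param ts a [TrackSet-class].
#' @param path output file path.
#' @param dim integer(3) reference grid dimensions.
#' @param voxelSizeMm isotropic voxel size in millimetres.
#' @return \code{path}, invisibly.
#' @export
writeTrk <- function(ts, path, dim, voxelSizeMm) {
  stopifnot(is(ts, "TrackSet"), length(dim) == 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(raw(1), con)
  writeBin(as.integer(dim), con, size = 2)
  writeBin(rep(as.numeric(voxelSizeMm), 3), con, size = 4)
  writeBin(rep(0, 3), con, size = 4)                  # origin
  writeBin(0L, con, size = 2)                         # n_scalars
  writeBin(raw(200), con)                             # scalar names
  writeBin(0L, con, size = 2)                         # n_properties
  writeBin(raw(200), con)                             # property names
  m <- diag(4); m[1, 1] <- m[2, 2] <- m[3, 3] <- voxelSizeMm
  writeBin(as.numeric(t(m)), con, size = 4)           # vox_to_ras
  writeBin(raw(444), con)                             # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                               # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4)        # orientation
  writeBin(raw(2), con)                               # pad1
  writeBin(raw(6), con)                               # invert/swap flags
  writeBin(length(ts@tracks), con, size = 4)          # n_count
  writeBin(2L, con, size = 4)                         # version
  writeBin(1000L, con, size = 4)                      # hdr_size
  for (t in ts@tracks) {
    writeBin(nrow(t), con, size = 4)
    writeBin(as.numeric(t(t)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis (.trk) file written by [writeTrk()]
#'
#' @param path file path.
#' @return list with \code{tracks} (list of n x 3 matrices), \code{dim},
#'   \code{voxelSize}, \code{nCount}.
#' @export
readTrk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 5))
  readBin(con, raw(), 1)
  if (magic != "TRACK") stop("not a TrackVis file", call. = FALSE)
  dim <- readBin(con, integer(), 3, size = 2)
  voxelSize <- readBin(con, numeric(), 3, size = 4)
  invisible(readBin(con, numeric(), 3, size = 4))
  invisible(readBin(con, integer(), 1, size = 2))
  invisible(readBin(con, raw(), 200))
  invisible(readBin(con, integer(), 1, size = 2))
  invisible(readBin(con, raw(), 200))
  invisible(readBin(con, numeric(), 16, size = 4))
  invisible(readBin(con, raw(), 444))
  invisible(readBin(con, raw(), 4))     # voxel order
  invisible(readBin(con, raw(), 4))
  invisible(readBin(con, numeric(), 6, size = 4))
  invisible(readBin(con, raw(), 2))
  invisible(readBin(con, raw(), 6))
  nCount <- readBin(con, integer(), 1, size = 4)
  version <- readBin(con, integer(), 1, size = 4)
  hdr <- readBin(con, integer(), 1, size = 4)
  if (hdr != 1000L) stop("unexpected TrackVis header size", call. = FALSE)
  tracks <- vector("list", nCount)
  for (i in seq_len(nCount)) {
    np <- readBin(con, integer(), 1, size = 4)
    pts <- readBin(con, numeric(), 3 * np, size = 4)
    tracks[[i]] <- matrix(pts, np, 3, byrow = TRUE)
  }
  list(tracks = tracks, dim = dim, voxelSize = voxelSize, nCount = nCount)
}
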
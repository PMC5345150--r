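# Vessel segmentation: threshold, dilate, connected components, size filter.

# 26-connected component labelling by breadth-first flood fill.
# Returns an integer array (0 = background).
#' @noRd
.labelComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, , drop = FALSE]
  offs <- nbr[, 1] + nbr[, 2] * d[1] + nbr[, 3] * d[1] * d[2]
  fg <- which(mask)
  cur <- 0L
  # precomputed coordinates guard against wrapping across faces
  coord <- arrayInd(fg, d)
  xs <- integer(prod(d)); ys <- integer(prod(d)); zs <- integer(prod(d))
  xs[fg] <- coord[, 1]; ys[fg] <- coord[, 2]; zs[fg] <- coord[, 3]
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      cand <- rep(frontier, each = nrow(nbr)) + offs
      cx <- rep(xs[frontier], each = nrow(nbr)) + nbr[, 1]
      cy <- rep(ys[frontier], each = nrow(nbr)) + nbr[, 2]
      cz <- rep(zs[frontier], each = nrow(nbr)) + nbr[, 3]
      ok <- cx >= 1L & cx <= d[1] & cy >= 1L & cy <= d[2] &
        cz >= 1L & cz <= d[3]
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  lab
}

# Binary dilation with a spherical structuring element of radius r voxels.
#' @noRd
.dilateSphere <- function(mask, rVox) {
  h <- as.integer(ceiling(rVox))
  ax <- seq(-h, h)
  se <- outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= rVox^2
  dim(se) <- c(length(ax), length(ax), length(ax))
  conv <- .convolveReal(mask * 1.0, se * 1.0, pad = "replicate")
  conv > 0.5
}

#' Segment bright vascular structures
#'
#' Thresholds the volume at an intensity magnitude, dilates the result with
#' a spherical structuring element of the given physical radius (so the
#' immediate neighbourhood of each vessel is included), labels 26-connected
#' components and discards components smaller than a minimum physical
#' volume. Defaults are the reference parameters: threshold 0.006, dilation
#' radius 4.4 um, minimum component volume 6.5e4 um^3.
#'
#' @param volume 3D numeric array.
#' @param voxelSize isotropic voxel size, micrometres.
#' @param threshold intensity magnitude threshold (voxels with
#'   \code{abs(volume) >= threshold} are retained).
#' @param dilationRadius dilation radius in micrometres; if smaller than
#'   one voxel, a warning is raised and a single-voxel element (no
#'   dilation) is used.
#' @param minVolume minimum component volume in cubic micrometres.
#' @return A [VesselMask-class].
#' @export
segmentVessels <- function(volume, voxelSize, threshold = 0.006,
                           dilationRadius = 4.4, minVolume = 6.5e4) {
  mask <- abs(volume) >= threshold
  if (any(mask)) {
    rVox <- dilationRadius / voxelSize
    if (rVox < 1) {
      warning("dilation radius below one voxel; using a single-voxel element")
    } else {
      mask <- .dilateSphere(mask, rVox)
    }
    lab <- .labelComponents(mask)
    if (max(lab) > 0L) {
      sizes <- tabulate(lab[lab > 0L])
      keepIds <- which(sizes * voxelSize^3 >= minVolume)
      mask <- array(lab %in% keepIds & lab > 0L, dim(mask))
    }
  }
  new("VesselMask", mask = mask, threshold = threshold,
      dilationRadius = dilationRadius, minVolume = minVolume,
      voxelSize = voxelSize)
}
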
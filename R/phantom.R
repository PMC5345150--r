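# Synthetic transmural myocardium: cuboidal-cell lattice with ground truth.

# Per-sheetlet helix angle. Sheetlets are indexed from the epicardial face;
# the ramp is linear in the sheetlet's fractional transmural position
# (s + 1/2) / nSheet, so the first and last sheetlets sit half a period
# inside the nominal range rather than at its extremes.
#' @noRd
.sheetletHA <- function(sIdx, nSheet, haRange) {
  haRange[1] + (haRange[2] - haRange[1]) * (sIdx + 0.5) / nSheet
}

#' @noRd
.phantomGeometry <- function(spec) {
  layerPeriod <- spec@cellThickness + spec@gapCellThickness
  periodX <- spec@sheetletDepth * spec@cellThickness +
    (spec@sheetletDepth - 1) * spec@gapCellThickness + spec@gapSheetlet
  periodW <- spec@cellWidth + spec@gapCellWidth
  extent <- spec@blockExtent * 1000  # mm -> um
  list(layerPeriod = layerPeriod, periodX = periodX, periodW = periodW,
       extent = extent, nSheet = ceiling(extent[1] / periodX))
}

#' Rasterise the cuboidal-cell myocardial phantom
#'
#' Builds the transmural slab on an isotropic voxel grid. The lattice starts
#' flush at the epicardial face (x = 0). Each sheetlet consists of
#' \code{sheetletDepth} cell layers separated by \code{gapCellThickness}
#' along x, followed by the \code{gapSheetlet} cleavage gap; within a
#' sheetlet the in-plane lattice (cells of width \code{cellWidth} separated
#' by \code{gapCellWidth}) is rigidly rotated about the radial axis by the
#' sheetlet's helix angle, so the cell long-axis lies in the
#' circumferential-longitudinal plane at that angle. Cells abut end-to-end
#' along their long axis (no inter-cell gap is defined in that direction),
#' and cells are clipped at the block boundaries.
#'
#' Grid dimensions are \code{round(extent / resolution)} per axis; with the
#' default 0.1 mm slab thickness at 3.6 um this rounds 27.78 voxels up to 28.
#'
#' @param spec a [phantomSpec()].
#' @return A [LabelledVolume-class] with noiseless intensities
#'   (\code{sIntra} inside cells, \code{sExtra} in gaps), intracellular
#'   occupancy and the ground-truth helix angle per intracellular voxel.
#' @examples
#' vol <- buildPhantom(phantomSpec(blockExtent = c(0.2, 0.1, 0.05)))
#' vol
#' @export
buildPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  g <- .phantomGeometry(spec)
  if (g$extent[1] < g$periodX || g$extent[2] < g$periodW ||
      g$extent[3] < spec@gridResolution)
    stop("block extent is smaller than one unit cell of the lattice",
         call. = FALSE)
  dims <- pmax(1L, as.integer(round(g$extent / spec@gridResolution)))
  cx <- .voxelCentres(dims[1], spec@gridResolution)
  cy <- .voxelCentres(dims[2], spec@gridResolution)
  cz <- .voxelCentres(dims[3], spec@gridResolution)

  sIdx <- floor(cx / g$periodX)
  xp <- cx - sIdx * g$periodX
  inCellX <- (xp %% g$layerPeriod) < spec@cellThickness &
    xp < spec@sheetletDepth * g$layerPeriod - spec@gapCellThickness
  ha <- .sheetletHA(sIdx, g$nSheet, spec@haRange)

  occ <- array(FALSE, dims)
  haMap <- array(NA_real_, dims)
  for (i in seq_len(dims[1])) {
    if (!inCellX[i]) next
    th <- ha[i] * pi / 180
    # in-plane width coordinate of the rotated lattice (rotation about the
    # radial axis, origin at the block corner)
    w <- outer(-cy * sin(th), cz * cos(th), "+")
    inPlane <- (w %% g$periodW) < spec@cellWidth
    occ[i, , ] <- inPlane
    haMap[i, , ][inPlane] <- ha[i]
  }
  inten <- array(spec@sExtra, dims)
  inten[occ] <- spec@sIntra
  new("LabelledVolume", intensity = inten, occupancy = occ, haMap = haMap,
      voxelSize = spec@gridResolution, spec = spec)
}

#' Ground-truth orientation axes of a phantom volume
#'
#' Reconstructs the per-voxel orthonormal triad from the stored helix angle.
#' Under the slab convention the sheet-normal is the transmural axis
#' \code{(1, 0, 0)}; the cell long-axis is
#' \code{(0, cos HA, sin HA)} and the in-sheet (sheetlet) direction
#' \code{(0, -sin HA, cos HA)}, so long x sheet = normal (right-handed).
#'
#' @param vol a [LabelledVolume-class].
#' @param which one of "long", "sheet", "normal".
#' @return A \code{c(dim(vol), 3)} array of unit vectors, NA outside cells.
#' @export
truthAxes <- function(vol, which = c("long", "sheet", "normal")) {
  which <- match.arg(which)
  th <- vol@haMap * pi / 180
  d <- dim(th)
  out <- array(NA_real_, c(d, 3))
  switch(which,
    long = {
      out[, , , 1][!is.na(th)] <- 0
      out[, , , 2] <- cos(th)
      out[, , , 3] <- sin(th)
    },
    sheet = {
      out[, , , 1][!is.na(th)] <- 0
      out[, , , 2] <- -sin(th)
      out[, , , 3] <- cos(th)
    },
    normal = {
      out[, , , 1][!is.na(th)] <- 1
      out[, , , 2][!is.na(th)] <- 0
      out[, , , 3][!is.na(th)] <- 0
    })
  out
}

#' Add Poisson counting noise to a volume
#'
#' Each voxel is replaced by a Poisson draw with mean equal to its noiseless
#' intensity, so the per-voxel standard deviation is sqrt(S_i). The draw is
#' deterministic under a fixed seed and the caller's RNG state is restored.
#'
#' @param vol a [LabelledVolume-class] with non-negative intensities.
#' @param seed integer seed.
#' @return The volume with noisy intensities; occupancy and ground truth are
#'   unchanged.
#' @export
addPoissonNoise <- function(vol, seed) {
  stopifnot(is(vol, "LabelledVolume"))
  if (any(vol@intensity < 0))
    stop("Poisson noise requires non-negative intensities", call. = FALSE)
  noisy <- .withSeed(seed, {
    array(stats::rpois(length(vol@intensity), vol@intensity),
          dim(vol@intensity))
  })
  vol@intensity <- noisy * 1.0
  vol
}

#' Voxel-averaged ground-truth reference orientations and angles
#'
#' For each coarse voxel the outer products (dyadics) of the intracellular
#' ground-truth cell long-axis vectors are averaged; the principal
#' eigenvector of the mean dyadic is the reference orientation. Averaging
#' dyadics rather than vectors respects the axial (+v = -v) nature of
#' orientation data: two equal populations at +theta and -theta average to
#' 0 degrees instead of cancelling. Helix and transverse angles are then
#' computed in the slab frame (radial = x, circumferential = y,
#' longitudinal = z).
#'
#' @param vol a [LabelledVolume-class].
#' @param coarseSize coarse voxel edge in micrometres; must be an integer
#'   multiple of the grid resolution.
#' @param partial keep trailing partial blocks (default TRUE, so the
#'   endocardial-most layer reaches the endocardial face even when the grid
#'   is not an exact multiple of the block size).
#' @return A list with \code{angles} (coarse [AngleMaps-class]),
#'   \code{orientation} (\code{c(coarseDim, 3)} unit vectors),
#'   \code{count} (intracellular voxels per block; blocks with no
#'   intracellular content are NA in all outputs).
#' @export
voxelAverageReference <- function(vol, coarseSize, partial = TRUE) {
  stopifnot(is(vol, "LabelledVolume"))
  f <- coarseSize / vol@voxelSize
  if (abs(f - round(f)) > 1e-8)
    stop("coarseSize must be an integer multiple of the grid resolution",
         call. = FALSE)
  f <- as.integer(round(f))
  th <- vol@haMap * pi / 180
  uy <- cos(th); uz <- sin(th)
  occ <- vol@occupancy
  # dyadic elements (u_x = 0 for the slab phantom, so xx/xy/xz vanish)
  dyy <- .blockMean(uy * uy, f, occ, partial)
  dyz <- .blockMean(uy * uz, f, occ, partial)
  dzz <- .blockMean(uz * uz, f, occ, partial)
  cnt <- .blockCount(dim(occ), f, occ, partial)
  cd <- dim(dyy)
  orient <- array(NA_real_, c(cd, 3))
  haC <- array(NA_real_, cd); taC <- array(NA_real_, cd)
  for (i in seq_len(prod(cd))) {
    if (is.na(dyy[i])) next
    M <- matrix(c(dyy[i], dyz[i], dyz[i], dzz[i]), 2, 2)
    v <- eigen(M, symmetric = TRUE)$vectors[, 1]
    if (v[1] < 0) v <- -v  # axial: canonicalise toward +circumferential
    ijk <- arrayInd(i, cd)
    orient[ijk[1], ijk[2], ijk[3], ] <- c(0, v)
    haC[i] <- .foldAxial(atan2(v[2], v[1]) * 180 / pi)
    taC[i] <- 0  # the slab-phantom truth axis has no radial component
  }
  taC[is.na(haC)] <- NA_real_
  angles <- new("AngleMaps", ha = haC, ta = taC,
                se = array(NA_real_, cd), sa = array(NA_real_, cd),
                voxelSize = f * vol@voxelSize)
  list(angles = angles, orientation = orient, count = cnt)
}

#' Ground-truth diffusion tensors from voxel-averaged triads
#'
#' Assembles one symmetric positive-definite tensor per coarse voxel from
#' the voxel-averaged orientation triad, assigning the supplied eigenvalues
#' to the cell long-axis (first), sheetlet (second) and sheet-normal (third)
#' directions — the diffusion-tensor eigenvector convention. The long-axis
#' is the principal eigenvector of the mean intracellular long-axis dyadic;
#' the sheet-normal is the mean sheet-normal re-orthogonalised against it,
#' and the sheetlet direction completes the right-handed triad.
#'
#' @param vol a [LabelledVolume-class].
#' @param coarseSize coarse voxel edge in micrometres (integer multiple of
#'   the grid resolution).
#' @param eigenvalues numeric(3), decreasing and positive (mm^2/s for a
#'   diffusion interpretation).
#' @param partial keep trailing partial blocks (default TRUE).
#' @return A [TensorField-class] with provenance "truth"; coarse voxels with
#'   no intracellular content are NA.
#' @export
makeTruthTensors <- function(vol, coarseSize,
                             eigenvalues = c(1.5e-3, 1.0e-3, 0.7e-3),
                             partial = TRUE) {
  stopifnot(is(vol, "LabelledVolume"))
  if (length(eigenvalues) != 3L || any(diff(eigenvalues) > 0) ||
      any(eigenvalues <= 0))
    stop("eigenvalues must be three positive values in decreasing order",
         call. = FALSE)
  ref <- voxelAverageReference(vol, coarseSize, partial)
  cd <- dim(ref$count)
  el <- array(NA_real_, c(cd, 6))
  for (i in seq_len(prod(cd))) {
    ijk <- arrayInd(i, cd)
    u <- ref$orientation[ijk[1], ijk[2], ijk[3], ]
    if (anyNA(u)) next
    nrm <- c(1, 0, 0)                      # slab sheet-normal
    nrm <- nrm - sum(nrm * u) * u
    nrm <- nrm / sqrt(sum(nrm^2))
    s <- c(nrm[2] * u[3] - nrm[3] * u[2],  # sheet = normal x long
           nrm[3] * u[1] - nrm[1] * u[3],
           nrm[1] * u[2] - nrm[2] * u[1])
    D <- eigenvalues[1] * tcrossprod(u) + eigenvalues[2] * tcrossprod(s) +
      eigenvalues[3] * tcrossprod(nrm)
    el[ijk[1], ijk[2], ijk[3], ] <- .matrixToElements(D)
  }
  .tensorField(el, coarseSize, "truth")
}
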
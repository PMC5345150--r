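#' @import methods
NULL

# ---------------------------------------------------------------------------
# PhantomSpec
# ---------------------------------------------------------------------------

#' Parametric specification of the cuboidal-cell myocardial phantom
#'
#' Describes a transmural slab of close-packed elongated cuboidal
#' cardiomyocytes arranged in sheetlets. Axes follow the slab convention:
#' x is transmural (radial), y circumferential, z longitudinal. Cells within
#' one sheetlet share a helix angle; the helix angle is constant per sheetlet
#' and varies linearly with transmural position between the two ends of
#' \code{haRange}.
#'
#' @slot blockExtent numeric(3), slab extent in mm (x, y, z).
#' @slot gridResolution isotropic voxel size in micrometres.
#' @slot cellLength,cellWidth,cellThickness cell dimensions in micrometres
#'   (length along the cell long-axis, width along the in-sheet transverse
#'   direction, thickness along the sheet-normal).
#' @slot gapSheetlet gap between adjacent sheetlets (thickness direction), um.
#' @slot gapCellWidth gap between cells along the width direction, um.
#' @slot gapCellThickness gap between cell layers inside a sheetlet, um.
#' @slot sheetletDepth number of cell layers per sheetlet.
#' @slot haRange numeric(2), helix angle in degrees at the subepicardial and
#'   subendocardial faces.
#' @slot ta transverse angle in degrees (applied uniformly).
#' @slot sIntra,sExtra intracellular / extracellular signal intensity
#'   (arbitrary units); these are also the Poisson means when noise is added.
#' @seealso [buildPhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(blockExtent = "numeric", gridResolution = "numeric",
    cellLength = "numeric", cellWidth = "numeric", cellThickness = "numeric",
    gapSheetlet = "numeric", gapCellWidth = "numeric",
    gapCellThickness = "numeric", sheetletDepth = "numeric",
    haRange = "numeric", ta = "numeric", sIntra = "numeric",
    sExtra = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  lens <- c(object@blockExtent, object@gridResolution, object@cellLength,
            object@cellWidth, object@cellThickness)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all lengths must be positive")
  if (any(c(object@gapSheetlet, object@gapCellWidth,
            object@gapCellThickness) < 0))
    msg <- c(msg, "gaps must be non-negative")
  if (length(object@blockExtent) != 3L)
    msg <- c(msg, "blockExtent must have length 3")
  if (length(object@haRange) != 2L || any(abs(object@haRange) > 90))
    msg <- c(msg, "haRange must be two angles within [-90, 90] degrees")
  if (object@sheetletDepth < 1)
    msg <- c(msg, "sheetletDepth must be >= 1")
  if (object@sIntra < 0 || object@sExtra < 0)
    msg <- c(msg, "signal intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Create a phantom specification
#'
#' Defaults reproduce the reference simulation conditions: a
#' 0.9 x 0.9 x 0.1 mm transmural block at 3.6 um isotropic resolution,
#' 108 x 18 x 14 um cells in sheetlets three cells deep, 7 um sheetlet gaps,
#' 7 um in-width gaps, 4 um in-thickness gaps, helix angle ramping linearly
#' from -88 deg (subepicardium) to +88 deg (subendocardium), transverse angle
#' 0 deg, and signal intensities 50 (intracellular) / 100 (extracellular).
#'
#' @param blockExtent slab extent in mm (x = transmural, y = circumferential,
#'   z = longitudinal).
#' @param gridResolution isotropic voxel size, micrometres.
#' @param cellLength,cellWidth,cellThickness cell dimensions, micrometres.
#' @param gapSheetlet,gapCellWidth,gapCellThickness gap dimensions,
#'   micrometres.
#' @param sheetletDepth cell layers per sheetlet.
#' @param haRange helix angle at the epicardial and endocardial faces,
#'   degrees.
#' @param ta transverse angle, degrees.
#' @param sIntra,sExtra intracellular / extracellular intensities.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec()
#' spec
#' @export
phantomSpec <- function(blockExtent = c(0.9, 0.9, 0.1), gridResolution = 3.6,
                        cellLength = 108, cellWidth = 18, cellThickness = 14,
                        gapSheetlet = 7, gapCellWidth = 7,
                        gapCellThickness = 4, sheetletDepth = 3,
                        haRange = c(-88, 88), ta = 0,
                        sIntra = 50, sExtra = 100) {
  new("PhantomSpec", blockExtent = as.numeric(blockExtent),
      gridResolution = gridResolution, cellLength = cellLength,
      cellWidth = cellWidth, cellThickness = cellThickness,
      gapSheetlet = gapSheetlet, gapCellWidth = gapCellWidth,
      gapCellThickness = gapCellThickness, sheetletDepth = sheetletDepth,
      haRange = as.numeric(haRange), ta = ta, sIntra = sIntra,
      sExtra = sExtra)
}

# ---------------------------------------------------------------------------
# LabelledVolume
# ---------------------------------------------------------------------------

#' Voxelised phantom with ground-truth orientations
#'
#' Holds the rasterised phantom: an intensity grid, an intracellular
#' occupancy grid and the per-voxel ground-truth helix angle from which the
#' orthonormal orientation triad (cell long-axis, sheetlet, sheet-normal) is
#' reconstructed on demand by [truthAxes()]. The sheet-normal is the
#' transmural (x) axis under the slab convention, so a single angle per voxel
#' determines the triad exactly.
#'
#' @slot intensity 3D numeric array of signal intensities.
#' @slot occupancy 3D logical array, TRUE for intracellular voxels.
#' @slot haMap 3D numeric array of ground-truth helix angles in degrees,
#'   NA outside cells.
#' @slot voxelSize isotropic voxel size in micrometres.
#' @slot spec the generating [PhantomSpec-class].
#' @exportClass LabelledVolume
setClass("LabelledVolume",
  representation(intensity = "array", occupancy = "array", haMap = "array",
                 voxelSize = "numeric", spec = "PhantomSpec"))

setValidity("LabelledVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@intensity), dim(object@occupancy)) ||
      !identical(dim(object@intensity), dim(object@haMap)))
    msg <- c(msg, "intensity, occupancy and haMap must share dimensions")
  if (any(object@intensity < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TensorField
# ---------------------------------------------------------------------------

#' Dense field of symmetric 3x3 tensors
#'
#' A per-voxel symmetric tensor (structure, diffusion or ground truth) stored
#' as its six unique elements in NIfTI lower-triangular order
#' (xx, xy, yy, xz, yz, zz) along the fourth array dimension. Undefined
#' voxels carry NA in all six elements.
#'
#' @slot elements 4D numeric array, \code{dim = c(nx, ny, nz, 6)}.
#' @slot voxelSize isotropic voxel size in micrometres.
#' @slot provenance one of "structure", "diffusion", "truth".
#' @exportClass TensorField
setClass("TensorField",
  representation(elements = "array", voxelSize = "numeric",
                 provenance = "character"))

setValidity("TensorField", function(object) {
  msg <- character()
  d <- dim(object@elements)
  if (length(d) != 4L || d[4] != 6L)
    msg <- c(msg, "elements must be an nx x ny x nz x 6 array")
  if (!object@provenance %in% c("structure", "diffusion", "truth"))
    msg <- c(msg, "provenance must be structure, diffusion or truth")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' @noRd
.tensorField <- function(elements, voxelSize, provenance) {
  new("TensorField", elements = elements, voxelSize = voxelSize,
      provenance = provenance)
}

# ---------------------------------------------------------------------------
# EigenSystem
# ---------------------------------------------------------------------------

#' Per-voxel eigendecomposition of a tensor field
#'
#' Eigenvalues are sorted descending (\code{values[, , , 1]} is the largest).
#' For structure tensors the cell long-axis is the third eigenvector (least
#' intensity variation); for diffusion tensors it is the first. Eigenvector
#' signs are canonicalised so the first non-zero component is positive.
#'
#' @slot values 4D array \code{c(nx, ny, nz, 3)}, descending per voxel.
#' @slot vectors 5D array \code{c(nx, ny, nz, 3, 3)}; \code{[, , , i, k]} is
#'   component i of eigenvector k.
#' @slot degenerate 3D logical array flagging (near-)equal eigenvalue pairs.
#' @slot voxelSize isotropic voxel size in micrometres.
#' @exportClass EigenSystem
setClass("EigenSystem",
  representation(values = "array", vectors = "array", degenerate = "array",
                 voxelSize = "numeric"))

# ---------------------------------------------------------------------------
# FrameField
# ---------------------------------------------------------------------------

#' Local cardiac coordinate frames with transmural depth
#'
#' Per-voxel right-handed orthonormal axes (radial, circumferential,
#' longitudinal) and the normalised transmural depth (0 at the epicardial
#' boundary, 1 at the endocardial boundary) obtained from a harmonic
#' (Laplace) interpolation between the two surfaces.
#'
#' @slot depth 3D numeric array in [0, 1], NA outside the myocardium.
#' @slot radial,circumferential,longitudinal 4D arrays \code{c(dim, 3)} of
#'   unit axes, NA where undefined.
#' @slot voxelSize isotropic voxel size in micrometres.
#' @exportClass FrameField
setClass("FrameField",
  representation(depth = "array", radial = "array",
                 circumferential = "array", longitudinal = "array",
                 voxelSize = "numeric"))

# ---------------------------------------------------------------------------
# AngleMaps
# ---------------------------------------------------------------------------

#' Helix, transverse and sheet angle maps
#'
#' Degree-valued maps folded to (-90, 90] (orientations are axial).
#' HA/TA describe the cell-axis eigenvector, SE/SA the sheet-associated
#' eigenvector; SE/SA are NA-filled when no sheet vector was supplied.
#'
#' @slot ha,ta,se,sa 3D numeric arrays in degrees, NA where undefined.
#' @slot voxelSize isotropic voxel size in micrometres.
#' @exportClass AngleMaps
setClass("AngleMaps",
  representation(ha = "array", ta = "array", se = "array", sa = "array",
                 voxelSize = "numeric"))

setValidity("AngleMaps", function(object) {
  v <- c(object@ha, object@ta, object@se, object@sa)
  v <- v[!is.na(v)]
  if (length(v) && (min(v) <= -90 - 1e-9 || max(v) > 90 + 1e-9))
    "angles must lie in (-90, 90] degrees" else TRUE
})

# ---------------------------------------------------------------------------
# AgreementReport
# ---------------------------------------------------------------------------

#' Bland-Altman agreement between two angle maps
#'
#' Voxel-wise angular differences are wrapped to (-90, 90] before statistics
#' (the data are axial). Limits of agreement are bias +/- 1.96 SD.
#'
#' @slot bias mean wrapped difference, degrees.
#' @slot sdDiff standard deviation of the wrapped differences.
#' @slot loa numeric(2), lower and upper limits of agreement.
#' @slot differences,means paired per-voxel values for the scatter.
#' @slot n number of voxels compared.
#' @exportClass AgreementReport
setClass("AgreementReport",
  representation(bias = "numeric", sdDiff = "numeric", loa = "numeric",
                 differences = "numeric", means = "numeric", n = "integer"))

setValidity("AgreementReport", function(object) {
  if (length(object@loa) == 2L &&
      abs((object@loa[1] + object@loa[2]) / 2 - object@bias) > 1e-8)
    "limits of agreement must be symmetric about the bias" else TRUE
})

# ---------------------------------------------------------------------------
# FilterBank
# ---------------------------------------------------------------------------

#' Bank of six 3D lognormal quadrature filters
#'
#' Complex-valued direction-selective band-pass kernels whose response
#' magnitude is phase invariant. Directions are the six icosahedral
#' half-axes; the radial frequency profile is lognormal with the given
#' centre frequency (radians/sample) and bandwidth (octaves).
#'
#' @slot directions 6 x 3 matrix of unit filter directions.
#' @slot centreFreq centre frequency rho0 in radians/sample, in (0, pi).
#' @slot bandwidth relative bandwidth in octaves.
#' @slot size spatial kernel size per side (odd).
#' @slot kernels complex array \code{c(size, size, size, 6)}.
#' @exportClass FilterBank
setClass("FilterBank",
  representation(directions = "matrix", centreFreq = "numeric",
                 bandwidth = "numeric", size = "integer",
                 kernels = "array"))

setValidity("FilterBank", function(object) {
  msg <- character()
  if (nrow(object@directions) != 6L)
    msg <- c(msg, "exactly six filter directions are required")
  cross <- abs(tcrossprod(object@directions))
  diag(cross) <- 0
  if (any(cross > 1 - 1e-8))
    msg <- c(msg, "filter directions must be pairwise non-collinear")
  if (object@size %% 2L == 0L) msg <- c(msg, "kernel size must be odd")
  if (object@centreFreq <= 0 || object@centreFreq >= pi)
    msg <- c(msg, "centre frequency must lie in (0, pi)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# VesselMask
# ---------------------------------------------------------------------------

#' Binary vessel segmentation with its parameters
#'
#' @slot mask 3D logical array at the source resolution.
#' @slot threshold intensity magnitude threshold.
#' @slot dilationRadius dilation radius in micrometres.
#' @slot minVolume minimum connected-component volume in cubic micrometres.
#' @slot voxelSize isotropic voxel size in micrometres.
#' @exportClass VesselMask
setClass("VesselMask",
  representation(mask = "array", threshold = "numeric",
                 dilationRadius = "numeric", minVolume = "numeric",
                 voxelSize = "numeric"))

# ---------------------------------------------------------------------------
# Projections / physics
# ---------------------------------------------------------------------------

#' Stack of tomographic projections with correction frames
#'
#' @slot projections 3D array \code{c(nu, nv, nAngles)} of intensities
#'   I(x, y) per rotation angle.
#' @slot flat 2D flat-field (background illumination) frame I0(x, y).
#' @slot dark 2D dark-current frame.
#' @slot angles projection angles in degrees, strictly increasing in
#'   [0, 180).
#' @slot pixelSize detector pixel size in micrometres.
#' @exportClass ProjectionStack
setClass("ProjectionStack",
  representation(projections = "array", flat = "matrix", dark = "matrix",
                 angles = "numeric", pixelSize = "numeric"))

setValidity("ProjectionStack", function(object) {
  msg <- character()
  d <- dim(object@projections)
  if (!identical(d[1:2], dim(object@flat)) ||
      !identical(d[1:2], dim(object@dark)))
    msg <- c(msg, "flat/dark frames must match projection shape")
  if (length(object@angles) != d[3])
    msg <- c(msg, "one angle per projection is required")
  if (is.unsorted(object@angles, strictly = TRUE))
    msg <- c(msg, "angles must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname ProjectionStack-class
#' @param projections,flat,dark,angles,pixelSize see slots.
#' @export
projectionStack <- function(projections, flat, dark, angles, pixelSize) {
  new("ProjectionStack", projections = projections, flat = flat, dark = dark,
      angles = as.numeric(angles), pixelSize = pixelSize)
}

#' Physical parameters of single-distance phase retrieval
#'
#' Defaults follow the reference acquisition: wavelength 6.2e-11 m (20 keV
#' average energy), propagation distance 0.50 m, and a fixed
#' refractive-decrement to extinction ratio delta/beta of 1000.
#'
#' @slot wavelength X-ray wavelength lambda, metres.
#' @slot distance propagation distance z, metres.
#' @slot deltaOverBeta dimensionless delta_lambda / beta_lambda ratio.
#' @exportClass PhysicsParams
setClass("PhysicsParams",
  representation(wavelength = "numeric", distance = "numeric",
                 deltaOverBeta = "numeric"))

setValidity("PhysicsParams", function(object) {
  if (object@wavelength <= 0 || object@distance <= 0 ||
      object@deltaOverBeta <= 0)
    "all physics parameters must be positive" else TRUE
})

#' @rdname PhysicsParams-class
#' @param wavelength,distance,deltaOverBeta see slots.
#' @export
physicsParams <- function(wavelength = 6.2e-11, distance = 0.50,
                          deltaOverBeta = 1000) {
  new("PhysicsParams", wavelength = wavelength, distance = distance,
      deltaOverBeta = deltaOverBeta)
}

# ---------------------------------------------------------------------------
# DWI protocol / rigid transform
# ---------------------------------------------------------------------------

#' Diffusion-weighted acquisition protocol
#'
#' @slot bValue diffusion weighting in s/mm^2.
#' @slot directions n x 3 matrix of unit gradient directions.
#' @slot nB0 number of non-diffusion-weighted volumes acquired first.
#' @exportClass DwiProtocol
setClass("DwiProtocol",
  representation(bValue = "numeric", directions = "matrix", nB0 = "integer"))

setValidity("DwiProtocol", function(object) {
  msg <- character()
  if (object@bValue < 0) msg <- c(msg, "b-value must be non-negative")
  nrm <- sqrt(rowSums(object@directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "gradient directions must be unit norm")
  if (length(msg)) msg else TRUE
})

#' @rdname DwiProtocol-class
#' @param bValue,directions,nB0 see slots.
#' @export
dwiProtocol <- function(bValue = 1000, directions, nB0 = 4L) {
  new("DwiProtocol", bValue = bValue, directions = as.matrix(directions),
      nB0 = as.integer(nB0))
}

#' Rigid-body transform
#'
#' Rotation plus translation in millimetres; \code{v_new = R v + t}.
#'
#' @slot rotation 3 x 3 proper rotation matrix.
#' @slot translation numeric(3) in millimetres.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    "rotation must be orthonormal with determinant +1" else TRUE
})

#' @rdname RigidTransform-class
#' @param rotation,translation see slots.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

# ---------------------------------------------------------------------------
# TrackSet
# ---------------------------------------------------------------------------

#' Set of deterministic streamlines
#'
#' @slot tracks list of n x 3 matrices of point coordinates in millimetres.
#' @slot parameters list of generation parameters (step, angle threshold,
#'   minimum length, eigenvector selector, smoothing).
#' @exportClass TrackSet
setClass("TrackSet",
  representation(tracks = "list", parameters = "list"))

setValidity("TrackSet", function(object) {
  if (length(object@tracks) &&
      any(vapply(object@tracks, nrow, 1L) < 2L))
    "every track must have at least two points" else TRUE
})

# ---------------------------------------------------------------------------
# Generics and accessors
# ---------------------------------------------------------------------------

#' Voxel size accessor
#' @param object an object carrying voxel-size metadata.
#' @return isotropic voxel size in micrometres.
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "LabelledVolume", function(object) object@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "TensorField", function(object) object@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "EigenSystem", function(object) object@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "FrameField", function(object) object@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "AngleMaps", function(object) object@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VesselMask", function(object) object@voxelSize)

#' Intensity grid of a labelled volume
#' @param object a [LabelledVolume-class].
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname intensity
#' @export
setMethod("intensity", "LabelledVolume", function(object) object@intensity)

#' Intracellular occupancy of a labelled volume
#' @param object a [LabelledVolume-class].
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
#' @rdname occupancy
#' @export
setMethod("occupancy", "LabelledVolume", function(object) object@occupancy)

#' Tensor elements accessor
#' @param object a [TensorField-class].
#' @return 4D array of the six unique elements in (xx, xy, yy, xz, yz, zz)
#'   order.
#' @export
setGeneric("tensorElements", function(object) standardGeneric("tensorElements"))
#' @rdname tensorElements
#' @export
setMethod("tensorElements", "TensorField", function(object) object@elements)

#' Eigenvalue accessor
#' @param object an [EigenSystem-class].
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))
#' @rdname eigenValues
#' @export
setMethod("eigenValues", "EigenSystem", function(object) object@values)

#' Eigenvector accessor
#'
#' @param object an [EigenSystem-class].
#' @param which eigenvector index 1..3 (descending eigenvalue order); if
#'   missing, the full 5D array.
#' @return a \code{c(dim, 3)} array of vector components, or the full array.
#' @export
setGeneric("eigenVectors",
           function(object, which) standardGeneric("eigenVectors"))
#' @rdname eigenVectors
#' @export
setMethod("eigenVectors", "EigenSystem", function(object, which) {
  if (missing(which)) return(object@vectors)
  v <- object@vectors[, , , , which, drop = FALSE]
  dim(v) <- dim(v)[1:4]
  v
})

#' Angle map accessor
#' @param object an [AngleMaps-class].
#' @param which one of "ha", "ta", "se", "sa".
#' @export
setGeneric("angleMap", function(object, which) standardGeneric("angleMap"))
#' @rdname angleMap
#' @export
setMethod("angleMap", "AngleMaps", function(object, which = "ha") {
  slot(object, match.arg(which, c("ha", "ta", "se", "sa")))
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:",
      sprintf("%.2f x %.2f x %.2f mm slab at %.2f um", object@blockExtent[1],
              object@blockExtent[2], object@blockExtent[3],
              object@gridResolution), "\n")
  cat(sprintf("  cells %g x %g x %g um, sheetlets %g deep; HA %g..%g deg, TA %g deg\n",
              object@cellLength, object@cellWidth, object@cellThickness,
              object@sheetletDepth, object@haRange[1], object@haRange[2],
              object@ta))
  cat(sprintf("  intensities S_intra = %g, S_extra = %g\n",
              object@sIntra, object@sExtra))
})

setMethod("show", "LabelledVolume", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("LabelledVolume: %d x %d x %d voxels at %.2f um; %.1f%% intracellular\n",
              d[1], d[2], d[3], object@voxelSize,
              100 * mean(object@occupancy)))
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object@elements)
  cat(sprintf("TensorField (%s): %d x %d x %d voxels at %.2f um, %d undefined\n",
              object@provenance, d[1], d[2], d[3], object@voxelSize,
              sum(is.na(object@elements[, , , 1]))))
})

setMethod("show", "EigenSystem", function(object) {
  d <- dim(object@values)
  cat(sprintf("EigenSystem: %d x %d x %d voxels, %d degenerate\n",
              d[1], d[2], d[3], sum(object@degenerate, na.rm = TRUE)))
})

setMethod("show", "FrameField", function(object) {
  d <- dim(object@depth)
  cat(sprintf("FrameField: %d x %d x %d voxels, depth defined in %d\n",
              d[1], d[2], d[3], sum(!is.na(object@depth))))
})

setMethod("show", "AngleMaps", function(object) {
  d <- dim(object@ha)
  cat(sprintf("AngleMaps: %d x %d x %d voxels; HA defined in %d\n",
              d[1], d[2], d[3], sum(!is.na(object@ha))))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("Bland-Altman agreement over %d voxels: %.2f deg +/- %.2f (LoA %.2f .. %.2f)\n",
              object@n, object@bias, 1.96 * object@sdDiff, object@loa[1],
              object@loa[2]))
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank: 6 lognormal quadrature filters, rho0 = %.4f rad/sample, %g octaves, %d^3 kernels\n",
              object@centreFreq, object@bandwidth, object@size))
})

setMethod("show", "TrackSet", function(object) {
  len <- vapply(object@tracks, function(t)
    sum(sqrt(rowSums(diff(t)^2))), numeric(1))
  cat(sprintf("TrackSet: %d tracks, mean length %.2f mm\n",
              length(object@tracks),
              if (length(len)) mean(len) else NA_real_))
})

setMethod("show", "DwiProtocol", function(object) {
  cat(sprintf("DwiProtocol: b = %g s/mm^2, %d directions, %d b0 volumes\n",
              object@bValue, nrow(object@directions), object@nB0))
})
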
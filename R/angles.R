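# Helix, transverse and sheet angle maps in local cardiac frames.

# Components of a vector field in the local frame; each input is a
# c(dim, 3) array.
#' @noRd
.frameComponents <- function(v, frames) {
  dot <- function(axes) {
    .comp4(v, 1) * .comp4(axes, 1) + .comp4(v, 2) * .comp4(axes, 2) +
      .comp4(v, 3) * .comp4(axes, 3)
  }
  list(r = dot(frames@radial), c = dot(frames@circumferential),
       l = dot(frames@longitudinal))
}

#' Angle maps from per-voxel orientation vectors
#'
#' Computes the four cardiac angles from a cell-axis vector field and an
#' optional sheet-associated vector field, in the local (radial,
#' circumferential, longitudinal) frames:
#' \itemize{
#'   \item HA: signed angle between the cell vector's projection onto the
#'     circumferential-longitudinal (tangential) plane and the short-axis
#'     plane; positive toward +longitudinal.
#'   \item TA: signed angle between the cell vector's projection onto the
#'     short-axis plane and the circumferential axis; positive toward
#'     +radial.
#'   \item SE: signed angle between the sheet vector's projection onto the
#'     radial-longitudinal plane and the short-axis plane.
#'   \item SA: signed angle between the sheet vector's short-axis
#'     projection and the radial axis.
#' }
#' All angles are folded to (-90, 90]: orientations are axial, so the maps
#' are invariant to eigenvector sign flips.
#'
#' @param cellVectors \code{c(dim, 3)} array of cell long-axis vectors.
#' @param frames a [FrameField-class] on the same grid.
#' @param sheetVectors optional \code{c(dim, 3)} array of sheet-associated
#'   vectors.
#' @return An [AngleMaps-class].
#' @export
anglesFromVectors <- function(cellVectors, frames, sheetVectors = NULL) {
  stopifnot(is(frames, "FrameField"))
  d <- dim(cellVectors)[1:3]
  comp <- .frameComponents(cellVectors, frames)
  planar <- function(num, den) {
    a <- .foldAxial(atan2(num, den) * 180 / pi)
    # undefined when the projection onto the relevant plane vanishes
    a[is.na(num) | (abs(num) < 1e-12 & abs(den) < 1e-12)] <- NA_real_
    a
  }
  ha <- planar(comp$l, comp$c)
  ta <- planar(comp$r, comp$c)
  se <- array(NA_real_, d); sa <- array(NA_real_, d)
  if (!is.null(sheetVectors)) {
    sc <- .frameComponents(sheetVectors, frames)
    se <- planar(sc$l, sc$r)
    sa <- planar(sc$c, sc$r)
  }
  new("AngleMaps", ha = ha, ta = ta, se = se, sa = sa,
      voxelSize = frames@voxelSize)
}

#' Angle maps from an eigensystem
#'
#' Selects the modality-appropriate eigenvectors and delegates to
#' [anglesFromVectors()]. For diffusion tensors the cell axis is v1 and the
#' sheet-normal-associated vector v3; for structure tensors the cell axis
#' is v3 and the sheet vector v2 (3.6 um data) or v1 (1.1 um data).
#'
#' @param es an [EigenSystem-class].
#' @param frames a [FrameField-class] on the same grid.
#' @param cellVector eigenvector index for the cell long-axis ("v1".."v3").
#' @param sheetVector eigenvector index for the sheet-associated vector, or
#'   NULL to skip SE/SA.
#' @return An [AngleMaps-class].
#' @export
computeAngles <- function(es, frames, cellVector = c("v3", "v1", "v2"),
                          sheetVector = "v2") {
  stopifnot(is(es, "EigenSystem"))
  cellVector <- match.arg(cellVector)
  sel <- function(tag) as.integer(substring(tag, 2))
  cv <- eigenVectors(es, sel(cellVector))
  sv <- if (is.null(sheetVector)) NULL else
    eigenVectors(es, sel(match.arg(sheetVector, c("v1", "v2", "v3"))))
  anglesFromVectors(cv, frames, sv)
}

#' Bland-Altman agreement between two angle maps
#'
#' Differences are wrapped to (-90, 90] before statistics because the
#' angles are axial: +89 deg and -89 deg describe nearly identical
#' orientations, so their difference is -2 deg, not 178 deg. Reports the
#' mean difference (bias) and limits of agreement (bias +/- 1.96 SD),
#' together with the per-voxel (mean, difference) pairs for scatter plots.
#'
#' @param a,b 3D numeric arrays of angles in degrees, or
#'   [AngleMaps-class] objects (then \code{which} selects the map).
#' @param mask optional logical array restricting the comparison.
#' @param which map selector when a/b are [AngleMaps-class].
#' @return An [AgreementReport-class].
#' @export
blandAltman <- function(a, b, mask = NULL, which = "ha") {
  if (is(a, "AngleMaps")) a <- angleMap(a, which)
  if (is(b, "AngleMaps")) b <- angleMap(b, which)
  stopifnot(identical(dim(a), dim(b)))
  keep <- !is.na(a) & !is.na(b)
  if (!is.null(mask)) keep <- keep & mask
  if (!any(keep)) stop("no voxels to compare", call. = FALSE)
  da <- a[keep]; db <- b[keep]
  diffs <- ((da - db + 90) %% 180) - 90
  diffs[diffs == -90] <- 90
  m <- (da + db) / 2
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  if (is.na(s)) s <- 0
  new("AgreementReport", bias = bias, sdDiff = s,
      loa = c(bias - 1.96 * s, bias + 1.96 * s),
      differences = diffs, means = m, n = as.integer(sum(keep)))
}
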
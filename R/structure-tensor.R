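# Structure tensor estimation, smoothing, downsampling and eigen-analysis.

#' Compute the structure tensor field of a volume
#'
#' Convolves the volume with the six complex quadrature kernels and
#' assembles per voxel
#' \deqn{T = \sum_k \lVert q_k\rVert \left(n_k n_k^T - I/(m-1)\right)}
#' with \eqn{m = 3} and \eqn{\lVert q_k\rVert} the voxel-wise complex
#' magnitude of the k-th filter response. The \code{"classical"} variant
#' uses the dual-tensor weighting \eqn{(5/4)\, n_k n_k^T - I/4} instead;
#' for this direction set the two differ only by a multiple of the identity
#' (plus a global scale), so eigenvectors and their ordering agree.
#' Eigenvalue order: v1 (largest) is the direction of strongest intensity
#' variation; the cell long-axis of striated tissue is v3.
#'
#' Convolution uses FFTs with edge padding (default replicate/nearest-edge;
#' mirror padding is available but reflects structures touching the faces,
#' which biases boundary-layer orientations).
#'
#' @param volume 3D numeric array (isotropic voxels).
#' @param bank a [designBank()] filter bank.
#' @param voxelSize isotropic voxel size, micrometres.
#' @param variant "printed" (default) or "classical".
#' @param pad "replicate" or "symmetric" edge handling.
#' @return A [TensorField-class] with provenance "structure".
#' @export
computeStructureTensor <- function(volume, bank, voxelSize = 1,
                                   variant = c("printed", "classical"),
                                   pad = c("replicate", "symmetric")) {
  variant <- match.arg(variant)
  pad <- match.arg(pad)
  stopifnot(is(bank, "FilterBank"))
  if (length(voxelSize) != 1L)
    stop("anisotropic voxel sizes are not supported", call. = FALSE)
  d <- dim(volume)
  if (any(d < bank@size))
    stop("volume must be at least the kernel size per side", call. = FALSE)
  p <- (bank@size - 1L) %/% 2L
  vp <- .padVolume(volume, p, pad)
  vhat <- stats::fft(vp)
  el <- array(0, c(d, 6))
  diagTerm <- if (variant == "printed") 0.5 else 0.25
  dirScale <- if (variant == "printed") 1 else 1.25
  for (k in 1:6) {
    q <- Mod(.fftConvolve(vhat, bank@kernels[, , , k], dim(vp), p, d))
    nd <- bank@directions[k, ]
    el[, , , 1] <- el[, , , 1] + q * (dirScale * nd[1]^2 - diagTerm)
    el[, , , 3] <- el[, , , 3] + q * (dirScale * nd[2]^2 - diagTerm)
    el[, , , 6] <- el[, , , 6] + q * (dirScale * nd[3]^2 - diagTerm)
    el[, , , 2] <- el[, , , 2] + q * dirScale * nd[1] * nd[2]
    el[, , , 4] <- el[, , , 4] + q * dirScale * nd[1] * nd[3]
    el[, , , 5] <- el[, , , 5] + q * dirScale * nd[2] * nd[3]
  }
  .tensorField(el, voxelSize, "structure")
}

#' Smooth a tensor field element-wise with a truncated Gaussian
#'
#' Each of the six unique elements is convolved independently with a
#' normalised Gaussian kernel truncated to \code{size}^3 support
#' (sigma defaults to (size - 1) / 4 voxels). A constant field is left
#' unchanged and the kernel weights sum to one.
#'
#' @param tf a [TensorField-class].
#' @param size odd kernel size (default 7).
#' @param sigma Gaussian standard deviation in voxels.
#' @param pad edge handling, as in [computeStructureTensor()].
#' @return The smoothed [TensorField-class].
#' @export
smoothTensors <- function(tf, size = 7L, sigma = (size - 1) / 4,
                          pad = c("replicate", "symmetric")) {
  stopifnot(is(tf, "TensorField"))
  size <- .assertOddSize(size)
  pad <- match.arg(pad)
  h <- (size - 1L) %/% 2L
  g <- stats::dnorm(seq(-h, h), 0, sigma)
  g <- g / sum(g)
  kern <- outer(outer(g, g), g)
  dim(kern) <- c(size, size, size)
  el <- tf@elements
  for (j in 1:6) el[, , , j] <- .convolveReal(.comp4(el, j), kern, pad)
  tf@elements <- el
  tf
}

#' Block-downsample a tensor field
#'
#' Non-overlapping block means of each tensor element, with blocks anchored
#' at the volume origin. An optional exclusion mask (e.g. segmented vessels)
#' removes voxels from every block mean; fully excluded blocks become NA.
#' Trailing blocks that do not fill the factor are dropped by default;
#' \code{partial = TRUE} keeps them (their mean is over the available
#' voxels), which lets the coarse grid reach the far faces of the volume.
#'
#' @param tf a [TensorField-class].
#' @param factor integer block edge in voxels (default 28, mapping 3.6 um
#'   data onto a nominal 100 um grid).
#' @param exclude optional [VesselMask-class] or logical array of voxels to
#'   exclude.
#' @param partial keep trailing partial blocks.
#' @return A coarse [TensorField-class]; voxel size is scaled by
#'   \code{factor}.
#' @export
downsampleTensors <- function(tf, factor = 28L, exclude = NULL,
                              partial = FALSE) {
  stopifnot(is(tf, "TensorField"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  d <- dim(tf@elements)[1:3]
  if (any(factor > d))
    stop("factor larger than a volume dimension", call. = FALSE)
  keep <- NULL
  if (!is.null(exclude)) {
    m <- if (is(exclude, "VesselMask")) exclude@mask else exclude
    if (!identical(dim(m), d))
      stop("exclusion mask shape must match the tensor field", call. = FALSE)
    keep <- !m
  }
  first <- .blockMean(.comp4(tf@elements, 1), factor, keep, partial)
  out <- array(NA_real_, c(dim(first), 6))
  out[, , , 1] <- first
  for (j in 2:6)
    out[, , , j] <- .blockMean(.comp4(tf@elements, j), factor, keep,
                               partial)
  .tensorField(out, tf@voxelSize * factor, tf@provenance)
}

#' Eigendecomposition of a tensor field
#'
#' Eigenvalues sorted descending; eigenvector signs canonicalised so the
#' first non-zero component is positive. Voxels whose adjacent eigenvalues
#' differ by less than \code{degTol} relative to the largest magnitude are
#' flagged degenerate. Non-finite tensors yield NA voxels.
#'
#' @param tf a [TensorField-class].
#' @param degTol relative tolerance for the degeneracy flag.
#' @return An [EigenSystem-class].
#' @export
eigenDecompose <- function(tf, degTol = 1e-6) {
  stopifnot(is(tf, "TensorField"))
  d <- dim(tf@elements)[1:3]
  vals <- array(NA_real_, c(d, 3))
  vecs <- array(NA_real_, c(d, 3, 3))
  degen <- array(FALSE, d)
  n <- prod(d)
  el <- matrix(tf@elements, n, 6)
  for (i in seq_len(n)) {
    e6 <- el[i, ]
    if (any(!is.finite(e6))) { degen[i] <- NA; next }
    es <- eigen(.elementsToMatrix(e6), symmetric = TRUE)
    ijk <- arrayInd(i, d)
    vals[ijk[1], ijk[2], ijk[3], ] <- es$values
    V <- es$vectors
    for (k in 1:3) {
      nz <- which(abs(V[, k]) > 1e-12)[1]
      if (!is.na(nz) && V[nz, k] < 0) V[, k] <- -V[, k]
    }
    vecs[ijk[1], ijk[2], ijk[3], , ] <- V
    scale <- max(abs(es$values), 1e-300)
    degen[i] <- any(abs(diff(es$values)) / scale < degTol)
  }
  new("EigenSystem", values = vals, vectors = vecs, degenerate = degen,
      voxelSize = tf@voxelSize)
}

#' Eigenvalue ratio maps
#'
#' Per-voxel ratios lambda2/lambda1 and lambda3/lambda2, both in [0, 1]
#' for a positive-semidefinite field with descending eigenvalues. Voxels
#' with lambda1 <= 0 (or lambda2 <= 0 for the second ratio) are NA.
#'
#' @param es an [EigenSystem-class].
#' @return list with arrays \code{r21} and \code{r32}.
#' @export
eigenvalueRatios <- function(es) {
  stopifnot(is(es, "EigenSystem"))
  d <- dim(es@values)[1:3]
  grab <- function(k) array(es@values[, , , k, drop = FALSE], d)
  l1 <- grab(1); l2 <- grab(2); l3 <- grab(3)
  r21 <- ifelse(!is.na(l1) & l1 > 0, l2 / l1, NA_real_)
  r32 <- ifelse(!is.na(l2) & l2 > 0, l3 / l2, NA_real_)
  list(r21 = r21, r32 = r32)
}
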
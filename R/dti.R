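# Diffusion tensor fitting, ADC, heart segmentation and rigid alignment.

# Design matrix of the log-linear tensor model: columns
# (ln s0, xx, xy, yy, xz, yz, zz) against -b weightings.
#' @noRd
.dtDesign <- function(protocol) {
  m <- nrow(protocol@directions)
  G <- protocol@directions
  bRows <- cbind(G[, 1]^2, 2 * G[, 1] * G[, 2], G[, 2]^2,
                 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3], G[, 3]^2)
  X <- rbind(
    cbind(1, matrix(0, protocol@nB0, 6)),
    cbind(1, -protocol@bValue * bRows))
  X
}

#' Fit diffusion tensors by nonlinear least squares
#'
#' Per voxel, minimises \eqn{\sum_i (S_i - s_0 \exp(-b\, g_i^T D g_i))^2}
#' over \eqn{s_0} and the six tensor elements, initialised from the
#' log-linear least-squares solution (signals floored at a small positive
#' value before the logarithm). No positivity constraint is imposed on D;
#' negative eigenvalues are flagged downstream rather than repaired. In the
#' noiseless case the log-linear initialisation already solves the
#' consistent system exactly and the refinement leaves it unchanged.
#'
#' @param dwi 4D array with volumes along the fourth dimension: the first
#'   \code{protocol@nB0} are non-diffusion-weighted.
#' @param protocol a [DwiProtocol-class].
#' @param voxelSize isotropic voxel size, micrometres.
#' @param maxit maximum Levenberg-Marquardt iterations.
#' @return list with \code{tensors} (a [TensorField-class], provenance
#'   "diffusion"), \code{s0} (array), \code{converged} (logical array;
#'   NA for undefined voxels).
#' @export
fitDiffusionTensor <- function(dwi, protocol, voxelSize = 100, maxit = 50L) {
  stopifnot(is(protocol, "DwiProtocol"))
  d <- dim(dwi)
  nVol <- protocol@nB0 + nrow(protocol@directions)
  if (length(d) != 4L || d[4] != nVol)
    stop("dwi must have nB0 + nDirections volumes", call. = FALSE)
  if (nVol < 7L || protocol@nB0 < 1L)
    stop("at least one b0 and six weighted volumes are required",
         call. = FALSE)
  X <- .dtDesign(protocol)
  n <- prod(d[1:3])
  S <- matrix(dwi, n, nVol)
  el <- array(NA_real_, c(d[1:3], 6))
  elM <- matrix(NA_real_, n, 6)
  s0 <- rep(NA_real_, n)
  conv <- rep(NA, n)
  bDesign <- X[, -1, drop = FALSE]
  for (i in seq_len(n)) {
    y <- S[i, ]
    if (anyNA(y) || all(y == 0)) next
    ly <- log(pmax(y, 1e-12 * max(y)))
    beta <- stats::lm.fit(X, ly)$coefficients
    resFun <- function(p) {
      y - exp(p[1]) * exp(drop(bDesign %*% p[-1]))
    }
    fit <- minpack.lm::nls.lm(par = beta, fn = resFun,
                              control = minpack.lm::nls.lm.control(
                                maxiter = maxit))
    p <- fit$par
    s0[i] <- exp(p[1])
    elM[i, ] <- p[2:7]
    conv[i] <- fit$info %in% c(1, 2, 3, 4)
  }
  el[, , , 1] <- array(elM[, 1], d[1:3]); el[, , , 2] <- array(elM[, 2], d[1:3])
  el[, , , 3] <- array(elM[, 3], d[1:3]); el[, , , 4] <- array(elM[, 4], d[1:3])
  el[, , , 5] <- array(elM[, 5], d[1:3]); el[, , , 6] <- array(elM[, 6], d[1:3])
  list(tensors = .tensorField(el, voxelSize, "diffusion"),
       s0 = array(s0, d[1:3]),
       converged = array(conv, d[1:3]))
}

#' Mean apparent diffusion coefficient
#'
#' The mean of the three principal eigenvalues, identical to trace(D)/3.
#'
#' @param es an [EigenSystem-class].
#' @return 3D array (NA for undefined voxels).
#' @export
meanADC <- function(es) {
  stopifnot(is(es, "EigenSystem"))
  (.comp4(es@values, 1) + .comp4(es@values, 2) + .comp4(es@values, 3)) / 3
}

#' Segment the heart from non-diffusion-weighted signal and ADC
#'
#' Boolean AND of the two criteria: signal intensity in the mean
#' non-diffusion-weighted image above a fraction of its global maximum
#' (default 20 percent) and mean ADC below a ceiling (default
#' 1.8e-3 mm^2/s).
#'
#' @param nonDwMean 3D array, mean of the b = 0 volumes.
#' @param adc 3D array of mean ADC values, same shape.
#' @param intensityFraction fraction of the global maximum.
#' @param adcMax ADC ceiling in mm^2/s.
#' @return logical 3D array.
#' @export
segmentHeart <- function(nonDwMean, adc, intensityFraction = 0.2,
                         adcMax = 1.8e-3) {
  stopifnot(identical(dim(nonDwMean), dim(adc)))
  m <- !is.na(nonDwMean) & !is.na(adc) &
    nonDwMean > intensityFraction * max(nonDwMean, na.rm = TRUE) &
    adc < adcMax
  if (!any(m)) warning("heart segmentation is empty")
  m
}

#' Rigid long-axis alignment transform
#'
#' Fits the left-ventricular long axis as the total-least-squares line
#' through the centres of mass of the cavity mask in each short-axis (z)
#' plane, and orients the in-plane axes from a landmark chord: the
#' component of \code{landmarks[2, ] - landmarks[1, ]} orthogonal to the
#' long axis defines +y (anterior-posterior), x completes the right-handed
#' frame (lateral-septal), and the long axis maps to +z (apico-basal). The
#' translation carries the fitted axis through the volume centre.
#'
#' @param cavityMask logical 3D array, non-empty in at least 3 z-slices.
#' @param landmarks 2 x 3 matrix of points in mm (rows: anterior then
#'   posterior LV/RV intersection).
#' @param voxelSizeMm isotropic voxel size in millimetres.
#' @return A [RigidTransform-class].
#' @export
longAxisTransform <- function(cavityMask, landmarks, voxelSizeMm = 1) {
  d <- dim(cavityMask)
  zs <- which(apply(cavityMask, 3, any))
  if (length(zs) < 3L)
    stop("cavity mask must be non-empty in at least 3 slices", call. = FALSE)
  cent <- t(vapply(zs, function(z) {
    idx <- which(cavityMask[, , z], arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]), z)
  }, numeric(3))) * voxelSizeMm
  p0 <- colMeans(cent)
  ax <- stats::prcomp(cent)$rotation[, 1]
  if (ax[3] < 0) ax <- -ax
  chord <- landmarks[2, ] - landmarks[1, ]
  yAxis <- chord - sum(chord * ax) * ax
  ny <- sqrt(sum(yAxis^2))
  if (ny < 1e-9)
    stop("landmark chord is parallel to the long axis", call. = FALSE)
  yAxis <- yAxis / ny
  xAxis <- c(yAxis[2] * ax[3] - yAxis[3] * ax[2],
             yAxis[3] * ax[1] - yAxis[1] * ax[3],
             yAxis[1] * ax[2] - yAxis[2] * ax[1])
  R <- rbind(xAxis, yAxis, ax)
  dimnames(R) <- NULL
  centreMm <- (d / 2) * voxelSizeMm
  new("RigidTransform", rotation = R,
      translation = as.numeric(centreMm - R %*% p0))
}

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based). Out-of-range points yield NA.
#' @noRd
.trilinear <- function(a, x, y, z) {
  d <- dim(a)
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3] &
    !is.na(x)
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  x <- pmin(x[ok], d[1] - 1e-9); y <- pmin(y[ok], d[2] - 1e-9)
  z <- pmin(z[ok], d[3] - 1e-9)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  g <- function(i, j, k) a[cbind(i, j, k)]
  out[ok] <-
    g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    g(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    g(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    g(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    g(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    g(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    g(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out
}

# Catmull-Rom cubic weights for fractional offset t in [0,1).
#' @noRd
.cubicWeights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind(-0.5 * t3 + t2 - 0.5 * t,
        1.5 * t3 - 2.5 * t2 + 1,
        -1.5 * t3 + 2 * t2 + 0.5 * t,
        0.5 * t3 - 0.5 * t2)
}

#' @noRd
.cubicInterp <- function(a, x, y, z) {
  d <- dim(a)
  ok <- x >= 2 & x <= d[1] - 1 & y >= 2 & y <= d[2] - 1 &
    z >= 2 & z <= d[3] - 1 & !is.na(x)
  out <- .trilinear(a, x, y, z)   # fall back near the border
  if (!any(ok)) return(out)
  xo <- x[ok]; yo <- y[ok]; zo <- z[ok]
  x0 <- floor(xo); y0 <- floor(yo); z0 <- floor(zo)
  wx <- .cubicWeights(xo - x0); wy <- .cubicWeights(yo - y0)
  wz <- .cubicWeights(zo - z0)
  acc <- numeric(sum(ok))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    xi <- pmin(pmax(x0 + i - 2, 1), d[1])
    yj <- pmin(pmax(y0 + j - 2, 1), d[2])
    zk <- pmin(pmax(z0 + k - 2, 1), d[3])
    acc <- acc + wx[, i] * wy[, j] * wz[, k] * a[cbind(xi, yj, zk)]
  }
  out[ok] <- acc
  out
}

#' Apply a rigid transform to a scalar, vector or tensor field
#'
#' Resamples on the input grid: for each output voxel centre p (mm), the
#' source location is \eqn{R^{-1}(p - t)} and the input is sampled there
#' with the chosen interpolation; locations outside the input yield NA.
#' Tensor fields are additionally conjugated \eqn{T \to R T R^T}; vector
#' fields (arrays with a trailing dimension of 3) are rotated.
#'
#' @param field 3D array, \code{c(dim, 3)} vector array, or a
#'   [TensorField-class].
#' @param M a [RigidTransform-class].
#' @param interpolation "cubic" (default), "linear" or "nearest".
#' @param voxelSizeMm voxel size in mm (defaults to the tensor field's
#'   metadata, interpreted as micrometres and converted).
#' @return The transformed field of the same type.
#' @export
applyRigid <- function(field, M,
                       interpolation = c("cubic", "linear", "nearest"),
                       voxelSizeMm = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(is(M, "RigidTransform"))
  isTF <- is(field, "TensorField")
  arr <- if (isTF) field@elements else field
  if (is.null(voxelSizeMm))
    voxelSizeMm <- if (isTF) field@voxelSize / 1000 else 1
  d <- dim(arr)
  sd3 <- d[1:3]
  grid <- as.matrix(expand.grid(x = seq_len(sd3[1]), y = seq_len(sd3[2]),
                                z = seq_len(sd3[3])))
  pOut <- (grid - 0.5) * voxelSizeMm
  pSrc <- t(crossprod(M@rotation, t(pOut) - M@translation))
  src <- pSrc / voxelSizeMm + 0.5
  sample1 <- function(a) {
    v <- switch(interpolation,
      nearest = {
        xi <- round(src[, 1]); yi <- round(src[, 2]); zi <- round(src[, 3])
        ok <- xi >= 1 & xi <= sd3[1] & yi >= 1 & yi <= sd3[2] &
          zi >= 1 & zi <= sd3[3]
        out <- rep(NA_real_, nrow(src))
        out[ok] <- a[cbind(xi[ok], yi[ok], zi[ok])]
        out
      },
      linear = .trilinear(a, src[, 1], src[, 2], src[, 3]),
      cubic = .cubicInterp(a, src[, 1], src[, 2], src[, 3]))
    array(v, sd3)
  }
  if (length(d) == 3L) {
    out <- sample1(arr)
    return(out)
  }
  nc <- d[4]
  out <- array(NA_real_, d)
  for (j in seq_len(nc)) out[, , , j] <- sample1(arr[, , , j])
  R <- M@rotation
  if (isTF) {
    # conjugate each tensor: T -> R T R'
    flat <- matrix(out, prod(sd3), 6)
    for (i in seq_len(nrow(flat))) {
      if (anyNA(flat[i, ])) next
      Tm <- .elementsToMatrix(flat[i, ])
      flat[i, ] <- .matrixToElements(R %*% Tm %*% t(R))
    }
    field@elements <- array(flat, d)
    return(field)
  }
  if (nc == 3L) {
    flat <- matrix(out, prod(sd3), 3)
    flat <- flat %*% t(R)
    return(array(flat, d))
  }
  out
}
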
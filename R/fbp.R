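# Parallel-beam forward projection and filtered back-projection.

# Bilinear sampling of a matrix at fractional (row, col) coordinates.
# Out-of-range samples are 0 (objects are assumed inside the field of view).
#' @noRd
.bilinear <- function(img, r, cc) {
  d <- dim(img)
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  val <- numeric(length(r))
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  val <- get(r0, c0) * (1 - fr) * (1 - fc) +
    get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc +
    get(r0 + 1, c0 + 1) * fr * fc
  val
}

#' Parallel-beam forward projection (Radon transform) of a 2D image
#'
#' Line integrals along rays perpendicular to the detector for each angle,
#' with bilinear sampling on an implicit grid centred on the image. Used as
#' the geometric oracle for [fbpReconstruct()] round trips and to build
#' synthetic sinograms.
#'
#' @param img square 2D matrix.
#' @param angles projection angles in degrees.
#' @return matrix \code{c(nrow(img), length(angles))}; detector sample
#'   spacing equals the pixel spacing.
#' @export
forwardProject <- function(img, angles) {
  n <- nrow(img)
  stopifnot(ncol(img) == n)
  ctr <- (n + 1) / 2
  t <- seq_len(n) - ctr
  s <- t
  sino <- matrix(0, n, length(angles))
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    # ray for detector position t runs along direction (-sin, cos)
    X <- outer(t * cos(th), -s * sin(th), "+") + ctr
    Y <- outer(t * sin(th), s * cos(th), "+") + ctr
    sino[, a] <- rowSums(matrix(.bilinear(img, X, Y), n, n))
  }
  sino
}

# Ramp (Ram-Lak) filter one sinogram: the discrete spatial-domain kernel
# h(0) = 1/4, h(odd n) = -1/(pi n)^2, h(even n) = 0, applied by
# zero-padded FFT. The discrete kernel avoids the DC bias of a naive
# frequency ramp.
#' @noRd
.rampFilter <- function(sino) {
  n <- nrow(sino)
  np <- 2^ceiling(log2(2 * n))
  k <- c(0:(np / 2), -(np / 2 - 1):-1)
  h <- numeric(np)
  h[1] <- 0.25
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd])^2
  H <- Re(stats::fft(h))   # DTFT approximates |f|, f in cycles/sample
  out <- matrix(0, n, ncol(sino))
  for (a in seq_len(ncol(sino))) {
    p <- c(sino[, a], rep(0, np - n))
    q <- Re(stats::fft(stats::fft(p) * H, inverse = TRUE) / np)
    out[, a] <- q[seq_len(n)]
  }
  out
}

#' Filtered back-projection of a parallel-beam sinogram stack
#'
#' Slice-wise ramp-filtered back-projection. The input follows the
#' [ProjectionStack-class] layout: \code{sinogram[u, v, angle]} where u is
#' the in-slice detector coordinate and v indexes slices along the rotation
#' axis. The output voxel size equals the detector pixel size.
#'
#' @param sinogram 3D array \code{c(nu, nv, nAngles)} (a 2D
#'   \code{c(nu, nAngles)} sinogram is treated as one slice).
#' @param angles projection angles in degrees, distinct, in [0, 180).
#' @param pixelSize detector pixel size in micrometres.
#' @return list with \code{volume} (\code{c(nu, nu, nv)} array) and
#'   \code{voxelSize}.
#' @export
fbpReconstruct <- function(sinogram, angles, pixelSize = 1) {
  if (length(dim(sinogram)) == 2L)
    sinogram <- array(sinogram, c(dim(sinogram)[1], 1L, dim(sinogram)[2]))
  d <- dim(sinogram)
  if (length(angles) != d[3])
    stop("one angle per projection required", call. = FALSE)
  if (anyDuplicated(angles)) stop("duplicate angles", call. = FALSE)
  if (length(angles) < 2L || diff(range(angles)) <= 0 ||
      any(angles < 0 | angles >= 180))
    stop("need at least two distinct angles in [0, 180)", call. = FALSE)
  n <- d[1]
  ctr <- (n + 1) / 2
  xy <- seq_len(n) - ctr
  vol <- array(0, c(n, n, d[2]))
  dTheta <- pi / length(angles)
  for (v in seq_len(d[2])) {
    filt <- .rampFilter(sinogram[, v, , drop = FALSE][, 1, ])
    img <- matrix(0, n, n)
    for (a in seq_along(angles)) {
      th <- angles[a] * pi / 180
      tpos <- outer(xy * cos(th), xy * sin(th), "+") + ctr
      t0 <- floor(tpos); ft <- tpos - t0
      p <- filt[, a]
      pa <- function(i) {
        ok <- i >= 1 & i <= n
        out <- numeric(length(i)); out[ok] <- p[i[ok]]; out
      }
      img <- img + matrix(pa(t0) * (1 - ft) + pa(t0 + 1) * ft, n, n)
    }
    vol[, , v] <- img * dTheta
  }
  list(volume = vol, voxelSize = pixelSize)
}
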
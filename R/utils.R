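# Internal array helpers shared across modules.

#' @keywords internal
#' @noRd
.assertOddSize <- function(size) {
  if (length(size) != 1L || size < 1L || size %% 2L == 0L)
    stop("kernel size must be a single odd positive integer", call. = FALSE)
  as.integer(size)
}

# Pad a 3D array by `p` voxels on every side.
# mode "replicate" repeats the edge sample, "symmetric" mirrors without
# repeating the edge, "zero" pads with zeros.
#' @noRd
.padVolume <- function(a, p, mode = c("replicate", "symmetric", "zero")) {
  mode <- match.arg(mode)
  d <- dim(a)
  if (p == 0L) return(a)
  idx <- lapply(d, function(n) {
    switch(mode,
      replicate = c(rep(1L, p), seq_len(n), rep(n, p)),
      symmetric = {
        if (p > n) stop("symmetric padding wider than the array", call. = FALSE)
        c(p:1, seq_len(n), n:(n - p + 1L))
      },
      zero = seq_len(n))
  })
  if (mode == "zero") {
    out <- array(0, d + 2L * p)
    out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- a
    out
  } else {
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
}

# Circular FFT convolution of a (possibly complex) padded volume with a small
# centred kernel; the caller supplies fft(volume) so the transform is reused
# across the filter bank. Returns the valid region of size `dorig`.
#' @noRd
.fftConvolve <- function(vhat, kern, dpad, p, dorig) {
  s <- dim(kern)[1]
  h <- (s - 1L) %/% 2L
  kp <- array(complex(real = 0), dpad)
  kp[seq_len(s), seq_len(s), seq_len(s)] <- kern
  # rotate so the kernel centre sits at index (1,1,1)
  for (ax in 1:3) {
    idx <- c((h + 1L):dpad[ax], seq_len(h))
    kp <- switch(ax, kp[idx, , , drop = FALSE], kp[, idx, , drop = FALSE],
                 kp[, , idx, drop = FALSE])
  }
  r <- stats::fft(vhat * stats::fft(kp), inverse = TRUE) / prod(dpad)
  r[p + seq_len(dorig[1]), p + seq_len(dorig[2]), p + seq_len(dorig[3]),
    drop = FALSE]
}

# Same-size convolution of a real 3D array with a small centred real kernel,
# with the package's edge handling.
#' @noRd
.convolveReal <- function(a, kern, pad = "replicate") {
  s <- dim(kern)[1]
  p <- (s - 1L) %/% 2L
  ap <- .padVolume(a, p, pad)
  Re(.fftConvolve(stats::fft(ap), kern, dim(ap), p, dim(a)))
}

# Non-overlapping block means of a 3D array, anchored at the array origin.
# Masked-out voxels (mask FALSE) and NAs are excluded from each block's mean;
# fully excluded blocks yield NA. With partial = TRUE trailing blocks that do
# not fill the factor are kept, otherwise they are dropped.
#' @noRd
.blockMean <- function(a, f, mask = NULL, partial = FALSE) {
  d <- dim(a)
  if (!partial && any(f > d))
    stop("block factor exceeds a volume dimension", call. = FALSE)
  if (!is.null(mask)) a[!mask] <- NA_real_
  nb <- if (partial) ceiling(d / f) else floor(d / f)
  full <- nb * f
  A <- array(NA_real_, full)
  keep <- pmin(d, full)
  A[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3])] <-
    a[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3])]
  dim(A) <- c(f, nb[1], f, nb[2], f, nb[3])
  A <- aperm(A, c(1, 3, 5, 2, 4, 6))
  dim(A) <- c(f^3, prod(nb))
  out <- colMeans(A, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  array(out, nb)
}

# Count of contributing voxels per block, matching .blockMean's layout.
#' @noRd
.blockCount <- function(d, f, mask, partial = FALSE) {
  cnt <- array(1, d)
  cnt[!mask] <- 0
  nb <- if (partial) ceiling(d / f) else floor(d / f)
  full <- nb * f
  A <- array(0, full)
  keep <- pmin(d, full)
  A[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3])] <-
    cnt[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3])]
  dim(A) <- c(f, nb[1], f, nb[2], f, nb[3])
  A <- aperm(A, c(1, 3, 5, 2, 4, 6))
  dim(A) <- c(f^3, prod(nb))
  array(colSums(A), nb)
}

# 6-element symmetric tensor storage order used throughout:
# (xx, xy, yy, xz, yz, zz) -- NIfTI lower-triangular order.
#' @noRd
.elementsToMatrix <- function(e6) {
  matrix(c(e6[1], e6[2], e6[4],
           e6[2], e6[3], e6[5],
           e6[4], e6[5], e6[6]), 3L, 3L)
}

#' @noRd
.matrixToElements <- function(m) {
  c(m[1, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3], m[3, 3])
}

# Fold an angle in degrees to the axial range (-90, 90].
#' @noRd
.foldAxial <- function(a) {
  a <- ((a + 90) %% 180) - 90
  a[!is.na(a) & a == -90] <- 90
  a
}

# Run `expr` with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Voxel-centre coordinates (in micrometres) along one axis.
#' @noRd
.voxelCentres <- function(n, voxelSize) (seq_len(n) - 0.5) * voxelSize

# Slice component k of a c(dim3, m) array without losing singleton
# dimensions.
#' @noRd
.comp4 <- function(a, k) {
  d <- dim(a)
  array(a[, , , k, drop = FALSE], d[1:3])
}
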
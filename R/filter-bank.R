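# Lognormal quadrature filter bank for 3D orientation estimation.

#' Icosahedral half-axis filter directions
#'
#' The six unit vectors through opposite vertex pairs of a regular
#' icosahedron, built from the golden ratio. This is the canonical
#' direction set for six-filter 3D orientation estimation: the outer
#' products of the six axes span the space of symmetric 3x3 tensors
#' isotropically.
#'
#' @return 6 x 3 matrix of unit vectors.
#' @export
quadratureDirections <- function() {
  phi <- (1 + sqrt(5)) / 2
  d <- rbind(c(1, phi, 0), c(1, -phi, 0),
             c(phi, 0, 1), c(phi, 0, -1),
             c(0, 1, phi), c(0, 1, -phi))
  d / sqrt(1 + phi^2)
}

#' Lognormal radial frequency profile
#'
#' \deqn{R(\rho) = \exp(-4 \ln^2(\rho/\rho_0) / (B^2 \ln 2))}
#' which peaks at 1 for \eqn{\rho = \rho_0} and has relative bandwidth B in
#' octaves.
#'
#' @param rho radial frequency (radians/sample).
#' @param rho0 centre frequency.
#' @param bandwidth bandwidth in octaves.
#' @export
lognormalRadial <- function(rho, rho0, bandwidth = 2) {
  r <- exp(-4 * log(rho / rho0)^2 / (bandwidth^2 * log(2)))
  r[rho <= 0] <- 0
  r
}

#' Design a bank of six 3D quadrature filters
#'
#' Each filter is defined in the Fourier domain as the product of the
#' lognormal radial profile and the angular profile
#' \eqn{(n_k \cdot \hat u)^2} on the hemisphere \eqn{n_k \cdot \hat u > 0}
#' (zero on the other half-space). Because the frequency response is real
#' and one-sided, the spatial kernel is complex and its response magnitude
#' is invariant to the local signal phase (lines and edges are treated
#' alike). Kernels are obtained by inverse FFT on a large design grid and
#' truncated (no window) to \code{size}^3 samples.
#'
#' Frequency convention: u, v, w are angular frequencies in radians per
#' sample, so \code{centreFreq} is comparable across kernel sizes.
#'
#' @param centreFreq centre frequency rho0 in radians/sample, in (0, pi).
#'   The reference configuration is \code{pi / (3 * sqrt(2))} with
#'   \code{size = 11}; \code{2 * pi / 3} with \code{size = 7} probes
#'   finer-scale structure.
#' @param bandwidth bandwidth in octaves.
#' @param size spatial kernel size per side (odd).
#' @param designGrid edge of the Fourier design grid.
#' @return A [FilterBank-class].
#' @examples
#' bank <- designBank(pi / (3 * sqrt(2)), 2, 11)
#' bank
#' @export
designBank <- function(centreFreq, bandwidth = 2, size = 11L,
                       designGrid = 64L) {
  size <- .assertOddSize(size)
  if (centreFreq <= 0 || centreFreq >= pi)
    stop("centre frequency must lie in (0, pi) radians/sample",
         call. = FALSE)
  if (centreFreq * size < 2 * pi)
    warning("kernel smaller than one period of the centre frequency")
  N <- as.integer(designGrid)
  om <- 2 * pi * (seq_len(N) - 1) / N
  om[om >= pi] <- om[om >= pi] - 2 * pi
  W1 <- array(om, c(N, N, N))
  W2 <- array(rep(om, each = N), c(N, N, N))
  W3 <- array(rep(om, each = N * N), c(N, N, N))
  rho <- sqrt(W1^2 + W2^2 + W3^2)
  R <- lognormalRadial(rho, centreFreq, bandwidth)
  dirs <- quadratureDirections()
  h <- (size - 1L) %/% 2L
  crop <- c(seq_len(h + 1L), (N - h + 1L):N)   # wrapped spatial origin
  centre <- c((h + 2L):(2L * h + 1L), seq_len(h + 1L))
  kerns <- array(complex(real = 0), c(size, size, size, 6L))
  rhoSafe <- pmax(rho, 1e-300)
  for (k in 1:6) {
    nd <- dirs[k, ]
    cosA <- (W1 * nd[1] + W2 * nd[2] + W3 * nd[3]) / rhoSafe
    Fk <- R * ifelse(cosA > 0, cosA^2, 0)
    sp <- stats::fft(Fk, inverse = TRUE) / N^3
    kk <- sp[crop, crop, crop][centre, centre, centre]
    # truncation re-introduces a small DC component; remove it so the
    # band-pass response to constant volumes is exactly zero
    kerns[, , , k] <- kk - mean(kk)
  }
  new("FilterBank", directions = dirs, centreFreq = centreFreq,
      bandwidth = bandwidth, size = size, kernels = kerns)
}

#' The kernel-size / centre-frequency pairs of the reconstruction sweep
#'
#' Centre frequencies 2pi/3, sqrt(2)pi/3, pi/3, pi/(3 sqrt 2), pi/6 with
#' matched kernel sizes 7, 7, 9, 11, 17.
#'
#' @return data.frame with columns \code{centreFreq} and \code{size}.
#' @export
kernelSweepTable <- function() {
  data.frame(
    centreFreq = c(2 * pi / 3, sqrt(2) * pi / 3, pi / 3, pi / (3 * sqrt(2)),
                   pi / 6),
    size = c(7L, 7L, 9L, 11L, 17L))
}
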
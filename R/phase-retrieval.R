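# Single-distance phase retrieval and projection correction.

#' Flat-field and dark-frame correction
#'
#' Maps every projection frame to \code{(I - dark) / (flat - dark)},
#' clipped below at a small positive floor so downstream logarithms stay
#' finite.
#'
#' @param stack a [ProjectionStack-class]; \code{flat - dark} must be
#'   strictly positive everywhere.
#' @param floor lower clip value.
#' @return The corrected [ProjectionStack-class] (flat becomes all-ones,
#'   dark all-zeros).
#' @export
flatDarkCorrect <- function(stack, floor = 1e-6) {
  stopifnot(is(stack, "ProjectionStack"))
  denom <- stack@flat - stack@dark
  if (any(denom <= 0))
    stop("flat field must exceed the dark frame everywhere", call. = FALSE)
  pr <- stack@projections
  for (a in seq_len(dim(pr)[3]))
    pr[, , a] <- pmax((pr[, , a] - stack@dark) / denom, floor)
  stack@projections <- pr
  stack@flat <- array(1, dim(stack@flat))
  stack@dark <- array(0, dim(stack@dark))
  stack
}

# Angular FFT frequencies (radians per metre) for an n-sample axis.
#' @noRd
.fftOmega <- function(n, pixelM) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  2 * pi * k / (n * pixelM)
}

#' Single-distance (Paganin) phase retrieval
#'
#' Recovers the projected phase shift from one propagation-distance frame
#' under the homogeneous-object assumption:
#' \deqn{\varphi = \frac{\delta}{2\beta}\,\ln\!\left(\mathcal F^{-1}\left\{
#'   \frac{\mathcal F[I/I_0]}{1 + (\lambda z \delta / 4\pi\beta)(u^2+v^2)}
#'   \right\}\right)}
#' where u, v are angular spatial frequencies in radians per metre.
#' The filter has unit DC gain, so a constant frame k yields
#' \eqn{(\delta/2\beta)\ln k} everywhere.
#'
#' @param frame 2D matrix of flat/dark-corrected intensities I/I0
#'   (strictly positive).
#' @param params a [physicsParams()].
#' @param pixelSize detector pixel size in micrometres.
#' @param pad symmetric-pad the frame to the next power of two before
#'   filtering (suppresses wrap-around ringing); disable for exact
#'   periodic-domain analyses.
#' @param logFloor relative floor applied before the logarithm (times the
#'   frame maximum); the number of clipped pixels is reported in the
#'   \code{"clipped"} attribute.
#' @return Matrix of phase values with attribute \code{clipped}.
#' @export
paganinRetrieve <- function(frame, params = physicsParams(), pixelSize,
                            pad = TRUE, logFloor = 1e-9) {
  stopifnot(is(params, "PhysicsParams"), is.matrix(frame))
  if (any(frame <= 0))
    stop("frame must be strictly positive (corrected intensities)",
         call. = FALSE)
  d0 <- dim(frame)
  if (pad) {
    n1 <- 2^ceiling(log2(d0[1])); n2 <- 2^ceiling(log2(d0[2]))
    p1 <- n1 - d0[1]; p2 <- n2 - d0[2]
    ix <- c(seq_len(d0[1]), d0[1]:(d0[1] - p1 + 1))[seq_len(n1)]
    iy <- c(seq_len(d0[2]), d0[2]:(d0[2] - p2 + 1))[seq_len(n2)]
    fr <- frame[ix, iy]
  } else fr <- frame
  d <- dim(fr)
  pixelM <- pixelSize * 1e-6
  u <- .fftOmega(d[1], pixelM)
  v <- .fftOmega(d[2], pixelM)
  coef <- params@wavelength * params@distance * params@deltaOverBeta / (4 * pi)
  H <- 1 / (1 + coef * outer(u^2, v^2, "+"))
  filt <- Re(stats::fft(stats::fft(fr) * H, inverse = TRUE) / prod(d))
  flo <- logFloor * max(fr)
  clipped <- sum(filt[seq_len(d0[1]), seq_len(d0[2])] < flo)
  filt <- pmax(filt, flo)
  phi <- (params@deltaOverBeta / 2) * log(filt)
  out <- phi[seq_len(d0[1]), seq_len(d0[2]), drop = FALSE]
  attr(out, "clipped") <- clipped
  out
}

#' Retrieve phase for every frame of a projection stack
#'
#' @param stack a corrected [ProjectionStack-class].
#' @param params a [physicsParams()].
#' @param ... passed to [paganinRetrieve()].
#' @return 3D array of phase maps (one per angle).
#' @export
retrieveStack <- function(stack, params = physicsParams(), ...) {
  stopifnot(is(stack, "ProjectionStack"))
  pr <- stack@projections
  out <- array(NA_real_, dim(pr))
  for (a in seq_len(dim(pr)[3]))
    out[, , a] <- paganinRetrieve(pr[, , a], params, stack@pixelSize, ...)
  out
}
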
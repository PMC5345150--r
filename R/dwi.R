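# Diffusion-weighted signal simulation and gradient schemes.

#' Electrostatic-repulsion gradient direction scheme
#'
#' Distributes n directions on the unit hemisphere by minimising the
#' electrostatic energy of the 2n antipodally symmetric charges, the
#' standard construction for diffusion gradient tables. Deterministic under
#' a fixed seed. The 30-direction table shipped in
#' \code{inst/extdata/directions30.txt} was generated with this function
#' (seed 1) and is a synthetic stand-in for an unpublished acquisition
#' scheme.
#'
#' @param n number of directions.
#' @param seed integer seed for the random initialisation.
#' @param maxit BFGS iteration cap.
#' @return n x 3 matrix of unit vectors.
#' @export
repulsionDirections <- function(n, seed = 1L, maxit = 500L) {
  toVec <- function(p) {
    th <- p[seq_len(n)]; ph <- p[n + seq_len(n)]
    cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  energy <- function(p) {
    v <- toVec(p)
    e <- 0
    for (i in seq_len(n - 1)) {
      dd1 <- sweep(v[(i + 1):n, , drop = FALSE], 2, v[i, ])
      dd2 <- sweep(-v[(i + 1):n, , drop = FALSE], 2, v[i, ])
      e <- e + sum(1 / sqrt(rowSums(dd1^2))) + sum(1 / sqrt(rowSums(dd2^2)))
    }
    e
  }
  p0 <- .withSeed(seed, stats::runif(2 * n, 0, pi))
  fit <- stats::optim(p0, energy, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  v <- toVec(fit$par)
  flip <- v[, 3] < 0   # canonical sign: z >= 0
  v[flip, ] <- -v[flip, ]
  v
}

#' Load the packaged 30-direction scheme
#'
#' @return 30 x 3 matrix of unit gradient directions.
#' @export
directions30 <- function() {
  f <- system.file("extdata", "directions30.txt", package = "MyoTensor")
  as.matrix(utils::read.table(f, col.names = c("x", "y", "z")))
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Generates the monoexponential tensor signal
#' \deqn{S = S_0 \exp(-b\, g^T D g)} per voxel and gradient direction,
#' preceded by \code{nB0} non-diffusion-weighted volumes. Optional additive
#' Gaussian noise per channel (default noiseless). Voxels whose tensor gives
#' a negative diffusivity along some direction would produce an amplifying
#' exponent; those exponents are clamped at zero and the policy is recorded
#' in the result's \code{clamp} field.
#'
#' @param tensors a [TensorField-class] (diffusivities in mm^2/s).
#' @param bValue b-value in s/mm^2.
#' @param directions m x 3 matrix of unit gradient directions.
#' @param s0 non-diffusion-weighted signal.
#' @param nB0 number of leading b = 0 volumes.
#' @param noiseSd additive Gaussian noise standard deviation (0 = none).
#' @param seed integer seed used when \code{noiseSd > 0}.
#' @return list with \code{dwi} (4D array, volumes along dim 4),
#'   \code{protocol} (a [DwiProtocol-class]), \code{clamp} (metadata: number
#'   of clamped voxel-direction pairs and the policy).
#' @export
simulateDwi <- function(tensors, bValue = 1000, directions, s0 = 1000,
                        nB0 = 4L, noiseSd = 0, seed = NULL) {
  stopifnot(is(tensors, "TensorField"))
  directions <- as.matrix(directions)
  if (any(abs(sqrt(rowSums(directions^2)) - 1) > 1e-6))
    stop("gradient directions must be unit norm", call. = FALSE)
  if (bValue < 0) stop("b-value must be non-negative", call. = FALSE)
  el <- tensors@elements
  d <- dim(el)[1:3]
  m <- nrow(directions)
  dwi <- array(NA_real_, c(d, nB0 + m))
  for (v in seq_len(nB0)) dwi[, , , v][!is.na(el[, , , 1])] <- s0
  nClamped <- 0L
  ec <- lapply(1:6, function(k) .comp4(el, k))
  for (j in seq_len(m)) {
    g <- directions[j, ]
    # g^T D g from the six unique elements
    q <- ec[[1]] * g[1]^2 + ec[[3]] * g[2]^2 + ec[[6]] * g[3]^2 +
      2 * (ec[[2]] * g[1] * g[2] + ec[[4]] * g[1] * g[3] +
             ec[[5]] * g[2] * g[3])
    neg <- !is.na(q) & q < 0
    nClamped <- nClamped + sum(neg)
    q[neg] <- 0
    dwi[, , , nB0 + j] <- s0 * exp(-bValue * q)
  }
  if (nClamped > 0L)
    warning(sprintf("%d voxel-direction pairs had negative diffusivity; exponent clamped at 0",
                    nClamped))
  if (noiseSd > 0) {
    dwi <- .withSeed(seed, {
      dwi + array(stats::rnorm(length(dwi), 0, noiseSd), dim(dwi))
    })
  }
  list(dwi = dwi,
       protocol = dwiProtocol(bValue = bValue, directions = directions,
                              nB0 = nB0),
       clamp = list(n = nClamped,
                    policy = "negative g'Dg clamped to 0 before exp"))
}
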
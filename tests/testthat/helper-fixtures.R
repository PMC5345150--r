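# Shared fixtures, all built in code at test time.

# Memoised results that several test files share (the full-resolution
# phantom experiment is expensive, so it is computed once per run).
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Full printed-parameter phantom experiment: default phantom, Poisson
# noise, 11^3 kernel at pi/(3 sqrt 2), plus the 7^3 / 2pi/3 sweep entry
# used for the eigenvector-correspondence contrast.
fullPhantomRun <- function() {
  memo("fullRun", {
    cfg <- validationConfig(
      noiseSeed = 1L,
      sweep = data.frame(centreFreq = c(2 * pi / 3, pi / (3 * sqrt(2))),
                         size = c(7L, 11L)))
    runPhantomValidation(cfg)
  })
}

# Default noiseless phantom (used by reference-angle tests).
defaultPhantom <- function() memo("defaultPhantom", buildPhantom(phantomSpec()))

# A small uniform-angle phantom for orientation arithmetic.
uniformPhantom <- function(ha, extent = c(0.12, 0.12, 0.05)) {
  buildPhantom(phantomSpec(blockExtent = extent, haRange = c(ha, ha)))
}

# Random symmetric positive-definite 3x3 matrices.
randomSpd <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    A <- matrix(rnorm(9), 3, 3)
    crossprod(A) + diag(3) * 0.1
  })
}

# Wrap a list of 3x3 matrices into a TensorField on a 1D grid.
tensorFieldFromMatrices <- function(mats, voxelSize = 1,
                                    provenance = "truth") {
  el <- array(NA_real_, c(length(mats), 1, 1, 6))
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    el[i, 1, 1, ] <- c(m[1, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3], m[3, 3])
  }
  new("TensorField", elements = el, voxelSize = voxelSize,
      provenance = provenance)
}

# Rotation matrices about the grid axes.
rotX <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rotY <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# 2D annulus mask stack (single slice) with single-voxel boundary shells.
annulusProblem <- function(n = 200, a = 40, b = 90) {
  xs <- (1:n) - (n + 1) / 2
  r <- sqrt(outer(xs^2, xs^2, "+"))
  mask <- r >= a & r <= b
  endo <- mask & r < a + 1
  epi <- mask & r > b - 1
  dim(mask) <- dim(endo) <- dim(epi) <- c(n, n, 1)
  list(mask = mask, endo = endo, epi = epi, r = r, n = n, a = a, b = b)
}
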
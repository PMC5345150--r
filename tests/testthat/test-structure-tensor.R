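test_that("lognormal radial profile peaks at the centre frequency", {
  rho0 <- pi / (3 * sqrt(2))
  expect_equal(lognormalRadial(rho0, rho0), 1)
  # one octave away with B = 2: R = exp(-4 ln^2 2 / (4 ln 2)) = 2^-1
  expect_equal(lognormalRadial(2 * rho0, rho0, 2),
               exp(-4 * log(2)^2 / (4 * log(2))))
  expect_equal(lognormalRadial(2 * rho0, rho0, 2) /
                 lognormalRadial(rho0, rho0, 2), 0.5)
  expect_equal(lognormalRadial(0, rho0), 0)
})

test_that("the sweep configurations all construct valid banks", {
  sw <- kernelSweepTable()
  expect_identical(sw$size, c(7L, 7L, 9L, 11L, 17L))
  for (i in seq_len(nrow(sw))) {
    bank <- designBank(sw$centreFreq[i], 2, sw$size[i])
    expect_s4_class(bank, "FilterBank")
    expect_identical(dim(bank@kernels), c(sw$size[i], sw$size[i],
                                          sw$size[i], 6L))
  }
  expect_error(designBank(pi / 3, 2, 8), "odd")
  expect_error(designBank(4, 2, 11), "\\(0, pi\\)")
  d <- quadratureDirections()
  expect_equal(unname(sqrt(rowSums(d^2))), rep(1, 6), tolerance = 1e-12)
})

test_that("structure tensor vanishes on constant volumes", {
  bank <- designBank(pi / (3 * sqrt(2)), 2, 11)
  vol <- array(7, c(16, 16, 16))
  st <- computeStructureTensor(vol, bank)
  expect_lt(max(abs(tensorElements(st))), 1e-8 * 7)
})

test_that("principal axis of a 1D-varying volume matches the gradient oracle", {
  bank <- designBank(pi / 3, 2, 9)
  n <- 24
  x <- array(rep(1:n, n * n), c(n, n, n))
  vol <- sin(2 * pi * x / 6)            # varies along x only
  st <- computeStructureTensor(vol, bank)
  es <- eigenDecompose(st)
  # brute-force gradient-outer-product oracle at interior voxels
  gx <- (vol[3:n, , ] - vol[1:(n - 2), , ]) / 2
  M <- matrix(0, 3, 3)
  M[1, 1] <- sum(gx^2)                  # y/z gradients are exactly zero
  oracleAxis <- eigen(M, symmetric = TRUE)$vectors[, 1]
  ctr <- n / 2
  v1 <- eigenVectors(es, 1)[ctr, ctr, ctr, ]
  expect_gt(abs(sum(v1 * oracleAxis)), cos(1 * pi / 180))
  lam <- eigenValues(es)[ctr, ctr, ctr, ]
  expect_lt(lam[2] / lam[1], 0.05)
  expect_lt(lam[3] / lam[1], 0.05)
})

test_that("lamellar stacks put v1 on the plane normal and v3 in-plane", {
  bank <- designBank(pi / 3, 2, 9)
  n <- 24
  z <- array(rep(1:n, each = n * n), c(n, n, n))
  vol <- ifelse(z %% 6 < 3, 0, 1)       # planes normal to z
  es <- eigenDecompose(computeStructureTensor(vol, bank))
  ctr <- n / 2
  v1 <- eigenVectors(es, 1)[ctr, ctr, ctr, ]
  v3 <- eigenVectors(es, 3)[ctr, ctr, ctr, ]
  expect_gt(abs(v1[3]), cos(3 * pi / 180))
  expect_lt(abs(v3[3]), sin(3 * pi / 180))
})

test_that("the printed tensor normalisation satisfies the trace identity", {
  # trace(T) = sum_k |q_k| (1 - 3/(m-1)) = -0.5 sum_k |q_k| for m = 3;
  # |q_k| recomputed by direct spatial convolution at centre voxels
  bank <- designBank(pi / 3, 2, 7)
  set.seed(7)
  n <- 15
  vol <- array(rnorm(n^3), c(n, n, n))
  st <- computeStructureTensor(vol, bank)
  tr <- st@elements[, , , 1] + st@elements[, , , 3] + st@elements[, , , 6]
  h <- 3
  for (ctr in list(c(8, 8, 8), c(7, 9, 8))) {
    sq <- 0
    for (k in 1:6) {
      kern <- bank@kernels[, , , k]
      acc <- 0 + 0i
      for (a in -h:h) for (b in -h:h) for (cc in -h:h)
        acc <- acc + vol[ctr[1] - a, ctr[2] - b, ctr[3] - cc] *
          kern[h + 1 + a, h + 1 + b, h + 1 + cc]
      sq <- sq + Mod(acc)
    }
    expect_equal(tr[ctr[1], ctr[2], ctr[3]], -0.5 * sq, tolerance = 1e-10)
  }
  # classical variant differs only by a multiple of the identity
  stC <- computeStructureTensor(vol, bank, variant = "classical")
  esA <- eigenDecompose(st); esC <- eigenDecompose(stC)
  ctr <- c(8, 8, 8)
  vA <- eigenVectors(esA, 1)[8, 8, 8, ]; vC <- eigenVectors(esC, 1)[8, 8, 8, ]
  expect_gt(abs(sum(vA * vC)), 1 - 1e-8)
})

test_that("90-degree grid rotations rotate the principal axis exactly", {
  bank <- designBank(pi / 3, 2, 9)
  n <- 20
  z <- array(rep(1:n, each = n * n), c(n, n, n))
  vol <- ifelse(z %% 6 < 3, 0, 1)
  # rotate the volume 90 degrees about y: z -> x
  volR <- aperm(vol[, , n:1], c(3, 2, 1))
  ctr <- n / 2
  v1 <- eigenVectors(eigenDecompose(computeStructureTensor(vol, bank)),
                     1)[ctr, ctr, ctr, ]
  v1R <- eigenVectors(eigenDecompose(computeStructureTensor(volR, bank)),
                      1)[ctr, ctr, ctr, ]
  expect_gt(abs(v1[3]), 1 - 1e-4)
  expect_gt(abs(v1R[1]), 1 - 1e-4)
})

test_that("tensor smoothing preserves constants, mass and symmetry", {
  d <- c(12, 12, 12)
  elC <- array(rep(c(2, 0.5, 3, -0.25, 0.1, 1), each = prod(d)), c(d, 6))
  tfC <- new("TensorField", elements = elC, voxelSize = 1,
             provenance = "structure")
  smC <- smoothTensors(tfC)
  expect_equal(tensorElements(smC), elC, tolerance = 1e-12)
  # impulse spreads exactly into the kernel weights and preserves the sum
  elI <- array(0, c(d, 6))
  elI[6, 6, 6, 1] <- 1
  tfI <- new("TensorField", elements = elI, voxelSize = 1,
             provenance = "structure")
  smI <- smoothTensors(tfI)
  expect_equal(sum(smI@elements[, , , 1]), 1, tolerance = 1e-10)
  g <- dnorm(-3:3, 0, 1.5); g <- g / sum(g)
  expect_equal(smI@elements[6, 6, 6, 1], g[4]^3, tolerance = 1e-12)
  expect_equal(smI@elements[5, 6, 7, 1], g[3] * g[4] * g[3],
               tolerance = 1e-12)
})

test_that("block downsampling equals brute-force block means", {
  set.seed(8)
  d <- c(12, 8, 8)
  el <- array(rnorm(prod(d) * 6), c(d, 6))
  tf <- new("TensorField", elements = el, voxelSize = 1,
            provenance = "structure")
  ds <- downsampleTensors(tf, 4L)
  expect_equal(voxelSize(ds), 4)
  for (j in 1:6) for (i in 1:3) for (k in 1:2) {
    expect_equal(ds@elements[i, k, 1, j],
                 mean(el[(4 * i - 3):(4 * i), (4 * k - 3):(4 * k), 1:4, j]))
  }
  # constant field: any factor returns the constant
  elc <- array(rep(c(1, 2, 3, 4, 5, 6), each = prod(d)), c(d, 6))
  tfc <- new("TensorField", elements = elc, voxelSize = 1,
             provenance = "structure")
  expect_equal(unique(as.vector(downsampleTensors(tfc, 2L)@elements[, , , 4])),
               4)
  # exclusion: masked voxels never contribute to the mean
  excl <- array(FALSE, d)
  excl[1:2, , ] <- TRUE
  el2 <- el
  for (j in 1:6) el2[1:2, , , j] <- 1e6
  tf2 <- new("TensorField", elements = el2, voxelSize = 1,
             provenance = "structure")
  ds2 <- downsampleTensors(tf2, 4L, exclude = excl)
  expect_equal(ds2@elements[1, 1, 1, 1],
               mean(el[3:4, 1:4, 1:4, 1]))
  # fully excluded block -> NA
  excl2 <- array(FALSE, d); excl2[1:4, 1:4, 1:4] <- TRUE
  expect_true(is.na(downsampleTensors(tf, 4L,
                                      exclude = excl2)@elements[1, 1, 1, 1]))
  expect_error(downsampleTensors(tf, 16L), "dimension")
})

test_that("eigendecomposition is sorted, canonical and self-consistent", {
  tfI <- tensorFieldFromMatrices(list(diag(3)))
  esI <- eigenDecompose(tfI)
  expect_equal(esI@values[1, 1, 1, ], c(1, 1, 1))
  expect_true(esI@degenerate[1, 1, 1])
  tfD <- tensorFieldFromMatrices(list(diag(c(3, 2, 1))))
  esD <- eigenDecompose(tfD)
  expect_equal(abs(eigenVectors(esD, 1)[1, 1, 1, ]), c(1, 0, 0))
  expect_equal(abs(eigenVectors(esD, 3)[1, 1, 1, ]), c(0, 0, 1))
  expect_false(esD@degenerate[1, 1, 1])
  # spectral identity on random SPD tensors
  mats <- randomSpd(20, seed = 9)
  es <- eigenDecompose(tensorFieldFromMatrices(mats))
  for (i in seq_along(mats)) {
    lam <- es@values[i, 1, 1, ]
    expect_true(all(diff(lam) <= 0))
    V <- es@vectors[i, 1, 1, , ]
    rec <- V %*% diag(lam) %*% t(V)
    expect_lt(max(abs(rec - mats[[i]])), 1e-8)
    expect_lt(max(abs(crossprod(V) - diag(3))), 1e-8)
  }
  # non-finite tensors propagate as undefined markers
  tfN <- tensorFieldFromMatrices(list(diag(c(NA, 1, 1))))
  esN <- eigenDecompose(tfN)
  expect_true(all(is.na(esN@values[1, 1, 1, ])))
})

test_that("eigenvalue ratios respect their range and trivial cases", {
  es <- eigenDecompose(tensorFieldFromMatrices(
    c(list(diag(3) * 2, diag(c(4, 2, 1))), randomSpd(10, seed = 10))))
  r <- eigenvalueRatios(es)
  expect_equal(r$r21[1, 1, 1], 1)
  expect_equal(r$r32[1, 1, 1], 1)
  expect_equal(r$r21[2, 1, 1], 0.5)
  expect_equal(r$r32[2, 1, 1], 0.5)
  expect_true(all(r$r21 >= 0 & r$r21 <= 1, na.rm = TRUE))
  expect_true(all(r$r32 >= 0 & r$r32 <= 1, na.rm = TRUE))
})

test_that("anisotropic voxel sizes and undersized volumes are rejected", {
  bank <- designBank(pi / 3, 2, 9)
  expect_error(computeStructureTensor(array(0, c(4, 4, 4)), bank),
               "kernel size")
  expect_error(computeStructureTensor(array(0, c(16, 16, 16)), bank,
                                      voxelSize = c(1, 1, 2)),
               "anisotropic")
})
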
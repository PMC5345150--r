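test_that("noiseless simulated signals are refit exactly", {
  dirs <- directions30()
  truth <- diag(c(1.5e-3, 1.0e-3, 0.5e-3))
  tf <- tensorFieldFromMatrices(c(list(truth), randomSpd(5, seed = 11)),
                                provenance = "truth")
  tf@elements[, , , ] <- tf@elements * ifelse(tf@provenance == "truth", 1, 1)
  # scale the random SPD examples into diffusivity range
  tf@elements[2:6, , , ] <- tf@elements[2:6, , , ] * 1e-4
  sim <- simulateDwi(tf, 1000, dirs, s0 = 800)
  fit <- fitDiffusionTensor(sim$dwi, sim$protocol)
  rel <- abs(tensorElements(fit$tensors) - tf@elements) /
    max(abs(tf@elements))
  expect_lt(max(rel, na.rm = TRUE), 1e-8)
  expect_equal(as.vector(fit$s0), rep(800, 6), tolerance = 1e-8)
  expect_true(all(fit$converged))
  # isotropic signals give D = d I
  iso <- tensorFieldFromMatrices(list(diag(3) * 1e-3), provenance = "truth")
  fitI <- fitDiffusionTensor(simulateDwi(iso, 1000, dirs)$dwi,
                             sim$protocol)
  expect_equal(fitI$tensors@elements[1, 1, 1, ],
               c(1e-3, 0, 1e-3, 0, 0, 1e-3), tolerance = 1e-8)
})

test_that("the fit is invariant to gradient direction order and flags empty voxels", {
  dirs <- directions30()
  tf <- tensorFieldFromMatrices(randomSpd(2, seed = 12), provenance = "truth")
  tf@elements <- tf@elements * 1e-4
  sim <- simulateDwi(tf, 1000, dirs, s0 = 500)
  perm <- sample(30)
  dwiPerm <- sim$dwi
  dwiPerm[, , , 5:34] <- dwiPerm[, , , 4 + perm]
  protPerm <- dwiProtocol(1000, dirs[perm, ], nB0 = 4L)
  fitA <- fitDiffusionTensor(sim$dwi, sim$protocol)
  fitB <- fitDiffusionTensor(dwiPerm, protPerm)
  expect_equal(tensorElements(fitA$tensors), tensorElements(fitB$tensors),
               tolerance = 1e-9)
  # an all-zero voxel yields undefined markers
  dwi0 <- sim$dwi
  dwi0[1, 1, 1, ] <- 0
  fit0 <- fitDiffusionTensor(dwi0, sim$protocol)
  expect_true(all(is.na(fit0$tensors@elements[1, 1, 1, ])))
})

test_that("mean ADC equals the eigenvalue mean and the trace identity", {
  es <- eigenDecompose(tensorFieldFromMatrices(
    c(list(diag(c(3, 2, 1)) * 1e-3, diag(3)), randomSpd(10, seed = 13))))
  adc <- meanADC(es)
  expect_equal(adc[1, 1, 1], 2e-3)
  expect_equal(adc[2, 1, 1], 1)
  mats <- randomSpd(10, seed = 13)
  for (i in seq_along(mats))
    expect_equal(adc[i + 2, 1, 1], sum(diag(mats[[i]])) / 3,
                 tolerance = 1e-10)
  # rotation invariance: conjugating by a rotation leaves the ADC unchanged
  R <- rotZ(34) %*% rotX(12)
  rot <- lapply(mats, function(m) R %*% m %*% t(R))
  adcR <- meanADC(eigenDecompose(tensorFieldFromMatrices(rot)))
  expect_equal(as.vector(adcR), vapply(mats, function(m) sum(diag(m)) / 3,
                                       1), tolerance = 1e-10)
})

test_that("heart segmentation applies both printed criteria and is monotone", {
  set.seed(14)
  d <- c(10, 10, 4)
  b0 <- array(runif(prod(d), 0, 100), d)
  adc <- array(runif(prod(d), 0, 3e-3), d)
  m <- segmentHeart(b0, adc)
  census <- sum(b0 > 0.2 * max(b0) & adc < 1.8e-3)  # brute-force count
  expect_equal(sum(m), census)
  # raising the ADC ceiling never removes voxels
  m2 <- segmentHeart(b0, adc, adcMax = 2.4e-3)
  expect_true(all(m2[m]))
  expect_warning(segmentHeart(array(0, d), adc), "empty")
})

test_that("the long-axis transform recovers constructed geometries", {
  d <- c(32, 32, 20)
  xs <- (1:32) - 16.5
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  cyl <- array(rep(rr < 6, 20), d)
  lm <- rbind(c(16.5, 30, 10), c(16.5, 3, 10))  # chord along -y
  M <- longAxisTransform(cyl, rbind(lm[2, ], lm[1, ]))
  expect_equal(M@rotation, diag(3), tolerance = 1e-8)
  # translation centres the fitted axis: the axis point maps to the centre
  p0 <- c(16.5, 16.5, 10.5)
  expect_equal(as.numeric(M@rotation %*% p0 + M@translation),
               d / 2, tolerance = 0.6)
  # cylinder tilted 10 degrees about y
  tilt <- array(FALSE, d)
  for (z in 1:20) {
    cx <- 16.5 + (z - 10.5) * tan(10 * pi / 180)
    tilt[, , z] <- sqrt(outer((xs + 16.5 - cx)^2, xs^2, "+")) < 6
  }
  Mt <- longAxisTransform(tilt, rbind(c(16.5, 30, 10), c(16.5, 3, 10)))
  zNew <- Mt@rotation %*% c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  ang <- acos(min(1, zNew[3])) * 180 / pi
  expect_lt(ang, 0.1)
  expect_error(longAxisTransform(array(FALSE, d), lm), "3 slices")
})

test_that("rigid application permutes, conjugates and round-trips fields", {
  # identity transform with nearest neighbour leaves a field unchanged
  set.seed(15)
  f <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  id <- rigidTransform()
  expect_equal(applyRigid(f, id, "nearest"), f)
  # 90 degrees about z maps diag(a,b,c) tensors to diag(b,a,c)
  el <- array(rep(c(2, 0, 5, 0, 0, 9), each = 7^3), c(7, 7, 7, 6))
  tf <- new("TensorField", elements = el, voxelSize = 1000,
            provenance = "diffusion")
  Mz <- rigidTransform(rotation = rotZ(90),
                       translation = c(7, 0, 0))  # keep the grid in range
  out <- applyRigid(tf, Mz, "nearest", voxelSizeMm = 1)
  inner <- out@elements[3:5, 3:5, 3:5, ]
  expect_equal(inner[1, 1, 1, ], c(5, 0, 2, 0, 0, 9), tolerance = 1e-9)
  # rotate then inverse-rotate approximates identity on smooth fields
  g <- array(0, c(16, 16, 16))
  for (i in 1:16) g[i, , ] <- sin(i / 3)
  ang <- 20
  ctr <- c(8.5, 8.5, 8.5)
  Rf <- rotZ(ang)
  Mf <- rigidTransform(Rf, as.numeric(ctr - Rf %*% ctr))
  Mb <- rigidTransform(t(Rf), as.numeric(ctr - t(Rf) %*% ctr))
  back <- applyRigid(applyRigid(g, Mf, "cubic"), Mb, "cubic")
  keep <- !is.na(back)
  expect_gt(mean(keep), 0.5)
  expect_lt(max(abs(back - g)[keep]), 0.05)
  expect_lt(mean(abs(back - g)[keep]), 0.01)
})
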
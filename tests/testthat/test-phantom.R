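test_that("default phantom has the expected grid and lattice arithmetic", {
  vol <- defaultPhantom()
  expect_identical(dim(intensity(vol)), c(250L, 250L, 28L))
  expect_equal(voxelSize(vol), 3.6)
  # intensities take exactly the two configured values
  expect_setequal(unique(as.vector(intensity(vol))), c(50, 100))
  expect_true(all(!is.na(vol@haMap[occupancy(vol)])))
  expect_true(all(is.na(vol@haMap[!occupancy(vol)])))
})

test_that("occupancy fraction matches closed-form unit-cell arithmetic", {
  # grid resolution dividing every length, zero helix angle, and extents
  # that are whole numbers of lattice periods: the intracellular fraction
  # is exactly (depth * thickness / periodX) * (width / periodW)
  spec <- phantomSpec(blockExtent = c(0.114, 0.1, 0.025),
                      gridResolution = 1, haRange = c(0, 0))
  vol <- buildPhantom(spec)
  expected <- (3 * 14 / 57) * (18 / 25)
  expect_equal(mean(occupancy(vol)), expected, tolerance = 1e-12)
})

test_that("zero helix ramp aligns every truth axis with the circumferential axis", {
  vol <- uniformPhantom(0)
  u <- truthAxes(vol, "long")
  occ <- occupancy(vol)
  expect_true(all(u[, , , 2][occ] == 1))
  expect_true(all(u[, , , 3][occ] == 0))
})

test_that("truth triads are orthonormal and right-handed", {
  vol <- uniformPhantom(37)
  occ <- which(occupancy(vol))[1:50]
  u <- truthAxes(vol, "long"); s <- truthAxes(vol, "sheet")
  nr <- truthAxes(vol, "normal")
  pick <- function(a, i) c(a[, , , 1][i], a[, , , 2][i], a[, , , 3][i])
  for (i in occ[c(1, 25, 50)]) {
    ui <- pick(u, i); si <- pick(s, i); ni <- pick(nr, i)
    expect_equal(sum(ui * si), 0, tolerance = 1e-12)
    expect_equal(sqrt(sum(ui^2)), 1, tolerance = 1e-12)
    # u x s = n
    expect_equal(c(ui[2] * si[3] - ui[3] * si[2],
                   ui[3] * si[1] - ui[1] * si[3],
                   ui[1] * si[2] - ui[2] * si[1]), ni, tolerance = 1e-12)
  }
})

test_that("a block smaller than one unit cell is rejected", {
  expect_error(buildPhantom(phantomSpec(blockExtent = c(0.02, 0.02, 0.01))),
               "unit cell")
  expect_error(phantomSpec(haRange = c(-120, 88)), "haRange")
})

test_that("Poisson noise has the configured moments and is seed-deterministic", {
  spec <- phantomSpec(blockExtent = c(0.36, 0.36, 0.36),
                      sIntra = 100, sExtra = 100)  # flat mean 100
  vol <- buildPhantom(spec)
  expect_gte(length(intensity(vol)), 1e6)
  noisy <- addPoissonNoise(vol, seed = 11)
  expect_equal(mean(intensity(noisy)), 100, tolerance = 0.5 / 100)
  expect_lt(abs(stats::var(as.vector(intensity(noisy))) - 100), 2)
  again <- addPoissonNoise(vol, seed = 11)
  expect_identical(intensity(noisy), intensity(again))
  other <- addPoissonNoise(vol, seed = 12)
  expect_false(identical(intensity(noisy), intensity(other)))
  # zero intensity stays zero with probability one
  vol0 <- vol
  vol0@intensity[] <- 0
  expect_true(all(intensity(addPoissonNoise(vol0, 1)) == 0))
  volNeg <- vol
  volNeg@intensity[1] <- -1
  expect_error(addPoissonNoise(volNeg, 1), "non-negative")
})

test_that("dyadic voxel averaging reproduces single and mixed orientations", {
  # uniform 30 degree field: reference equals the input angle exactly
  vol <- uniformPhantom(30)
  ref <- voxelAverageReference(vol, 14 * 3.6)
  expect_true(all(abs(ref$angles@ha - 30) < 1e-9, na.rm = TRUE))
  # two equal populations at +/- theta in one coarse voxel average to 0
  theta <- 35
  d <- c(8L, 8L, 8L)
  ha <- array(theta, d)
  ha[, , 1:4] <- -theta
  mix <- new("LabelledVolume", intensity = array(50, d),
             occupancy = array(TRUE, d), haMap = ha, voxelSize = 1,
             spec = phantomSpec())
  ref2 <- voxelAverageReference(mix, 8)
  expect_equal(as.vector(ref2$angles@ha), 0, tolerance = 1e-9)
  # a coarse voxel with no intracellular content is flagged undefined
  none <- mix
  none@occupancy[] <- FALSE
  none@haMap[] <- NA_real_
  ref3 <- voxelAverageReference(none, 8)
  expect_true(is.na(ref3$angles@ha[1, 1, 1]))
})

test_that("reference layers are antisymmetric when the lattice tiles the wall exactly", {
  # period 60 um divides both the 0.9 mm extent and the 2 um grid, and a
  # 60 um coarse layer is exactly one sheetlet, so HA(layer k) must mirror
  # HA(layer n+1-k) exactly for the symmetric default range
  spec <- phantomSpec(blockExtent = c(0.36, 0.12, 0.03), gridResolution = 2,
                      cellThickness = 16, gapCellThickness = 4,
                      gapSheetlet = 4)
  vol <- buildPhantom(spec)
  ref <- voxelAverageReference(vol, 60)
  ha <- apply(ref$angles@ha, 1, mean, na.rm = TRUE)
  expect_equal(ha, -rev(ha), tolerance = 1e-6)
})

test_that("coarse size must divide into the fine grid", {
  vol <- uniformPhantom(10)
  expect_error(voxelAverageReference(vol, 10), "integer multiple")
})

test_that("truth tensors reproduce triads, eigenvalues and equivariance", {
  ev <- c(3, 2, 1)
  vol0 <- uniformPhantom(0)
  tt <- makeTruthTensors(vol0, 14 * 3.6, eigenvalues = ev)
  el <- tensorElements(tt)[1, 1, 1, ]
  # long axis = y, sheet = z, normal = x -> diag(lambda3, lambda1, lambda2)
  expect_equal(el, c(1, 0, 3, 0, 0, 2), tolerance = 1e-12)
  # eigenvectors of the output match the input triads up to sign
  vol <- uniformPhantom(25)
  tt2 <- makeTruthTensors(vol, 14 * 3.6, eigenvalues = ev)
  es <- eigenDecompose(tt2)
  v1 <- eigenVectors(es, 1)[1, 1, 1, ]
  th <- 25 * pi / 180
  expect_equal(abs(sum(v1 * c(0, cos(th), sin(th)))), 1, tolerance = 1e-9)
  # rotating the triads by R conjugates the tensors by R: a -90 degree
  # rotation about the radial axis maps helix angle 20 to -70
  tA <- makeTruthTensors(uniformPhantom(20), 14 * 3.6, eigenvalues = ev)
  tB <- makeTruthTensors(uniformPhantom(-70), 14 * 3.6, eigenvalues = ev)
  R <- rotX(-90)
  A <- matrix(c(tA@elements[1, 1, 1, c(1, 2, 4)],
                tA@elements[1, 1, 1, c(2, 3, 5)],
                tA@elements[1, 1, 1, c(4, 5, 6)]), 3, 3)
  B <- matrix(c(tB@elements[1, 1, 1, c(1, 2, 4)],
                tB@elements[1, 1, 1, c(2, 3, 5)],
                tB@elements[1, 1, 1, c(4, 5, 6)]), 3, 3)
  expect_equal(B, R %*% A %*% t(R), tolerance = 1e-9)
  expect_error(makeTruthTensors(vol, 14 * 3.6, eigenvalues = c(1, 2, 3)),
               "decreasing")
})
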
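test_that("a uniform field yields straight tracks spanning the box", {
  d <- c(6, 6, 20)
  vf <- array(0, c(d, 3)); vf[, , , 3] <- 1
  mask <- array(TRUE, d)
  seeds <- cbind(3, 3, c(5, 10, 15))
  ts <- trackStreamlines(vf, mask, voxelSizeMm = 0.1, minLength = 0.5,
                         smooth = FALSE, seeds = seeds)
  expect_length(ts@tracks, 3)
  for (t in ts@tracks) {
    len <- sum(sqrt(rowSums(diff(t)^2)))
    expect_equal(len, 1.9, tolerance = 0.06)  # 19 voxels x 0.1 mm
    # straight: x/y constant
    expect_lt(max(abs(t[, 1] - t[1, 1])), 1e-9)
  }
})

test_that("circular fields track circles within 2 percent radius drift", {
  n <- 40
  xs <- (1:n) - (n + 1) / 2
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  mask <- array(rep(rr > 8 & rr < 16, 3), c(n, n, 3))
  vf <- array(0, c(n, n, 3, 3))
  for (z in 1:3) {
    vf[, , z, 1] <- -outer(rep(1, n), xs) / pmax(rr, 1e-9)
    vf[, , z, 2] <- outer(xs, rep(1, n)) / pmax(rr, 1e-9)
  }
  seeds <- cbind((n + 1) / 2 + 12, (n + 1) / 2, 2)
  ts <- trackStreamlines(vf, mask, voxelSizeMm = 0.1, stepVox = 0.25,
                         minLength = 0.5, smooth = FALSE, seeds = seeds,
                         maxSteps = 600L)
  expect_length(ts@tracks, 1)
  t1 <- ts@tracks[[1]] / 0.1
  rad <- sqrt((t1[, 1] - (n + 1) / 2)^2 + (t1[, 2] - (n + 1) / 2)^2)
  expect_lt((max(rad) - min(rad)) / mean(rad), 0.02)
  # halving the step changes the radius by < 1 percent (convergence)
  ts2 <- trackStreamlines(vf, mask, voxelSizeMm = 0.1, stepVox = 0.125,
                          minLength = 0.5, smooth = FALSE, seeds = seeds,
                          maxSteps = 1200L)
  t2 <- ts2@tracks[[1]] / 0.1
  rad2 <- sqrt((t2[, 1] - (n + 1) / 2)^2 + (t2[, 2] - (n + 1) / 2)^2)
  expect_lt(abs(mean(rad2) - mean(rad)) / mean(rad), 0.01)
  # global sign flip of the axial field leaves tracking unchanged
  ts3 <- trackStreamlines(-vf, mask, voxelSizeMm = 0.1, stepVox = 0.25,
                          minLength = 0.5, smooth = FALSE, seeds = seeds,
                          maxSteps = 600L)
  expect_equal(dim(ts3@tracks[[1]]), dim(ts@tracks[[1]]))
  rad3 <- sqrt((ts3@tracks[[1]][, 1] / 0.1 - (n + 1) / 2)^2 +
                 (ts3@tracks[[1]][, 2] / 0.1 - (n + 1) / 2)^2)
  expect_equal(mean(rad3), mean(rad), tolerance = 1e-6)
})

test_that("the minimum length threshold removes tracks in a small pocket", {
  # 0.3 mm pocket: every track is shorter than the 0.5 mm minimum
  d <- c(3, 3, 3)                       # 0.3 mm cube at 0.1 mm voxels
  vf <- array(0, c(d, 3)); vf[, , , 3] <- 1
  mask <- array(TRUE, d)
  ts <- trackStreamlines(vf, mask, voxelSizeMm = 0.1, minLength = 0.5)
  expect_length(ts@tracks, 0)
  # empty mask gives an empty set
  ts0 <- trackStreamlines(vf, array(FALSE, d), voxelSizeMm = 0.1)
  expect_length(ts0@tracks, 0)
})

test_that("the turning-angle threshold terminates sharp turns", {
  d <- c(30, 10, 3)
  vf <- array(0, c(d, 3))
  vf[1:14, , , 1] <- 1                   # along +x
  vf[15:30, , , 3] <- 1                  # 90-degree turn to +z
  mask <- array(TRUE, d)
  ts <- trackStreamlines(vf, mask, voxelSizeMm = 0.1, minLength = 0.4,
                         smooth = FALSE, seeds = cbind(5, 5, 2))
  # the track stays in the +x limb instead of turning 90 degrees
  expect_length(ts@tracks, 1)
  expect_lt(max(ts@tracks[[1]][, 3]), 0.4)
})

test_that("TrackVis files round-trip exactly", {
  d <- c(6, 6, 20)
  vf <- array(0, c(d, 3)); vf[, , , 3] <- 1
  ts <- trackStreamlines(vf, array(TRUE, d), voxelSizeMm = 0.1,
                         seeds = cbind(c(2, 4), c(2, 4), c(10, 10)))
  path <- tempfile(fileext = ".trk")
  writeTrk(ts, path, dim = d, voxelSizeMm = 0.1)
  back <- readTrk(path)
  expect_equal(back$nCount, length(ts@tracks))
  expect_equal(back$dim, d)
  for (i in seq_along(ts@tracks))
    expect_equal(back$tracks[[i]], unname(ts@tracks[[i]]),
                 tolerance = 1e-6)
  # empty set still writes a valid header
  empty <- new("TrackSet", tracks = list(), parameters = list())
  p2 <- tempfile(fileext = ".trk")
  writeTrk(empty, p2, dim = d, voxelSizeMm = 0.1)
  expect_equal(readTrk(p2)$nCount, 0)
})
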
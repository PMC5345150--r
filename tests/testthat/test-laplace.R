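test_that("a planar slab has an exactly linear transmural depth", {
  d <- c(22, 10, 6)
  mask <- array(TRUE, d)
  epi <- array(FALSE, d); epi[1, , ] <- TRUE
  endo <- array(FALSE, d); endo[22, , ] <- TRUE
  ld <- laplaceDepth(mask, epi, endo)
  # the discrete harmonic solution on a slab is linear in depth
  expected <- (0:21) / 21
  for (k in c(1, 6)) expect_equal(ld$depth[, 5, k], expected,
                                  tolerance = 1e-4)
  expect_true(all(ld$depth >= 0 & ld$depth <= 1))
})

test_that("the annulus solution matches the closed-form harmonic profile", {
  prob <- annulusProblem(200, 40, 90)
  ld <- laplaceDepth(prob$mask, prob$epi, prob$endo)
  # compare against ln(r/b)/ln(a/b) at the effective (discrete-shell) radii
  aEff <- mean(prob$r[which(prob$endo)])
  bEff <- mean(prob$r[which(prob$epi)])
  phiTrue <- log(prob$r / bEff) / log(aEff / bEff)
  dim(phiTrue) <- dim(prob$mask)
  interior <- prob$mask & !prob$epi & !prob$endo
  expect_lt(max(abs(ld$depth - phiTrue)[interior]), 1e-2)
  # maximum principle
  expect_true(all(ld$depth >= -1e-12 & ld$depth <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(is.na(ld$depth[!prob$mask])))
})

test_that("components that miss a boundary are left undefined", {
  d <- c(10, 10, 1)
  mask <- array(FALSE, d)
  mask[2:4, 2:9, 1] <- TRUE    # strip with both boundaries
  mask[7:9, 2:9, 1] <- TRUE    # island with neither
  epi <- array(FALSE, d); epi[2:4, 2, 1] <- TRUE
  endo <- array(FALSE, d); endo[2:4, 9, 1] <- TRUE
  ld <- laplaceDepth(mask, epi, endo)
  expect_true(all(!is.na(ld$depth[2:4, 2:9, 1])))
  expect_true(all(is.na(ld$depth[7:9, 2:9, 1])))
})

test_that("depth is invariant under a 90-degree rotation of the mask", {
  prob <- annulusProblem(60, 12, 26)
  ld <- laplaceDepth(prob$mask, prob$epi, prob$endo)
  rot <- function(a) {
    b <- aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
    b
  }
  ldR <- laplaceDepth(rot(prob$mask), rot(prob$epi), rot(prob$endo))
  expect_equal(ldR$depth, rot(ld$depth), tolerance = 1e-10)
})

test_that("local frames are orthonormal and match slab and annulus geometry", {
  d <- c(16, 8, 8)
  mask <- array(TRUE, d)
  epi <- array(FALSE, d); epi[1, , ] <- TRUE
  endo <- array(FALSE, d); endo[16, , ] <- TRUE
  fr <- localFrames(laplaceDepth(mask, epi, endo))
  # depth along x, long axis z: r = +x, l = +z, c = +y
  i <- c(8, 4, 4)
  expect_equal(fr@radial[8, 4, 4, ], c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr@longitudinal[8, 4, 4, ], c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr@circumferential[8, 4, 4, ], c(0, 1, 0), tolerance = 1e-9)
  # orthonormality wherever defined
  ok <- which(!is.na(fr@radial[, , , 1]))[1:50]
  for (i in ok[c(1, 25, 50)]) {
    r <- c(fr@radial[, , , 1][i], fr@radial[, , , 2][i],
           fr@radial[, , , 3][i])
    cc <- c(fr@circumferential[, , , 1][i], fr@circumferential[, , , 2][i],
            fr@circumferential[, , , 3][i])
    expect_equal(sum(r * cc), 0, tolerance = 1e-9)
    expect_equal(sqrt(sum(cc^2)), 1, tolerance = 1e-9)
  }
  # annulus: circumferential axes are tangent to circles
  prob <- annulusProblem(80, 16, 34)
  frA <- localFrames(laplaceDepth(prob$mask, prob$epi, prob$endo))
  interior <- which(prob$mask & !prob$epi & !prob$endo)
  n <- 80
  co <- arrayInd(interior, dim(prob$mask))
  tx <- -(co[, 2] - (n + 1) / 2); ty <- co[, 1] - (n + 1) / 2
  tn <- sqrt(tx^2 + ty^2)
  cdot <- abs(frA@circumferential[, , , 1][interior] * tx / tn +
                frA@circumferential[, , , 2][interior] * ty / tn)
  expect_gt(stats::quantile(cdot, 0.05, na.rm = TRUE), 0.99)
})
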
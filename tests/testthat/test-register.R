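test_that("pyramid extents halve with ceiling at each level", {
  shapes <- pyramidShapes(c(320, 456, 528), 3, 2)
  expect_equal(shapes[[1]], c(320L, 456L, 528L))
  expect_equal(shapes[[2]], c(160L, 228L, 264L))
  expect_equal(shapes[[3]], c(80L, 114L, 132L))
  expect_equal(pyramidShapes(c(7, 9, 11), 2, 2)[[2]], c(4L, 5L, 6L))
  expect_error(pyramidShapes(c(2, 2, 2), 4, 2), "degenerate extent")
})

test_that("bundle pyramids downsample intensities and keep masks binary", {
  p <- makePhantomBrain(c(24, 28, 32), 3, seed = 1)
  b <- phantomBundle(p)
  pyr <- buildPyramid(b, 3, 2)
  expect_length(pyr, 3L)
  expect_identical(pyr[[1]], b)
  expect_equal(dim(volData(pyr[[2]]@original)), c(12, 14, 16))
  expect_equal(dim(volData(pyr[[3]]@original)), c(6, 7, 8))
  for (l in 2:3) {
    for (m in pyr[[l]]@regionMasks) {
      expect_true(all(volData(m) %in% c(0, 1)))
    }
  }
  expect_length(buildPyramid(b, 1, 2), 1L)
})

test_that("applyTransform composes stages and maps points exactly", {
  p <- makePhantomBrain(c(24, 28, 32), 3, seed = 2)
  v <- intensity(p)
  idt <- applyTransform(v)
  expect_identical(volData(idt), volData(v))

  t <- axocarto:::centeredAffine(
    axocarto:::eulerRotation(0.07, 0, -0.04) %*% diag(c(1.02, 0.97, 1.01)),
    c(1, -0.5, 2), c(24, 28, 32))
  pts <- landmarks(p)
  fwd <- applyTransform(pts, affine = t)
  back <- transformPoints(axocarto:::invertAffineMat(t), fwd)
  expect_lt(max(abs(back - pts)), 1e-6)

  labs <- labels3d(p)
  warped <- applyTransform(labs, affine = t)
  expect_true(all(unique(as.vector(volData(warped))) %in%
                    c(0, unique(as.vector(volData(labs))))))
  expect_error(applyTransform(labs, affine = t, interp = "linear"),
               "label")
})

test_that("self-registration stays at the identity", {
  p <- makePhantomBrain(c(40, 57, 66), 4, seed = 3)
  b <- phantomBundle(p)
  cfg <- registrationConfig(levels = 2, rigidIter = 30)
  rig <- fitRigid(b, b, cfg)
  err <- affineError(rig, c(40, 57, 66))
  expect_lt(err["angle"], 0.5)
  expect_lt(err["shift"], 0.5)
  tr <- attr(rig, "trace")
  expect_true(all(diff(tr) <= 1e-8))
})

test_that("a rigid perturbation is recovered at the coarsest level", {
  p <- makePhantomBrain(c(40, 57, 66), 4, seed = 4)
  shape <- dim(volData(intensity(p)))
  tTrue <- axocarto:::centeredAffine(
    axocarto:::eulerRotation(4 * pi / 180, 0, 0), c(2, -1.5, 1), shape)
  src <- deformPhantom(p, tTrue, noiseSd = 2, seed = 5)
  cfg <- registrationConfig(levels = 2, rigidIter = 40)
  rig <- fitRigid(phantomBundle(src), phantomBundle(p), cfg)
  err <- affineError(composeAffine(rig, tTrue), shape)
  expect_lt(err["angle"], 1)
  expect_lt(err["shift"], 1)
})

test_that("affine scale perturbations are recovered within tolerance", {
  p <- makePhantomBrain(c(40, 57, 66), 4, seed = 6)
  shape <- dim(volData(intensity(p)))
  tTrue <- axocarto:::centeredAffine(diag(c(1.1, 0.95, 1.05)), c(0, 0, 0),
                                     shape)
  src <- deformPhantom(p, tTrue, noiseSd = 2, seed = 7)
  cfg <- registrationConfig(levels = 2, affineIter = 50)
  bs <- phantomBundle(src)
  br <- phantomBundle(p)
  rig <- fitRigid(bs, br, cfg)
  aff <- fitAffine(bs, br, cfg, init = rig)
  comp <- composeAffine(aff, tTrue)  # should be near the identity
  expect_lt(max(abs(diag(comp@A) - 1)), 0.02)
  # descent contract: the trace never goes above its starting value
  tra <- attr(aff, "trace")
  expect_lte(tra[length(tra)], tra[1] + 1e-10)
})

test_that("deformable self-registration keeps the field near zero", {
  p <- makePhantomBrain(c(32, 40, 48), 3, seed = 8)
  b <- phantomBundle(p)
  cfg <- registrationConfig(levels = 2, deformLevels = 1, deformIter = 8)
  fd <- fitDeformable(b, b, cfg)
  expect_lt(stats::quantile(abs(fieldDisp(fd)), 0.99), 0.5)
})

test_that("deformable registration improves region overlap", {
  p <- makePhantomBrain(c(32, 40, 48), 3, seed = 9)
  shape <- dim(volData(intensity(p)))
  f <- smoothField(shape, sd = 1.4, seed = 10)
  src <- deformPhantom(p, f, noiseSd = 2, seed = 11)
  cfg <- registrationConfig(levels = 2, deformLevels = 2,
                            deformIter = c(10, 2))
  fd <- fitDeformable(phantomBundle(src), phantomBundle(p), cfg)
  before <- regionDiceReport(labels3d(src), labels3d(p))$averageMedian
  warped <- applyTransform(labels3d(src), field = fd)
  after <- regionDiceReport(warped, labels3d(p))$averageMedian
  expect_gte(after, before)
  # diffeomorphism-friendly in practice: Jacobian of (id + Phi) positive
  disp <- fieldDisp(fd)
  d <- dim(disp)[1:3]
  J <- array(0, c(d - 1L, 3, 3))
  for (k in 1:3) {
    comp <- disp[, , , k]
    J[, , , k, 1] <- (comp[-1, , ] - comp[-d[1], , ])[, -d[2], -d[3]]
    J[, , , k, 2] <- (comp[, -1, ] - comp[, -d[2], ])[-d[1], , -d[3]]
    J[, , , k, 3] <- (comp[, , -1] - comp[, , -d[3]])[-d[1], -d[2], ]
  }
  for (k in 1:3) J[, , , k, k] <- J[, , , k, k] + 1
  dets <- J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] -
                             J[, , , 2, 3] * J[, , , 3, 2]) -
    J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] -
                       J[, , , 2, 3] * J[, , , 3, 1]) +
    J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] -
                       J[, , , 2, 2] * J[, , , 3, 1])
  expect_gte(mean(dets > 0), 0.99)
})

test_that("stronger smoothness weights never roughen the field", {
  p <- makePhantomBrain(c(20, 24, 28), 3, seed = 12)
  shape <- dim(volData(intensity(p)))
  f <- smoothField(shape, sd = 1.2, seed = 13)
  src <- deformPhantom(p, f, noiseSd = 1, seed = 14)
  bs <- phantomBundle(src)
  br <- phantomBundle(p)
  tv <- vapply(c(0.1, 1, 10), function(lam) {
    cfg <- registrationConfig(levels = 1, deformLevels = 1, deformIter = 4,
                              lambdaDeform = lam, controlSpacing = 12)
    fieldSmoothness(fitDeformable(bs, br, cfg))
  }, 0)
  expect_lte(tv[2], tv[1] + 1e-6)
  expect_lte(tv[3], tv[2] + 1e-6)
})
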
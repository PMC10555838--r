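test_that("axon cubes carry exact ground truth", {
  p <- makeAxonCube(64, 1, 2.0, 10, seed = 0)
  ann <- volData(annotation(p))
  sk <- skeleton(p)
  expect_true(all(sk[ann == 0] == 0))     # skeleton inside the annotation
  expect_lt(mean(ann), 0.10)              # sparse axons
  expect_gt(sum(ann), 0)
  expect_identical(provenance(p), "synthetic")
  p2 <- makeAxonCube(64, 1, 2.0, 10, seed = 0)
  expect_identical(volData(intensity(p)), volData(intensity(p2)))
  expect_identical(volData(annotation(p)), volData(annotation(p2)))
  expect_error(makeAxonCube(64, 0, 2, 10, 0), "nTrees")
  expect_error(makeAxonCube(8, 1, 2, 10, 0), "extent")
})

test_that("generated skeletons are single-voxel-wide 26-connected curves", {
  p <- makeAxonCube(48, 1, 2.0, 10, seed = 3)
  sk <- skeleton(p) > 0
  # neighbor counts: <= 2 on simple curve interiors, more only at branches
  nb <- array(0, dim(sk))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz | dy | dx) {
      nb <- nb + axocarto:::shift3d(sk, dz, dy, dx, fill = FALSE)
    }
  }
  counts <- nb[sk]
  expect_gte(mean(counts <= 3), 0.95)
  # one 26-connected curve per tree: components = small number
  ncomp <- max(axocarto:::labelComponents(sk))
  expect_lte(ncomp, 4L)
})

test_that("artifact cubes are bright structures with empty annotation", {
  for (kind in c("vessel", "bright_spot", "edge")) {
    p <- makeArtifactCube(64, kind, seed = 1)
    expect_equal(sum(volData(annotation(p))), 0)
    # structure raised above background by >= 5 x noise sd (sd = 10)
    expect_gte(max(volData(intensity(p))) - 20, 5 * 10)
  }
  a <- makeArtifactCube(32, "vessel", seed = 9)
  b <- makeArtifactCube(32, "vessel", seed = 9)
  expect_identical(volData(intensity(a)), volData(intensity(b)))
  expect_error(makeArtifactCube(32, "unknown", seed = 1))
})

test_that("phantom brains have labeled regions with landmarks at centers", {
  p <- makePhantomBrain(c(40, 57, 66), 6, seed = 1)
  lab <- volData(labels3d(p))
  expect_setequal(setdiff(unique(as.vector(lab)), 0), 1:6)
  lm <- landmarks(p)
  for (i in seq_len(nrow(lm))) {
    expect_equal(lab[lm[i, 1] + 1, lm[i, 2] + 1, lm[i, 3] + 1], i)
  }
  p2 <- makePhantomBrain(c(40, 57, 66), 6, seed = 1)
  expect_identical(volData(intensity(p)), volData(intensity(p2)))
  expect_error(makePhantomBrain(c(18, 18, 18), 11, seed = 1), "too small")
})

test_that("deformPhantom maps grids and landmarks consistently", {
  p <- makePhantomBrain(c(32, 40, 44), 3, seed = 2)
  idt <- affineTransform()
  same <- deformPhantom(p, idt, noiseSd = 0)
  expect_identical(volData(intensity(same)), volData(intensity(p)))
  expect_identical(volData(labels3d(same)), volData(labels3d(p)))

  tr <- affineTransform(b = c(2, 0, 0))
  shifted <- deformPhantom(p, tr, noiseSd = 0)
  expect_equal(landmarks(shifted), landmarks(p) + rep(c(2, 0, 0), each = nrow(landmarks(p))))
  expect_true(all(unique(as.vector(volData(labels3d(shifted)))) %in%
                    c(0, 1, 2, 3)))
  expect_setequal(setdiff(unique(as.vector(volData(labels3d(shifted)))), 0),
                  1:3)

  expect_error(deformPhantom(p, affineTransform(diag(c(-1, 1, 1)))))
})

test_that("a known affine and its analytic inverse recover landmarks", {
  p <- makePhantomBrain(c(32, 40, 44), 3, seed = 4)
  A <- axocarto:::eulerRotation(0.1, -0.05, 0.08) %*% diag(c(1.05, 0.95, 1.02))
  t <- axocarto:::centeredAffine(A, c(1.5, -2, 0.5), c(32, 40, 44))
  fwd <- deformPhantom(p, t, noiseSd = 0)
  back <- transformPoints(axocarto:::invertAffineMat(t), landmarks(fwd))
  expect_lt(max(abs(back - landmarks(p))), 0.5)
})

test_that("scatterPoints draws the requested counts inside each region", {
  p <- makePhantomBrain(c(32, 40, 44), 3, seed = 5)
  pts <- scatterPoints(labels3d(p), list(`1` = 5, `2` = 0, `3` = 7), seed = 6)
  expect_equal(sum(pts$region_id == 1), 5L)
  expect_equal(sum(pts$region_id == 2), 0L)
  expect_equal(sum(pts$region_id == 3), 7L)
  lab <- volData(labels3d(p))
  for (i in seq_len(nrow(pts))) {
    expect_equal(lab[pts$z[i] + 1, pts$y[i] + 1, pts$x[i] + 1],
                 pts$region_id[i])
  }
  expect_identical(scatterPoints(labels3d(p), list(`1` = 5), seed = 6),
                   scatterPoints(labels3d(p), list(`1` = 5), seed = 6))
  expect_error(scatterPoints(labels3d(p), list(`9` = 1), seed = 0), "empty")
})

test_that("region tables validate ids and forest structure", {
  expect_silent(regionTable(defaultRegionTable()))
  bad <- data.frame(region_id = c(1, 1), acronym = c("a", "b"),
                    parent_id = c(NA, NA))
  expect_error(regionTable(bad), "unique")
  cyc <- data.frame(region_id = c(1, 2), acronym = c("a", "b"),
                    parent_id = c(2, 1))
  expect_error(regionTable(cyc), "cycle")
  expect_setequal(defaultRegionTable()$acronym,
                  c("CTX", "CP", "HPF", "BS", "CB", "CBX",
                    "act", "fr", "mtt", "Hb", "IPN"))
})
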
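ax <- makeAxonCube(32, 1, 2.0, 10, seed = 1)
ar <- makeArtifactCube(32, "vessel", seed = 2)

test_that("cutmix partitions voxels between the two sources", {
  out <- cutmix(ax, ar, frac = 0.3, seed = 3)
  A <- volData(intensity(ax))
  B <- volData(intensity(ar))
  O <- volData(intensity(out))
  expect_true(all(O == A | O == B))
  # annotation cleared inside the pasted box
  rec <- out@chain[[length(out@chain)]]
  box <- list(rec$low + 1, rec$low + rec$extent)
  annBox <- volData(annotation(out))[box[[1]][1]:box[[2]][1],
                                     box[[1]][2]:box[[2]][2],
                                     box[[1]][3]:box[[2]][3]]
  expect_equal(sum(annBox), 0)
  expect_identical(provenance(out), "augmented")
  # frac -> 0 limit: unchanged pair
  same <- cutmix(ax, ar, frac = 1e-9, seed = 3)
  expect_identical(volData(intensity(same)), A)
  small <- makeArtifactCube(16, "edge", seed = 1)
  expect_error(cutmix(ax, small, 0.3, 1), "shape")
})

test_that("histogram matching preserves axon intensities bit-exactly", {
  out <- histogramMatchAug(ax, intensity(ar), seed = 4)
  axv <- volData(annotation(ax)) > 0
  expect_identical(volData(intensity(out))[axv], volData(intensity(ax))[axv])
  expect_identical(volData(annotation(out)), volData(annotation(ax)))
  # the background KS distance to the reference must not increase
  ks <- function(a, b) stats::ks.test(a, b)$statistic
  bg <- !axv
  before <- suppressWarnings(ks(volData(intensity(ax))[bg],
                                as.vector(volData(intensity(ar)))))
  after <- suppressWarnings(ks(volData(intensity(out))[bg],
                               as.vector(volData(intensity(ar)))))
  expect_lte(after, before + 1e-8)
  expect_error(histogramMatchAug(ax, array(5, c(4, 4, 4))), "distinct")
})

test_that("matching a cube to itself changes background only by quantization",
{
  # an artifact pair has an empty annotation, so its background histogram IS
  # its histogram: self-matching must be the identity up to quantization
  out <- histogramMatchAug(ar, intensity(ar), seed = 5)
  src <- as.vector(volData(intensity(ar)))
  gap <- max(diff(sort(src)))
  expect_lt(max(abs(as.vector(volData(intensity(out))) - src)),
            2 * gap + 1e-6)
})

test_that("local contrast scales selected components only", {
  idt <- localContrastAug(ax, c(1, 1), seed = 6)
  expect_equal(volData(intensity(idt)), volData(intensity(ax)))
  out <- localContrastAug(ax, c(1.5, 2), seed = 6)
  expect_identical(volData(annotation(out)), volData(annotation(ax)))
  changed <- volData(intensity(out)) != volData(intensity(ax))
  expect_true(all(volData(annotation(ax))[changed] == 1))
  emptyPair <- CubePair(volData(intensity(ar)), array(0, c(32, 32, 32)))
  expect_warning(same <- localContrastAug(emptyPair, c(1, 2), seed = 1),
                 "empty")
  expect_identical(volData(intensity(same)), volData(intensity(ar)))
})

test_that("standard geometric ops move both grids, photometric ops neither", {
  r0 <- standardAug(ax, "rotation", list(angle = 0, axis = 1), seed = 7)
  expect_equal(volData(intensity(r0)), volData(intensity(ax)))
  r <- ax
  for (i in 1:4) r <- standardAug(r, "rotation", list(angle = 90, axis = 2),
                                  seed = 7)
  expect_lt(max(abs(volData(intensity(r)) - volData(intensity(ax)))), 1e-9)
  expect_identical(volData(annotation(r)), volData(annotation(ax)))
  for (op in c("gaussian_noise", "blur", "brightness")) {
    out <- standardAug(ax, op, seed = 8)
    expect_identical(volData(annotation(out)), volData(annotation(ax)))
  }
  sc <- standardAug(ax, "scaling", list(factor = 1.1), seed = 9)
  expect_identical(dim(volData(intensity(sc))), dim(volData(intensity(ax))))
  expect_true(all(volData(annotation(sc)) %in% c(0, 1)))
  expect_error(standardAug(ax, "warp", seed = 1), "unknown op")
})

test_that("augmentPool applies the recipe deterministically", {
  axons <- list(ax, makeAxonCube(32, 2, 2.0, 8, seed = 10))
  artifacts <- list(ar, makeArtifactCube(32, "bright_spot", seed = 11))
  out <- augmentPool(axons, artifacts, augmentRecipe(), seed = 0)
  expect_length(out, 10L * 2L)
  expect_true(all(vapply(out, provenance, "") == "augmented"))
  expect_true(all(vapply(out, function(p) length(p@chain) > 0, TRUE)))
  out2 <- augmentPool(axons, artifacts, augmentRecipe(), seed = 0)
  expect_identical(lapply(out, function(p) volData(intensity(p))),
                   lapply(out2, function(p) volData(intensity(p))))
  none <- augmentRecipe(cutmix = 0, histogramMatch = 0, localContrast = 0,
                        standard = 0)
  expect_length(augmentPool(axons, artifacts, none, seed = 0), 0L)
  expect_error(augmentPool(axons, list(), augmentRecipe(), seed = 0),
               "artifact pool")
})

test_that("replaying a recorded operator chain reproduces the output", {
  out <- augmentPool(list(ax), list(ar), augmentRecipe(), seed = 42)
  cm <- Filter(function(p) p@chain[[1]]$op == "cutmix", out)[[1]]
  rec <- cm@chain[[1]]
  replay <- cutmix(ax, ar, frac = rec$frac, seed = rec$seed)
  expect_identical(volData(intensity(replay)), volData(intensity(cm)))
  expect_identical(volData(annotation(replay)), volData(annotation(cm)))
})
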
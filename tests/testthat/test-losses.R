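test_that("weighted sigmoid BCE matches closed forms", {
  one <- array(0, c(1, 1, 1))
  expect_equal(axonBCE(one, array(0, c(1, 1, 1))), log(2))
  expect_equal(axonBCE(one, array(1, c(1, 1, 1)), wPos = 3), 3 * log(2))
  # perfect extreme logits drive the loss to zero
  expect_lt(axonBCE(array(50, c(2, 2, 2)), array(1, c(2, 2, 2))), 1e-10)
  expect_lt(axonBCE(array(-50, c(2, 2, 2)), array(0, c(2, 2, 2))), 1e-10)
  expect_error(axonBCE(one, array(0.5, c(1, 1, 1))), "binary")
})

test_that("adversarial loss matches its expectation form", {
  expect_equal(ganLoss(0.5, 0.5), 2 * log(0.5))
  expect_gt(ganLoss(0.999, 0.001), -0.01)  # supremum approached at (1, 0)
  withr::with_seed(1, {
    r <- stats::runif(100, 0.1, 0.9)
    f <- stats::runif(100, 0.1, 0.9)
    perm <- sample(100)
  })
  expect_equal(ganLoss(r, f), ganLoss(r[perm], f[perm]))
  expect_error(ganLoss(c(0.5, 1), 0.5), "inside")
})

test_that("cycle loss is mean L1 over both directions", {
  x <- array(stats::runif(8), c(2, 2, 2))
  y <- array(stats::runif(8), c(2, 2, 2))
  expect_equal(cycleLoss(x, x, y, y), 0)
  expect_equal(cycleLoss(x, x + 0.25, y, y), 0.25)
  expect_gte(cycleLoss(x, y, y, x), 0)
  expect_error(cycleLoss(x, array(0, c(3, 3, 3)), y, y), "shape")
})

test_that("outline BCE is summed and scales with voxel count", {
  expect_equal(outlineBCE(array(0.5, c(2, 2, 2)), array(0, c(2, 2, 2))),
               8 * log(2))
  expect_lt(outlineBCE(array(1 - 1e-9, c(2, 2, 2)), array(1, c(2, 2, 2))),
            1e-6)
  l1 <- outlineBCE(array(0.3, c(2, 2, 2)), array(0, c(2, 2, 2)))
  l2 <- outlineBCE(array(0.3, c(4, 2, 2)), array(0, c(4, 2, 2)))
  expect_equal(l2, 2 * l1)
  expect_warning(outlineBCE(array(c(0, 0.5), c(2, 1, 1)),
                            array(0, c(2, 1, 1))), "clamped")
})

test_that("multiview semi-supervised components add up", {
  p <- array(0.7, c(4, 4))
  g <- array(1, c(4, 4))
  u <- array(0.4, c(4, 4))
  out <- semiMultiviewLoss(p, g, u, u, u, u)
  expect_equal(out$qua, 0)
  expect_equal(out$l3d, 0)
  u2 <- u; u2[1, 1] <- u[1, 1] + 1
  expect_equal(semiMultiviewLoss(p, g, u, u2, u, u)$qua, 1)
  v <- semiMultiviewLoss(p, g, u, u2, u, u2)
  expect_equal(v$total, 2 * v$view + v$l3d)
  expect_equal(v$view, v$sup + v$qua)
})

test_that("mutual information matches the two-bin closed form", {
  X <- array(rep(c(0, 1), each = 32), c(4, 4, 4))
  expect_equal(simMI(X, X, bins = 2), -log(2))
  expect_warning(z <- simMI(X, array(5, c(4, 4, 4)), bins = 4), "degenerate")
  expect_equal(z, 0)
  withr::with_seed(2, {
    Y <- array(stats::runif(64), c(4, 4, 4))
  })
  expect_equal(simMI(X, Y, 8), simMI(Y, X, 8))
})

test_that("local cross-correlation detects affine dependence", {
  withr::with_seed(3, {
    X <- array(stats::runif(6^3), c(6, 6, 6))
    N <- array(stats::runif(12^3), c(12, 12, 12))
    M <- array(stats::runif(12^3), c(12, 12, 12))
  })
  expect_equal(simLCC(X, 2 * X + 5, 3), -1)
  expect_lt(abs(simLCC(N, M, 5)), 0.25)   # independent noise: near zero
  expect_gte(simLCC(N, M, 5), -1)
  expect_lte(simLCC(N, M, 5), 1)
  expect_error(simLCC(X, X, 9), "exceeds")
})

test_that("root-mean-square similarity matches closed forms", {
  x <- array(stats::runif(27), c(3, 3, 3))
  expect_equal(simMSE(x, x), 0)
  expect_equal(simMSE(x, x + 0.4), 0.4)
  expect_equal(simMSE(x, x * 2), simMSE(x * 2, x))
})

test_that("affine penalties match the printed forms", {
  expect_equal(affineIdentityPenalty(affineTransform()), 0)
  expect_equal(affineIdentityPenalty(affineTransform(diag(c(2, 1, 1)))), 1)
  expect_equal(affineIdentityPenalty(affineTransform(b = c(1, 2, 2))), 9)
  expect_equal(affineScalingPenalty(affineTransform()), 0)
  expect_equal(affineScalingPenalty(affineTransform(diag(c(2, 1, 1)))), 1)
  expect_equal(affineScalingPenalty(affineTransform(), "literal_rank"), 2)
})

test_that("field smoothness is the mean L1 forward-difference gradient", {
  z <- deformationField(array(0, c(4, 4, 4, 3)))
  expect_equal(fieldSmoothness(z), 0)
  cst <- deformationField(array(2.5, c(4, 4, 4, 3)))
  expect_equal(fieldSmoothness(cst), 0)
  # unit ramp: independent enumeration of all forward differences
  d <- array(0, c(4, 4, 4, 3))
  d[, , , 1] <- axocarto:::coordGrid(c(4, 4, 4))[, 1]  # Phi_z = z
  ramp <- deformationField(d)
  tot <- 0; cnt <- 0
  for (k in 1:3) for (ax in 1:3) {
    diffs <- apply(d[, , , k], setdiff(1:3, ax), diff)
    tot <- tot + sum(abs(diffs))
    cnt <- cnt + length(diffs)
  }
  expect_equal(fieldSmoothness(ramp), tot / cnt)
  expect_gt(fieldSmoothness(ramp), 0)
})

test_that("the approximate field inverse behaves to first order", {
  z <- deformationField(array(0, c(5, 5, 5, 3)))
  expect_equal(fieldDisp(approxInverseField(z)), fieldDisp(z))
  cst <- array(0, c(8, 8, 8, 3)); cst[, , , 2] <- 1.25
  inv <- approxInverseField(deformationField(cst))
  expect_equal(max(abs(fieldDisp(inv)[, , , 2] + 1.25)), 0)
  expect_equal(max(abs(fieldDisp(inv)[, , , c(1, 3)])), 0)
  # composition residual small relative to the field for smooth fields with
  # max |disp| <= 2 voxels (rms norms over the grid interior; the first-order
  # inverse error grows with the field gradient, so the relative bound is a
  # smoothness statement)
  f <- smoothField(c(32, 32, 32), sd = 0.3, ctrlDims = c(3, 3, 3), seed = 11)
  d <- fieldDisp(f)
  expect_lte(max(abs(d)), 2)
  finv <- approxInverseField(f)
  g <- axocarto:::coordGrid(c(32, 32, 32))
  pos <- g + matrix(d, ncol = 3)
  for (k in 1:3) pos[, k] <- pmin(pmax(pos[, k], 0), 31)  # clamp, as Phi^-1
  inner <- array(FALSE, c(32, 32, 32))
  inner[8:24, 8:24, 8:24] <- TRUE
  resv <- NULL
  fv <- NULL
  for (k in 1:3) {
    comp <- axocarto:::sampleAt(fieldDisp(finv)[, , , k], pos, "linear")
    resv <- c(resv, (d[, , , k] + comp)[inner])
    fv <- c(fv, d[, , , k][inner])
  }
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(resv), 0.1 * rms(fv))
})

test_that("inverse consistency is zero for trivial cases and shrinks with
           the field", {
  Y <- array(stats::runif(10^3), c(10, 10, 10))
  z <- deformationField(array(0, c(10, 10, 10, 3)))
  expect_equal(inverseConsistency(Y, z), 0)
  cY <- array(3, c(10, 10, 10))
  f <- smoothField(c(10, 10, 10), sd = 1, seed = 5)
  expect_equal(inverseConsistency(cY, f), 0)
  smooth <- gaussianSmooth <- axocarto:::gaussianSmooth3d(Y, 1.5)
  v1 <- inverseConsistency(smooth, f)
  half <- deformationField(fieldDisp(f) / 2)
  quarter <- deformationField(fieldDisp(f) / 4)
  expect_gt(v1, inverseConsistency(smooth, half))
  expect_gt(inverseConsistency(smooth, half),
            inverseConsistency(smooth, quarter))
})

test_that("the multi-constraint objective weights channels and stages", {
  withr::with_seed(6, {
    X <- array(stats::runif(12^3) * 10, c(12, 12, 12))
    M <- array((axocarto:::coordGrid(c(12, 12, 12))[, 1] < 6) * 1,
               c(12, 12, 12))
  })
  chans <- list(
    list(x = X, y = X, spec = similaritySpec("mi", 0.70)),
    list(x = X, y = X, spec = similaritySpec("lcc", 0.15, window = 5)),
    list(x = M, y = M, spec = similaritySpec("mse", 0.15))
  )
  base <- multiconstraintObjective(chans, "rigid")
  sims <- c(simMI(X, X, 32), simLCC(X, X, 5), simMSE(M, M))
  expect_equal(base, sum(c(0.70, 0.15, 0.15) * sims))
  # rigid stage adds no penalty; deformable with a zero field adds exactly 0
  zf <- deformationField(array(0, c(12, 12, 12, 3)))
  expect_equal(multiconstraintObjective(chans, "deformable", f = zf), base)
  # linearity in the weights
  chans2 <- chans
  chans2[[1]]$spec <- similaritySpec("mi", 0.55)
  chans2[[3]]$spec <- similaritySpec("mse", 0.30)
  expect_equal(multiconstraintObjective(chans2, "rigid") - base,
               -0.15 * sims[1] + 0.15 * sims[3])
  badw <- chans
  badw[[1]]$spec <- similaritySpec("mi", 0.5)
  expect_error(multiconstraintObjective(badw, "rigid"), "sum to 1")
  expect_equal(defaultChannelWeights(6)[1], 0.70)
  expect_equal(sum(defaultChannelWeights(6)), 1)
})

test_that("losses are invariant to congruent axis permutations", {
  withr::with_seed(7, {
    X <- array(stats::runif(6 * 8 * 10), c(6, 8, 10))
    Y <- array(stats::runif(6 * 8 * 10), c(6, 8, 10))
    L <- array(stats::runif(6 * 8 * 10) < 0.3, c(6, 8, 10)) * 1
  })
  pm <- c(3, 1, 2)
  expect_equal(simMI(aperm(X, pm), aperm(Y, pm), 8), simMI(X, Y, 8))
  expect_equal(simMSE(aperm(X, pm), aperm(Y, pm)), simMSE(X, Y))
  expect_equal(simLCC(aperm(X, pm), aperm(Y, pm), 3), simLCC(X, Y, 3))
  expect_equal(axonBCE(aperm(X, pm), aperm(L, pm)), axonBCE(X, L))
})

test_that("MI and LCC similarities are minimized at self-alignment", {
  p <- makePhantomBrain(c(24, 28, 32), 3, seed = 8)
  X <- volData(intensity(p))
  atIdentity_mi <- simMI(X, X, 16)
  atIdentity_lcc <- simLCC(X, X, 5)
  for (shift in list(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3), c(1, 1, 1))) {
    Y <- axocarto:::shift3d(X, shift[1], shift[2], shift[3])
    expect_lt(atIdentity_mi, simMI(X, Y, 16))
    expect_lt(atIdentity_lcc, simLCC(X, Y, 5))
  }
})
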
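# Shared fixture builders.  Everything is generated in code from fixed seeds.

# registration bundle (original + per-region masks + landmarks) of a phantom
phantomBundle <- function(p) {
  labv <- volData(labels3d(p))
  ids <- sort(setdiff(unique(as.vector(labv)), 0))
  masks <- stats::setNames(lapply(ids, function(id) Volume((labv == id) * 1)),
                           as.character(ids))
  registrationBundle(intensity(p), regionMasks = masks,
                     landmarks = landmarks(p))
}

# smooth random deformation field: a small control grid of normal
# displacements trilinearly upsampled to the full shape
smoothField <- function(shape, sd = 1.5, ctrlDims = c(4, 4, 4), seed = 7) {
  disp <- array(0, c(shape, 3))
  withr::with_seed(seed, {
    for (k in 1:3) {
      ctl <- array(stats::rnorm(prod(ctrlDims), sd = sd), ctrlDims)
      pos <- sweep(axocarto:::coordGrid(shape), 2,
                   (shape - 1) / (ctrlDims - 1), "/")
      disp[, , , k] <- array(axocarto:::sampleAt(ctl, pos, "linear"), shape)
    }
  })
  deformationField(disp)
}

# random thin tubular mask (random-walk curve) for skeletonization tests
randomCurveMask <- function(extent = 24, seed = 0) {
  withr::with_seed(seed, {
    m <- array(FALSE, rep(extent, 3))
    p <- runif(3, 0.3, 0.7) * (extent - 1)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    for (s in seq_len(extent * 2)) {
      dir <- dir + stats::rnorm(3, sd = 0.2)
      dir <- dir / sqrt(sum(dir^2))
      p <- pmin(pmax(p + dir, 1), extent - 2)
      v <- round(p) + 1
      m[v[1], v[2], v[3]] <- TRUE
    }
    m
  })
}

# composition of two affine point maps: a after b
composeAffine <- function(a, b) {
  affineTransform(a@A %*% b@A, as.numeric(a@A %*% b@b + a@b))
}

# rotation angle (degrees) and center displacement (voxels) of a near-identity
# affine map; used to measure recovery error of transform compositions
affineError <- function(t, shape) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(t@A)) - 1) / 2))) * 180 / pi
  ctr <- (shape - 1) / 2
  shift <- sqrt(sum((transformPoints(t, ctr) - ctr)^2))
  c(angle = ang, shift = shift)
}
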
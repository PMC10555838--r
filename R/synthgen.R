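# Synthetic data with exact ground truth: axon cubes (tubular branching
# trees), artifact cubes (vessels, bright spots, edges) and phantom brains
# (nested ellipsoidal regions), so the whole pipeline is testable without
# external datasets.

#' Default hierarchical region table
#'
#' The six major mouse brain regions used as default registration constraints
#' (CTX, CP, HPF, BS, CB, CBX — cerebellar cortex nested under cerebellum)
#' followed by five small structures (act, fr, mtt, Hb, IPN).  Region id 0 is
#' reserved for outside-brain.
#'
#' @return data.frame with columns `region_id`, `acronym`, `parent_id`
#'   (NA for roots).
#' @export
defaultRegionTable <- function() {
  regionTable(data.frame(
    region_id = 1:11,
    acronym = c("CTX", "CP", "HPF", "BS", "CB", "CBX",
                "act", "fr", "mtt", "Hb", "IPN"),
    parent_id = c(NA, NA, NA, NA, NA, 5L, NA, NA, NA, NA, 4L)
  ))
}

#' Validate a region table
#'
#' Checks that region ids are unique positive integers, that 0 is not used
#' (it is reserved for outside-brain) and that parent links form a forest.
#'
#' @param df data.frame with columns `region_id`, `acronym`, `parent_id`.
#' @return the validated data.frame.
#' @export
regionTable <- function(df) {
  stopifnot(all(c("region_id", "acronym", "parent_id") %in% names(df)))
  if (anyDuplicated(df$region_id)) stop("region ids must be unique")
  if (any(df$region_id <= 0)) stop("region ids must be positive (0 reserved)")
  par <- df$parent_id
  if (any(!is.na(par) & !par %in% df$region_id)) {
    stop("parent_id refers to an unknown region")
  }
  # forest check: following parents must terminate
  idx <- match(par, df$region_id)
  for (i in seq_len(nrow(df))) {
    seen <- integer(0)
    j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stop("cycle in parent links")
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  df
}

# rasterize centerline points as tubes: returns list(annotation, skeletonIdx,
# intensity contribution); points is an n x 3 matrix of continuous (z,y,x)
rasterizeTube <- function(shape, points, radius, peak) {
  ann <- array(FALSE, shape)
  intens <- array(0, shape)
  r <- ceiling(radius + 2)
  off <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  d2 <- off$dz^2 + off$dy^2 + off$dx^2
  keep <- d2 <= (radius + 2)^2
  off <- as.matrix(off[keep, ])
  sigma <- radius  # Gaussian cross-section: sigma tied to the tube radius
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    vox <- sweep(off, 2, round(p), "+")
    inb <- vox[, 1] >= 0 & vox[, 2] >= 0 & vox[, 3] >= 0 &
      vox[, 1] < shape[1] & vox[, 2] < shape[2] & vox[, 3] < shape[3]
    vox <- vox[inb, , drop = FALSE]
    dd <- sweep(vox, 2, p, "-")
    dist2 <- rowSums(dd^2)
    lin <- vox[, 1] + shape[1] * (vox[, 2] + shape[2] * vox[, 3]) + 1
    ann[lin[dist2 <= radius^2]] <- TRUE
    g <- peak * exp(-dist2 / (2 * sigma^2))
    intens[lin] <- pmax(intens[lin], g)
  }
  list(annotation = ann, intensity = intens)
}

# a branching random-walk centerline tree; returns a list of polylines
# (matrices of continuous points, ~1 voxel apart)
growTree <- function(shape, maxBranches = 4L) {
  start <- runif(3, 0.15, 0.85) * (shape - 1)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  segments <- list()
  stack <- list(list(p = start, dir = dir, depth = 0L))
  nb <- 0L
  while (length(stack) > 0) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    len <- round(runif(1, 0.4, 0.9) * min(shape))
    pts <- matrix(0, len, 3)
    p <- st$p
    dir <- st$dir
    for (s in seq_len(len)) {
      dir <- dir + stats::rnorm(3, sd = 0.15)
      dir <- dir / sqrt(sum(dir^2))
      p <- p + dir
      p <- pmin(pmax(p, 1), shape - 2)  # reflectless clamp at faces
      pts[s, ] <- p
      if (nb < maxBranches && st$depth < 2L && runif(1) < 0.02) {
        nb <- nb + 1L
        ndir <- dir + stats::rnorm(3, sd = 0.8)
        ndir <- ndir / sqrt(sum(ndir^2))
        stack[[length(stack) + 1L]] <-
          list(p = p, dir = ndir, depth = st$depth + 1L)
      }
    }
    segments[[length(segments) + 1L]] <- pts
  }
  segments
}

#' Generate a synthetic axon cube with exact ground truth
#'
#' Branching random-walk centerline trees are rasterized as tubes with a
#' Gaussian intensity cross-section (sigma equal to the tube radius,
#' mimicking light-sheet point-spread blur) over a low background with
#' additive Gaussian noise.  The ground-truth annotation contains every voxel
#' within `radius` of a centerline; the ground-truth skeleton is the
#' thinned centerline raster (single-voxel-wide, a subset of the
#' annotation).
#'
#' @param extent cube edge length (>= 16).
#' @param nTrees number of axon trees (>= 1).
#' @param radius tube radius in voxels (>= 1).
#' @param snr peak signal over noise standard deviation (> 0).
#' @param seed integer seed; the same seed reproduces the pair exactly.
#' @return a [CubePair] with provenance "synthetic".
#' @export
makeAxonCube <- function(extent = 64L, nTrees = 2L, radius = 2, snr = 10,
                         seed = 0L) {
  extent <- as.integer(extent)
  if (extent < 16L) stop("extent must be >= 16")
  if (nTrees < 1L) stop("nTrees must be >= 1")
  if (radius < 1) stop("radius must be >= 1")
  if (snr <= 0) stop("snr must be > 0")
  shape <- rep(extent, 3L)
  noiseSd <- 10
  peak <- snr * noiseSd
  background <- 20
  withSeed(seed, {
    ann <- array(FALSE, shape)
    intens <- array(0, shape)
    cl <- array(FALSE, shape)
    for (tr in seq_len(nTrees)) {
      for (seg in growTree(shape)) {
        rs <- rasterizeTube(shape, seg, radius, peak)
        ann <- ann | rs$annotation
        intens <- pmax(intens, rs$intensity)
        vox <- round(seg)
        lin <- vox[, 1] + shape[1] * (vox[, 2] + shape[2] * vox[, 3]) + 1
        cl[lin] <- TRUE
      }
    }
    if (!any(ann)) stop("parameters produced zero axon voxels")
    data <- background + intens + stats::rnorm(length(intens), sd = noiseSd)
    data <- pmax(data, 0)
  })
  skel <- skeletonizeMask(cl) & ann  # single-voxel-wide, inside the tubes
  storage.mode(skel) <- "double"
  CubePair(IntensityCube(array(data, shape)), AnnotationCube(ann * 1),
           skeleton = skel, provenance = "synthetic", seed = seed)
}

#' Generate a synthetic artifact cube
#'
#' Emulates the non-axonal structures a user would harvest as negative
#' examples: a thick bright curved vessel (radius much larger than an axon),
#' Gaussian bright spots, or a bright planar band near one face.  The paired
#' ground-truth annotation of an artifact cube is all-zero.
#'
#' @param extent cube edge length (>= 16).
#' @param kind "vessel", "bright_spot" or "edge".
#' @param seed integer seed.
#' @return a [CubePair] with all-zero annotation, provenance "synthetic".
#' @export
makeArtifactCube <- function(extent = 64L, kind = c("vessel", "bright_spot",
                                                    "edge"), seed = 0L) {
  extent <- as.integer(extent)
  if (extent < 16L) stop("extent must be >= 16")
  kind <- match.arg(kind)
  shape <- rep(extent, 3L)
  noiseSd <- 10
  background <- 20
  withSeed(seed, {
    intens <- array(0, shape)
    if (kind == "vessel") {
      seg <- growTree(shape)[[1]]
      rs <- rasterizeTube(shape, seg, radius = max(6, extent / 10),
                          peak = 8 * noiseSd)
      intens <- rs$intensity
    } else if (kind == "bright_spot") {
      nspot <- sample(3:6, 1)
      ctr <- matrix(runif(3 * nspot, 0.1, 0.9), ncol = 3) %*% diag(shape - 1)
      g <- coordGrid(shape)
      for (i in seq_len(nspot)) {
        d2 <- rowSums(sweep(g, 2, ctr[i, ], "-")^2)
        s <- runif(1, 2, 4)
        intens <- pmax(intens, array(8 * noiseSd * exp(-d2 / (2 * s^2)),
                                     shape))
      }
    } else {
      axis <- sample(1:3, 1)
      pos <- sample(c(2, shape[axis] - 3), 1)
      width <- 2
      idx <- slice.index(intens, axis)
      prof <- 8 * noiseSd * exp(-((idx - 1) - pos)^2 / (2 * width^2))
      intens <- prof
    }
    data <- background + intens + stats::rnorm(length(intens), sd = noiseSd)
    data <- pmax(data, 0)
  })
  CubePair(IntensityCube(array(data, shape)),
           AnnotationCube(array(0, shape)),
           provenance = "synthetic", seed = seed)
}

#' Generate a phantom brain with labeled regions and landmarks
#'
#' A smooth ellipsoidal "brain" containing `nRegions` disjoint ellipsoidal
#' regions with distinct mean intensities, labeled with the first `nRegions`
#' ids of the region table.  Landmarks sit at the region centers.  The
#' default shape equals the coarsest level of the registration pyramid so
#' registration tests run fast.
#'
#' @param shape integer(3) extents (default c(80, 114, 132)).
#' @param nRegions number of labeled regions (>= 2).
#' @param seed integer seed.
#' @param table region table supplying ids and acronyms.
#' @param noiseSd additive intensity noise standard deviation.
#' @return a [PhantomBrain].
#' @export
makePhantomBrain <- function(shape = c(80L, 114L, 132L), nRegions = 6L,
                             seed = 0L, table = defaultRegionTable(),
                             noiseSd = 4) {
  shape <- as.integer(shape)
  if (nRegions < 2L) stop("nRegions must be >= 2")
  if (nRegions > nrow(table)) stop("region table too small")
  g <- coordGrid(shape)
  ctr <- (shape - 1) / 2
  semi <- 0.45 * (shape - 1)
  inBrain <- rowSums(sweep(sweep(g, 2, ctr, "-"), 2, semi, "/")^2) <= 1
  rmin <- 0.09 * min(shape)
  rmax <- 0.16 * min(shape)
  withSeed(seed, {
    centers <- matrix(0, 0, 3)
    radii <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(centers) < nRegions) {
      tries <- tries + 1L
      if (tries > 2000L) {
        stop("shape too small to host ", nRegions, " disjoint regions")
      }
      cand <- ctr + (runif(3) * 2 - 1) * semi * 0.62
      rr <- runif(3, rmin, rmax)
      ok <- TRUE
      if (nrow(centers) > 0) {
        for (i in seq_len(nrow(centers))) {
          gap <- sqrt(sum((cand - centers[i, ])^2))
          if (gap < max(rr) + max(radii[i, ]) + 2) { ok <- FALSE; break }
        }
      }
      if (ok) {
        centers <- rbind(centers, cand)
        radii <- rbind(radii, rr)
      }
    }
    labels <- array(0, shape)
    intens <- array(0, shape)
    intens[inBrain] <- 100
    # smooth intensity gradient across the brain
    intens <- intens + inBrain * (g[, 3] / max(shape)) * 20
    ids <- table$region_id[seq_len(nRegions)]
    means <- 160 + 35 * seq_len(nRegions)
    for (i in seq_len(nRegions)) {
      inside <- rowSums(sweep(sweep(g, 2, centers[i, ], "-"), 2, radii[i, ],
                              "/")^2) <= 1
      labels[inside] <- ids[i]
      intens[inside] <- means[i]
    }
    intens <- intens + stats::rnorm(length(intens), sd = noiseSd) *
      as.numeric(inBrain)
    intens <- pmax(intens, 0)
    landmarks <- round(centers)
  })
  dimnames(landmarks) <- NULL
  new("PhantomBrain",
      intensity = Volume(array(intens, shape)),
      labels = LabelVolume(array(labels, shape), regionTable = table),
      table = table, landmarks = landmarks)
}

#' Deform a phantom brain by a known transform
#'
#' Warps the phantom by an [AffineTransform3D] (forward point map y = A x +
#' b) or a [DeformationField]: intensity is resampled with trilinear
#' interpolation, labels with nearest-neighbor, and landmarks are mapped
#' exactly through the point map (for a field, through its first-order
#' push-forward, the negated-and-resampled approximate inverse).  Additive
#' Gaussian noise is then applied to the intensity.
#'
#' @param p a [PhantomBrain].
#' @param t an [AffineTransform3D] or [DeformationField].
#' @param noiseSd intensity noise standard deviation (0 for none).
#' @param seed integer seed for the noise.
#' @return the deformed [PhantomBrain].
#' @export
deformPhantom <- function(p, t, noiseSd = 0, seed = 0L) {
  stopifnot(is(p, "PhantomBrain"))
  shape <- dim(p@intensity@data)
  g <- coordGrid(shape)
  if (is(t, "AffineTransform3D")) {
    if (det(t@A) <= 0) stop("non-invertible affine (determinant <= 0)")
    inv <- invertAffineMat(t)
    src <- transformPoints(inv, g)
    lm <- transformPoints(t, p@landmarks)
  } else if (is(t, "DeformationField")) {
    checkCongruent(t@disp[, , , 1], p@intensity@data)
    src <- g + matrix(t@disp, ncol = 3)
    fwd <- approxInverseField(t)
    lmDisp <- vapply(1:3, function(k) {
      sampleAt(fwd@disp[, , , k], p@landmarks)
    }, numeric(nrow(p@landmarks)))
    lm <- p@landmarks + matrix(lmDisp, ncol = 3)
  } else {
    stop("t must be an AffineTransform3D or a DeformationField")
  }
  intens <- array(sampleAt(p@intensity@data, src, "linear"), shape)
  labs <- array(sampleAt(p@labels@data, src, "nearest"), shape)
  if (noiseSd > 0) {
    withSeed(seed, {
      intens <- pmax(intens + stats::rnorm(length(intens), sd = noiseSd), 0)
    })
  }
  new("PhantomBrain",
      intensity = Volume(intens, p@intensity@spacing),
      labels = LabelVolume(labs, p@labels@spacing,
                           regionTable = p@table),
      table = p@table, landmarks = lm)
}

#' Scatter points uniformly inside labeled regions
#'
#' Draws the requested number of points per region, uniformly over that
#' region's voxels, as a test double for detected-cell coordinates.
#'
#' @param labels a [LabelVolume] (or integer 3D array).
#' @param counts named list/vector: region id -> number of points.
#' @param seed integer seed.
#' @return data.frame with columns z, y, x (0-based voxel coordinates) and
#'   region_id.
#' @export
scatterPoints <- function(labels, counts, seed = 0L) {
  a <- if (is(labels, "Volume")) labels@data else labels
  counts <- unlist(counts)
  ids <- as.integer(names(counts))
  if (any(is.na(ids))) stop("counts must be named by region id")
  out <- NULL
  withSeed(seed, {
    for (i in seq_along(ids)) {
      n <- counts[i]
      vox <- which(a == ids[i])
      if (!length(vox)) stop("region ", ids[i], " is empty or absent")
      if (n == 0) next
      pick <- vox[sample.int(length(vox), n, replace = TRUE)]
      d <- dim(a)
      z <- (pick - 1) %% d[1]
      y <- ((pick - 1) %/% d[1]) %% d[2]
      x <- (pick - 1) %/% (d[1] * d[2])
      out <- rbind(out, data.frame(z = z, y = y, x = x, region_id = ids[i]))
    }
  })
  if (is.null(out)) {
    out <- data.frame(z = integer(0), y = integer(0), x = integer(0),
                      region_id = integer(0))
  }
  rownames(out) <- NULL
  out
}
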
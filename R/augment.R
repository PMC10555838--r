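# Training-pool augmentation: CutMix, background histogram matching, local
# contrast enhancement, and standard geometric/photometric operators, plus
# the pool expander that turns ~100 annotated axon cubes into >= 1,000
# training pairs.

#' Augmentation recipe
#'
#' Per-axon-cube counts of each operator and the parameter ranges of the
#' standard operators.  The default recipe yields 10 derivatives per axon
#' cube, so a pool of 100 axon cubes expands to at least 1,000 annotated
#' cubes.
#'
#' @param cutmix number of CutMix derivatives per axon cube.
#' @param histogramMatch number of histogram-matching derivatives.
#' @param localContrast number of local-contrast derivatives.
#' @param standard number of standard-operator derivatives (operator drawn
#'   uniformly from `standardOps`).
#' @param standardOps the standard operator set.
#' @param cutmixFrac relative volume of the pasted artifact box.
#' @param scaleRange zoom factor range for the scaling operator.
#' @param rotationAxes axes about which random rotations are drawn.
#' @param contrastRange factor range for local contrast enhancement.
#' @param brightnessRange additive brightness range (fraction of the
#'   intensity range).
#' @param noiseSdRange Gaussian noise sigma range (fraction of the intensity
#'   range).
#' @param blurSigmaRange Gaussian blur sigma range in voxels.
#' @return a validated recipe list.
#' @export
augmentRecipe <- function(cutmix = 2L, histogramMatch = 2L,
                          localContrast = 2L, standard = 4L,
                          standardOps = c("rotation", "scaling",
                                          "gaussian_noise", "blur",
                                          "brightness"),
                          cutmixFrac = 0.3,
                          scaleRange = c(0.8, 1.25),
                          rotationAxes = 1:3,
                          contrastRange = c(0.5, 2),
                          brightnessRange = c(-0.1, 0.1),
                          noiseSdRange = c(0.01, 0.05),
                          blurSigmaRange = c(0.5, 1.5)) {
  counts <- c(cutmix, histogramMatch, localContrast, standard)
  if (any(counts < 0)) stop("operator counts must be >= 0")
  if (scaleRange[1] <= 0 || scaleRange[1] > scaleRange[2]) {
    stop("invalid scaleRange")
  }
  list(cutmix = as.integer(cutmix),
       histogramMatch = as.integer(histogramMatch),
       localContrast = as.integer(localContrast),
       standard = as.integer(standard), standardOps = standardOps,
       cutmixFrac = cutmixFrac, scaleRange = scaleRange,
       rotationAxes = rotationAxes, contrastRange = contrastRange,
       brightnessRange = brightnessRange, noiseSdRange = noiseSdRange,
       blurSigmaRange = blurSigmaRange)
}

appendChain <- function(pair, op, params) {
  c(pair@chain, list(c(list(op = op), params)))
}

#' CutMix: paste an artifact box into an axon cube
#'
#' An axis-aligned random sub-box of relative volume about `frac` is cut from
#' the artifact cube and pasted into the axon cube at the same location;
#' annotation voxels inside the pasted box are cleared.  Every output voxel
#' equals the corresponding voxel of exactly one source.
#'
#' @param axon a [CubePair] containing axons.
#' @param artifact a congruent [CubePair] with empty annotation.
#' @param frac target relative volume of the pasted box, in (0, 1).
#' @param seed integer seed.
#' @return the mixed [CubePair], provenance "augmented".
#' @export
cutmix <- function(axon, artifact, frac = 0.3, seed = 0L) {
  checkCongruent(axon@intensity@data, artifact@intensity@data)
  if (frac < 0 || frac >= 1) stop("frac must be in [0, 1)")
  d <- dim(axon@intensity@data)
  withSeed(seed, {
    # per-axis fractions with geometric mean frac^(1/3)
    e <- stats::rnorm(3, sd = 0.25)
    e <- e - mean(e)
    f <- pmin(frac^(1 / 3) * exp(e), 1)
    ext <- as.integer(round(f * d))
    lo <- vapply(1:3, function(k) {
      if (ext[k] < 1L) 1L else sample.int(d[k] - ext[k] + 1L, 1L)
    }, 0L)
  })
  if (any(ext < 1L)) return(axon)  # empty-box limit: unchanged
  iz <- lo[1]:(lo[1] + ext[1] - 1L)
  iy <- lo[2]:(lo[2] + ext[2] - 1L)
  ix <- lo[3]:(lo[3] + ext[3] - 1L)
  intens <- axon@intensity@data
  ann <- axon@annotation@data
  intens[iz, iy, ix] <- artifact@intensity@data[iz, iy, ix]
  ann[iz, iy, ix] <- 0
  CubePair(IntensityCube(intens, axon@intensity@offset,
                         axon@intensity@parentId),
           AnnotationCube(ann), provenance = "augmented", seed = seed,
           chain = appendChain(axon, "cutmix",
                               list(frac = frac, low = lo - 1L,
                                    extent = ext, seed = seed)))
}

#' Histogram matching of the background
#'
#' Transfers the background appearance of a reference cube onto the source:
#' a monotone intensity mapping (quantile matching) carries the source
#' background histogram (annotation == 0 voxels) onto the reference
#' histogram, and is applied to background voxels only.  Annotated axon
#' voxels keep their original intensities bit-exactly; the annotation is
#' unchanged.
#'
#' @param pair a [CubePair].
#' @param reference an [IntensityCube] (or 3D array); need not be congruent.
#' @param seed integer seed (recorded for the operator chain; the mapping
#'   itself is deterministic).
#' @return the matched [CubePair], provenance "augmented".
#' @export
histogramMatchAug <- function(pair, reference, seed = 0L) {
  ref <- if (is(reference, "IntensityCube")) reference@data else reference
  if (length(unique(as.vector(ref))) < 2L) {
    stop("reference must have at least 2 distinct values")
  }
  intens <- pair@intensity@data
  bg <- pair@annotation@data == 0
  src <- intens[bg]
  probs <- (rank(src, ties.method = "average") - 0.5) / length(src)
  mapped <- stats::quantile(as.vector(ref), probs = probs, names = FALSE,
                            type = 4)
  intens[bg] <- mapped
  CubePair(IntensityCube(intens, pair@intensity@offset,
                         pair@intensity@parentId),
           pair@annotation, skeleton = pair@skeleton,
           provenance = "augmented", seed = seed,
           chain = appendChain(pair, "histogram_match", list(seed = seed)))
}

#' Local contrast enhancement of stochastic axons
#'
#' Randomly selects a subset of the 26-connected components of the
#' annotation and scales the intensity of those components' voxels by a
#' factor drawn from `factorRange`.  All other voxels and the annotation are
#' unchanged.
#'
#' @param pair a [CubePair].
#' @param factorRange (lo, hi) multiplicative factor range, lo > 0.
#' @param seed integer seed.
#' @return the adjusted [CubePair], provenance "augmented".
#' @export
localContrastAug <- function(pair, factorRange = c(0.5, 2), seed = 0L) {
  if (factorRange[1] <= 0) stop("factorRange lower bound must be > 0")
  ann <- pair@annotation@data
  if (!any(ann > 0)) {
    warning("annotation is empty; returning the input unchanged")
    return(pair)
  }
  comp <- labelComponents(ann > 0)
  ncomp <- max(comp)
  intens <- pair@intensity@data
  withSeed(seed, {
    nsel <- sample.int(ncomp, 1L)
    sel <- sample.int(ncomp, nsel)
    factors <- stats::runif(length(sel), factorRange[1], factorRange[2])
  })
  for (i in seq_along(sel)) {
    vox <- comp == sel[i]
    intens[vox] <- intens[vox] * factors[i]
  }
  CubePair(IntensityCube(intens, pair@intensity@offset,
                         pair@intensity@parentId),
           pair@annotation, skeleton = pair@skeleton,
           provenance = "augmented", seed = seed,
           chain = appendChain(pair, "local_contrast",
                               list(components = sel, factors = factors,
                                    seed = seed)))
}

# rotate/zoom a 3D array about the grid center, preserving shape
warpInPlace <- function(a, A, interp) {
  t <- centeredAffine(A, c(0, 0, 0), dim(a))
  src <- transformPoints(invertAffineMat(t), coordGrid(dim(a)))
  array(sampleAt(a, src, interp), dim(a))
}

#' Standard augmentation operators
#'
#' The common volumetric augmentations: random rotation and scaling
#' (geometric; applied identically to the intensity with trilinear
#' interpolation and to the annotation with nearest-neighbor resampling,
#' re-binarized), and Gaussian noise, blur and brightness adjustment
#' (photometric; the annotation is left untouched).  Geometric operators
#' resample about the cube center within the original shape.
#'
#' @param pair a [CubePair].
#' @param op one of "rotation", "scaling", "gaussian_noise", "blur",
#'   "brightness".
#' @param params named list of operator parameters: rotation takes `angle`
#'   (degrees) and `axis` (1 = z, 2 = y, 3 = x); scaling takes `factor`;
#'   gaussian_noise takes `sd`; blur takes `sigma`; brightness takes `delta`.
#' @param seed integer seed (used when a parameter is not supplied).
#' @return the augmented [CubePair], provenance "augmented".
#' @export
standardAug <- function(pair, op, params = list(), seed = 0L) {
  ops <- c("rotation", "scaling", "gaussian_noise", "blur", "brightness")
  if (!op %in% ops) stop("unknown op: ", op)
  intens <- pair@intensity@data
  ann <- pair@annotation@data
  skel <- pair@skeleton
  rng <- diff(range(intens))
  withSeed(seed, {
    if (op == "rotation") {
      angle <- params$angle %||% stats::runif(1, -30, 30)
      axis <- params$axis %||% sample(1:3, 1)
      rad <- angle * pi / 180
      ax <- c(0, 0, 0)
      ax[axis] <- rad
      A <- eulerRotation(ax[1], ax[2], ax[3])
      if (abs(angle) > 1e-12) {
        intens <- warpInPlace(intens, A, "linear")
        ann <- (warpInPlace(ann, A, "nearest") > 0.5) * 1
        if (!is.null(skel)) {
          skel <- (warpInPlace(skel, A, "nearest") > 0.5) * 1 * (ann > 0)
        }
      }
      params <- list(angle = angle, axis = axis)
    } else if (op == "scaling") {
      factor <- params$factor %||% stats::runif(1, 0.8, 1.25)
      A <- diag(3) * factor
      if (abs(factor - 1) > 1e-12) {
        intens <- warpInPlace(intens, A, "linear")
        ann <- (warpInPlace(ann, A, "nearest") > 0.5) * 1
        if (!is.null(skel)) {
          skel <- (warpInPlace(skel, A, "nearest") > 0.5) * 1 * (ann > 0)
        }
      }
      params <- list(factor = factor)
    } else if (op == "gaussian_noise") {
      sd <- params$sd %||% (stats::runif(1, 0.01, 0.05) * rng)
      intens <- intens + stats::rnorm(length(intens), sd = sd)
      params <- list(sd = sd)
    } else if (op == "blur") {
      sigma <- params$sigma %||% stats::runif(1, 0.5, 1.5)
      intens <- gaussianSmooth3d(intens, sigma)
      params <- list(sigma = sigma)
    } else {
      delta <- params$delta %||% (stats::runif(1, -0.1, 0.1) * rng)
      intens <- intens + delta
      params <- list(delta = delta)
    }
  })
  CubePair(IntensityCube(intens, pair@intensity@offset,
                         pair@intensity@parentId),
           AnnotationCube(ann), skeleton = skel, provenance = "augmented",
           seed = seed,
           chain = appendChain(pair, op, c(params, list(seed = seed))))
}

#' Expand an annotated pool by augmentation
#'
#' Applies the recipe's per-cube operator counts to every axon pair, drawing
#' partners and parameters deterministically from the master seed, and
#' returns the augmented derivatives.  Each output records its provenance
#' and the operator chain that produced it, so any output can be replayed
#' bit-exactly from its sources.
#'
#' @param axonPairs list of axon [CubePair]s.
#' @param artifactPairs list of artifact [CubePair]s (needed when the recipe
#'   requests CutMix).
#' @param recipe a recipe from [augmentRecipe()].
#' @param seed master seed; all per-output seeds and partner choices derive
#'   from it.
#' @return list of augmented [CubePair]s (recipe total per axon cube).
#' @export
augmentPool <- function(axonPairs, artifactPairs = list(),
                        recipe = augmentRecipe(), seed = 0L) {
  nPer <- recipe$cutmix + recipe$histogramMatch + recipe$localContrast +
    recipe$standard
  if (nPer == 0L || !length(axonPairs)) return(list())
  if (recipe$cutmix > 0L && !length(artifactPairs)) {
    stop("cutmix requested but the artifact pool is empty")
  }
  nOut <- nPer * length(axonPairs)
  withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max, nOut)
    partners <- if (length(artifactPairs)) {
      sample.int(length(artifactPairs), nOut, replace = TRUE)
    } else integer(nOut)
    refs <- sample.int(length(axonPairs), nOut, replace = TRUE)
    stdOps <- sample(recipe$standardOps, nOut, replace = TRUE)
  })
  out <- vector("list", nOut)
  k <- 0L
  for (i in seq_along(axonPairs)) {
    pair <- axonPairs[[i]]
    for (j in seq_len(recipe$cutmix)) {
      k <- k + 1L
      out[[k]] <- cutmix(pair, artifactPairs[[partners[k]]],
                         frac = recipe$cutmixFrac, seed = seeds[k])
    }
    for (j in seq_len(recipe$histogramMatch)) {
      k <- k + 1L
      out[[k]] <- histogramMatchAug(pair, axonPairs[[refs[k]]]@intensity,
                                    seed = seeds[k])
    }
    for (j in seq_len(recipe$localContrast)) {
      k <- k + 1L
      out[[k]] <- localContrastAug(pair, recipe$contrastRange,
                                   seed = seeds[k])
    }
    for (j in seq_len(recipe$standard)) {
      k <- k + 1L
      out[[k]] <- standardAug(pair, stdOps[k], seed = seeds[k])
    }
  }
  out
}
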
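# Desk-scale multi-constraint, multiscale 3D registration: rigid -> affine ->
# deformable, minimizing the multi-constraint objective by direct
# optimization on an image pyramid.  Rigid and affine parameters are fitted
# at the coarsest pyramid level and applied (not re-fitted) at finer levels;
# the deformable stage optimizes a control-point displacement field
# coarse-to-fine, each coarser solution initializing the next level, and the
# final field is trilinearly upsampled to the reference grid.

#' Registration configuration
#'
#' @param levels pyramid levels (default 3).
#' @param factor per-axis downsampling factor between levels (default 2).
#' @param weights channel weights (original, style proxy, regions); default
#'   0.70 / 0.15 / 0.15 split evenly across region masks.
#' @param miBins mutual-information bins for the original-brain channel.
#' @param lccWindow local cross-correlation window for the style-proxy
#'   channel.
#' @param rigidIter,affineIter optimizer iteration caps at the coarsest
#'   level.
#' @param deformLevels number of (coarsest) pyramid levels on which the
#'   deformable field is optimized (default 2); the result is upsampled to
#'   the full grid.
#' @param deformIter iteration caps per deformable level, coarsest first.
#' @param controlSpacing control-point spacing of the deformable field in
#'   coarsest-level voxels; the physical spacing is kept constant across
#'   levels so the number of control points does not grow.
#' @param lambdaAffine weight of the affine identity/scaling penalties
#'   (evaluated with the offset normalized by the grid half-extent).
#' @param lambdaDeform weight of the smoothness + inverse-consistency
#'   penalties.
#' @param maskSigma Gaussian sigma (voxels) used to soften region masks so
#'   the mask channels carry gradient information.
#' @param seed integer seed (optimization is deterministic; recorded for
#'   provenance).
#' @return a validated configuration list.
#' @export
registrationConfig <- function(levels = 3L, factor = 2L, weights = NULL,
                               miBins = 32L, lccWindow = 9L,
                               rigidIter = 40L, affineIter = 40L,
                               deformLevels = 2L, deformIter = c(10L, 1L),
                               controlSpacing = 10, lambdaAffine = 0.01,
                               lambdaDeform = 1, maskSigma = 1, seed = 0L) {
  if (levels < 1L) stop("levels must be >= 1")
  if (factor < 2L) stop("factor must be >= 2")
  deformLevels <- min(deformLevels, levels)
  deformIter <- rep_len(deformIter, deformLevels)
  list(levels = as.integer(levels), factor = as.integer(factor),
       weights = weights, miBins = as.integer(miBins),
       lccWindow = as.integer(lccWindow), rigidIter = as.integer(rigidIter),
       affineIter = as.integer(affineIter),
       deformLevels = as.integer(deformLevels),
       deformIter = as.integer(deformIter), controlSpacing = controlSpacing,
       lambdaAffine = lambdaAffine, lambdaDeform = lambdaDeform,
       maskSigma = maskSigma, seed = as.integer(seed))
}

#' Pyramid level extents
#'
#' Extents of each pyramid level: level 1 is the input shape and each next
#' level is ceil(previous / factor) per axis.  A level whose extent would
#' fall below 2 voxels on any axis raises an error.
#'
#' @param shape integer(3) input extents.
#' @param levels number of levels.
#' @param factor downsampling factor.
#' @return list of integer(3) extents, finest first.
#' @export
pyramidShapes <- function(shape, levels, factor = 2L) {
  out <- list(as.integer(shape))
  for (l in seq_len(levels - 1L)) {
    nxt <- as.integer(ceiling(out[[l]] / factor))
    if (any(nxt < 2L)) {
      stop("pyramid level ", l + 1L, " has a degenerate extent (",
           paste(nxt, collapse = "x"), "); reduce the number of levels")
    }
    out[[l + 1L]] <- nxt
  }
  out
}

#' Build a bundle pyramid
#'
#' Level 1 is the input bundle; each next level is block-mean downsampled by
#' `factor` per axis (region masks by majority vote, so they stay binary).
#'
#' @param b a [RegistrationBundle].
#' @param levels number of levels.
#' @param factor downsampling factor.
#' @return list of [RegistrationBundle]s, finest first.
#' @export
buildPyramid <- function(b, levels = 3L, factor = 2L) {
  stopifnot(is(b, "RegistrationBundle"))
  pyramidShapes(dim(b@original@data), levels, factor)  # validates extents
  out <- vector("list", levels)
  out[[1]] <- b
  cur <- b
  for (l in seq_len(levels - 1L)) {
    sp <- cur@original@spacing * factor
    masks <- lapply(cur@regionMasks, function(m) {
      Volume((blockReduce(m@data, factor, "mean") > 0.5) * 1, sp)
    })
    lm <- if (is.null(cur@landmarks)) NULL else
      (cur@landmarks - (factor - 1) / 2) / factor
    cur <- new("RegistrationBundle",
               original = Volume(blockReduce(cur@original@data, factor), sp),
               styleProxy = Volume(blockReduce(cur@styleProxy@data, factor),
                                   sp),
               regionMasks = masks, landmarks = lm)
    out[[l + 1L]] <- cur
  }
  out
}

# rescale a pull-back/forward affine map from coarse to fine coordinates:
# fine q = f * u + s with s = (f - 1)/2 (block-mean centers)
rescaleAffine <- function(t, f) {
  s <- rep((f - 1) / 2, 3)
  affineTransform(t@A, as.numeric(f * t@b + s - t@A %*% s))
}

minMaxNorm <- function(a) {
  r <- range(a)
  if (diff(r) == 0) return(a * 0)
  (a - r[1]) / diff(r)
}

# assemble per-level channel data: normalized original and style proxy,
# softened region masks, plus similarity specs
makeChannels <- function(srcLevel, refLevel, cfg) {
  nR <- length(refLevel@regionMasks)
  w <- cfg$weights %||% defaultChannelWeights(nR)
  specs <- c(list(similaritySpec("mi", w[1], bins = cfg$miBins),
                  similaritySpec("lcc", w[2], window = cfg$lccWindow)),
             lapply(seq_len(nR), function(i) {
               similaritySpec("mse", w[2 + i])
             }))
  soft <- function(m) gaussianSmooth3d(m@data, cfg$maskSigma)
  srcGrids <- c(list(minMaxNorm(srcLevel@original@data),
                     minMaxNorm(srcLevel@styleProxy@data)),
                lapply(srcLevel@regionMasks, soft))
  refGrids <- c(list(minMaxNorm(refLevel@original@data),
                     minMaxNorm(refLevel@styleProxy@data)),
                lapply(refLevel@regionMasks, soft))
  list(src = srcGrids, ref = refGrids, specs = specs)
}

# evaluate the multi-constraint objective for warped source channels: the
# sample positions are shared across channels.  Degenerate-similarity
# warnings are silenced here: a trial step that warps the brain out of view
# yields a constant channel, which the losses already handle by scoring 0.
channelObjective <- function(chan, pos, shape, stage, t = NULL, f = NULL,
                             penaltyWeight = 1) {
  channels <- lapply(seq_along(chan$specs), function(i) {
    y <- array(sampleAt(chan$src[[i]], pos, "linear"), shape)
    list(x = chan$ref[[i]], y = y, spec = chan$specs[[i]])
  })
  suppressWarnings(
    multiconstraintObjective(channels, stage = stage, t = t, f = f,
                             penaltyWeight = penaltyWeight)
  )
}

# forward-difference numerical gradient
numGrad <- function(fn, eps) {
  function(par) {
    f0 <- fn(par)
    g <- numeric(length(par))
    for (i in seq_along(par)) {
      p <- par
      p[i] <- p[i] + eps[min(i, length(eps))]
      g[i] <- (fn(p) - f0) / eps[min(i, length(eps))]
    }
    g
  }
}

# central-difference numerical gradient: twice the cost of forward
# differences, but unbiased at the kinks of the L1 smoothness penalty (a
# one-sided difference at a kink sees only the upward slope and can pin the
# field at zero)
numGradCentral <- function(fn, eps) {
  function(par) {
    g <- numeric(length(par))
    for (i in seq_along(par)) {
      e <- eps[min(i, length(eps))]
      pp <- par
      pp[i] <- par[i] + e
      fp <- fn(pp)
      pp[i] <- par[i] - e
      fm <- fn(pp)
      g[i] <- (fp - fm) / (2 * e)
    }
    g
  }
}

# monotone gradient descent with backtracking line search: one numerical
# gradient per iteration, fn-only line search (unlike optim's L-BFGS-B, which
# evaluates the gradient at every line-search point -- prohibitive when the
# gradient costs one objective evaluation per parameter)
descentOptim <- function(par, fn, gr, maxit, maxStep = 0.5) {
  f0 <- fn(par)
  g <- gr(par)
  step <- if (max(abs(g)) > 0) maxStep / max(abs(g)) else 1
  for (it in seq_len(maxit)) {
    gn2 <- sum(g^2)
    if (gn2 < 1e-16) break
    accepted <- FALSE
    for (ls in 1:10) {
      cand <- par - step * g
      fc <- fn(cand)
      if (fc <= f0 - 1e-4 * step * gn2) {
        par <- cand
        f0 <- fc
        step <- step * 1.8
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    if (it < maxit) g <- gr(par)
  }
  list(par = par, value = f0)
}

# wrap an objective so every evaluation is recorded; trace() returns the
# best-so-far (non-increasing) sequence
tracedFn <- function(fn) {
  env <- new.env()
  env$vals <- numeric(0)
  wrapped <- function(par) {
    v <- fn(par)
    env$vals <- c(env$vals, v)
    v
  }
  list(fn = wrapped, trace = function() cummin(env$vals))
}

rigidPullback <- function(par, shape) {
  R <- eulerRotation(par[1], par[2], par[3])
  centeredAffine(R, par[4:6], shape)
}

#' Fit a rigid transform at the coarsest pyramid level
#'
#' Six-parameter (Euler z-y-x rotation about the grid center plus
#' translation) minimization of the multi-constraint objective at the
#' coarsest level of the configured pyramid, with numerically evaluated
#' gradients.
#'
#' @param src,ref congruent [RegistrationBundle]s.
#' @param cfg a [registrationConfig()].
#' @return the fitted [AffineTransform3D] forward map (source to reference,
#'   full-resolution voxel coordinates), with the objective trace in
#'   attribute "trace".
#' @export
fitRigid <- function(src, ref, cfg = registrationConfig()) {
  fitRigidPyr(buildPyramid(src, cfg$levels, cfg$factor),
              buildPyramid(ref, cfg$levels, cfg$factor), cfg)
}

fitRigidPyr <- function(pyrSrc, pyrRef, cfg) {
  srcC <- pyrSrc[[cfg$levels]]
  refC <- pyrRef[[cfg$levels]]
  chan <- makeChannels(srcC, refC, cfg)
  shape <- dim(refC@original@data)
  grid <- coordGrid(shape)
  obj <- function(par) {
    P <- rigidPullback(par, shape)
    pos <- transformPoints(P, grid)
    v <- channelObjective(chan, pos, shape, "rigid")
    if (!is.finite(v)) stop("non-finite rigid objective at par = ",
                            paste(signif(par, 4), collapse = ", "))
    v
  }
  tf <- tracedFn(obj)
  fit <- stats::optim(rep(0, 6), tf$fn,
                      gr = numGrad(tf$fn, c(rep(2e-3, 3), rep(2e-2, 3))),
                      method = "L-BFGS-B",
                      control = list(maxit = cfg$rigidIter))
  # bounded derivative-free refinement (see the affine stage): sharpens the
  # six parameters below the finite-difference kink scale, which the affine
  # stage depends on for its initialization
  fit <- stats::optim(fit$par, tf$fn, method = "Nelder-Mead",
                      control = list(maxit = min(10L * cfg$rigidIter, 400L),
                                     reltol = 1e-9))
  pullCoarse <- rigidPullback(fit$par, shape)
  pullFull <- rescaleAffine(pullCoarse, cfg$factor^(cfg$levels - 1L))
  out <- invertAffineMat(pullFull)
  attr(out, "trace") <- tf$trace()
  out
}

#' Fit an affine transform at the coarsest pyramid level
#'
#' Twelve-parameter affine minimization of the multi-constraint objective
#' plus the identity and scaling penalties, started from `init` (typically
#' the fitted rigid transform).  Steps with non-positive determinant are
#' rejected through a barrier.  Penalties are evaluated with the offset
#' normalized by the grid half-extent.
#'
#' @param src,ref congruent [RegistrationBundle]s.
#' @param cfg a [registrationConfig()].
#' @param init forward [AffineTransform3D] initialization (full-resolution
#'   coordinates), e.g. the result of [fitRigid()].
#' @return the fitted forward [AffineTransform3D] (full-resolution), trace in
#'   attribute "trace".
#' @export
fitAffine <- function(src, ref, cfg = registrationConfig(),
                      init = affineTransform()) {
  fitAffinePyr(buildPyramid(src, cfg$levels, cfg$factor),
               buildPyramid(ref, cfg$levels, cfg$factor), cfg, init)
}

fitAffinePyr <- function(pyrSrc, pyrRef, cfg, init = affineTransform()) {
  srcC <- pyrSrc[[cfg$levels]]
  refC <- pyrRef[[cfg$levels]]
  chan <- makeChannels(srcC, refC, cfg)
  shape <- dim(refC@original@data)
  grid <- coordGrid(shape)
  halfExt <- (shape - 1) / 2
  f <- cfg$factor^(cfg$levels - 1L)
  initPullCoarse <- rescaleAffine(invertAffineMat(init), 1 / f)
  # the offset is parameterized in half-extent units so that all twelve
  # parameters move on comparable scales
  par0 <- c(as.vector(initPullCoarse@A), initPullCoarse@b / halfExt)
  obj <- function(par) {
    A <- matrix(par[1:9], 3, 3)
    dt <- det(A)
    if (dt <= 1e-6) return(1e6 * (1 + abs(dt)))  # barrier: reject the step
    P <- affineTransform(A, par[10:12] * halfExt)
    pos <- transformPoints(P, grid)
    # penalties on the centered transform with normalized offset
    ctr <- (shape - 1) / 2
    bC <- as.numeric(P@A %*% ctr + P@b - ctr) / halfExt
    tPen <- affineTransform(A, bC)
    sim <- channelObjective(chan, pos, shape, "rigid")
    v <- sim + cfg$lambdaAffine *
      (affineIdentityPenalty(tPen) + affineScalingPenalty(tPen, "det"))
    if (!is.finite(v)) return(1e6)
    v
  }
  tf <- tracedFn(obj)
  fit <- stats::optim(par0, tf$fn,
                      gr = numGrad(tf$fn, 1e-3),
                      method = "L-BFGS-B",
                      control = list(maxit = cfg$affineIter))
  # derivative-free refinement: the partial-volume binning makes the
  # objective piecewise smooth, which finite-difference gradients resolve
  # only down to the kink scale
  fit <- stats::optim(fit$par, tf$fn, method = "Nelder-Mead",
                      control = list(maxit = min(60L * cfg$affineIter, 2400L),
                                     reltol = 1e-12))
  par <- if (fit$value <= obj(par0)) fit$par else par0  # descent contract
  pullCoarse <- affineTransform(matrix(par[1:9], 3, 3),
                                par[10:12] * halfExt)
  out <- invertAffineMat(rescaleAffine(pullCoarse, f))
  attr(out, "trace") <- tf$trace()
  out
}

# control grid geometry for a level shape
controlGrid <- function(shape, spacing) {
  nc <- as.integer(ceiling((shape - 1) / spacing) + 1L)
  list(nc = nc, spacing = spacing)
}

# upsample control-point displacements (array nc x 3) to a dense voxel field
controlToField <- function(ctrl, cg, shape) {
  g <- coordGrid(shape)
  pos <- sweep(g, 2, cg$spacing, "/")
  disp <- array(0, c(shape, 3))
  for (k in 1:3) {
    comp <- array(ctrl[, k], cg$nc)
    disp[, , , k] <- array(sampleAt(comp, pos, "linear"), shape)
  }
  disp
}

#' Fit a deformable field coarse-to-fine
#'
#' Optimizes a control-point displacement field (trilinearly upsampled to
#' voxel resolution) under the multi-constraint objective plus field
#' smoothness and inverse consistency, over the coarsest `cfg$deformLevels`
#' pyramid levels: the coarser solution is upsampled to initialize the next
#' level, and the final field is upsampled to the full reference grid.  The
#' source is pre-aligned by the affine pull-back at every level.
#'
#' @param src,ref congruent [RegistrationBundle]s.
#' @param cfg a [registrationConfig()].
#' @param init forward [AffineTransform3D] pre-alignment (full-resolution),
#'   e.g. the result of [fitAffine()].
#' @return the fitted [DeformationField] on the full reference grid
#'   (displacements in voxels), traces in attribute "trace".
#' @export
fitDeformable <- function(src, ref, cfg = registrationConfig(),
                          init = affineTransform()) {
  fitDeformablePyr(buildPyramid(src, cfg$levels, cfg$factor),
                   buildPyramid(ref, cfg$levels, cfg$factor), cfg, init)
}

fitDeformablePyr <- function(pyrSrc, pyrRef, cfg, init = affineTransform()) {
  pullFull <- invertAffineMat(init)
  lvls <- seq(cfg$levels, by = -1L, length.out = cfg$deformLevels)
  ctrl <- NULL
  traces <- list()
  for (li in seq_along(lvls)) {
    l <- lvls[li]
    shape <- dim(pyrRef[[l]]@original@data)
    fTot <- cfg$factor^(l - 1L)
    pull <- rescaleAffine(pullFull, 1 / fTot)
    spacing <- cfg$controlSpacing * cfg$factor^(cfg$levels - l)
    cg <- controlGrid(shape, spacing)
    chan <- makeChannels(pyrSrc[[l]], pyrRef[[l]], cfg)
    grid <- coordGrid(shape)
    if (is.null(ctrl)) {
      ctrl <- matrix(0, prod(cg$nc), 3)
    } else {
      # sample the previous level's dense field at this level's control
      # points (positions /factor in the coarser frame, displacements x2)
      cpos <- coordGrid(cg$nc)
      cpos <- sweep(cpos, 2, cg$spacing, "*")
      prevPos <- (cpos - (cfg$factor - 1) / 2) / cfg$factor
      newCtrl <- matrix(0, prod(cg$nc), 3)
      for (k in 1:3) {
        newCtrl[, k] <- cfg$factor *
          sampleAt(prevField[, , , k], prevPos, "linear")
      }
      ctrl <- newCtrl
    }
    obj <- function(par) {
      ctl <- matrix(par, ncol = 3)
      disp <- controlToField(ctl, cg, shape)
      pos <- transformPoints(pull, grid + matrix(disp, ncol = 3))
      channelObjective(chan, pos, shape, "deformable",
                       f = deformationField(disp),
                       penaltyWeight = cfg$lambdaDeform)
    }
    tf <- tracedFn(obj)
    best <- as.vector(ctrl)
    bestVal <- tf$fn(best)
    if (cfg$deformIter[li] > 0L) {
      fit <- descentOptim(best, tf$fn, gr = numGradCentral(tf$fn, 2e-2),
                          maxit = cfg$deformIter[li])
      if (fit$value <= bestVal) {
        best <- fit$par
        bestVal <- fit$value
      }
    }
    ctrl <- matrix(best, ncol = 3)
    prevField <- controlToField(ctrl, cg, shape)
    traces[[paste0("level", l)]] <- tf$trace()
  }
  # upsample the last optimized field to the full reference grid
  lLast <- lvls[length(lvls)]
  fTot <- cfg$factor^(lLast - 1L)
  fullShape <- dim(pyrRef[[1]]@original@data)
  if (fTot > 1) {
    g <- coordGrid(fullShape)
    posCoarse <- (g - (fTot - 1) / 2) / fTot
    disp <- array(0, c(fullShape, 3))
    for (k in 1:3) {
      disp[, , , k] <- fTot *
        array(sampleAt(prevField[, , , k], posCoarse, "linear"), fullShape)
    }
  } else {
    disp <- prevField
  }
  out <- deformationField(disp)
  attr(out, "trace") <- traces
  out
}

#' Apply fitted transforms to a volume, labels or points
#'
#' Composes the stages in order rigid, then affine, then deformable field.
#' Volumes are resampled with trilinear interpolation, label volumes with
#' nearest-neighbor (requesting linear interpolation for labels is an
#' error), and points are mapped exactly through the forward maps (the field
#' contribution uses its first-order approximate inverse).
#'
#' @param x a [Volume], [LabelVolume], or n x 3 matrix of points.
#' @param rigid,affine forward [AffineTransform3D]s (NULL = identity).
#' @param field a [DeformationField] on the reference grid (NULL = none).
#' @param interp "linear" or "nearest"; chosen automatically by input kind
#'   when NULL.
#' @param shape output extents (defaults to the input grid).
#' @return the warped object, same kind as the input.
#' @export
applyTransform <- function(x, rigid = NULL, affine = NULL, field = NULL,
                           interp = NULL, shape = NULL) {
  idt <- affineTransform()
  rigid <- rigid %||% idt
  affine <- affine %||% idt
  fwd <- affineTransform(affine@A %*% rigid@A,
                         as.numeric(affine@A %*% rigid@b + affine@b))
  if (is.matrix(x) && !is(x, "Volume")) {
    pts <- transformPoints(fwd, x)
    if (!is.null(field)) {
      inv <- approxInverseField(field)
      d <- dim(field@disp)[1:3]
      p <- pts
      for (k in 1:3) p[, k] <- pmin(pmax(p[, k], 0), d[k] - 1)
      for (k in 1:3) {
        pts[, k] <- pts[, k] + sampleAt(inv@disp[, , , k], p, "linear")
      }
    }
    return(pts)
  }
  stopifnot(is(x, "Volume"))
  isLabels <- is(x, "LabelVolume")
  if (is.null(interp)) interp <- if (isLabels) "nearest" else "linear"
  if (isLabels && interp == "linear") {
    stop("linear interpolation is not valid for label volumes")
  }
  shape <- as.integer(shape %||% dim(x@data))
  g <- coordGrid(shape)
  if (!is.null(field)) {
    checkCongruent(field@disp[, , , 1], array(0, shape))
    g <- g + matrix(field@disp, ncol = 3)
  }
  pos <- transformPoints(invertAffineMat(fwd), g)
  out <- array(sampleAt(x@data, pos, interp), shape)
  if (isLabels) {
    LabelVolume(out, x@spacing, x@origin, regionTable = x@regionTable)
  } else {
    Volume(out, x@spacing, x@origin)
  }
}

#' Register a source brain onto a reference
#'
#' Runs the full pipeline — rigid, affine, then deformable — on the
#' configured pyramid and returns the composed result, the warped bundle and
#' the per-stage objective traces.
#'
#' @param src,ref congruent [RegistrationBundle]s.
#' @param cfg a [registrationConfig()].
#' @return a [RegistrationResult]; the `rigid` and `affine` slots hold the
#'   forward maps of the two stages (total affine = affine after rigid).
#' @export
registerBrain <- function(src, ref, cfg = registrationConfig()) {
  pyrSrc <- buildPyramid(src, cfg$levels, cfg$factor)
  pyrRef <- buildPyramid(ref, cfg$levels, cfg$factor)
  rigid <- fitRigidPyr(pyrSrc, pyrRef, cfg)
  total <- fitAffinePyr(pyrSrc, pyrRef, cfg, init = rigid)
  field <- fitDeformablePyr(pyrSrc, pyrRef, cfg, init = total)
  rigidInv <- invertAffineMat(rigid)
  incr <- affineTransform(total@A %*% rigidInv@A,
                          as.numeric(total@A %*% rigidInv@b + total@b))
  warp <- function(v, nn = FALSE) {
    applyTransform(v, rigid = rigid, affine = incr, field = field,
                   interp = if (nn) "nearest" else "linear")
  }
  warpedMasks <- lapply(src@regionMasks, function(m) {
    Volume((warp(m, nn = TRUE)@data > 0.5) * 1, m@spacing)
  })
  warpedLm <- if (is.null(src@landmarks)) NULL else
    applyTransform(src@landmarks, rigid = rigid, affine = incr,
                   field = field)
  warped <- new("RegistrationBundle", original = warp(src@original),
                styleProxy = warp(src@styleProxy),
                regionMasks = warpedMasks, landmarks = warpedLm)
  new("RegistrationResult", rigid = rigid, affine = incr, field = field,
      traces = c(list(rigid = attr(rigid, "trace"),
                      affine = attr(total, "trace")),
                 attr(field, "trace")),
      warped = warped)
}
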
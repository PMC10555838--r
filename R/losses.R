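# The full published loss family as pure, side-effect-free numeric functions
# over arrays: the weighted sigmoid BCE for axon segmentation, the
# style-transfer (adversarial / cycle / outline) losses, the multiview
# semi-supervised losses, and the registration similarity and regularization
# terms.  All similarities are returned as losses to minimize (mutual
# information and cross-correlation are negated).

#' Weighted sigmoid binary cross-entropy for axon segmentation
#'
#' Mean over voxels of -w [y log sigma(x) + (1 - y) log(1 - sigma(x))] with
#' raw logits x, binary targets y, and class weight w = `wPos` on axon voxels
#' (y = 1) and 1 on background.  Uses numerically stabilized log-sigmoid.
#' The default positive-class weight of 3 counteracts the extreme
#' foreground/background imbalance of axon cubes.
#'
#' @param logits numeric grid of raw predictions.
#' @param target congruent binary grid (1 = axon).
#' @param wPos positive-class weight (default 3).
#' @param reduction "mean" (default, as published) or "sum".
#' @return scalar loss.
#' @export
axonBCE <- function(logits, target, wPos = 3, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!all(target %in% c(0, 1))) stop("target must be binary")
  if (!identical(length(logits), length(target)) ||
      (!is.null(dim(logits)) && !identical(dim(logits), dim(target)))) {
    stop("shape mismatch between logits and target")
  }
  x <- as.numeric(logits)
  y <- as.numeric(target)
  # log sigma(x) = -log1p(exp(-x)); log(1 - sigma(x)) = -x - log1p(exp(-x))
  logSig <- ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
  log1mSig <- logSig - x
  w <- ifelse(y == 1, wPos, 1)
  per <- -w * (y * logSig + (1 - y) * log1mSig)
  if (reduction == "mean") mean(per) else sum(per)
}

#' Adversarial (GAN) loss from discriminator scores
#'
#' E[log d_real] + E[log(1 - d_fake)]: the adversarial value the
#' discriminator maximizes during style transfer, as a pure function of its
#' score arrays.
#'
#' @param dReal discriminator scores on real images, in (0, 1).
#' @param dFake discriminator scores on generated images, in (0, 1).
#' @return scalar (at most 0; approaches 0 for a perfect discriminator).
#' @export
ganLoss <- function(dReal, dFake) {
  if (any(dReal <= 0 | dReal >= 1) || any(dFake <= 0 | dFake >= 1)) {
    stop("scores must lie strictly inside (0, 1)")
  }
  mean(log(dReal)) + mean(log(1 - dFake))
}

#' Cycle-consistency loss
#'
#' Mean L1 distance between each original and its round-trip reconstruction,
#' summed over the two translation directions.
#'
#' @param x,xRec original and reconstructed grids for the first direction.
#' @param y,yRec original and reconstructed grids for the second direction.
#' @return scalar >= 0.
#' @export
cycleLoss <- function(x, xRec, y, yRec) {
  checkDims(x, xRec)
  checkDims(y, yRec)
  mean(abs(x - xRec)) + mean(abs(y - yRec))
}

checkDims <- function(a, b) {
  if (length(a) != length(b) ||
      (!is.null(dim(a)) && !is.null(dim(b)) && !identical(dim(a), dim(b)))) {
    stop("shape mismatch")
  }
  invisible(TRUE)
}

#' Outline segmentation binary cross-entropy (summed)
#'
#' Summed (not averaged, as published) binary cross-entropy between
#' probability predictions and binary ground truth, used for brain outline
#' preservation during style transfer.  Predictions at exactly 0 or 1 are
#' clamped by a small epsilon with a warning.
#'
#' @param pred probability grid in (0, 1).
#' @param gt congruent binary grid.
#' @param reduction "sum" (default, as published) or "mean".
#' @return scalar loss.
#' @export
outlineBCE <- function(pred, gt, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  checkDims(pred, gt)
  if (!all(gt %in% c(0, 1))) stop("gt must be binary")
  eps <- 1e-12
  if (any(pred <= 0) || any(pred >= 1)) {
    warning("predictions at 0/1 clamped by epsilon")
    pred <- pmin(pmax(pred, eps), 1 - eps)
  }
  per <- -(gt * log(pred) + (1 - gt) * log(1 - pred))
  if (reduction == "sum") sum(per) else mean(per)
}

#' Multiview semi-supervised segmentation loss components
#'
#' The loss family of the multiview mean-teacher region segmenter, as pure
#' functions of prediction arrays: the supervised summed BCE on annotated
#' slices; the quadratic consistency loss sum((yhat - yhat')^2) between
#' unannotated predictions and the mapped-back predictions of their
#' pi-rotated copies; and the 3D multiview loss, the summed squared
#' difference between coronal-view predictions and horizontal-view
#' predictions transformed into the coronal frame.  The per-view loss is the
#' supervised plus consistency term (the two views are weighted equally), and
#' the total is coronal + horizontal + 3D.
#'
#' @param supPred probability predictions for annotated slices, in (0, 1).
#' @param supGt binary ground truth for annotated slices.
#' @param unsupPred predictions for unannotated slices.
#' @param unsupPredRot predictions for the same slices rotated by pi and
#'   mapped back.
#' @param cor3d 3D-assembled coronal-view predictions.
#' @param hor3dInCor 3D-assembled horizontal-view predictions transformed to
#'   the coronal frame.
#' @return named list: sup, qua, view (= sup + qua, per view), l3d, total
#'   (= 2 * view + l3d).
#' @export
semiMultiviewLoss <- function(supPred, supGt, unsupPred, unsupPredRot,
                              cor3d, hor3dInCor) {
  checkDims(supPred, supGt)
  checkDims(unsupPred, unsupPredRot)
  checkDims(cor3d, hor3dInCor)
  sup <- outlineBCE(supPred, supGt, reduction = "sum")
  qua <- sum((unsupPred - unsupPredRot)^2)
  l3d <- sum((cor3d - hor3dInCor)^2)
  view <- sup + qua
  list(sup = sup, qua = qua, view = view, l3d = l3d,
       total = 2 * view + l3d)
}

# shared joint-histogram machinery for mutual information.  The fixed grid X
# is hard-binned; the moving grid Y uses linear (partial-volume) binning so
# the loss is continuous in any transform that resamples Y.
jointHistogram <- function(X, Y, bins) {
  rx <- range(X)
  ry <- range(Y)
  if (diff(rx) == 0 || diff(ry) == 0) return(NULL)
  bx <- pmin(bins, 1L + floor((as.numeric(X) - rx[1]) / diff(rx) * bins))
  fy <- (as.numeric(Y) - ry[1]) / diff(ry) * bins - 0.5
  fy <- pmin(pmax(fy, 0), bins - 1)  # clamp to the bin-center range
  y0 <- floor(fy)
  wy <- fy - y0
  y0 <- y0 + 1L
  y1 <- pmin(y0 + 1L, bins)
  n <- length(bx)
  idx0 <- (bx - 1L) * bins + y0
  idx1 <- (bx - 1L) * bins + y1
  h <- numeric(bins * bins)
  h0 <- rowsum(c(1 - wy, wy), c(idx0, idx1))
  h[as.integer(rownames(h0))] <- h0
  matrix(h / n, bins, bins)
}

#' Mutual-information similarity loss
#'
#' Negative mutual information of the joint intensity histogram of X and Y
#' over equal-width bins (natural logarithm), so that minimization increases
#' similarity.  Used for the original source brain channel, where intensity
#' distributions differ across modalities.  The joint histogram is
#' accumulated with linear partial-volume weights (and symmetrized, so the
#' loss is exactly symmetric in its arguments) so that it varies smoothly
#' under resampling of either grid.
#'
#' @param X,Y congruent numeric grids.
#' @param bins number of histogram bins (default 32).
#' @return scalar loss (more negative = more similar).
#' @export
simMI <- function(X, Y, bins = 32L) {
  checkDims(X, Y)
  h1 <- jointHistogram(X, Y, as.integer(bins))
  h2 <- jointHistogram(Y, X, as.integer(bins))
  if (is.null(h1) || is.null(h2)) {
    warning("degenerate single-bin input; mutual information is 0")
    return(0)
  }
  h <- (h1 + t(h2)) / 2  # symmetrized: exact in X <-> Y
  px <- rowSums(h)
  py <- colSums(h)
  nz <- h > 0
  outer_pp <- outer(px, py)
  -sum(h[nz] * log(h[nz] / outer_pp[nz]))
}

#' Local cross-correlation similarity loss
#'
#' Negative mean over voxels of the local Pearson correlation between X and
#' Y within the s x s x s window centered at each voxel (windows clipped at
#' faces; zero-variance windows contribute 0).  Used for the style-proxy
#' channel, whose intensities are directly comparable to the reference.
#' The value lies in [-1, 1]; -1 means perfect local correlation.
#'
#' @param X,Y congruent numeric grids.
#' @param s odd window edge length (default 9).
#' @return scalar loss in [-1, 1].
#' @export
simLCC <- function(X, Y, s = 9L) {
  checkDims(X, Y)
  s <- as.integer(s)
  if (s < 3L || s %% 2L == 0L) stop("s must be odd and >= 3")
  if (any(s > dim(X))) stop("window exceeds grid extent")
  n <- boxSums3d(array(1, dim(X)), s)
  sx <- boxSums3d(X, s)
  sy <- boxSums3d(Y, s)
  sxx <- boxSums3d(X * X, s)
  syy <- boxSums3d(Y * Y, s)
  sxy <- boxSums3d(X * Y, s)
  cov <- sxy - sx * sy / n
  vx <- pmax(sxx - sx^2 / n, 0)
  vy <- pmax(syy - sy^2 / n, 0)
  den <- sqrt(vx * vy)
  cc <- ifelse(den > 1e-10, cov / den, 0)
  -mean(cc)
}

#' Root-mean-square similarity loss
#'
#' The square root of the mean squared difference, as published; used for
#' the per-region mask channels.
#'
#' @param X,Y congruent numeric grids.
#' @return scalar >= 0.
#' @export
simMSE <- function(X, Y) {
  checkDims(X, Y)
  sqrt(mean((X - Y)^2))
}

#' Identity penalty of an affine transform
#'
#' ||A - I||_F^2 + ||b||_2^2: the squared Frobenius distance of the linear
#' part from the identity plus the squared offset norm, penalizing affine
#' transforms that stray from the identity.
#'
#' @param t an [AffineTransform3D].
#' @return scalar >= 0.
#' @export
affineIdentityPenalty <- function(t) {
  sum((t@A - diag(3))^2) + sum(t@b^2)
}

#' Scaling penalty of an affine transform
#'
#' Constrains brain scaling in the affine matrix.  The default "det" mode
#' penalizes |det(A) - 1| (volume change).  The "literal_rank" mode computes
#' |rank(A) - 1| exactly as printed in the source formulation; it is
#' integer-valued and equals 2 for any invertible A, so it is kept only as a
#' documented alternative reading.
#'
#' @param t an [AffineTransform3D].
#' @param mode "det" (default) or "literal_rank".
#' @return scalar >= 0.
#' @export
affineScalingPenalty <- function(t, mode = c("det", "literal_rank")) {
  mode <- match.arg(mode)
  if (mode == "det") {
    abs(det(t@A) - 1)
  } else {
    abs(qr(t@A)$rank - 1)
  }
}

#' Smoothness penalty of a deformation field
#'
#' Mean L1 norm of the forward-difference spatial gradients of all three
#' displacement components (||grad Phi||_1), zero iff the field is spatially
#' constant.
#'
#' @param f a [DeformationField].
#' @return scalar >= 0.
#' @export
fieldSmoothness <- function(f) {
  disp <- f@disp
  d <- dim(disp)[1:3]
  tot <- 0
  cnt <- 0
  for (k in 1:3) {
    comp <- disp[, , , k]
    for (axis in 1:3) {
      if (d[axis] < 2L) next
      idx1 <- lapply(1:3, function(a) seq_len(d[a]))
      idx0 <- idx1
      idx1[[axis]] <- 2:d[axis]
      idx0[[axis]] <- 1:(d[axis] - 1L)
      g <- comp[idx1[[1]], idx1[[2]], idx1[[3]]] -
        comp[idx0[[1]], idx0[[2]], idx0[[3]]]
      tot <- tot + sum(abs(g))
      cnt <- cnt + length(g)
    }
  }
  if (cnt == 0) return(0)
  tot / cnt
}

#' Approximate inverse of a deformation field
#'
#' First-order inverse in the nonlinear transformation space: each component
#' is resampled (trilinear interpolation) at the field-displaced positions
#' and negated, Phi^-1 = (-Phi_z o Phi, -Phi_y o Phi, -Phi_x o Phi).
#' Displaced sample positions are clamped to the grid.  For smooth fields of
#' modest magnitude the composition residual ||Phi o Phi^-1|| is small
#' relative to ||Phi||.
#'
#' @param f a [DeformationField].
#' @return the approximate inverse [DeformationField].
#' @export
approxInverseField <- function(f) {
  disp <- f@disp
  d <- dim(disp)[1:3]
  g <- coordGrid(d)
  pos <- g + matrix(disp, ncol = 3)
  for (k in 1:3) pos[, k] <- pmin(pmax(pos[, k], 0), d[k] - 1)
  out <- array(0, dim(disp))
  for (k in 1:3) {
    out[, , , k] <- -array(sampleAt(disp[, , , k], pos, "linear"), d)
  }
  deformationField(out)
}

#' Inverse-consistency loss
#'
#' Root-mean-square difference between the registered grid Y and Y resampled
#' through the approximate inverse field, rms(Y - Y o Phi^-1): a constraint
#' on the nonlinear transformation space that discourages non-invertible
#' fields.  Zero for a zero field or a constant grid.
#'
#' @param Y numeric 3D grid (the registered brain).
#' @param f a [DeformationField] congruent with Y.
#' @return scalar >= 0.
#' @export
inverseConsistency <- function(Y, f) {
  checkCongruent(Y, f@disp[, , , 1])
  inv <- approxInverseField(f)
  d <- dim(Y)
  pos <- coordGrid(d) + matrix(inv@disp, ncol = 3)
  for (k in 1:3) pos[, k] <- pmin(pmax(pos[, k], 0), d[k] - 1)
  I <- array(sampleAt(Y, pos, "linear"), d)
  sqrt(mean((Y - I)^2))
}

#' Multi-constraint registration objective
#'
#' The weighted sum of per-channel similarity losses — mutual information
#' for the original brain, local cross-correlation for the style-proxy
#' brain, root-mean-square difference for each region mask — plus the
#' penalties of the requested stage: the affine stage adds the identity and
#' scaling penalties, the deformable stage adds the field smoothness and
#' inverse-consistency terms.  Default channel weights are 0.70 for the
#' original brain, 0.15 for the style proxy and 0.15 split evenly across the
#' region masks.
#'
#' @param channels list of channels, each `list(x = reference grid, y =
#'   warped source grid, spec = similaritySpec(...))`; the spec weights must
#'   sum to 1 (tolerance 1e-6).
#' @param stage "rigid", "affine" or "deformable".
#' @param t the [AffineTransform3D] under evaluation (affine stage).
#' @param f the [DeformationField] under evaluation (deformable stage).
#' @param penaltyWeight multiplier on the stage penalties (default 1).
#' @param scalingMode passed to [affineScalingPenalty()].
#' @return scalar objective (lower is better).
#' @export
multiconstraintObjective <- function(channels,
                                     stage = c("rigid", "affine",
                                               "deformable"),
                                     t = NULL, f = NULL, penaltyWeight = 1,
                                     scalingMode = "det") {
  stage <- match.arg(stage)
  w <- vapply(channels, function(ch) ch$spec@weight, 0)
  if (abs(sum(w) - 1) > 1e-6) {
    stop("channel weights must sum to 1 (got ", sum(w), ")")
  }
  val <- 0
  for (ch in channels) {
    sim <- switch(ch$spec@kind,
      mi = simMI(ch$x, ch$y, ch$spec@bins),
      lcc = simLCC(ch$x, ch$y, ch$spec@window),
      mse = simMSE(ch$x, ch$y)
    )
    val <- val + ch$spec@weight * sim
  }
  if (stage == "affine") {
    if (is.null(t)) stop("affine stage requires t")
    val <- val + penaltyWeight *
      (affineIdentityPenalty(t) + affineScalingPenalty(t, scalingMode))
  } else if (stage == "deformable") {
    if (is.null(f)) stop("deformable stage requires f")
    # the inverse-consistency term is evaluated on the registered original
    # brain (the highest-weight channel)
    yMain <- channels[[which.max(w)]]$y
    val <- val + penaltyWeight *
      (fieldSmoothness(f) + inverseConsistency(yMain, f))
  }
  val
}

#' Default registration channel weights
#'
#' 0.70 on the original brain, 0.15 on the style proxy, 0.15 split evenly
#' across region masks.
#'
#' @param nRegions number of region-mask channels.
#' @return numeric vector of weights summing to 1: original, style proxy,
#'   then one per region.
#' @export
defaultChannelWeights <- function(nRegions) {
  if (nRegions > 0) {
    c(0.70, 0.15, rep(0.15 / nRegions, nRegions))
  } else {
    c(0.70 / 0.85, 0.15 / 0.85)
  }
}
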
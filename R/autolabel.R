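# Automated voxel-level axon annotation: adaptive binarization (Gaussian
# pre-smoothing, difference of Gaussians, thresholding), fragment connection
# by dilation, topology-preserving 3D skeletonization, and unified-thickness
# dilation of the centerlines.

#' Annotation parameters
#'
#' @param gaussianKernel odd Gaussian pre-smoothing kernel edge length
#'   (default 3, i.e. a 3 x 3 x 3 kernel).
#' @param dogSigmas two difference-of-Gaussians sigmas in voxels (small,
#'   large); the defaults (1.0, 2.5) band-pass axons one to three voxels
#'   wide.
#' @param threshold numeric DoG threshold, or "auto" for Otsu's method on the
#'   DoG response of nonzero voxels.
#' @param connectRadius dilation ball radius (voxels) used to connect
#'   adjacent binarized fragments.
#' @param dense if TRUE the binarized-and-connected mask itself is the
#'   annotation (for extremely dense axon cubes whose skeletons would not
#'   reflect real structure); if FALSE (sparse mode) the annotation is the
#'   thickened skeleton.
#' @return a list of validated parameters.
#' @export
annotateParams <- function(gaussianKernel = 3L, dogSigmas = c(1.0, 2.5),
                           threshold = "auto", connectRadius = 1L,
                           dense = FALSE) {
  gaussianKernel <- as.integer(gaussianKernel)
  if (gaussianKernel < 1L || gaussianKernel %% 2L == 0L) {
    stop("gaussianKernel must be odd and >= 1")
  }
  if (length(dogSigmas) != 2L || dogSigmas[1] >= dogSigmas[2]) {
    stop("dogSigmas must be (small, large) with small < large")
  }
  if (!identical(threshold, "auto") && !is.numeric(threshold)) {
    stop("threshold must be numeric or \"auto\"")
  }
  if (connectRadius < 0L) stop("connectRadius must be >= 0")
  list(gaussianKernel = gaussianKernel, dogSigmas = dogSigmas,
       threshold = threshold, connectRadius = as.integer(connectRadius),
       dense = isTRUE(dense))
}

#' Binarize axons by difference of Gaussians and thresholding
#'
#' Pre-smooths the cube with a small Gaussian kernel, computes a difference
#' of Gaussians to increase the visibility of thin tubular axons, and
#' thresholds the response.  The "auto" threshold is Otsu's method computed
#' on the DoG response of the cube's nonzero voxels.
#'
#' @param cube an [IntensityCube] or 3D array.
#' @param p parameters from [annotateParams()].
#' @return logical 3D mask.
#' @export
binarizeAxons <- function(cube, p = annotateParams()) {
  a <- if (is(cube, "IntensityCube")) cube@data else cube
  if (length(a) == 0) stop("cube is empty")
  preSigma <- 0.3 * ((p$gaussianKernel - 1) / 2 - 1) + 0.8
  sm <- gaussianSmooth3d(a, preSigma)
  dog <- gaussianSmooth3d(sm, p$dogSigmas[1]) -
    gaussianSmooth3d(sm, p$dogSigmas[2])
  thr <- p$threshold
  if (identical(thr, "auto")) {
    v <- dog[a != 0]
    if (!length(v) || diff(range(v)) == 0) {
      warning("constant cube: auto threshold undefined, returning empty mask")
      return(array(FALSE, dim(a)))
    }
    thr <- otsuThreshold(v)
  }
  dog >= thr
}

#' Connect adjacent binarized fragments
#'
#' Morphological dilation by a Euclidean ball, used to bridge small gaps in
#' the binarized axons so the tree topology survives skeletonization.
#' Radius 0 is the identity.
#'
#' @param mask logical 3D mask.
#' @param radius ball radius in voxels (>= 0).
#' @return logical 3D mask (superset of the input).
#' @export
connectFragments <- function(mask, radius = 1L) {
  mask <- asMask(mask)
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0L) return(mask)
  dilateOffsets(mask, ballOffsets(radius))
}

#' Skeletonize a binary mask
#'
#' Topology-preserving 3D thinning (sequential six-subiteration removal of
#' simple points, keeping curve endpoints), reducing tubular structures to
#' single-voxel-wide centerlines.  The skeleton is a subset of the mask and
#' the operation is idempotent on already-thin curves.
#'
#' @param mask logical 3D mask.
#' @return logical 3D skeleton.
#' @export
skeletonizeMask <- function(mask) {
  mask <- asMask(mask)
  if (!any(mask)) return(mask)
  .cpp_thin3d(mask, dim(mask))
}

#' Thicken a skeleton to unified-thickness annotation
#'
#' Every centerline voxel extends one more voxel in the six axis directions
#' of 3D space (left/right, top/bottom, front/back), clipped at cube faces,
#' yielding annotations of uniform local thickness.
#'
#' @param skel logical 3D skeleton.
#' @return an [AnnotationCube].
#' @export
thickenSkeleton <- function(skel) {
  skel <- asMask(skel)
  out <- skel
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    out <- out | shift3d(skel, off[1], off[2], off[3], fill = FALSE)
  }
  AnnotationCube(out * 1)
}

#' Automatically annotate an axon cube
#'
#' The full automated annotation workflow: binarize (Gaussian smoothing,
#' difference of Gaussians, thresholding), connect fragments by dilation,
#' skeletonize, and thicken the centerlines to unified thickness.  In sparse
#' mode (default) the annotation is the thickened skeleton; in dense mode
#' (`p$dense = TRUE`) it is the binarized-and-connected mask, whose skeleton
#' would be too dense to reflect real axon structure.
#'
#' @param cube an [IntensityCube] or 3D array.
#' @param p parameters from [annotateParams()].
#' @return a [CubePair] with provenance "auto_annotated"; both the skeleton
#'   and the annotation are retained.
#' @export
annotateAxonCube <- function(cube, p = annotateParams()) {
  if (!is(cube, "IntensityCube")) cube <- IntensityCube(cube)
  mask <- binarizeAxons(cube, p)
  mask <- connectFragments(mask, p$connectRadius)
  skel <- skeletonizeMask(mask)
  ann <- if (p$dense) AnnotationCube(mask * 1) else thickenSkeleton(skel)
  storage.mode(skel) <- "double"
  skel <- skel * (ann@data > 0)  # clip to the annotation support
  CubePair(cube, ann, skeleton = skel, provenance = "auto_annotated")
}

#' Annotate an artifact cube
#'
#' Artifact cubes represent areas with no axons; their annotation is all
#' zero by definition.
#'
#' @param cube an [IntensityCube] or 3D array.
#' @return a [CubePair] with an all-zero annotation, provenance
#'   "auto_annotated".
#' @export
annotateArtifactCube <- function(cube) {
  if (!is(cube, "IntensityCube")) cube <- IntensityCube(cube)
  CubePair(cube, AnnotationCube(array(0, dim(cube@data))),
           provenance = "auto_annotated")
}
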
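# Volumetric and centerline-aware segmentation metrics, region-wise Dice
# reporting and landmark deviation.

#' Dice score of two binary masks
#'
#' 2|P intersect G| / (|P| + |G|).  Two empty masks score 1 (a perfect empty
#' prediction is not penalized).
#'
#' @param pred,gt congruent binary 3D masks.
#' @return scalar in [0, 1].
#' @export
diceScore <- function(pred, gt) {
  pred <- asMask(pred)
  gt <- asMask(gt)
  checkCongruent(pred, gt)
  np <- sum(pred)
  ng <- sum(gt)
  if (np + ng == 0) return(1)
  2 * sum(pred & gt) / (np + ng)
}

#' Centerline scores: ClDice, ClPrecision, ClRecall
#'
#' With S() the 3D skeletonization of [skeletonizeMask()] and V() the
#' volumetric mask: ClPrecision = |S(P) intersect V(G)| / |S(P)| (how much of
#' the predicted centerline lies inside the true axon volume), ClRecall =
#' |S(G) intersect V(P)| / |S(G)| (how much of the true centerline is covered
#' by the prediction), and ClDice is their harmonic mean.  These
#' centerline-aware scores evaluate the connectivity of tubular structures
#' that volumetric Dice cannot.  Conventions: both masks empty scores all 1;
#' exactly one empty scores all 0.  Raw (unthickened) skeletons are used.
#'
#' @param pred,gt congruent binary 3D masks.
#' @return named numeric: cl_dice, cl_precision, cl_recall.
#' @export
clScores <- function(pred, gt) {
  pred <- asMask(pred)
  gt <- asMask(gt)
  checkCongruent(pred, gt)
  if (!any(pred) && !any(gt)) {
    return(c(cl_dice = 1, cl_precision = 1, cl_recall = 1))
  }
  if (!any(pred) || !any(gt)) {
    return(c(cl_dice = 0, cl_precision = 0, cl_recall = 0))
  }
  sp <- skeletonizeMask(pred)
  sg <- skeletonizeMask(gt)
  prec <- sum(sp & gt) / sum(sp)
  rec <- sum(sg & pred) / sum(sg)
  cld <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(cl_dice = cld, cl_precision = prec, cl_recall = rec)
}

#' Region-wise Dice report across brains
#'
#' Computes the per-region binary Dice between predicted and ground-truth
#' label volumes for one or several brains, the median score per region
#' across brains, and the average of the per-region medians (the headline
#' registration quality summary).
#'
#' @param predLabels a [LabelVolume] (or integer array) or a list of them.
#' @param gtLabels matching ground-truth label volume(s).
#' @param regions region table (see [regionTable()]); defaults to the ids
#'   present in the ground truth.
#' @return list with `items` (data.frame brain x region Dice), `medians`
#'   (named per-region medians), `averageMedian`, and `notes` for regions
#'   absent from both grids.
#' @export
regionDiceReport <- function(predLabels, gtLabels, regions = NULL) {
  asList <- function(x) if (is.list(x)) x else list(x)
  pl <- lapply(asList(predLabels), function(v) {
    if (is(v, "Volume")) v@data else v
  })
  gl <- lapply(asList(gtLabels), function(v) {
    if (is(v, "Volume")) v@data else v
  })
  if (length(pl) != length(gl)) stop("prediction/truth count mismatch")
  ids <- if (!is.null(regions)) {
    regions$region_id
  } else {
    sort(setdiff(unique(unlist(lapply(gl, function(a) unique(as.vector(a))))),
                 0))
  }
  items <- NULL
  notes <- character(0)
  for (b in seq_along(pl)) {
    checkCongruent(pl[[b]], gl[[b]])
    for (id in ids) {
      p <- pl[[b]] == id
      g <- gl[[b]] == id
      if (!any(p) && !any(g)) {
        notes <- c(notes, sprintf("region %d absent from brain %d", id, b))
        next
      }
      items <- rbind(items, data.frame(brain = b, region_id = id,
                                       dice = diceScore(p, g)))
    }
  }
  if (is.null(items)) {
    return(list(items = data.frame(), medians = numeric(0),
                averageMedian = NA_real_, notes = notes))
  }
  meds <- c(tapply(items$dice, items$region_id, stats::median))
  list(items = items, medians = meds, averageMedian = mean(meds),
       notes = notes)
}

#' Landmark deviation in physical units
#'
#' Euclidean distance between matched landmark pairs, in micrometers given
#' the voxel spacing.
#'
#' @param a,b n x 3 matrices of (z, y, x) voxel coordinates, matched by row.
#' @param spacing voxel size per axis in micrometers.
#' @return list with `distances` (per pair, um), `mean` and `median`.
#' @export
landmarkDeviation <- function(a, b, spacing = c(1, 1, 1)) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  if (nrow(a) != nrow(b)) stop("landmark lists differ in length")
  d <- sweep(a - b, 2, spacing, "*")
  dist <- sqrt(rowSums(d^2))
  list(distances = dist, mean = mean(dist), median = stats::median(dist))
}
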
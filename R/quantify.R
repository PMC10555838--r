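# Region-wise axon density and point-count quantification in atlas space,
# with hierarchical rollups and heatmap export.

#' Region-wise axon density
#'
#' Counts axon voxels and region support per label and reports the density
#' (axon voxels / region voxels, a unit-free fraction in [0, 1]) for every
#' region.  Label 0 (outside brain) is excluded; axon voxels falling on
#' labels missing from the region table are counted under an "unknown" row
#' with a warning.  Raw counts are emitted alongside densities.
#'
#' @param axons binary axon [Volume] (or 3D array) in reference space.
#' @param labels congruent [LabelVolume] (or integer array).
#' @param table region table (see [regionTable()]); defaults to the label
#'   volume's table or the ids present.
#' @return data.frame with columns region_id, acronym, parent_id,
#'   region_voxels, axon_voxels, density, depth.
#' @export
regionAxonDensity <- function(axons, labels, table = NULL) {
  a <- if (is(axons, "Volume")) axons@data else axons
  l <- if (is(labels, "Volume")) labels@data else labels
  checkCongruent(a, l)
  if (!all(a %in% c(0, 1))) stop("axon volume must be binary")
  if (is.null(table)) {
    table <- if (is(labels, "LabelVolume") && nrow(labels@regionTable)) {
      labels@regionTable
    } else {
      ids <- sort(setdiff(unique(as.vector(l)), 0))
      data.frame(region_id = ids, acronym = paste0("R", ids),
                 parent_id = NA_integer_)
    }
  }
  present <- sort(setdiff(unique(as.vector(l)), 0))
  unknown <- setdiff(present, table$region_id)
  if (length(unknown)) {
    warning("labels lacking table entries counted as unknown: ",
            paste(unknown, collapse = ", "))
    table <- rbind(table[, c("region_id", "acronym", "parent_id")],
                   data.frame(region_id = unknown,
                              acronym = paste0("unknown_", unknown),
                              parent_id = NA_integer_))
  }
  maxId <- max(c(table$region_id, 1L))
  regionVox <- tabulate(l[l > 0], maxId)
  axonVox <- tabulate(l[l > 0 & a > 0], maxId)
  out <- data.frame(
    region_id = table$region_id,
    acronym = table$acronym,
    parent_id = table$parent_id,
    region_voxels = regionVox[table$region_id],
    axon_voxels = axonVox[table$region_id],
    stringsAsFactors = FALSE
  )
  out$density <- ifelse(out$region_voxels > 0,
                        out$axon_voxels / out$region_voxels, 0)
  out$depth <- regionDepth(out)
  rownames(out) <- NULL
  out
}

regionDepth <- function(df) {
  idx <- match(df$parent_id, df$region_id)
  depth <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    d <- 0L
    j <- i
    while (!is.na(idx[j])) {
      d <- d + 1L
      j <- idx[j]
      if (d > nrow(df)) stop("cycle in parent links")
    }
    depth[i] <- d
  }
  depth
}

#' Roll region counts up the hierarchy
#'
#' Sums axon and region voxel counts bottom-up so that every parent row
#' contains its own voxels plus all descendants', and recomputes densities
#' from the rolled-up counts.  Idempotent.
#'
#' @param t density table from [regionAxonDensity()].
#' @param table region table supplying the hierarchy (defaults to the parent
#'   links in `t`).
#' @return the table with rolled-up counts and densities (attribute
#'   `rolledUp` marks it, making the rollup idempotent).
#' @export
aggregateHierarchy <- function(t, table = NULL) {
  if (isTRUE(attr(t, "rolledUp"))) return(t)
  if (!is.null(table)) {
    t$parent_id <- table$parent_id[match(t$region_id, table$region_id)]
  }
  idx <- match(t$parent_id, t$region_id)
  depth <- regionDepth(t)  # errors on cycles
  own_region <- t$region_voxels
  own_axon <- t$axon_voxels
  # deepest first so children are final before their parents accumulate
  for (i in order(depth, decreasing = TRUE)) {
    j <- idx[i]
    if (!is.na(j)) {
      t$region_voxels[j] <- t$region_voxels[j] + t$region_voxels[i]
      t$axon_voxels[j] <- t$axon_voxels[j] + t$axon_voxels[i]
    }
  }
  t$density <- ifelse(t$region_voxels > 0,
                      t$axon_voxels / t$region_voxels, 0)
  attr(t, "rolledUp") <- TRUE
  t
}

#' Count points per labeled region
#'
#' Looks up the region label under each point (rounded to the nearest
#' voxel).  Out-of-bounds points are counted under the sentinel id -1 with a
#' warning.
#'
#' @param points n x 3 matrix (or data.frame with z, y, x columns) of
#'   0-based voxel coordinates.
#' @param labels a [LabelVolume] (or integer 3D array).
#' @return named integer vector: region id -> count.
#' @export
countPointsByRegion <- function(points, labels) {
  l <- if (is(labels, "Volume")) labels@data else labels
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("z", "y", "x")])
  }
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) == 0) return(integer(0))
  d <- dim(l)
  p <- round(points)
  oob <- p[, 1] < 0 | p[, 2] < 0 | p[, 3] < 0 |
    p[, 1] > d[1] - 1 | p[, 2] > d[2] - 1 | p[, 3] > d[3] - 1
  ids <- rep(-1L, nrow(p))
  if (any(!oob)) {
    lin <- p[!oob, 1] + d[1] * (p[!oob, 2] + d[2] * p[!oob, 3]) + 1
    ids[!oob] <- as.integer(l[lin])
  }
  if (any(oob)) warning(sum(oob), " out-of-bounds points counted under -1")
  tab <- table(ids)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Axon density heatmap
#'
#' Gaussian-smoothed axon density volume (sigma in voxels; sigma 0 returns
#' the input).  Smoothing conserves total mass away from the faces.  Use
#' [maxProjections()] for the per-view maximum-intensity projections.
#'
#' @param axons binary axon [Volume] (or 3D array).
#' @param sigma Gaussian sigma in voxels (>= 0).
#' @return a [Volume] heatmap.
#' @export
densityHeatmap <- function(axons, sigma = 2) {
  if (sigma < 0) stop("sigma must be >= 0")
  sp <- if (is(axons, "Volume")) axons@spacing else c(1, 1, 1)
  a <- if (is(axons, "Volume")) axons@data else axons
  if (sigma == 0) return(Volume(a, sp))
  Volume(gaussianSmooth3d(a, sigma), sp)
}

#' Maximum-intensity projections
#'
#' Per-view maximum-intensity projections of a volume: horizontal (along z),
#' coronal (along y) and sagittal (along x).
#'
#' @param v a [Volume] or 3D array.
#' @return list of three matrices: horizontal, coronal, sagittal.
#' @export
maxProjections <- function(v) {
  a <- if (is(v, "Volume")) v@data else v
  list(horizontal = apply(a, c(2, 3), max),
       coronal = apply(a, c(1, 3), max),
       sagittal = apply(a, c(1, 2), max))
}
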
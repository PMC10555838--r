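#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib axocarto, .registration = TRUE
NULL

# Axis convention used throughout the package: arrays have
# dim = (depth, height, width) = (z, y, x); voxel coordinates are 0-based
# (z, y, x) triples with voxel centers at integer positions, and all index
# ranges are half-open [low, low + extent).

setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Volume: a whole-brain scalar intensity grid
#'
#' A 3D scalar grid with per-axis voxel spacing and a physical origin, both in
#' micrometers.  Axis order is (depth, height, width) = (z, y, x) and voxel
#' coordinates are 0-based.
#'
#' @slot data 3D numeric array, dim = (depth, height, width).
#' @slot spacing numeric(3), voxel size per axis in micrometers.
#' @slot origin numeric(3), physical offset of voxel (0,0,0) in micrometers.
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("Volume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all extents must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be three strictly positive finite values")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite values")
  if (any(!is.finite(object@data))) return("intensities must be finite")
  TRUE
})

#' LabelVolume: an integer region-label grid
#'
#' A [Volume] whose voxels carry integer region ids (0 = outside brain),
#' optionally tied to a hierarchical region table (see [regionTable()]).
#'
#' @slot regionTable data.frame with columns `region_id`, `acronym`,
#'   `parent_id` (NA for roots), or an empty data.frame.
#' @export
setClass("LabelVolume", contains = "Volume",
  representation(regionTable = "data.frame"),
  prototype(regionTable = data.frame())
)

setValidity("LabelVolume", function(object) {
  v <- object@data
  if (any(v != round(v)) || any(v < 0)) {
    return("labels must be non-negative integers")
  }
  if (nrow(object@regionTable) > 0) {
    bad <- setdiff(setdiff(unique(as.vector(v)), 0),
                   object@regionTable$region_id)
    if (length(bad)) {
      return(paste("label ids missing from region table:",
                   paste(bad, collapse = ", ")))
    }
  }
  TRUE
})

#' IntensityCube: a fixed-size sub-volume
#'
#' The unit of axon annotation and augmentation: a cubic (by default
#' 150 voxels per axis) intensity grid cut from a parent [Volume], carrying
#' the 0-based voxel offset of its low corner inside the parent.
#'
#' @slot data 3D numeric array.
#' @slot offset integer(3), 0-based low-corner voxel coordinate in the parent.
#' @slot parentId character provenance string ("" when standalone).
#' @slot padded logical flag: TRUE when part of the cube fell outside the
#'   parent volume and was zero-filled.
#' @export
setClass("IntensityCube",
  representation(data = "array", offset = "integer", parentId = "character",
                 padded = "logical"),
  prototype(offset = c(0L, 0L, 0L), parentId = "", padded = FALSE)
)

setValidity("IntensityCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || any(d < 1L)) return("data must be a 3D array")
  if (length(object@offset) != 3L) return("offset must be integer(3)")
  if (any(!is.finite(object@data))) return("intensities must be finite")
  TRUE
})

#' AnnotationCube: a binary axon mask
#'
#' Binary mask congruent with an [IntensityCube]; 1 = axon, 0 = background.
#'
#' @slot data 3D array of 0/1 values.
#' @export
setClass("AnnotationCube", representation(data = "array"))

setValidity("AnnotationCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || any(d < 1L)) return("data must be a 3D array")
  if (!all(object@data %in% c(0, 1))) return("values must be 0 or 1")
  TRUE
})

#' CubePair: an intensity cube with its annotation
#'
#' A 3D intensity cube paired with its binary axon annotation, an optional
#' ground-truth centerline skeleton, a provenance tag and the seed it was
#' generated from.  Augmented pairs additionally record the operator chain
#' that produced them.
#'
#' @slot intensity an [IntensityCube].
#' @slot annotation an [AnnotationCube] congruent with `intensity`.
#' @slot skeleton optional binary 3D array (centerline voxels), subset of the
#'   annotation, or NULL.
#' @slot provenance one of "synthetic", "auto_annotated", "augmented".
#' @slot seed integer seed used to generate the pair (NA if not applicable).
#' @slot chain list of operator records (name + parameters) for augmented
#'   pairs; empty otherwise.
#' @export
setClass("CubePair",
  representation(intensity = "IntensityCube", annotation = "AnnotationCube",
                 skeleton = "arrayOrNULL", provenance = "character",
                 seed = "integer", chain = "list"),
  prototype(skeleton = NULL, provenance = "synthetic", seed = NA_integer_,
            chain = list())
)

setValidity("CubePair", function(object) {
  if (!identical(dim(object@intensity@data), dim(object@annotation@data)))
    return("intensity and annotation must be congruent")
  if (!object@provenance %in% c("synthetic", "auto_annotated", "augmented"))
    return("unknown provenance")
  if (!is.null(object@skeleton)) {
    if (!identical(dim(object@skeleton), dim(object@annotation@data)))
      return("skeleton must be congruent with the annotation")
    if (any(object@skeleton == 1 & object@annotation@data == 0))
      return("skeleton must be a subset of the annotation")
  }
  TRUE
})

#' PhantomBrain: a synthetic brain with exact ground truth
#'
#' Smooth ellipsoidal "brain" volume with nested ellipsoidal labeled regions,
#' a region table and landmarks at region centroids.  Serves as a test double
#' for an LSFM brain plus its atlas annotation.
#'
#' @slot intensity a [Volume].
#' @slot labels a [LabelVolume] congruent with `intensity`.
#' @slot table region table data.frame (see [regionTable()]).
#' @slot landmarks numeric matrix, one 0-based (z, y, x) voxel triple per row.
#' @export
setClass("PhantomBrain",
  representation(intensity = "Volume", labels = "LabelVolume",
                 table = "data.frame", landmarks = "matrix")
)

setValidity("PhantomBrain", function(object) {
  if (!identical(dim(object@intensity@data), dim(object@labels@data)))
    return("labels must be congruent with intensity")
  if (ncol(object@landmarks) != 3L) return("landmarks must be n x 3")
  bad <- setdiff(setdiff(unique(as.vector(object@labels@data)), 0),
                 object@table$region_id)
  if (length(bad)) return("every label id must be in the region table")
  TRUE
})

#' AffineTransform3D: rigid/affine point map
#'
#' Represents the point map y = A x + b on 0-based (z, y, x) voxel
#' coordinates.  Warping a volume "by" a transform moves image content the
#' way the point map moves points (the resampler pulls back through the
#' inverse map).
#'
#' @slot A 3x3 linear matrix.
#' @slot b numeric(3) offset in voxels.
#' @export
setClass("AffineTransform3D",
  representation(A = "matrix", b = "numeric"),
  prototype(A = diag(3), b = c(0, 0, 0))
)

setValidity("AffineTransform3D", function(object) {
  if (!all(dim(object@A) == c(3L, 3L))) return("A must be 3x3")
  if (length(object@b) != 3L) return("b must have length 3")
  if (any(!is.finite(object@A)) || any(!is.finite(object@b)))
    return("entries must be finite")
  if (det(object@A) <= 0) return("det(A) must be positive")
  TRUE
})

#' DeformationField: per-voxel displacement field
#'
#' Dense displacement field on the reference grid: `disp[z, y, x, k]` is the
#' displacement (in voxels) along axis k at reference voxel (z, y, x).  The
#' pull-back convention is used: a warped image samples the moving image at
#' position q + disp(q).
#'
#' @slot disp 4D numeric array, dim = (depth, height, width, 3).
#' @export
setClass("DeformationField", representation(disp = "array"))

setValidity("DeformationField", function(object) {
  d <- dim(object@disp)
  if (length(d) != 4L || d[4] != 3L) {
    return("disp must be a 4D array with last extent 3")
  }
  if (any(!is.finite(object@disp))) return("displacements must be finite")
  TRUE
})

#' SimilaritySpec: per-channel similarity configuration
#'
#' Which similarity loss a registration channel contributes (mutual
#' information, local cross-correlation or root-mean-square difference),
#' its parameters and its weight in the multi-constraint objective.
#'
#' @slot kind "mi", "lcc" or "mse".
#' @slot weight non-negative channel weight; weights sum to 1 across
#'   channels.
#' @slot bins number of histogram bins for "mi" (default 32).
#' @slot window odd local-window edge length for "lcc" (default 9).
#' @export
setClass("SimilaritySpec",
  representation(kind = "character", weight = "numeric", bins = "integer",
                 window = "integer"),
  prototype(kind = "mi", weight = 1, bins = 32L, window = 9L)
)

setValidity("SimilaritySpec", function(object) {
  if (!object@kind %in% c("mi", "lcc", "mse")) return("unknown kind")
  if (object@weight < 0) return("weight must be >= 0")
  if (object@bins < 2L) return("bins must be >= 2")
  if (object@window < 3L || object@window %% 2L == 0L)
    return("window must be odd and >= 3")
  TRUE
})

#' RegistrationBundle: multi-channel registration input
#'
#' The multi-constraint registration input: the original brain, an
#' intensity-normalized style-proxy brain, per-region binary masks and
#' optional landmarks, all on one grid.
#'
#' @slot original a [Volume].
#' @slot styleProxy a [Volume] congruent with `original`.
#' @slot regionMasks named list of congruent binary [Volume]s, names are
#'   region ids.
#' @slot landmarks optional numeric matrix of 0-based (z, y, x) rows.
#' @export
setClass("RegistrationBundle",
  representation(original = "Volume", styleProxy = "Volume",
                 regionMasks = "list", landmarks = "matrixOrNULL"),
  prototype(landmarks = NULL)
)

setValidity("RegistrationBundle", function(object) {
  d <- dim(object@original@data)
  if (!identical(dim(object@styleProxy@data), d))
    return("styleProxy must be congruent with original")
  for (m in object@regionMasks) {
    if (!is(m, "Volume") || !identical(dim(m@data), d))
      return("every region mask must be a congruent Volume")
  }
  if (!is.null(object@landmarks) && ncol(object@landmarks) != 3L)
    return("landmarks must be n x 3")
  TRUE
})

#' RegistrationResult: fitted transforms and diagnostics
#'
#' @slot rigid fitted rigid [AffineTransform3D] (forward map, source to
#'   reference coordinates).
#' @slot affine fitted affine [AffineTransform3D] (forward map, composed
#'   after rigid).
#' @slot field fitted [DeformationField] on the reference grid.
#' @slot traces named list of per-stage best-objective traces.
#' @slot warped the source [RegistrationBundle] warped onto the reference
#'   grid.
#' @export
setClass("RegistrationResult",
  representation(rigid = "AffineTransform3D", affine = "AffineTransform3D",
                 field = "DeformationField", traces = "list",
                 warped = "RegistrationBundle")
)

# ---- show methods ----------------------------------------------------------

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %d x %d x %d (z,y,x), spacing %s um, range [%g, %g]\n",
              class(object), d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "IntensityCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("IntensityCube %d x %d x %d, offset (%s)%s\n", d[1], d[2], d[3],
              paste(object@offset, collapse = ", "),
              if (object@padded) ", zero-padded" else ""))
})

setMethod("show", "CubePair", function(object) {
  d <- dim(object@intensity@data)
  cat(sprintf(
    "CubePair %d x %d x %d [%s], %d axon voxels%s%s\n", d[1], d[2], d[3],
    object@provenance, sum(object@annotation@data),
    if (!is.null(object@skeleton))
      sprintf(", %d skeleton voxels", sum(object@skeleton)) else "",
    if (length(object@chain))
      sprintf(", chain: %s",
              paste(vapply(object@chain, `[[`, "", "op"), collapse = " -> "))
    else ""))
})

setMethod("show", "AffineTransform3D", function(object) {
  cat("AffineTransform3D (y = A x + b, voxel coordinates z,y,x)\n")
  print(round(object@A, 5))
  cat("b:", paste(round(object@b, 5), collapse = ", "), "\n")
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@disp)
  cat(sprintf("DeformationField on %d x %d x %d grid, max |disp| %.3f vox\n",
              d[1], d[2], d[3], max(abs(object@disp))))
})

setMethod("show", "PhantomBrain", function(object) {
  d <- dim(object@intensity@data)
  cat(sprintf("PhantomBrain %d x %d x %d, %d regions, %d landmarks\n",
              d[1], d[2], d[3],
              length(setdiff(unique(as.vector(object@labels@data)), 0)),
              nrow(object@landmarks)))
})

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult\n  rigid/affine forward maps fitted;",
      sprintf("field max |disp| %.3f vox\n", max(abs(object@field@disp))))
  for (nm in names(object@traces)) {
    tr <- object@traces[[nm]]
    cat(sprintf("  %s: %d evaluations, objective %.6g -> %.6g\n", nm,
                length(tr), tr[1], tr[length(tr)]))
  }
})

# ---- constructors and accessors --------------------------------------------

#' Construct a Volume
#'
#' @param data 3D numeric array, axis order (depth, height, width).
#' @param spacing voxel size per axis in micrometers.
#' @param origin physical offset in micrometers.
#' @return a [Volume].
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume", data = as.array(data) * 1.0, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelVolume
#'
#' @inheritParams Volume
#' @param regionTable optional region table (see [regionTable()]).
#' @return a [LabelVolume].
#' @export
LabelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        regionTable = data.frame()) {
  new("LabelVolume", data = as.array(data) * 1.0,
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      regionTable = regionTable)
}

#' Construct an IntensityCube
#'
#' @param data 3D numeric array.
#' @param offset 0-based low-corner voxel coordinate inside the parent.
#' @param parentId provenance string.
#' @param padded TRUE if out-of-bounds portions were zero-filled.
#' @return an [IntensityCube].
#' @export
IntensityCube <- function(data, offset = c(0L, 0L, 0L), parentId = "",
                          padded = FALSE) {
  new("IntensityCube", data = as.array(data) * 1.0,
      offset = as.integer(offset), parentId = parentId, padded = padded)
}

#' Construct an AnnotationCube
#'
#' @param data 3D array of 0/1 values.
#' @return an [AnnotationCube].
#' @export
AnnotationCube <- function(data) {
  new("AnnotationCube", data = as.array(data) * 1.0)
}

#' Construct a CubePair
#'
#' @param intensity an [IntensityCube] (a bare 3D array is accepted).
#' @param annotation an [AnnotationCube] (a bare 3D array is accepted).
#' @param skeleton optional binary 3D array of centerline voxels.
#' @param provenance "synthetic", "auto_annotated" or "augmented".
#' @param seed generating seed (or NA).
#' @param chain operator chain for augmented pairs.
#' @return a [CubePair].
#' @export
CubePair <- function(intensity, annotation, skeleton = NULL,
                     provenance = "synthetic", seed = NA_integer_,
                     chain = list()) {
  if (!is(intensity, "IntensityCube")) intensity <- IntensityCube(intensity)
  if (!is(annotation, "AnnotationCube")) {
    annotation <- AnnotationCube(annotation)
  }
  new("CubePair", intensity = intensity, annotation = annotation,
      skeleton = skeleton, provenance = provenance, seed = as.integer(seed),
      chain = chain)
}

#' Construct an affine transform
#'
#' @param A 3x3 linear matrix (default identity).
#' @param b length-3 offset in voxels (default zero).
#' @return an [AffineTransform3D] representing y = A x + b.
#' @export
affineTransform <- function(A = diag(3), b = c(0, 0, 0)) {
  new("AffineTransform3D", A = A, b = as.numeric(b))
}

#' Construct a deformation field
#'
#' @param disp 4D array (depth, height, width, 3) of voxel displacements.
#' @return a [DeformationField].
#' @export
deformationField <- function(disp) new("DeformationField", disp = disp)

#' Construct a similarity specification
#'
#' @param kind "mi", "lcc" or "mse".
#' @param weight channel weight.
#' @param bins histogram bins for mutual information.
#' @param window odd window edge length for local cross-correlation.
#' @return a [SimilaritySpec].
#' @export
similaritySpec <- function(kind = c("mi", "lcc", "mse"), weight = 1,
                           bins = 32, window = 9) {
  kind <- match.arg(kind)
  new("SimilaritySpec", kind = kind, weight = weight, bins = as.integer(bins),
      window = as.integer(window))
}

#' Construct a registration bundle
#'
#' @param original the source brain [Volume].
#' @param styleProxy intensity-normalized stand-in for the style-transferred
#'   brain; defaults to a rescaled copy of `original`.
#' @param regionMasks named list of binary [Volume]s (names = region ids).
#' @param landmarks optional n x 3 matrix of 0-based voxel coordinates.
#' @return a [RegistrationBundle].
#' @export
registrationBundle <- function(original, styleProxy = NULL,
                               regionMasks = list(), landmarks = NULL) {
  if (is.null(styleProxy)) {
    rng <- range(original@data)
    sc <- if (diff(rng) > 0) (original@data - rng[1]) / diff(rng)
          else original@data * 0
    styleProxy <- Volume(sc, original@spacing, original@origin)
  }
  new("RegistrationBundle", original = original, styleProxy = styleProxy,
      regionMasks = regionMasks, landmarks = landmarks)
}

#' @rdname accessors
#' @param object an axocarto data object.
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))

#' Accessors for axocarto data objects
#'
#' `volData()` returns the underlying 3D array; `voxelSpacing()` the per-axis
#' spacing in micrometers; `intensity()`, `annotation()` and `skeleton()` the
#' components of a [CubePair]; `cubeOffset()` the 0-based low corner of a
#' cube; `provenance()` the provenance tag; `fieldDisp()` the raw 4D
#' displacement array.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("volData", "Volume", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("volData", "IntensityCube", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("volData", "AnnotationCube", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "Volume", function(object) object@spacing)

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setMethod("intensity", "CubePair", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("intensity", "PhantomBrain", function(object) object@intensity)

#' @rdname accessors
#' @export
setGeneric("annotation", function(object) standardGeneric("annotation"))

#' @rdname accessors
#' @export
setMethod("annotation", "CubePair", function(object) object@annotation)

#' @rdname accessors
#' @export
setGeneric("skeleton", function(object) standardGeneric("skeleton"))

#' @rdname accessors
#' @export
setMethod("skeleton", "CubePair", function(object) object@skeleton)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("provenance", "CubePair", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("cubeOffset", function(object) standardGeneric("cubeOffset"))

#' @rdname accessors
#' @export
setMethod("cubeOffset", "IntensityCube", function(object) object@offset)

#' @rdname accessors
#' @export
setGeneric("labels3d", function(object) standardGeneric("labels3d"))

#' @rdname accessors
#' @export
setMethod("labels3d", "PhantomBrain", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("landmarks", function(object) standardGeneric("landmarks"))

#' @rdname accessors
#' @export
setMethod("landmarks", "PhantomBrain", function(object) object@landmarks)

#' @rdname accessors
#' @export
setMethod("landmarks", "RegistrationBundle",
          function(object) object@landmarks)

#' @rdname accessors
#' @export
setGeneric("fieldDisp", function(object) standardGeneric("fieldDisp"))

#' @rdname accessors
#' @export
setMethod("fieldDisp", "DeformationField", function(object) object@disp)
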
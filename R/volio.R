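# Volume input/output, cube extraction, whole-brain tiling and stitching.

#' Read a 3D volume
#'
#' Reads a multi-page TIFF, a directory of per-slice TIFFs (assembled in
#' lexicographic filename order, one z-slice per file) or an NRRD file into a
#' [Volume].  Axis order of the result is (depth, height, width); for TIFF
#' input, depth is the page/slice index.
#'
#' @param path file or directory path.
#' @param spacing optional voxel size override in micrometers; for NRRD the
#'   header spacing is used unless overridden.
#' @return a [Volume].
#' @export
readVolume <- function(path, spacing = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF slices found in ", path)
    slices <- vector("list", length(files))
    hdr <- tiff::readTIFF(files[1], payload = FALSE)
    intSamples <- !is.null(hdr$bits.per.sample) && hdr$bits.per.sample < 32L
    for (i in seq_along(files)) {
      s <- tryCatch(tiff::readTIFF(files[i], as.is = intSamples),
                    error = function(e) {
                      stop("cannot read slice ", files[i], ": ",
                           conditionMessage(e))
                    })
      if (length(dim(s)) > 2L) s <- s[, , 1]
      if (i > 1L && !identical(dim(s), dim(slices[[1]]))) {
        stop("slice ", files[i], " has size ",
             paste(dim(s), collapse = "x"), ", expected ",
             paste(dim(slices[[1]]), collapse = "x"))
      }
      slices[[i]] <- s
    }
    data <- array(0, c(length(slices), dim(slices[[1]])))
    for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
    return(Volume(data, spacing = spacing %||% c(1, 1, 1)))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    nr <- readNrrd(path)
    return(Volume(nr$data, spacing = spacing %||% nr$spacing))
  }
  hdr <- tiff::readTIFF(path, payload = FALSE)
  # integer TIFFs are read unscaled; 32-bit pages hold [0,1] float data
  intSamples <- !is.null(hdr$bits.per.sample) && hdr$bits.per.sample < 32L
  pages <- tiff::readTIFF(path, all = TRUE, as.is = intSamples)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("pages of ", path, " differ in size")
  }
  data <- array(0, c(length(pages), dims[[1]][1:2]))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) > 2L) p <- p[, , 1]
    data[i, , ] <- p
  }
  Volume(data, spacing = spacing %||% c(1, 1, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a 3D volume
#'
#' Writes a [Volume] as a multi-page TIFF (one page per depth slice) or an
#' NRRD file.  Integer-valued data in [0, 65535] are stored as 16-bit TIFF
#' samples without rescaling; float data in [0, 1] (e.g. probability maps) as
#' 32-bit samples; general float volumes must use NRRD, which round-trips
#' exactly.  NRRD files are written with raw little-endian encoding and the
#' volume spacing in the header.
#'
#' @param v a [Volume].
#' @param path output path.
#' @param format "tiff" or "nrrd"; inferred from the extension by default.
#' @return invisibly, `path`.
#' @export
writeVolume <- function(v, path, format = c("auto", "tiff", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
              else "tiff"
  }
  stopifnot(is(v, "Volume"))
  validObject(v)
  if (format == "nrrd") {
    writeNrrd(v@data, path, spacing = v@spacing)
    return(invisible(path))
  }
  a <- v@data
  d <- dim(a)
  int16 <- all(a == round(a)) && min(a) >= 0 && max(a) <= 65535
  if (!int16 && (min(a) < 0 || max(a) > 1)) {
    stop("TIFF output supports integer volumes in [0, 65535] or float ",
         "volumes in [0, 1]; use format = \"nrrd\" for general float data")
  }
  pages <- vector("list", d[1])
  for (i in seq_len(d[1])) {
    sl <- matrix(a[i, , ], d[2], d[3])
    pages[[i]] <- if (int16) sl / 65535 else sl
  }
  tiff::writeTIFF(pages, path, bits.per.sample = if (int16) 16L else 32L)
  invisible(path)
}

# minimal NRRD reader: attached header, raw or gzip encoding, 3D data
readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) {
      fields[[tolower(trimws(kv[1]))]] <- trimws(sub("^=", "", kv[2]))
    }
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]] %||% "raw")
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)",
                                fields[["space directions"]]))[[1]]
    vecs <- lapply(dirs, function(s) {
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
    })
    spacing <- vapply(vecs, function(v) sqrt(sum(v^2)), 0)
  }
  n <- prod(sizes)
  readPayload <- function(rcon) {
    switch(type,
      "unsigned short" = , "uint16" = , "ushort" =
        readBin(rcon, "integer", n, size = 2, signed = FALSE,
                endian = "little"),
      "short" = , "int16" =
        readBin(rcon, "integer", n, size = 2, signed = TRUE,
                endian = "little"),
      "int" = , "int32" = , "signed int" =
        readBin(rcon, "integer", n, size = 4, endian = "little"),
      "uchar" = , "unsigned char" = , "uint8" =
        readBin(rcon, "integer", n, size = 1, signed = FALSE),
      "float" = readBin(rcon, "double", n, size = 4, endian = "little"),
      "double" = readBin(rcon, "double", n, size = 8, endian = "little"),
      stop("unsupported NRRD type: ", type)
    )
  }
  if (enc == "raw") {
    vals <- readPayload(con)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", file.info(path)$size)
    raw <- memDecompress(comp, type = "gzip")
    rc <- rawConnection(raw)
    on.exit(close(rc), add = TRUE)
    vals <- readPayload(rc)
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  if (length(vals) < n) stop("truncated NRRD payload in ", path)
  list(data = array(as.numeric(vals), sizes), spacing = spacing)
}

writeNrrd <- function(data, path, spacing = c(1, 1, 1)) {
  d <- dim(data)
  int16 <- all(data == round(data)) && min(data) >= 0 && max(data) <= 65535
  type <- if (int16) "unsigned short" else "double"
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(d, collapse = " ")),
           paste0("spacings: ", paste(format(spacing, digits = 15),
                                      collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (int16) {
    writeBin(as.integer(data), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Extract a cube around a center voxel
#'
#' Cuts a cube of the requested extent centered on `center` (0-based voxel
#' coordinate).  Near volume faces the cube is clamped to the volume bounds:
#' the returned cube keeps the requested extent, out-of-bounds portions are
#' zero-filled and the cube is flagged as padded.  The recorded offset is the
#' 0-based low corner of the cube in parent coordinates (possibly negative
#' when padded).
#'
#' @param v a [Volume].
#' @param center 0-based (z, y, x) voxel triple; must lie inside the volume.
#' @param extent cube edge length in voxels (default 150).
#' @param parentId provenance string stored on the cube.
#' @return an [IntensityCube].
#' @export
extractCube <- function(v, center, extent = 150L, parentId = "") {
  stopifnot(is(v, "Volume"), extent >= 1)
  d <- dim(v@data)
  center <- as.integer(round(center))
  if (any(center < 0L) || any(center > d - 1L)) {
    stop("center (", paste(center, collapse = ", "),
         ") outside volume of shape ", paste(d, collapse = "x"))
  }
  extent <- as.integer(extent)
  low <- center - (extent - 1L) %/% 2L
  hi <- low + extent - 1L
  out <- array(0, rep(extent, 3))
  slo <- pmax(low, 0L)
  shi <- pmin(hi, d - 1L)
  dst <- lapply(1:3, function(k) (slo[k]:shi[k]) - low[k] + 1L)
  src <- lapply(1:3, function(k) (slo[k]:shi[k]) + 1L)
  out[dst[[1]], dst[[2]], dst[[3]]] <- v@data[src[[1]], src[[2]], src[[3]]]
  IntensityCube(out, offset = low, parentId = parentId,
                padded = any(low < 0L) || any(hi > d - 1L))
}

#' Tile a volume shape into cube coordinates
#'
#' Produces the low corners of fixed-size cubes covering every voxel of
#' `shape` at least once.  Tiles advance by `stride`; the last tile on each
#' axis is shifted inward so that all tiles are full-sized and within bounds.
#' Coordinates are 0-based and emitted in deterministic z-major order (z
#' fastest).
#'
#' @param shape integer(3) volume extents.
#' @param cubeExtent cube edge length (default 150).
#' @param stride step between tile corners, 0 < stride <= cubeExtent.
#' @return a data.frame with columns z, y, x (low corners) and extent.
#' @export
tileVolume <- function(shape, cubeExtent = 150L, stride = cubeExtent) {
  shape <- as.integer(shape)
  cubeExtent <- as.integer(cubeExtent)
  stride <- as.integer(stride)
  if (stride < 1L || stride > cubeExtent) {
    stop("stride must satisfy 0 < stride <= cubeExtent")
  }
  if (any(cubeExtent > shape)) {
    stop("cubeExtent ", cubeExtent, " exceeds volume shape ",
         paste(shape, collapse = "x"))
  }
  axisStarts <- function(n) {
    s <- seq.int(0L, max(n - cubeExtent, 0L), by = stride)
    if (s[length(s)] + cubeExtent < n) s <- c(s, n - cubeExtent)
    s
  }
  sz <- axisStarts(shape[1])
  sy <- axisStarts(shape[2])
  sx <- axisStarts(shape[3])
  g <- expand.grid(z = sz, y = sy, x = sx, KEEP.OUT.ATTRS = FALSE)
  g$extent <- cubeExtent
  g
}

#' Stitch per-cube grids back into a volume
#'
#' Reassembles cube-wise predictions into a whole volume.  Voxels covered by
#' several cubes are combined by the blend rule; voxels covered by none are
#' zero.  The default `max` blend is appropriate for binary or probability
#' axon maps, which should not be diluted by empty overlap.
#'
#' @param coords data.frame as returned by [tileVolume()] (columns z, y, x,
#'   extent).
#' @param grids list of 3D arrays, one per row of `coords`.
#' @param shape integer(3) output extents.
#' @param blend "max" or "mean".
#' @param spacing voxel spacing of the output volume.
#' @return a [Volume].
#' @export
stitchCubes <- function(coords, grids, shape, blend = c("max", "mean"),
                        spacing = c(1, 1, 1)) {
  blend <- match.arg(blend)
  shape <- as.integer(shape)
  if (nrow(coords) != length(grids)) {
    stop("coords and grids must have equal length")
  }
  acc <- array(if (blend == "max") -Inf else 0, shape)
  cnt <- array(0L, shape)
  for (i in seq_len(nrow(coords))) {
    g <- grids[[i]]
    ext <- rep(as.integer(coords$extent[i]), 3)
    if (!identical(dim(g), ext)) {
      stop("grid ", i, " has shape ", paste(dim(g), collapse = "x"),
           " but coord extent is ", ext[1])
    }
    lo <- as.integer(c(coords$z[i], coords$y[i], coords$x[i]))
    if (any(lo < 0L) || any(lo + ext[1] > shape)) {
      stop("cube ", i, " exceeds the output shape")
    }
    iz <- (lo[1] + 1L):(lo[1] + ext[1])
    iy <- (lo[2] + 1L):(lo[2] + ext[1])
    ix <- (lo[3] + 1L):(lo[3] + ext[1])
    if (blend == "max") {
      acc[iz, iy, ix] <- pmax(acc[iz, iy, ix], g)
    } else {
      acc[iz, iy, ix] <- acc[iz, iy, ix] + g
    }
    cnt[iz, iy, ix] <- cnt[iz, iy, ix] + 1L
  }
  if (blend == "max") {
    acc[cnt == 0L] <- 0
  } else {
    acc[cnt > 0L] <- acc[cnt > 0L] / cnt[cnt > 0L]
  }
  Volume(acc, spacing = spacing)
}
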
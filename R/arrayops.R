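# Internal voxel-grid utilities shared across modules.  All grids use axis
# order (z, y, x); coordinates are 0-based.

# run expr with a local RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

asMask <- function(x) {
  if (is(x, "AnnotationCube") || is(x, "Volume")) x <- x@data
  if (is(x, "IntensityCube")) x <- x@data
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("mask must be a 3D array")
  storage.mode(x) <- "logical"
  x
}

checkCongruent <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}

# shift a 3D array by integer offsets, filling vacated voxels with `fill`
shift3d <- function(a, dz, dy, dx, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- list(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  off <- c(dz, dy, dx)
  idx_src <- idx_dst <- vector("list", 3)
  for (k in 1:3) {
    s <- seq_len(d[k])
    keep <- s + off[k] >= 1 & s + off[k] <= d[k]
    if (!any(keep)) return(out)
    idx_src[[k]] <- s[keep]
    idx_dst[[k]] <- s[keep] + off[k]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# offsets (rows dz,dy,dx) of a Euclidean ball of radius r
ballOffsets <- function(r) {
  r <- as.integer(r)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

# binary dilation by an offset set
dilateOffsets <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offsets))) {
    out <- out | shift3d(mask, offsets[i, 1], offsets[i, 2], offsets[i, 3],
                         fill = FALSE)
  }
  out
}

gaussKernel1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution along one axis (1 = z, 2 = y, 3 = x), replicate-free
# zero boundary handling with kernel renormalization near faces so that a
# constant input stays constant
convAxis <- function(a, kernel, axis) {
  radius <- (length(kernel) - 1L) / 2L
  num <- array(0, dim(a))
  den <- array(0, dim(a))
  ones <- array(1, dim(a))
  for (i in seq_along(kernel)) {
    off <- c(0L, 0L, 0L)
    off[axis] <- i - 1L - radius
    num <- num + kernel[i] * shift3d(a, off[1], off[2], off[3])
    den <- den + kernel[i] * shift3d(ones, off[1], off[2], off[3])
  }
  num / den
}

gaussianSmooth3d <- function(a, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3)
  for (axis in 1:3) {
    if (sigma[axis] > 0) a <- convAxis(a, gaussKernel1d(sigma[axis]), axis)
  }
  a
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsuThreshold <- function(v, nbins = 256L) {
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(NA_real_)
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nbins]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  centers[which.max(between)]
}

# trilinear / nearest sampling of a 3D array at 0-based (z,y,x) coordinates
sampleAt <- function(a, coords, interp = c("linear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  storage.mode(a) <- "double"
  coords <- matrix(as.numeric(coords), ncol = 3)
  .cpp_interp3(a, dim(a), coords, interp == "nearest", fill)
}

# 0-based voxel-center coordinate grid for a shape, as an n x 3 matrix
# (memoized: registration objectives request the same grid thousands of
# times)
.gridCache <- new.env(parent = emptyenv())
coordGrid <- function(shape) {
  key <- paste(shape, collapse = "x")
  hit <- .gridCache[[key]]
  if (!is.null(hit)) return(hit)
  g <- cbind(
    z = rep.int(seq_len(shape[1]) - 1, shape[2] * shape[3]),
    y = rep.int(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3]),
    x = rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  )
  if (length(.gridCache) > 32L) rm(list = ls(.gridCache), envir = .gridCache)
  .gridCache[[key]] <- g
  g
}

# block reduction by integer factor per axis; fun = "mean" or "mode"
blockReduce <- function(a, factor, fun = c("mean", "mode")) {
  fun <- match.arg(fun)
  d <- dim(a)
  nd <- as.integer(ceiling(d / factor))
  gi <- lapply(1:3, function(k) (seq_len(d[k]) - 1L) %/% factor)
  grp <- 1L + gi[[1]][slice.index(a, 1)] +
    nd[1] * (gi[[2]][slice.index(a, 2)] + nd[2] * gi[[3]][slice.index(a, 3)])
  ng <- prod(nd)
  if (fun == "mean") {
    s <- unname(rowsum(as.vector(a), as.vector(grp)))
    cnt <- unname(rowsum(rep(1, length(a)), as.vector(grp)))
    out <- array(as.vector(s / cnt), nd)
  } else {
    vals <- as.vector(a)
    uv <- sort(unique(vals))
    counts <- matrix(0, ng, length(uv))
    for (i in seq_along(uv)) {
      counts[, i] <- unname(rowsum((vals == uv[i]) * 1, as.vector(grp),
                                   reorder = TRUE))
    }
    out <- array(uv[max.col(counts, ties.method = "first")], nd)
  }
  out
}

# 26-connected component labeling
labelComponents <- function(mask) {
  mask <- asMask(mask)
  .cpp_label26(mask, dim(mask))
}

# sliding-window box sums of edge length s (odd) via 3D summed-area table;
# windows are clipped at faces
boxSums3d <- function(a, s) {
  storage.mode(a) <- "double"
  .cpp_boxsum3(a, dim(a), as.integer(s))
}

invertAffineMat <- function(t) {
  Ai <- solve(t@A)
  affineTransform(Ai, as.numeric(-Ai %*% t@b))
}

#' Apply an affine point map to coordinates
#'
#' Maps 0-based (z, y, x) voxel coordinates through y = A x + b.
#'
#' @param t an [AffineTransform3D].
#' @param pts n x 3 matrix (or length-3 vector) of coordinates.
#' @return n x 3 matrix of mapped coordinates.
#' @export
transformPoints <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(t@A), 2, t@b, "+")
}

# rotation about grid center: A x + b with pivot c handled via b' = c - A c + b
centeredAffine <- function(A, b, shape) {
  ctr <- (shape - 1) / 2
  affineTransform(A, as.numeric(ctr - A %*% ctr) + b)
}

eulerRotation <- function(az, ay, ax) {
  # intrinsic rotations about the z, then y, then x grid axes (angles radians)
  cz <- cos(az); sz <- sin(az)
  cy <- cos(ay); sy <- sin(ay)
  cx <- cos(ax); sx <- sin(ax)
  # axis order of coordinates is (z, y, x); "rotation about z axis" mixes y,x
  Rz <- rbind(c(1, 0, 0), c(0, cz, -sz), c(0, sz, cz))
  Ry <- rbind(c(cy, 0, -sy), c(0, 1, 0), c(sy, 0, cy))
  Rx <- rbind(c(cx, -sx, 0), c(sx, cx, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}
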
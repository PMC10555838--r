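test_that("slice stacks are assembled in sorted filename order", {
  dir <- withr::local_tempdir()
  withr::with_seed(1, {
    slices <- lapply(1:10, function(i) {
      matrix(sample(0:4095, 32 * 32, TRUE), 32, 32)
    })
  })
  for (i in seq_along(slices)) {
    tiff::writeTIFF(slices[[i]] / 65535,
                    file.path(dir, sprintf("slice_%02d.tif", i)),
                    bits.per.sample = 16L)
  }
  v <- readVolume(dir)
  expect_identical(dim(volData(v)), c(10L, 32L, 32L))
  for (i in c(1, 5, 10)) {
    expect_equal(volData(v)[i, , ], slices[[i]])
  }
})

test_that("unequal slice sizes raise a format error naming the file", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0, 8, 8), file.path(dir, "a.tif"))
  tiff::writeTIFF(matrix(0, 9, 8), file.path(dir, "b.tif"))
  expect_error(readVolume(dir), "b.tif")
})

test_that("NRRD header spacing is passed through unless overridden", {
  f <- withr::local_tempfile(fileext = ".nrrd")
  v <- Volume(array(0:7, c(2, 2, 2)), spacing = c(25, 25, 25))
  writeVolume(v, f, "nrrd")
  expect_equal(voxelSpacing(readVolume(f)), c(25, 25, 25))
  expect_equal(voxelSpacing(readVolume(f, spacing = c(10, 10, 10))),
               c(10, 10, 10))
})

test_that("write/read round trips are voxel-identical", {
  withr::with_seed(2, {
    vi <- Volume(array(sample(0:65535, 8^3, TRUE), c(8, 8, 8)))
    vf <- Volume(array(stats::rnorm(8^3), c(8, 8, 8)))
  })
  ft <- withr::local_tempfile(fileext = ".tiff")
  writeVolume(vi, ft)
  expect_identical(volData(readVolume(ft)), volData(vi))  # 16-bit, unscaled
  fn <- withr::local_tempfile(fileext = ".nrrd")
  writeVolume(vf, fn)
  expect_identical(volData(readVolume(fn)), volData(vf))
  fn2 <- withr::local_tempfile(fileext = ".nrrd")
  writeVolume(vi, fn2)
  expect_identical(volData(readVolume(fn2)), volData(vi))
})

test_that("degenerate volumes are rejected", {
  expect_error(Volume(array(0, c(0, 2, 2))))
  expect_error(Volume(array(NA_real_, c(2, 2, 2))))
  expect_error(Volume(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)))
})

test_that("extractCube returns the requested extent, clamped and padded", {
  withr::with_seed(3, {
    v <- Volume(array(stats::runif(160^3), c(160, 160, 160)))
  })
  cube <- extractCube(v, c(80, 80, 80), 150)
  expect_identical(dim(volData(cube)), c(150L, 150L, 150L))
  expect_false(cube@padded)
  expect_identical(cubeOffset(cube), c(6L, 6L, 6L))  # 0-based low corner
  expect_equal(volData(cube), volData(v)[7:156, 7:156, 7:156])

  one <- extractCube(v, c(17, 3, 152), 1)
  expect_equal(as.vector(volData(one)), volData(v)[18, 4, 153])

  near <- extractCube(v, c(10, 80, 80), 150)
  expect_true(near@padded)
  lo <- cubeOffset(near)  # z offset negative: 64 zero-padded planes
  expect_equal(lo[1], 10L - 74L)
  inb <- volData(near)[(-lo[1] + 1):150, , ]
  expect_equal(inb, volData(v)[1:(150 + lo[1]), 7:156, 7:156])
  expect_error(extractCube(v, c(-1, 0, 0), 10), "outside")
})

test_that("tileVolume counts and bounds match the tiling rule", {
  expect_equal(nrow(tileVolume(c(300, 300, 300), 150, 150)), 8L)
  expect_equal(nrow(tileVolume(c(150, 150, 150), 150, 150)), 1L)
  co <- tileVolume(c(310, 310, 310), 150, 150)
  expect_equal(nrow(co), 27L)
  expect_true(all(co$z >= 0 & co$z + 150 <= 310))
  expect_true(all(co$y >= 0 & co$y + 150 <= 310))
  expect_true(all(co$x >= 0 & co$x + 150 <= 310))
  expect_error(tileVolume(c(100, 300, 300), 150), "exceeds")
  expect_error(tileVolume(c(300, 300, 300), 150, 0), "stride")
})

test_that("every voxel is covered at least once (brute force)", {
  for (stride in c(7, 10, 16)) {
    co <- tileVolume(c(40, 33, 21), 16, stride)
    cover <- array(0L, c(40, 33, 21))
    for (i in seq_len(nrow(co))) {
      iz <- co$z[i] + 1:16
      iy <- co$y[i] + 1:16
      ix <- co$x[i] + 1:16
      cover[iz, iy, ix] <- cover[iz, iy, ix] + 1L
    }
    expect_true(all(cover >= 1L))
  }
})

test_that("stitch(tile(V)) with stride = extent reproduces V exactly", {
  withr::with_seed(4, {
    v <- Volume(array(stats::runif(40 * 48 * 32), c(40, 48, 32)))
  })
  co <- tileVolume(c(40, 48, 32), 16, 16)
  grids <- lapply(seq_len(nrow(co)), function(i) {
    volData(v)[co$z[i] + 1:16, co$y[i] + 1:16, co$x[i] + 1:16]
  })
  for (blend in c("max", "mean")) {
    expect_identical(volData(stitchCubes(co, grids, c(40, 48, 32), blend)),
                     volData(v))
  }
})

test_that("stitch blend rules combine overlaps as specified", {
  co <- data.frame(z = c(0, 0), y = c(0, 0), x = c(0, 4), extent = 8)
  g0 <- array(0, c(8, 8, 8))
  g1 <- array(1, c(8, 8, 8))
  out <- stitchCubes(co, list(g0, g1), c(8, 8, 12), "max")
  expect_true(all(volData(out)[, , 5:8] == 1))  # overlap: max(0, 1)
  g2 <- array(2, c(8, 8, 8))
  g4 <- array(4, c(8, 8, 8))
  outm <- stitchCubes(co, list(g2, g4), c(8, 8, 12), "mean")
  expect_true(all(volData(outm)[, , 5:8] == 3))
  expect_true(all(volData(outm)[, , 1:4] == 2))
  expect_error(stitchCubes(co, list(g0, array(0, c(4, 4, 4))), c(8, 8, 12)),
               "shape")
})
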
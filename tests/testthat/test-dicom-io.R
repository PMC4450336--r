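test_that("CT series round-trip bit-identically at integer HU", {
  set.seed(41)
  vals <- array(sample(-1000:2000, 16 * 12 * 10, replace = TRUE),
                c(16, 12, 10))
  img <- volume_image(vals, c(1.5, 2, 3), c(-10, -12, 4.5))
  dir <- file.path(tempdir(), "ctseries")
  write_ct_series(img, dir)
  back <- read_ct_series(dir)
  expect_identical(back$values, img$values)
  expect_equal(back$spacing, img$spacing)
  expect_equal(back$origin, img$origin)
})

test_that("rescale slope and intercept map stored values to HU", {
  # stored 1024 with slope 1, intercept -1024 reads back as 0 HU
  img <- volume_image(array(0, c(4, 4, 3)), c(1, 1, 1))
  dir <- file.path(tempdir(), "ctrescale")
  write_ct_series(img, dir, slope = 1, intercept = -1024)
  expect_true(all(read_ct_series(dir)$values == 0))
})

test_that("slice order on disk does not matter", {
  set.seed(42)
  img <- volume_image(array(sample(-500:500, 8 * 8 * 6, replace = TRUE),
                            c(8, 8, 6)), c(2, 2, 3), c(0, 0, -9))
  dir <- file.path(tempdir(), "ctshuffle")
  paths <- write_ct_series(img, dir)
  shuffled <- sample(paths)
  expect_identical(read_ct_series(shuffled)$values, img$values)
})

test_that("missing slices and mixed series are format errors", {
  img <- volume_image(array(0, c(4, 4, 6)), c(1, 1, 2))
  dir <- file.path(tempdir(), "ctbroken")
  unlink(dir, recursive = TRUE)
  paths <- write_ct_series(img, dir)
  file.remove(paths[3])
  expect_error(read_ct_series(dir), "non-uniform slice gap")
  dir2 <- file.path(tempdir(), "ctmixed")
  unlink(dir2, recursive = TRUE)
  p1 <- write_ct_series(img, dir2)
  img2 <- img; img2$origin <- img$origin + c(0, 0, 100)
  p2 <- write_ct_series(img2, file.path(dir2, "other"))
  expect_error(read_ct_series(c(p1, p2)), "mixed series")
})

test_that("RT-DOSE files scale, round-trip and place voxels correctly", {
  # scaling 0.01 with a stored value of 7000 reads as 70 Gy
  dose70 <- volume_image(array(70, c(3, 3, 2)), c(4, 4, 4), c(1, 2, 3))
  f <- tempfile(fileext = ".dcm")
  write_rtdose(dose70, f, scaling = 0.01)
  back <- read_rtdose(f)
  expect_true(all(back$values == 70))
  # round-trip within the default scaling resolution
  set.seed(43)
  dose <- volume_image(array(runif(4 * 3 * 5, 0, 75), c(4, 3, 5)),
                       c(4, 4, 4), c(-8, -6, -10))
  f2 <- tempfile(fileext = ".dcm")
  write_rtdose(dose, f2)
  back2 <- read_rtdose(f2)
  expect_lt(max(abs(back2$values - dose$values)), 1e-6)
  # hand geometry check: voxel (2,1,2) center must sit at origin + (1,0,1)*spacing
  expect_equal(back2$spacing, dose$spacing)
  expect_equal(back2$origin, dose$origin)
  w <- voxel_world_coords(back2)
  expect_equal(w[matrix(c(2, 1, 2), 1) %*% c(1, 4, 12) - 16], # linear index of (2,1,2)
               unname(dose$origin[1] + 4))
  # absent scaling attribute is a format error (strip the element)
  bytes <- readBin(f2, "raw", file.size(f2))
  # (3004,000E) tag little-endian: 04 30 0E 00
  tag <- as.raw(c(0x04, 0x30, 0x0E, 0x00))
  hit <- which(bytes == tag[1])
  hit <- hit[bytes[hit + 1] == tag[2] & bytes[hit + 2] == tag[3] &
               bytes[hit + 3] == tag[4]][1]
  bytes[hit + 2] <- as.raw(0xFF) # corrupt the element tag
  f3 <- tempfile(fileext = ".dcm")
  writeBin(bytes, f3)
  expect_error(read_rtdose(f3), "DoseGridScaling")
})

test_that("RT-STRUCT files round-trip structures and contours", {
  sq <- cbind(c(0, 20, 20, 0), c(0, 0, 16, 16), rep(3, 4))
  tri <- cbind(c(5, 15, 10), c(5, 5, 14), rep(6, 3))
  ss <- structure_set(list(GTV = list(sq, tri), Node = list(sq + 2)))
  f <- tempfile(fileext = ".dcm")
  write_rtstruct(ss, f)
  back <- read_rtstruct(f)
  expect_setequal(names(back$structures), c("GTV", "Node"))
  expect_equal(back$structures$GTV[[1]], sq)
  expect_equal(back$structures$GTV[[2]], tri)
  expect_equal(back$structures$Node[[1]], sq + 2)
})

test_that("rasterization matches a point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  ref <- volume_image(array(0, c(12, 10, 3)), c(2, 2, 3), c(0, 0, 0))
  poly <- cbind(c(1.47, 18.03, 20.11, 3.07), c(0.53, 2.01, 15.13, 13.09))
  ss <- structure_set(list(t = list(cbind(poly, rep(3, 4)))))
  m <- rasterize_structure(ss, "t", ref)
  expect_true(all(!m$values[, , c(1, 3)])) # other slices empty
  centers <- as.matrix(expand.grid(x = seq(0, 22, by = 2), y = seq(0, 18, by = 2)))
  oracle <- mgcv::in.out(rbind(poly, poly[1, ]), centers)
  expect_equal(as.vector(m$values[, , 2]), oracle)
})

test_that("rasterization is insensitive to vertex order and handles edge cases", {
  ref <- volume_image(array(0, c(10, 10, 2)), c(1, 1, 1), c(0, 0, 0))
  sq <- cbind(c(2.5, 6.5, 6.5, 2.5), c(2.5, 2.5, 6.5, 6.5), rep(1, 4))
  ss_cw <- structure_set(list(s = list(sq)))
  ss_ccw <- structure_set(list(s = list(sq[4:1, ])))
  a <- rasterize_structure(ss_cw, "s", ref)
  b <- rasterize_structure(ss_ccw, "s", ref)
  expect_identical(a$values, b$values)
  expect_equal(sum(a$values), 16) # voxel centers 3..6 in both axes
  # unknown name is a lookup error; empty structure gives an empty mask
  expect_error(rasterize_structure(ss_cw, "nope", ref), "unknown structure")
  empty <- structure_set(list(e = list()))
  expect_equal(sum(rasterize_structure(empty, "e", ref)$values), 0)
})

test_that("a circle rasterizes to approximately its analytic area", {
  ref <- volume_image(array(0, c(20, 20, 1)), c(1, 1, 1), c(0, 0, 0))
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  r <- 5
  circ <- cbind(9.5 + r * cos(th), 9.5 + r * sin(th), rep(0, 72))
  m <- rasterize_structure(structure_set(list(c = list(circ))), "c", ref)
  expect_lt(abs(sum(m$values) - pi * r^2), 2 * pi * r)
})

test_that("volumes and fields round-trip through NIfTI and MetaImage", {
  img <- random_volume(d = c(7, 6, 5), spacing = c(2, 2, 3), seed = 44)
  img$origin <- c(-6, 5, -7.5)
  for (ext in c(".mhd", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_volume(img, f)
    back <- read_volume(f)
    expect_equal(back$values, img$values, tolerance = 1e-12)
    expect_equal(back$spacing, img$spacing, tolerance = 1e-5)
    expect_equal(back$origin, img$origin, tolerance = 1e-5)
  }
  # dose volume (Gy scale) through MetaImage
  dose <- volume_image(array(runif(60, 0, 75), c(5, 4, 3)), c(4, 4, 4))
  fd <- tempfile(fileext = ".mhd")
  write_volume(dose, fd)
  expect_equal(read_volume(fd)$values, dose$values)
  # 3-component displacement field
  set.seed(45)
  fld <- displacement_field(array(rnorm(7 * 6 * 5 * 3), c(7, 6, 5, 3)),
                            c(2, 2, 3), c(0, 1, 2))
  ff <- tempfile(fileext = ".mhd")
  write_volume(fld, ff)
  backf <- read_field(ff)
  expect_equal(backf$vectors, fld$vectors)
  expect_equal(backf$origin, fld$origin)
})
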
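test_that("volume, field and mask constructors enforce their invariants", {
  expect_error(volume_image(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(volume_image(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(volume_image(matrix(1, 2, 2)), "3D")
  expect_error(displacement_field(array(1, c(2, 2, 2, 2))), "last dimension 3")
  expect_error(binary_mask(array(2, c(2, 2, 2))), "0 or 1")
  m <- binary_mask(array(c(1, 0, 1, 1), c(2, 2, 1)), spacing = c(2, 2, 3))
  expect_equal(mask_volume_mm3(m), 3 * 12)
})

test_that("grid compatibility requires matching shape, spacing and origin", {
  a <- volume_image(array(0, c(4, 4, 4)), c(1, 1, 1), c(0, 0, 0))
  expect_true(grid_compatible(a, a))
  b <- a; b$origin <- c(0, 0, 0.5)
  expect_false(grid_compatible(a, b))
  d <- volume_image(array(0, c(4, 4, 3)), c(1, 1, 1))
  expect_false(grid_compatible(a, d))
  expect_error(warp_image(a, zero_field(d)), "grid-compatible")
})

test_that("resampling to the same spacing with nearest interpolation is the identity", {
  img <- random_volume()
  out <- resample_volume(img, img$spacing, "nearest")
  expect_identical(dim(out$values), dim(img$values))
  expect_equal(out$values, img$values)
  expect_equal(out$origin, img$origin)
})

test_that("resampling a constant image yields the same constant", {
  img <- volume_image(array(40, c(10, 8, 6)), c(1, 1.25, 2.5))
  for (m in c("nearest", "trilinear")) {
    out <- resample_volume(img, c(2, 2, 3), m)
    expect_true(all(out$values == 40))
  }
})

test_that("nearest-neighbor downsampling matches the loop oracle", {
  d <- c(4, 4, 4)
  img <- volume_image(array(seq_len(64), d), c(1, 1, 1))
  out <- resample_volume(img, c(2, 2, 2), "nearest")
  # oracle: world coords of output centers mapped to input voxel coords
  q <- sweep(sweep(voxel_world_coords(out), 2, img$origin, "-"), 2,
             img$spacing, "/")
  expect_equal(as.vector(out$values), oracle_nearest(img$values, q))
  # the resampled grid covers the same physical extent
  expect_equal(dim(out$values) * out$spacing, d * img$spacing)
})

test_that("warping with a zero field is the identity", {
  img <- random_volume()
  out <- warp_image(img, zero_field(img))
  expect_equal(out$values, img$values)
  m <- binary_mask(array(img$values > 0, dim(img$values)), img$spacing, img$origin)
  expect_equal(propagate_mask(m, zero_field(img))$values, m$values)
})

test_that("a one-voxel uniform field shifts the array by one column", {
  img <- random_volume(d = c(7, 6, 5), spacing = c(2, 1, 1))
  d <- dim(img$values)
  f <- displacement_field(array(rep(c(2, 0, 0), each = prod(d)), c(d, 3)),
                          img$spacing, img$origin)
  out <- warp_image(img, f, fill = -1000)
  expect_equal(out$values[1:6, , ], img$values[2:7, , ])
  expect_true(all(out$values[7, , ] == -1000))
})

test_that("trilinear warping matches the per-voxel interpolation oracle", {
  # quadratic-intensity phantom with a smooth random field
  d <- c(9, 8, 7)
  img <- volume_image(array(0, d), c(2, 2, 3))
  w <- voxel_world_coords(img)
  img$values <- array(0.3 * w[, 1]^2 - 0.2 * w[, 2]^2 + 0.1 * w[, 3]^2 +
                        w[, 1] * 0.5 + 10, d)
  set.seed(7)
  vec <- array(rnorm(prod(d) * 3, sd = 1.5), c(d, 3))
  f <- displacement_field(vec, img$spacing, img$origin)
  out <- warp_image(img, f, "trilinear")
  q <- sweep(sweep(voxel_world_coords(img) + matrix(vec, ncol = 3),
                   2, img$origin, "-"), 2, img$spacing, "/")
  expect_equal(as.vector(out$values), oracle_trilinear(img$values, q),
               tolerance = 1e-6)
})

test_that("gradients are zero on constants and analytic on ramps", {
  const <- volume_image(array(7, c(5, 5, 5)), c(1, 2, 3))
  expect_true(all(image_gradient(const) == 0))
  r <- ramp_volume() # 2 HU per mm along x
  g <- image_gradient(r)
  expect_true(all(abs(g[, , , 1] - 2) < 1e-12))
  expect_true(all(g[, , , 2:3] == 0))
})

test_that("gradient of an affine intensity function is constant in the interior", {
  d <- c(6, 7, 5)
  img <- volume_image(array(0, d), c(2, 1, 3))
  w <- voxel_world_coords(img)
  img$values <- array(3 * w[, 1] - 2 * w[, 2] + 0.5 * w[, 3] + 11, d)
  g <- image_gradient(img)
  interior <- g[2:5, 2:6, 2:4, ]
  expect_equal(max(abs(interior[, , , 1] - 3)), 0, tolerance = 1e-10)
  expect_equal(max(abs(interior[, , , 2] + 2)), 0, tolerance = 1e-10)
  expect_equal(max(abs(interior[, , , 3] - 0.5)), 0, tolerance = 1e-10)
})

test_that("gradients match the finite-difference oracle exactly", {
  img <- random_volume(d = c(6, 5, 4), seed = 11)
  expect_equal(image_gradient(img), oracle_gradient(img$values, img$spacing))
})

test_that("degenerate axes yield zero gradient components", {
  img <- volume_image(array(runif(20), c(5, 4, 1)), c(1, 1, 2))
  g <- image_gradient(img)
  expect_true(all(g[, , , 3] == 0))
  expect_false(all(g[, , , 1] == 0))
})
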
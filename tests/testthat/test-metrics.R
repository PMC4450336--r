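mk_mask <- function(vals, d = NULL) {
  if (is.null(d)) d <- dim(vals)
  binary_mask(array(vals, d), c(1, 1, 1))
}

test_that("Dice coefficient matches its definition and conventions", {
  d <- c(4, 4, 2)
  a <- mk_mask(seq_len(32) <= 8, d)
  expect_equal(dice_coefficient(a, a), 100)
  b <- mk_mask(seq_len(32) > 8 & seq_len(32) <= 16, d)
  expect_equal(dice_coefficient(a, b), 0)
  # |A| = 8, |B| = 8, |A intersect B| = 4 -> 50%
  c4 <- mk_mask(seq_len(32) > 4 & seq_len(32) <= 12, d)
  expect_equal(dice_coefficient(a, c4), 50)
  # symmetry and the empty conventions
  expect_equal(dice_coefficient(c4, a), 50)
  e <- mk_mask(rep(FALSE, 32), d)
  expect_equal(dice_coefficient(e, e), 100)
  expect_equal(dice_coefficient(e, a), 0)
})

test_that("Dice agrees with a brute-force voxel count on random masks", {
  set.seed(17)
  for (i in 1:5) {
    d <- c(6, 5, 4)
    a <- mk_mask(runif(120) < 0.4, d)
    b <- mk_mask(runif(120) < 0.4, d)
    n_int <- 0; na <- 0; nb <- 0
    for (p in seq_len(120)) {
      na <- na + a$values[p]; nb <- nb + b$values[p]
      n_int <- n_int + (a$values[p] && b$values[p])
    }
    expected <- if (na + nb == 0) 100 else 200 * n_int / (na + nb)
    expect_equal(dice_coefficient(a, b), expected)
  }
})

test_that("mask propagation shifts masks exactly on grid-aligned fields", {
  d <- c(8, 8, 4)
  m <- mk_mask(array(rep(c(TRUE, FALSE), length.out = prod(d)), d))
  f0 <- displacement_field(array(0, c(d, 3)), c(1, 1, 1))
  expect_equal(propagate_mask(m, f0)$values, m$values)
  f1 <- displacement_field(array(rep(c(1, 0, 0), each = prod(d)), c(d, 3)),
                           c(1, 1, 1))
  out <- propagate_mask(m, f1)
  expect_equal(out$values[1:7, , ], m$values[2:8, , ])
  expect_true(all(!out$values[8, , ]))
})

test_that("volume change under uniform scaling follows the Jacobian", {
  d <- c(56, 56, 56)
  img <- volume_image(array(0, d), c(1, 1, 1), -c(27.5, 27.5, 27.5))
  w <- voxel_world_coords(img)
  sphere <- mk_mask(array(sqrt(rowSums(w^2)) <= 20, d))
  sphere$origin <- img$origin
  a <- 0.15 # backward field u = a * x contracts content by 1/(1+a)
  f <- displacement_field(array(a * w, c(d, 3)), c(1, 1, 1), img$origin)
  out <- propagate_mask(sphere, f)
  ratio <- sum(out$values) / sum(sphere$values)
  expect_lt(abs(ratio - (1 + a)^-3) / (1 + a)^-3, 0.1)
})

test_that("shift recovery counts exactly the voxels within tolerance", {
  d <- c(5, 5, 4)
  n <- prod(d)
  truth <- displacement_field(array(0, c(d, 3)), c(1, 1, 1))
  rec <- truth
  expect_equal(shift_recovery(truth, rec, mk_mask(rep(TRUE, n), d)), 1)
  rec3 <- truth; rec3$vectors[, , , 1] <- 3
  expect_equal(shift_recovery(truth, rec3, mk_mask(rep(TRUE, n), d), tol_mm = 2), 0)
  # mixed errors against a loop oracle
  set.seed(23)
  rec_m <- truth
  rec_m$vectors <- array(rnorm(n * 3, sd = 1.5), c(d, 3))
  mask <- mk_mask(runif(n) < 0.7, d)
  got <- shift_recovery(truth, rec_m, mask, tol_mm = 2)
  errs <- numeric(0)
  for (p in which(mask$values)) {
    v <- matrix(rec_m$vectors, ncol = 3)[p, ]
    errs <- c(errs, sqrt(sum(v^2)))
  }
  expect_equal(got, mean(errs <= 2))
  # monotone: growing one error can only reduce the fraction
  worse <- rec_m; worse$vectors[2, 2, 2, 1] <- 50
  expect_lte(shift_recovery(truth, worse, mask), got)
})

test_that("field statistics match hand values and a loop oracle", {
  d <- c(4, 4, 3)
  n <- prod(d)
  z <- displacement_field(array(0, c(d, 3)), c(1, 1, 1))
  s <- field_stats(z)
  expect_equal(s$mean_magnitude_mm, 0)
  expect_equal(s$max_magnitude_mm, 0)
  f <- displacement_field(array(rep(c(3, 4, 0), each = n), c(d, 3)), c(1, 1, 1))
  expect_equal(field_stats(f)$mean_magnitude_mm, 5)
  set.seed(9)
  r <- displacement_field(array(rnorm(n * 3), c(d, 3)), c(1, 1, 1))
  mask <- mk_mask(runif(n) < 0.5, d)
  got <- field_stats(r, mask)
  v <- matrix(r$vectors, ncol = 3)[as.vector(mask$values), , drop = FALSE]
  expect_equal(got$mean_magnitude_mm, mean(sqrt(rowSums(v^2))))
  expect_equal(got$max_magnitude_mm, max(sqrt(rowSums(v^2))))
  expect_equal(got$mean_axis_mm, colMeans(v))
})

test_that("evaluation reports collect per-case DSC rows", {
  cases <- list(list(case = "a", dsc_rigid = 70, dsc_noimp = 72, dsc_imp = 90,
                     mean_disp_mm = 4, max_disp_mm = 9),
                list(case = "b", dsc_rigid = 65, dsc_noimp = 60, dsc_imp = 88))
  df <- evaluation_report(cases)
  expect_identical(df$case, c("a", "b"))
  expect_true(is.na(df$mean_disp_mm[2]))
  tmp <- tempfile(fileext = ".tsv")
  evaluation_report(cases, tmp)
  back <- read.delim(tmp)
  expect_equal(back$dsc_imp, c(90, 88))
})
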
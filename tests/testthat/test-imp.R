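p0 <- radiobiology_params() # alpha 0.33, alpha/beta 10, 35 fractions

test_that("HU-attenuation conversion fixes water and air and inverts exactly", {
  expect_equal(hu_to_mu(0, p0), 0.1928)
  expect_equal(hu_to_mu(-1000, p0), 0)
  expect_equal(hu_to_mu(1000, p0), 2 * 0.1928)
  for (x in c(-1000, 0, 37, 3000))
    expect_equal(mu_to_hu(hu_to_mu(x, p0), p0), x, tolerance = 1e-10)
  expect_equal(mu_to_hu(0.1928, p0), 0)
  expect_equal(mu_to_hu(0, p0), -1000)
})

test_that("LQ survival fraction matches direct evaluation and its bounds", {
  expect_equal(survival_fraction(0, p0), 1)
  # 70 Gy in 35 fractions (d = 2 Gy): exp(-0.33 * 70 * 1.2)
  expect_equal(survival_fraction(70, p0), exp(-27.72), tolerance = 1e-12)
  p2 <- radiobiology_params(alpha = 0.1, alpha_beta = 3, n_fractions = 35)
  expect_equal(survival_fraction(35, p2), exp(-0.1 * 35 * (1 + 1 / 3)),
               tolerance = 1e-12)
  expect_error(survival_fraction(-1, p0), "non-negative")
  # strictly decreasing in dose and in alpha; always in (0, 1]
  D <- seq(0, 80, by = 2.5)
  sf <- survival_fraction(D, p0)
  expect_true(all(diff(sf) < 0))
  expect_true(all(sf > 0 & sf <= 1))
  alphas <- c(0.05, 0.1, 0.33, 0.6, 1)
  sfa <- vapply(alphas, function(a)
    survival_fraction(50, radiobiology_params(alpha = a)), 0)
  expect_true(all(diff(sfa) < 0))
})

test_that("intensity modification agrees with its closed form", {
  expect_equal(modify_intensity(123, 1, p0), 123)
  expect_equal(modify_intensity(123, 0, p0), -1000)
  expect_equal(modify_intensity(50, 0.5, p0), -475)
  set.seed(31)
  I0 <- runif(200, -1000, 2000)
  SF <- runif(200)
  expect_equal(modify_intensity(I0, SF, p0), (I0 + 1000) * SF - 1000,
               tolerance = 1e-10)
})

test_that("radiobiology parameters reject invalid values", {
  expect_error(radiobiology_params(alpha = 0), "alpha")
  expect_error(radiobiology_params(alpha_beta = -1), "alpha_beta")
  expect_error(radiobiology_params(n_fractions = 0), "n_fractions")
})

test_that("dose resampling is exact on constant and affine dose fields", {
  ct <- volume_image(array(0, c(10, 10, 6)), c(2, 2, 3), c(-9, -9, -7.5))
  uni <- volume_image(array(70, c(12, 12, 10)), c(4, 4, 4), c(-22, -22, -18))
  expect_true(all(abs(resample_dose_to_ct(uni, ct)$values - 70) < 1e-12))
  # affine dose: trilinear reproduces it exactly where covered
  dose <- uni
  wd <- voxel_world_coords(dose)
  dose$values <- array(30 + 0.5 * wd[, 1] - 0.25 * wd[, 2] + wd[, 3], dim(dose$values))
  dose$values <- pmax(dose$values, 0)
  out <- resample_dose_to_ct(dose, ct)
  wc <- voxel_world_coords(ct)
  expected <- 30 + 0.5 * wc[, 1] - 0.25 * wc[, 2] + wc[, 3]
  inside <- expected > 1 # away from the clamped-at-zero region
  expect_equal(as.vector(out$values)[inside], expected[inside], tolerance = 1e-9)
})

test_that("dose resampling respects the offset dose-grid geometry", {
  # dose grid shifted by (1, 2, 1) mm relative to a unit-spacing CT
  dose <- volume_image(array(0, c(4, 4, 4)), c(2, 2, 2), c(1, 2, 1))
  wd <- voxel_world_coords(dose)
  dose$values <- array(10 + wd[, 1], dim(dose$values))
  ct <- volume_image(array(0, c(9, 9, 9)), c(1, 1, 1), c(2, 3, 2))
  out <- resample_dose_to_ct(dose, ct)
  # CT voxel (2, 1, 1) sits at world (3, 3, 2) -> dose voxel coords (1, .5, .5)
  # hand interpolation of 10 + x at x = 3 is 13
  expect_equal(out$values[2, 1, 1], 13, tolerance = 1e-12)
  # outside the dose extent (beyond world 7/8/7) the dose is zero
  expect_equal(out$values[9, 9, 9], 0)
})

test_that("tumor scaling conserves the offset sum exactly", {
  d <- c(8, 8, 4)
  set.seed(12)
  planning <- volume_image(array(runif(prod(d), 0, 100), d), c(2, 2, 3))
  static <- volume_image(array(runif(prod(d), 0, 100), d), c(2, 2, 3))
  mask <- binary_mask(array(seq_len(prod(d)) %% 5 == 0, d), c(2, 2, 3))
  out <- scale_tumor(planning, mask, static)
  expect_equal(sum(out$values[mask$values] + 1000),
               sum(static$values[mask$values] + 1000), tolerance = 1e-6)
  expect_equal(out$values[!mask$values], planning$values[!mask$values])
  # S = S0 leaves the image unchanged
  same <- scale_tumor(planning, mask, planning)
  expect_equal(same$values, planning$values, tolerance = 1e-10)
  # S = 2 * S0 doubles every tumor voxel's offset value
  double <- static
  double$values <- array(2 * (planning$values + 1000) - 1000, d)
  out2 <- scale_tumor(planning, mask, double)
  expect_equal(out2$values[mask$values] + 1000,
               2 * (planning$values[mask$values] + 1000), tolerance = 1e-9)
  # degenerate all-air tumor region
  air <- planning; air$values[mask$values] <- -1000
  expect_error(scale_tumor(air, mask, static), "degenerate")
})

test_that("the full intensity-modification procedure composes its parts", {
  # moderate dose: the sequential HU-domain composition is then numerically
  # identical to the offset-domain implementation
  st <- make_shrinkage_study(seed = 7, spec = small_spec(7), prescription = 25)
  out <- apply_imp(st$planning, st$dose, st$tumor, st$post, p0)
  # non-tumor voxels untouched
  expect_equal(out$values[!st$tumor$values], st$planning$values[!st$tumor$values])
  # offset-sum conservation over the tumor
  expect_equal(sum(out$values[st$tumor$values] + 1000),
               sum(st$post$values[st$tumor$values] + 1000), tolerance = 1e-6)
  # equals the sequential application of the tested sub-operations
  dose_ct <- resample_dose_to_ct(st$dose, st$planning)
  manual <- st$planning
  sel <- st$tumor$values
  manual$values[sel] <- modify_intensity(st$planning$values[sel],
                                         survival_fraction(dose_ct$values[sel], p0),
                                         p0)
  manual <- scale_tumor(manual, st$tumor, st$post)
  expect_equal(out$values, manual$values, tolerance = 1e-9)
})

test_that("extreme radiosensitivity does not collapse the scale step", {
  st <- make_shrinkage_study(seed = 8, spec = small_spec(8))
  p_hot <- radiobiology_params(alpha = 1.0, alpha_beta = 3)
  out <- apply_imp(st$planning, st$dose, st$tumor, st$post, p_hot)
  sel <- st$tumor$values
  expect_equal(sum(out$values[sel] + 1000), sum(st$post$values[sel] + 1000),
               tolerance = 1e-6)
  # near-uniform survival: the scale absorbs the parameter change almost
  # exactly, so the modified image barely differs from the nominal one
  nominal <- apply_imp(st$planning, st$dose, st$tumor, st$post, p0)
  expect_lt(max(abs(out$values[sel] - nominal$values[sel])), 1)
})

test_that("zero dose with matching sums leaves the planning image unchanged", {
  ph <- make_head_phantom(small_spec(9))
  zero_dose <- volume_image(array(0, c(10, 10, 10)), c(10, 10, 10),
                            c(-50, -50, -40))
  out <- apply_imp(ph$image, zero_dose, ph$tumor, ph$image, p0)
  expect_equal(out$values, ph$image$values, tolerance = 1e-9)
})

test_that("a uniform lethal dose drives the tumor to the sum-matched level", {
  ph <- make_head_phantom(small_spec(10, noise_sd = 0))
  d <- dim(ph$image$values)
  lethal <- volume_image(array(70, c(12, 12, 10)), c(10, 10, 10),
                         c(-60, -60, -45))
  static <- make_head_phantom(small_spec(11))$image
  out <- apply_imp(ph$image, lethal, ph$tumor, static, p0)
  sel <- ph$tumor$values
  # uniform dose + uniform pre-noise tumor HU: every tumor voxel lands at
  # the mean posttreatment offset level
  expected <- mean(static$values[sel] + 1000) - 1000
  expect_equal(unname(out$values[sel]), rep(expected, sum(sel)),
               tolerance = 1e-6)
})
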
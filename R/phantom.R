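#' Specification of the synthetic head phantom
#'
#' Describes the head-like phantom every test and validation experiment
#' runs on: an ellipsoidal cranium (bone shell at ~1200 HU) filled with
#' soft tissue (~40 HU) containing a spherical tumor (~60 HU), a couch slab
#' (~300 HU) posterior to the head, and additive Gaussian intensity noise
#' on all non-air voxels. The default grid (96 x 96 x 40 voxels at
#' 2 x 2 x 3 mm) matches the standard working resolution of the pipeline.
#' The same seed always yields a bit-identical phantom.
#'
#' @param shape grid size in voxels, default `c(96, 96, 40)`.
#' @param spacing voxel size in mm, default `c(2, 2, 3)`.
#' @param skull_hu,soft_hu,tumor_hu,couch_hu tissue CT numbers (HU).
#' @param bone_texture_hu amplitude of the smooth sinusoidal HU modulation
#'   of the skull (emulating cortical/trabecular density heterogeneity of
#'   real bone), default 150.
#' @param tissue_texture_hu amplitude of the smooth HU heterogeneity of the
#'   soft tissue (emulating muscle/fat/gland structure; pure white noise
#'   would leave intensity-based matching without anatomic landmarks),
#'   default 15.
#' @param noise_sd Gaussian intensity noise, HU, default 10.
#' @param head_center,head_radii ellipsoid center and semi-axes, mm (world
#'   coordinates; the grid is centered on the world origin).
#' @param skull_fraction inner skull surface as a fraction of the outer
#'   ellipsoid, default 0.92.
#' @param tumor_center,tumor_radius_mm tumor sphere, mm.
#' @param couch_y couch slab extent along y, mm.
#' @param seed random seed, default 1.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 40), spacing = c(2, 2, 3),
                         skull_hu = 1200, soft_hu = 40, tumor_hu = 60,
                         couch_hu = 300, bone_texture_hu = 150,
                         tissue_texture_hu = 15, noise_sd = 10,
                         head_center = c(0, 0, -20), head_radii = c(70, 70, 75),
                         skull_fraction = 0.92,
                         tumor_center = c(15, 10, -10), tumor_radius_mm = 16,
                         couch_y = c(78, 92), seed = 1) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 4L), all(spacing > 0),
            tumor_radius_mm > 0, skull_fraction > 0, skull_fraction < 1,
            noise_sd >= 0)
  structure(list(shape = shape, spacing = spacing, skull_hu = skull_hu,
                 soft_hu = soft_hu, tumor_hu = tumor_hu, couch_hu = couch_hu,
                 bone_texture_hu = bone_texture_hu,
                 tissue_texture_hu = tissue_texture_hu,
                 noise_sd = noise_sd, head_center = head_center,
                 head_radii = head_radii, skull_fraction = skull_fraction,
                 tumor_center = tumor_center, tumor_radius_mm = tumor_radius_mm,
                 couch_y = couch_y, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the synthetic head phantom
#'
#' Deterministic given the spec's seed. Returns the planning-like CT, the
#' tumor mask, the body mask (everything inside the outer head surface) and
#' the world-coordinate couch box that [remove_couch()] expects.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` ([volume_image()]), `tumor`
#'   ([binary_mask()]), `body` ([binary_mask()]) and `couch_box`.
#' @export
make_head_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape; sp <- spec$spacing
  origin <- -(d - 1) * sp / 2 # grid centered on the world origin
  img <- volume_image(array(-1000, d), sp, origin)
  w <- voxel_world_coords(img)

  # ellipsoidal head: outer surface = skull, inner = soft tissue
  e <- sweep(sweep(w, 2, spec$head_center, "-"), 2, spec$head_radii, "/")
  r2 <- rowSums(e^2)
  body <- r2 <= 1
  inner <- r2 <= spec$skull_fraction^2
  vals <- rep(-1000, nrow(w))
  # skull with smooth density heterogeneity, as in real cortical/trabecular
  # bone; a structureless shell would make intensity-based alignment of the
  # skeleton ill-posed
  skull_sel <- body & !inner
  vals[skull_sel] <- spec$skull_hu + spec$bone_texture_hu *
    (sin(2 * pi * w[skull_sel, 1] / 35) +
     sin(2 * pi * w[skull_sel, 2] / 42) +
     sin(2 * pi * w[skull_sel, 3] / 50))
  # soft tissue with smooth two-scale anatomic heterogeneity plus, later,
  # white noise; featureless tissue would carry no registration landmarks
  tt <- spec$tissue_texture_hu
  vals[inner] <- spec$soft_hu +
    tt * (sin(2 * pi * w[inner, 1] / 27) +
          sin(2 * pi * w[inner, 2] / 33) +
          sin(2 * pi * w[inner, 3] / 41)) +
    0.5 * tt * (sin(2 * pi * w[inner, 1] / 13 + 1) +
                sin(2 * pi * w[inner, 2] / 16 + 2) +
                sin(2 * pi * w[inner, 3] / 11 + 3))

  tum <- sqrt(rowSums(sweep(w, 2, spec$tumor_center, "-")^2)) <= spec$tumor_radius_mm
  if (any(tum & !inner))
    stop("tumor is not strictly inside the soft tissue", call. = FALSE)
  vals[tum] <- spec$tumor_hu

  ext_lo <- origin - sp / 2; ext_hi <- origin + (d - 0.5) * sp
  couch_box <- list(lo = c(ext_lo[1], spec$couch_y[1], ext_lo[3]),
                    hi = c(ext_hi[1], spec$couch_y[2], ext_hi[3]))
  couch <- w[, 2] >= spec$couch_y[1] & w[, 2] <= spec$couch_y[2]
  vals[couch] <- spec$couch_hu

  if (spec$noise_sd > 0) {
    sel <- vals > -1000
    vals[sel] <- with_seed(spec$seed,
                           vals[sel] + rnorm(sum(sel), 0, spec$noise_sd))
  }
  vals <- pmin(pmax(vals, -1000), 3000)
  img$values <- array(vals, d)
  list(image = img,
       tumor = binary_mask(array(tum, d), sp, origin),
       body = binary_mask(array(body, d), sp, origin),
       couch_box = couch_box)
}

#' Synthetic planned dose for a tumor
#'
#' Prescription dose inside the tumor's equivalent sphere plus a margin,
#' Gaussian falloff outside, generated on its own 4 mm grid deliberately
#' offset from the CT grid so that dose-to-CT alignment is exercised.
#'
#' @param tumor the tumor [binary_mask()].
#' @param prescription Gy, default 70.
#' @param margin_mm flat-dose margin beyond the tumor surface, default 6.
#' @param falloff_mm Gaussian falloff scale, default 8.
#' @param dose_spacing dose grid voxel size, mm, default `c(4, 4, 4)`.
#' @param grid_offset_mm shift of the dose grid relative to the CT voxel
#'   lattice, default `c(1, -1, 1.5)`.
#' @param pad_mm dose grid padding around the tumor, default 40.
#' @return A [volume_image()] of dose in Gy.
#' @export
make_dose <- function(tumor, prescription = 70, margin_mm = 6, falloff_mm = 8,
                      dose_spacing = c(4, 4, 4), grid_offset_mm = c(1, -1, 1.5),
                      pad_mm = 40) {
  stopifnot(inherits(tumor, "binary_mask"), prescription > 0, falloff_mm > 0)
  if (!any(tumor$values)) stop("tumor mask is empty", call. = FALSE)
  w <- voxel_world_coords(tumor)[as.vector(tumor$values), , drop = FALSE]
  ctr <- colMeans(w)
  r_eq <- (3 * mask_volume_mm3(tumor) / (4 * pi))^(1 / 3)

  lo <- apply(w, 2, min) - pad_mm + grid_offset_mm
  hi <- apply(w, 2, max) + pad_mm
  nd <- pmax(2L, as.integer(ceiling((hi - lo) / dose_spacing)) + 1L)
  dose <- volume_image(array(0, nd), dose_spacing, lo)
  dw <- voxel_world_coords(dose)
  dist <- sqrt(rowSums(sweep(dw, 2, ctr, "-")^2))
  excess <- pmax(dist - r_eq - margin_mm, 0)
  dose$values <- array(prescription * exp(-0.5 * (excess / falloff_mm)^2), nd)
  dose
}

# Design matrix of the full 2nd-order polynomial basis in normalized,
# centered world coordinates.
poly2_basis <- function(image) {
  w <- voxel_world_coords(image)
  ctr <- (apply(w, 2, min) + apply(w, 2, max)) / 2
  half <- pmax((apply(w, 2, max) - apply(w, 2, min)) / 2, 1e-9)
  x <- (w[, 1] - ctr[1]) / half[1]
  y <- (w[, 2] - ctr[2]) / half[2]
  z <- (w[, 3] - ctr[3]) / half[3]
  cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
}

#' Apply a random 2nd-order polynomial deformation with known ground truth
#'
#' Each displacement component is a full 2nd-order polynomial in
#' (normalized, centered) world coordinates. When `coeffs` is `NULL`,
#' random coefficients are drawn under the seed and rescaled so the mean
#' displacement magnitude over the body (voxels at or above
#' `body_threshold`) equals `target_mean_mm`. Returns the warped image
#' together with the exact analytic field, for displacement-recovery
#' validation of the deformable registration.
#'
#' @param image a [volume_image()].
#' @param target_mean_mm mean in-body displacement magnitude, mm, default
#'   5.5 (the validation experiments require more than 5 mm).
#' @param coeffs optional 10 x 3 coefficient matrix (basis order: 1, x, y,
#'   z, x^2, y^2, z^2, xy, xz, yz); when supplied it is used as-is, with no
#'   rescaling.
#' @param body_threshold HU defining the body, default -500.
#' @param seed random seed, default 1.
#' @return A list with `warped` ([volume_image()]), `truth`
#'   ([displacement_field()]) and `body` ([binary_mask()]).
#' @export
polynomial_transform <- function(image, target_mean_mm = 5.5, coeffs = NULL,
                                 body_threshold = -500, seed = 1) {
  stopifnot(inherits(image, "volume_image"))
  d <- dim(image$values)
  M <- poly2_basis(image)
  if (is.null(coeffs)) {
    coeffs <- with_seed(seed, matrix(rnorm(30), 10, 3))
    raw <- M %*% coeffs
    body_sel <- as.vector(image$values >= body_threshold)
    if (!any(body_sel)) stop("no body voxels above threshold", call. = FALSE)
    mag <- sqrt(rowSums(raw^2))
    m0 <- mean(mag[body_sel])
    if (m0 <= 0) stop("degenerate random field", call. = FALSE)
    raw <- raw * (target_mean_mm / m0)
  } else {
    stopifnot(is.matrix(coeffs), nrow(coeffs) == 10L, ncol(coeffs) == 3L)
    raw <- M %*% coeffs
  }
  truth <- displacement_field(array(raw, c(d, 3L)), image$spacing, image$origin)
  warped <- warp_image(image, truth, method = "trilinear")
  body <- binary_mask(array(image$values >= body_threshold, d),
                      image$spacing, image$origin)
  list(warped = warped, truth = truth, body = body)
}

#' Simulate radiation-induced tumor shrinkage
#'
#' Produces a posttreatment-like image by replacing the tumor with a
#' concentric smaller residual: the shrunken tumor keeps a (reduced)
#' tumor-like density `residual_hu`, vacated voxels take soft-tissue HU,
#' and the modified region receives fresh seeded noise. This constructs
#' exactly the no-correspondence condition that defeats plain
#' intensity-based registration: intensity mass present in the planning
#' tumor has no counterpart in the posttreatment image. Optionally a
#' smooth inward deformation of the surrounding tissue is applied.
#'
#' @param planning the planning [volume_image()].
#' @param tumor the planning tumor [binary_mask()].
#' @param volume_factor residual/original volume ratio in (0, 1], default
#'   0.67 (the radius scales by its cube root).
#' @param residual_hu CT number of the residual tumor, default 20 (the
#'   surviving tumor is markedly less dense than at planning).
#' @param soft_tissue_hu CT number filling vacated voxels, default 40.
#' @param noise_sd fresh Gaussian noise in the modified region, HU,
#'   default 10.
#' @param deform_amplitude_mm amplitude of the optional inward deformation
#'   of surrounding tissue, default 0 (off; keeps ground-truth masks
#'   exact).
#' @param deform_anisotropy translational weight of the collapse: 0 is a
#'   purely concentric contraction; larger values add a bulk displacement
#'   of the tumor bed along `deform_direction`, as real tumor beds
#'   collapse one-sidedly. Default 1.
#' @param deform_direction unit 3-vector (LPS) of the bed displacement;
#'   the default, left-posterior, mimics collapse toward the airway.
#' @param seed random seed, default 2.
#' @return A list with `image` (posttreatment [volume_image()]) and
#'   `tumor` (shrunken [binary_mask()]).
#' @export
simulate_shrinkage <- function(planning, tumor, volume_factor = 0.67,
                               residual_hu = 20, soft_tissue_hu = 40,
                               noise_sd = 10, deform_amplitude_mm = 0,
                               deform_anisotropy = 1,
                               deform_direction = c(1, 1, 0) / sqrt(2),
                               seed = 2) {
  stopifnot(inherits(planning, "volume_image"), inherits(tumor, "binary_mask"))
  stop_if_incompatible(planning, tumor, "planning image and tumor mask")
  if (!is.numeric(volume_factor) || volume_factor <= 0 || volume_factor > 1)
    stop("volume_factor must be in (0, 1]", call. = FALSE)
  if (!any(tumor$values)) stop("tumor mask is empty", call. = FALSE)
  d <- dim(planning$values)
  w <- voxel_world_coords(planning)
  sel <- as.vector(tumor$values)
  ctr <- colMeans(w[sel, , drop = FALSE])
  dist <- sqrt(rowSums(sweep(w, 2, ctr, "-")^2))
  r_max <- max(dist[sel])
  new_r <- r_max * volume_factor^(1 / 3)
  shrunk <- sel & dist <= new_r

  vals <- as.vector(planning$values)
  vacated <- sel & !shrunk
  vals[vacated] <- soft_tissue_hu
  vals[shrunk] <- residual_hu
  if (noise_sd > 0) {
    nmod <- sum(sel)
    vals[sel] <- with_seed(seed, vals[sel] + rnorm(nmod, 0, noise_sd))
  }
  vals <- pmin(pmax(vals, -1000), 3000)
  post <- volume_image(array(vals, d), planning$spacing, planning$origin)
  shrunk_mask <- binary_mask(array(shrunk, d), planning$spacing, planning$origin)

  if (deform_amplitude_mm > 0) {
    # smooth radial collapse of the vacated shell: peaks just outside the
    # original tumor surface, vanishes at the tumor center, decays over
    # roughly one tumor radius into the surrounding tissue; a seeded
    # random anisotropy makes the collapse one-sided, as in real tumor beds
    peak_r <- 1.15 * r_max
    sig <- ifelse(dist < peak_r, 0.35 * r_max, 0.8 * r_max)
    g <- deform_amplitude_mm * exp(-0.5 * ((dist - peak_r) / sig)^2)
    dirn <- sweep(w, 2, ctr, "-") / pmax(dist, 1e-9)
    if (deform_anisotropy > 0) {
      # one-sided collapse: the bed also translates along deform_direction
      udir <- deform_direction / sqrt(sum(deform_direction^2))
      dirn <- dirn + deform_anisotropy * matrix(udir, nrow(dirn), 3, byrow = TRUE)
    }
    fld <- displacement_field(array(dirn * g, c(d, 3L)),
                              planning$spacing, planning$origin)
    post <- warp_image(post, fld)
    shrunk_mask <- propagate_mask(shrunk_mask, fld)
  }
  list(image = post, tumor = shrunk_mask)
}

#' Translate a phantom image by a known shift
#'
#' Shifts the image content by `t_mm` (a feature at world position `p`
#' moves to `p + t_mm`), implemented as a warp with the constant backward
#' field `-t_mm`. This is the fixture for rigid-registration validation:
#' with the original image as static and the translated image as moving,
#' [register_rigid()] should recover `t_mm` as the aligning translation.
#'
#' @param image a [volume_image()].
#' @param t_mm length-3 shift in mm.
#' @param method interpolation, default trilinear.
#' @return A [volume_image()] on the same grid.
#' @export
translate_phantom <- function(image, t_mm, method = "trilinear") {
  apply_translation(image, -as.numeric(t_mm), method = method)
}

#' Generate a complete synthetic shrinkage study
#'
#' Bundles the standard phantom, its planned dose, and a posttreatment
#' image with simulated tumor shrinkage into one study: the inputs of the
#' full pipeline (planning CT, posttreatment CT, dose grid, tumor mask)
#' plus ground truth (shrunken tumor mask) that patient data cannot
#' provide. The posttreatment image is the same anatomy rendered with an
#' independent noise realization (the two scans are independent
#' acquisitions) before the tumor is shrunk.
#'
#' The tumor bed undergoes a one-sided inward collapse (3 mm amplitude by
#' default) so that a real, recoverable deformation accompanies the
#' non-recoverable cell loss, as it does in patients.
#'
#' @param seed study seed; derived seeds drive the planning noise, the
#'   independent posttreatment noise, and the shrinkage rendering.
#' @param deform_amplitude_mm amplitude of the tumor-bed collapse,
#'   default 3.
#' @param volume_factor residual tumor volume fraction, default 0.67.
#' @param prescription Gy, default 70 (lethal at the default
#'   radiosensitivity).
#' @param spec a [phantom_spec()]; its seed is overridden by `seed`.
#' @param ... passed to [simulate_shrinkage()].
#' @return A list with `planning`, `post`, `dose`, `tumor`,
#'   `tumor_post` (ground-truth shrunken mask), `body`, `couch_box`.
#' @export
make_shrinkage_study <- function(seed = 1, volume_factor = 0.67,
                                 prescription = 70, spec = NULL,
                                 deform_amplitude_mm = 3, ...) {
  if (is.null(spec)) spec <- phantom_spec(seed = seed)
  else spec$seed <- as.integer(seed)
  ph <- make_head_phantom(spec)
  spec_post <- spec
  spec_post$seed <- as.integer(seed + 500000L)
  ph_post <- make_head_phantom(spec_post) # same anatomy, independent noise
  shr <- simulate_shrinkage(ph_post$image, ph$tumor,
                            volume_factor = volume_factor,
                            deform_amplitude_mm = deform_amplitude_mm,
                            seed = seed + 1000000L, ...)
  list(planning = ph$image, post = shr$image,
       dose = make_dose(ph$tumor, prescription = prescription),
       tumor = ph$tumor, tumor_post = shr$tumor,
       body = ph$body, couch_box = ph$couch_box)
}
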
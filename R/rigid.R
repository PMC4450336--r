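#' Bone mask by HU thresholding
#'
#' Marks voxels at or above the threshold, so that only high-density bony
#' structures remain; used to restrict the rigid registration objective to
#' the skeleton.
#'
#' @param image a [volume_image()].
#' @param threshold HU, default 500.
#' @return A [binary_mask()].
#' @export
bone_mask <- function(image, threshold = 500) {
  stopifnot(inherits(image, "volume_image"))
  binary_mask(array(image$values >= threshold, dim(image$values)),
              image$spacing, image$origin)
}

#' Translation-only rigid registration of bone structures
#'
#' Finds the translation of the moving image that maximizes the Pearson
#' correlation coefficient between bone-thresholded intensities of the two
#' images, evaluated at the static image's bone voxels. The search is
#' exhaustive at voxel resolution over the whole search box (exact
#' integer-index lookups), then exhaustive at `step_mm` resolution within
#' one voxel of the coarse optimum (trilinear sampling), and finally
#' refined per axis by a parabolic fit through the correlation values at
#' the optimum and its two `step_mm` neighbors. Thresholding floors both
#' images at the bone threshold, so non-bone regions are constant and bone
#' shape and texture drive the objective without partial-volume outliers;
#' samples falling outside the moving extent are excluded.
#'
#' @param static,moving grid-compatible [volume_image()]s.
#' @param bone_threshold_hu HU threshold isolating bone, default 500.
#' @param search_radius_mm half-width of the per-axis search box, default 20.
#' @param step_mm fine search step, default 1.
#' @param max_points cap on the number of static bone voxels used in the
#'   objective (deterministic subsample), default 8000.
#' @return An object of class `rigid_registration` with elements
#'   `translation` (mm, applied to the moving image), `correlation` (at the
#'   optimum), `n_points` (bone voxels used).
#' @export
register_rigid <- function(static, moving, bone_threshold_hu = 500,
                           search_radius_mm = 20, step_mm = 1,
                           max_points = 8000) {
  stopifnot(inherits(static, "volume_image"), inherits(moving, "volume_image"))
  stop_if_incompatible(static, moving, "static and moving images")
  d <- dim(static$values)
  sel <- which(static$values >= bone_threshold_hu)
  if (length(sel) == 0L)
    stop("no bone voxels above threshold in the static image", call. = FALSE)
  if (length(sel) > max_points)
    sel <- sel[unique(round(seq(1, length(sel), length.out = max_points)))]
  ijk <- arrayInd(sel, d) - 1 # 0-based
  pts <- matrix(as.numeric(ijk), ncol = 3L)
  svals <- static$values[sel]
  mv <- as.numeric(pmax(moving$values, bone_threshold_hu))
  min_n <- max(50L, as.integer(0.05 * nrow(pts)))
  sp <- static$spacing

  # exhaustive voxel-resolution pass over the full search box
  rng <- lapply(1:3, function(a) seq(-floor(search_radius_mm / sp[a]),
                                     floor(search_radius_mm / sp[a])))
  coarse_vox <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  cc <- cpp_shift_correlation(mv, d, pts, svals, coarse_vox, 0L, min_n, -Inf)
  if (all(is.na(cc)))
    stop("empty bone overlap at every candidate translation", call. = FALSE)
  best_mm <- coarse_vox[which.max(cc), ] * sp

  # exhaustive step_mm pass within one voxel of the coarse optimum
  off <- lapply(1:3, function(a) seq(-ceiling(sp[a]), ceiling(sp[a]), by = step_mm))
  fine_mm <- sweep(as.matrix(expand.grid(x = off[[1]], y = off[[2]], z = off[[3]])),
                   2, best_mm, "+")
  fine_mm <- fine_mm[apply(abs(fine_mm) <= search_radius_mm + 1e-9, 1, all), ,
                     drop = FALSE]
  fine_vox <- sweep(fine_mm, 2, sp, "/")
  cf <- cpp_shift_correlation(mv, d, pts, svals, fine_vox, 1L, min_n, -Inf)
  if (all(is.na(cf)))
    stop("empty bone overlap at every candidate translation", call. = FALSE)
  ib <- which.max(cf)
  best_mm <- fine_mm[ib, ]
  best_cc <- cf[ib]

  # parabolic sub-step refinement per axis (skipped at a perfect match,
  # so self-registration recovers exactly zero)
  if (best_cc < 1 - 1e-12) {
    for (a in 1:3) {
      probe <- rbind(best_mm, best_mm)
      probe[1, a] <- probe[1, a] - step_mm
      probe[2, a] <- probe[2, a] + step_mm
      cp <- cpp_shift_correlation(mv, d, pts, svals,
                                  sweep(probe, 2, sp, "/"), 1L, min_n, -Inf)
      if (anyNA(cp)) next
      curv <- cp[1] - 2 * best_cc + cp[2]
      if (curv < -1e-12) {
        delta <- 0.5 * (cp[1] - cp[2]) / curv * step_mm
        if (abs(delta) <= step_mm) best_mm[a] <- best_mm[a] + delta
      }
    }
    cc_final <- cpp_shift_correlation(mv, d, pts, svals,
                                      matrix(best_mm / sp, nrow = 1), 1L,
                                      min_n, -Inf)
    if (!is.na(cc_final) && cc_final >= best_cc) best_cc <- cc_final
  }

  structure(list(translation = as.numeric(best_mm), correlation = best_cc,
                 n_points = nrow(pts), bone_threshold_hu = bone_threshold_hu,
                 search_radius_mm = search_radius_mm, step_mm = step_mm),
            class = "rigid_registration")
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat(sprintf("<rigid_registration> translation (%.3f, %.3f, %.3f) mm, r = %.5f (%d bone voxels)\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$correlation, x$n_points))
  invisible(x)
}

#' @export
coef.rigid_registration <- function(object, ...) object$translation

#' Apply a rigid translation to an image
#'
#' Equivalent to warping with a spatially constant displacement field equal
#' to the translation (backward mapping, trilinear interpolation, air fill).
#'
#' @param image a [volume_image()].
#' @param translation length-3 numeric (mm) or a `rigid_registration`.
#' @param method interpolation, default `"trilinear"`.
#' @return A [volume_image()] on the same grid.
#' @export
apply_translation <- function(image, translation, method = "trilinear") {
  stopifnot(inherits(image, "volume_image"))
  if (inherits(translation, "rigid_registration"))
    translation <- translation$translation
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  d <- dim(image$values)
  f <- displacement_field(
    array(rep(translation, each = prod(d)), c(d, 3L)),
    image$spacing, image$origin)
  warp_image(image, f, method = method)
}
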
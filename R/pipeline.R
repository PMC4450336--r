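# Resample a binary mask onto another grid (nearest voxel-center lookup).
resample_mask_to <- function(mask, target) {
  q <- world_to_voxel(mask, voxel_world_coords(target))
  vals <- cpp_sample3(as.numeric(mask$values), dim(mask$values), q, 0L, 0)
  binary_mask(array(vals != 0, grid_dim(target)), target$spacing, target$origin)
}

load_volume_arg <- function(x) {
  if (inherits(x, "volume_image")) x
  else if (is.character(x) && length(x) == 1L) read_volume(x)
  else stop("expected a volume_image or a file path", call. = FALSE)
}

load_mask_arg <- function(x, ref = NULL) {
  if (inherits(x, "binary_mask")) return(x)
  if (is.character(x) && length(x) == 1L) {
    v <- read_volume(x)
    return(binary_mask(array(v$values != 0, dim(v$values)), v$spacing, v$origin))
  }
  stop("expected a binary_mask or a file path", call. = FALSE)
}

#' Run the full shrinkage-aware registration pipeline
#'
#' Executes preprocessing, bone-driven rigid translation, the (optional)
#' LQ intensity-modification procedure, symmetric-force Demons deformable
#' registration, and evaluation, in that order. With `use_imp = FALSE` the
#' intensity modification is skipped, reproducing the plain-Demons
#' comparison arm with all other parameters identical.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{static}{posttreatment CT: [volume_image()] or file path.}
#'     \item{moving}{planning CT: [volume_image()] or file path.}
#'     \item{dose}{planned dose ([volume_image()] or path); required when
#'       `use_imp` is `TRUE`.}
#'     \item{tumor}{planning tumor mask ([binary_mask()] or path).}
#'     \item{tumor_static}{optional reference tumor mask on the static
#'       image, for DSC evaluation.}
#'     \item{use_imp}{logical, default `TRUE`.}
#'     \item{couch_box, crop_box}{optional world boxes for preprocessing.}
#'     \item{air_threshold, target_spacing}{preprocessing parameters
#'       (defaults -500 HU, 2 x 2 x 3 mm).}
#'     \item{radiobiology}{list passed to [radiobiology_params()].}
#'     \item{registration}{list passed to [registration_params()].}
#'     \item{rigid}{list passed to [register_rigid()] (thresholds, search
#'       radius, step).}
#'     \item{output_dir}{optional directory for result files.}
#'   }
#' @return An object of class `pipeline_result`: rigid and Demons results,
#'   the warped moving image, the propagated tumor mask, DSC values (when
#'   `tumor_static` is given) and a manifest of every parameter used.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  use_imp <- isTRUE(config$use_imp %||% TRUE)
  air_thr <- config$air_threshold %||% -500
  tsp <- config$target_spacing %||% c(2, 2, 3)
  rb <- do.call(radiobiology_params, config$radiobiology %||% list())
  rp <- do.call(registration_params, config$registration %||% list())

  static <- preprocess_ct(load_volume_arg(config$static),
                          couch_box = config$couch_box,
                          crop_box = config$crop_box,
                          air_threshold = air_thr, target_spacing = tsp)
  moving0 <- preprocess_ct(load_volume_arg(config$moving),
                           couch_box = config$couch_box,
                           crop_box = config$crop_box,
                           air_threshold = air_thr, target_spacing = tsp)
  tumor <- resample_mask_to(load_mask_arg(config$tumor), static)

  rigid_args <- c(list(static = static, moving = moving0),
                  config$rigid %||% list())
  rigid <- do.call(register_rigid, rigid_args)
  moving <- apply_translation(moving0, rigid)
  # the planning tumor mask and dose grid ride along with the translation
  tumor_moved <- tumor
  tumor_moved$origin <- tumor$origin - rigid$translation
  tumor_moved <- resample_mask_to(tumor_moved, static)

  if (use_imp) {
    if (is.null(config$dose))
      stop("config$dose is required when use_imp is TRUE", call. = FALSE)
    dose <- load_volume_arg(config$dose)
    dose$origin <- dose$origin - rigid$translation
    moving_reg <- apply_imp(moving, dose, tumor_moved, static, rb)
  } else {
    moving_reg <- moving
  }

  demons <- demons_register(static, moving_reg, rp)
  warped <- warp_image(moving, demons$field)
  tumor_prop <- propagate_mask(tumor_moved, demons$field)
  stats <- field_stats(demons$field, tumor_moved)

  dsc <- NULL
  if (!is.null(config$tumor_static)) {
    ref <- resample_mask_to(load_mask_arg(config$tumor_static), static)
    dsc <- c(rigid = dice_coefficient(tumor_moved, ref),
             deformable = dice_coefficient(tumor_prop, ref))
  }

  manifest <- list(
    package_version = as.character(packageVersion("shrinkreg")),
    use_imp = use_imp, air_threshold = air_thr, target_spacing = tsp,
    radiobiology = unclass(rb), registration = unclass(rp),
    rigid = list(translation_mm = rigid$translation,
                 correlation = rigid$correlation,
                 bone_threshold_hu = rigid$bone_threshold_hu,
                 search_radius_mm = rigid$search_radius_mm,
                 step_mm = rigid$step_mm),
    demons = list(iterations = demons$iterations, converged = demons$converged)
  )

  out <- structure(list(rigid = rigid, demons = demons, warped = warped,
                        tumor_rigid = tumor_moved, tumor_propagated = tumor_prop,
                        dsc = dsc, field_stats = stats, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config$output_dir)
  out
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(result$warped, file.path(dir, "warped_moving.mhd"))
  write_volume(result$demons$field, file.path(dir, "displacement_field.mhd"))
  pm <- result$tumor_propagated
  write_volume(volume_image(array(as.numeric(pm$values), dim(pm$values)),
                            pm$spacing, pm$origin),
               file.path(dir, "tumor_propagated.mhd"))
  write.table(data.frame(iteration = seq_along(result$demons$msd),
                         msd = result$demons$msd),
              file.path(dir, "msd_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$dsc))
    write.table(data.frame(metric = names(result$dsc), dsc = result$dsc),
                file.path(dir, "dsc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(result$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  rigid translation: (%.2f, %.2f, %.2f) mm\n",
              x$rigid$translation[1], x$rigid$translation[2], x$rigid$translation[3]))
  cat(sprintf("  demons: %d iterations, MSD %.4g -> %.4g\n",
              x$demons$iterations, x$demons$msd[1],
              x$demons$msd[length(x$demons$msd)]))
  if (!is.null(x$dsc))
    cat(sprintf("  tumor DSC: rigid %.1f%%, deformable %.1f%%\n",
                x$dsc["rigid"], x$dsc["deformable"]))
  invisible(x)
}

#' Displacement-recovery validation of the deformable registration
#'
#' Generates the standard head phantom, deforms it with a random 2nd-order
#' polynomial field of known analytic form (mean in-body magnitude
#' `target_mean_mm`), registers the original (moving) to the deformed
#' image (static) with the Demons algorithm, and scores the fraction of
#' body voxels whose recovered displacement lies within `tol_mm` of the
#' truth.
#'
#' @param seed experiment seed.
#' @param target_mean_mm mean in-body deformation magnitude, default 5.5.
#' @param tol_mm recovery tolerance, default 2.
#' @param spec a [phantom_spec()] (seed overridden by `seed`).
#' @param params a [registration_params()].
#' @return A list with `fraction` (within-tolerance fraction),
#'   `mean_error_mm`, `truth_mean_mm`, and the registration object.
#' @export
validate_deformable <- function(seed = 1, target_mean_mm = 5.5, tol_mm = 2,
                                spec = NULL, params = registration_params()) {
  if (is.null(spec)) spec <- phantom_spec(seed = seed)
  else spec$seed <- as.integer(seed)
  ph <- make_head_phantom(spec)
  img <- remove_couch(ph$image, ph$couch_box)
  pt <- polynomial_transform(img, target_mean_mm = target_mean_mm, seed = seed)
  reg <- demons_register(static = pt$warped, moving = img, params = params)
  err <- matrix(pt$truth$vectors - reg$field$vectors, ncol = 3L)
  sel <- as.vector(pt$body$values)
  emag <- sqrt(rowSums(err[sel, , drop = FALSE]^2))
  list(fraction = mean(emag <= tol_mm),
       mean_error_mm = mean(emag),
       truth_mean_mm = field_stats(pt$truth, pt$body)$mean_magnitude_mm,
       registration = reg)
}

#' Shift-recovery validation of the rigid registration
#'
#' Applies `n_shifts` seeded random translations (components uniform in
#' `[-max_shift_mm, max_shift_mm]`, generally sub-voxel) to the standard
#' head phantom and recovers each by bone-thresholded correlation search.
#'
#' @param seed experiment seed.
#' @param n_shifts number of translations, default 20.
#' @param max_shift_mm per-component shift bound, default 10.
#' @param spec a [phantom_spec()].
#' @param ... passed to [register_rigid()].
#' @return A list with `mean_residual_mm`, `residuals_mm` and the shift
#'   matrix.
#' @export
validate_rigid <- function(seed = 1, n_shifts = 20, max_shift_mm = 10,
                           spec = NULL, ...) {
  if (is.null(spec)) spec <- phantom_spec(seed = seed)
  else spec$seed <- as.integer(seed)
  ph <- make_head_phantom(spec)
  img <- ph$image
  shifts <- with_seed(seed + 1000,
                      matrix(runif(3 * n_shifts, -max_shift_mm, max_shift_mm),
                             ncol = 3L))
  residuals <- vapply(seq_len(n_shifts), function(i) {
    moving <- translate_phantom(img, shifts[i, ])
    reg <- register_rigid(static = img, moving = moving, ...)
    sqrt(sum((reg$translation - shifts[i, ])^2))
  }, 0)
  list(mean_residual_mm = mean(residuals), residuals_mm = residuals,
       shifts_mm = shifts)
}

#' Run both validation experiments
#'
#' The polynomial-deformation recovery experiment for the Demons stage and
#' the shift-recovery experiment for the rigid stage, with their headline
#' numbers.
#'
#' @param config list with optional entries `seed`, `target_mean_mm`,
#'   `tol_mm`, `n_shifts`, `max_shift_mm`, `output_dir`.
#' @return A list with `deformable_within_tol_pct`,
#'   `rigid_mean_residual_mm` and the two detailed results.
#' @export
run_validation <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  def <- validate_deformable(seed = seed,
                             target_mean_mm = config$target_mean_mm %||% 5.5,
                             tol_mm = config$tol_mm %||% 2)
  rig <- validate_rigid(seed = seed,
                        n_shifts = config$n_shifts %||% 20,
                        max_shift_mm = config$max_shift_mm %||% 10)
  out <- list(deformable_within_tol_pct = 100 * def$fraction,
              rigid_mean_residual_mm = rig$mean_residual_mm,
              deformable = def, rigid = rig,
              manifest = list(seed = seed,
                              target_mean_mm = config$target_mean_mm %||% 5.5,
                              tol_mm = config$tol_mm %||% 2,
                              n_shifts = config$n_shifts %||% 20,
                              max_shift_mm = config$max_shift_mm %||% 10))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(c(out$manifest,
                       list(deformable_within_tol_pct = out$deformable_within_tol_pct,
                            rigid_mean_residual_mm = out$rigid_mean_residual_mm)),
                     file.path(config$output_dir, "validation.yaml"))
  }
  out
}
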
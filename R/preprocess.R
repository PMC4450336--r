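#' Blank out the treatment couch
#'
#' Sets every voxel inside an axis-aligned world-coordinate box to air
#' (-1000 HU). The box is normally supplied by the user (it was selected
#' manually on the transverse plane in the clinical workflow); the phantom
#' generator emits the correct box for its own synthetic couch. A box that
#' misses the volume is a no-op.
#'
#' @param image a [volume_image()].
#' @param couch_box `list(lo = c(x,y,z), hi = c(x,y,z))` in mm, or `NULL`
#'   for a no-op.
#' @return A [volume_image()].
#' @export
remove_couch <- function(image, couch_box) {
  stopifnot(inherits(image, "volume_image"))
  if (is.null(couch_box)) return(image)
  sel <- box_mask(image, couch_box)
  image$values[sel] <- -1000
  image
}

#' Clamp sub-threshold voxels to air
#'
#' Voxels strictly below the threshold are set to -1000 HU; voxels at or
#' above it are untouched. The default threshold of -500 HU suppresses
#' low-density non-patient material while leaving lung-free head anatomy
#' intact.
#'
#' @param image a [volume_image()].
#' @param threshold HU, default -500.
#' @return A [volume_image()].
#' @export
clamp_air <- function(image, threshold = -500) {
  stopifnot(inherits(image, "volume_image"))
  image$values[image$values < threshold] <- -1000
  image
}

#' Crop a volume to a world-coordinate region of interest
#'
#' Retains the voxels whose centers fall inside the box and updates the
#' origin so the world coordinates of retained voxels are unchanged.
#'
#' @param image a [volume_image()].
#' @param box `list(lo, hi)` in mm, or `NULL` for a no-op.
#' @return A [volume_image()].
#' @export
crop_to_roi <- function(image, box) {
  stopifnot(inherits(image, "volume_image"))
  if (is.null(box)) return(image)
  box <- as_box(box)
  d <- dim(image$values)
  idx <- lapply(1:3, function(a) {
    c <- (seq_len(d[a]) - 1) * image$spacing[a] + image$origin[a]
    which(c >= box$lo[a] & c <= box$hi[a])
  })
  if (any(lengths(idx) == 0L))
    stop("crop box retains no voxels on at least one axis", call. = FALSE)
  new_origin <- image$origin + (vapply(idx, min, 1L) - 1) * image$spacing
  volume_image(image$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               image$spacing, new_origin)
}

#' Clamp to air and resample to the standard grid
#'
#' The composition [clamp_air()] then [resample_volume()] to the standard
#' working resolution (2 x 2 x 3 mm, nearest interpolation). Applied to
#' both images of a study with equal physical extents it returns
#' grid-compatible outputs.
#'
#' @param image a [volume_image()].
#' @param air_threshold HU, default -500.
#' @param target_spacing mm, default `c(2, 2, 3)`.
#' @return A [volume_image()].
#' @export
standardize <- function(image, air_threshold = -500, target_spacing = c(2, 2, 3)) {
  resample_volume(clamp_air(image, air_threshold), target_spacing, "nearest")
}

#' Full CT preparation chain
#'
#' Couch removal, air clamping, cropping, and standard-resolution
#' resampling, in that order.
#'
#' @param image a [volume_image()].
#' @param couch_box,crop_box world boxes (mm) or `NULL`.
#' @param air_threshold HU, default -500.
#' @param target_spacing mm, default `c(2, 2, 3)`.
#' @return A [volume_image()].
#' @export
preprocess_ct <- function(image, couch_box = NULL, crop_box = NULL,
                          air_threshold = -500, target_spacing = c(2, 2, 3)) {
  x <- remove_couch(image, couch_box)
  x <- clamp_air(x, air_threshold)
  x <- crop_to_roi(x, crop_box)
  resample_volume(x, target_spacing, "nearest")
}
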
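method_code <- function(method) {
  method <- match.arg(method, c("nearest", "trilinear"))
  if (method == "nearest") 0L else 1L
}

#' Resample a volume to a new voxel spacing
#'
#' The output grid covers the same physical extent as the input (the box
#' spanned by the voxels, from half a voxel before the first center to half
#' a voxel after the last). With `method = "nearest"` each output voxel
#' takes the value of the nearest input voxel center, the interpolation the
#' standard-resolution preprocessing step uses.
#'
#' @param image a [volume_image()].
#' @param target_spacing length-3 positive numeric, mm.
#' @param method `"nearest"` or `"trilinear"`.
#' @param fill value for samples outside the input extent (default -1000 HU,
#'   air).
#' @return A [volume_image()] with spacing `target_spacing`.
#' @export
resample_volume <- function(image, target_spacing, method = "nearest",
                            fill = -1000) {
  stopifnot(inherits(image, "volume_image"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("`target_spacing` must be 3 strictly positive numbers", call. = FALSE)
  d <- dim(image$values)
  extent <- d * image$spacing
  nd <- pmax(1L, as.integer(ceiling(extent / target_spacing - 1e-9)))
  new_origin <- image$origin - image$spacing / 2 + target_spacing / 2
  out <- volume_image(array(0, nd), target_spacing, new_origin)
  q <- world_to_voxel(image, voxel_world_coords(out))
  vals <- cpp_sample3(as.numeric(image$values), d, q, method_code(method), fill)
  out$values <- array(vals, nd)
  out
}

#' Warp an image through a displacement field
#'
#' Backward mapping: the output voxel at static-grid position `x` samples
#' the input image at `x + field(x)`. Samples outside the input extent
#' return `fill` (default -1000 HU, air). The output lives on the field's
#' (static) grid.
#'
#' @param image a [volume_image()] (the moving image).
#' @param field a [displacement_field()] on the static grid (mm).
#' @param method `"nearest"` or `"trilinear"`.
#' @param fill out-of-extent fill value.
#' @return A [volume_image()] on the static grid.
#' @export
warp_image <- function(image, field, method = "trilinear", fill = -1000) {
  stopifnot(inherits(image, "volume_image"), inherits(field, "displacement_field"))
  stop_if_incompatible(image, field, "image and field")
  d <- dim(image$values)
  vec <- matrix(field$vectors, ncol = 3L)
  base <- voxel_world_coords(field)
  q <- world_to_voxel(image, base + vec)
  vals <- cpp_sample3(as.numeric(image$values), d, q, method_code(method), fill)
  volume_image(array(vals, grid_dim(field)), field$spacing, field$origin)
}

#' Warp a binary mask through a displacement field
#'
#' Nearest-neighbor warp of the 0/1 values (backward mapping on the static
#' grid); used to propagate structure masks through a computed registration.
#'
#' @param mask a [binary_mask()].
#' @param field a [displacement_field()].
#' @return A [binary_mask()] on the static grid.
#' @export
propagate_mask <- function(mask, field) {
  stopifnot(inherits(mask, "binary_mask"), inherits(field, "displacement_field"))
  stop_if_incompatible(mask, field, "mask and field")
  img <- volume_image(array(as.numeric(mask$values), dim(mask$values)),
                      mask$spacing, mask$origin)
  w <- warp_image(img, field, method = "nearest", fill = 0)
  binary_mask(array(w$values != 0, dim(w$values)), field$spacing, field$origin)
}

#' Spatial gradient of a volume
#'
#' Central differences in the interior, one-sided differences at the faces,
#' scaled by the reciprocal voxel spacing, so components are in HU/mm. A
#' degenerate axis (length 1) yields a zero component.
#'
#' @param image a [volume_image()] with at least 2 voxels per non-degenerate
#'   axis.
#' @return A 4D array `dim(image) x 3` of gradient components (HU/mm).
#' @export
image_gradient <- function(image) {
  stopifnot(inherits(image, "volume_image"))
  d <- dim(image$values)
  g <- cpp_gradient3(as.numeric(image$values), d, image$spacing)
  array(g, c(d, 3L))
}
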
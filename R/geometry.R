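#' 3D scalar volume with grid geometry
#'
#' The basic image container of the package: a 3D numeric array of voxel
#' values (CT numbers in HU, or absorbed dose in Gy) together with its grid
#' geometry. Voxel `(i, j, k)` (1-based in R) has its center at world
#' position `origin + (c(i, j, k) - 1) * spacing`, in the DICOM patient
#' (LPS) coordinate system with axes aligned to the array axes.
#'
#' @param values numeric 3D array, finite everywhere.
#' @param spacing length-3 positive numeric, voxel size in mm per axis.
#' @param origin length-3 numeric, world position (mm) of the center of the
#'   first voxel.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite everywhere", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Dense 3D displacement field
#'
#' A per-voxel vector field on the static-image grid. `vectors[i, j, k, ]`
#' is the displacement in mm pointing from the static-grid voxel center to
#' its corresponding location in the moving image (backward-mapping
#' convention: warping samples the moving image at `x + field(x)`).
#'
#' @param vectors numeric 4D array with last dimension 3 (mm).
#' @param spacing,origin grid geometry of the static image (see
#'   [volume_image()]).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("`vectors` must be a 4D array with last dimension 3", call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("displacement vectors must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  storage.mode(vectors) <- "double"
  structure(list(vectors = vectors, spacing = spacing, origin = origin),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vectors)
  mag <- sqrt(rowSums(matrix(x$vectors, ncol = 3L)^2))
  cat(sprintf("<displacement_field> %d x %d x %d voxels, |u| mean %.3f mm, max %.3f mm\n",
              d[1], d[2], d[3], mean(mag), max(mag)))
  invisible(x)
}

#' Zero displacement field on an image grid
#'
#' @param image a [volume_image()] providing the grid.
#' @return A [displacement_field()] of zeros.
#' @export
zero_field <- function(image) {
  d <- dim(image$values)
  displacement_field(array(0, c(d, 3L)), image$spacing, image$origin)
}

#' Binary mask on an image grid
#'
#' @param values logical (or 0/1 numeric) 3D array.
#' @param spacing,origin grid geometry of the parent image.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1)))
      stop("numeric mask values must be 0 or 1", call. = FALSE)
    values <- array(values != 0, dim(values))
  }
  if (!is.logical(values) || anyNA(values))
    stop("`values` must be logical with no NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  n <- sum(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d set (%.2f cm^3)\n",
              d[1], d[2], d[3], n, n * prod(x$spacing) / 1000))
  invisible(x)
}

#' Physical volume of a mask
#'
#' @param mask a [binary_mask()].
#' @return Volume in mm^3 (voxel count times voxel volume).
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * prod(mask$spacing)
}

grid_of <- function(x) list(dim = dim(x$values %||% x$vectors),
                            spacing = x$spacing, origin = x$origin)

`%||%` <- function(a, b) if (is.null(a)) b else a

grid_dim <- function(x) {
  if (inherits(x, "displacement_field")) dim(x$vectors)[1:3] else dim(x$values)
}

#' Test grid compatibility of two images, masks or fields
#'
#' Two objects are grid-compatible iff their array shape, spacing and origin
#' all match (to a small floating-point tolerance on the geometry).
#'
#' @param a,b volumes, masks or displacement fields.
#' @param tol geometry tolerance in mm.
#' @return `TRUE` or `FALSE`.
#' @export
grid_compatible <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_incompatible <- function(a, b, what = "inputs") {
  if (!grid_compatible(a, b))
    stop(sprintf("%s are not grid-compatible (shape/spacing/origin must match)", what),
         call. = FALSE)
  invisible(TRUE)
}

# World coordinates (mm) of all voxel centers, as an n x 3 matrix in
# column-major voxel order.
voxel_world_coords <- function(image) {
  d <- grid_dim(image)
  i <- (seq_len(d[1]) - 1) * image$spacing[1] + image$origin[1]
  j <- (seq_len(d[2]) - 1) * image$spacing[2] + image$origin[2]
  k <- (seq_len(d[3]) - 1) * image$spacing[3] + image$origin[3]
  cbind(rep(i, times = d[2] * d[3]),
        rep(rep(j, each = d[1]), times = d[3]),
        rep(k, each = d[1] * d[2]))
}

# 0-based continuous voxel index of world coordinates on an image grid.
world_to_voxel <- function(image, world) {
  sweep(sweep(world, 2, image$origin, "-"), 2, image$spacing, "/")
}
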
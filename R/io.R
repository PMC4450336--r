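#' Structure set: named collections of planar contours
#'
#' The in-memory form of an RT-STRUCT: each structure is a list of closed
#' planar contours, each an `n x 3` matrix of world coordinates (mm, LPS)
#' with at least 3 vertices and constant z within a contour.
#'
#' @param structures named list of lists of contour matrices.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(structures) {
  if (!is.list(structures) || is.null(names(structures)) ||
      any(names(structures) == ""))
    stop("`structures` must be a named list", call. = FALSE)
  for (nm in names(structures)) {
    for (ct in structures[[nm]]) {
      if (!is.matrix(ct) || ncol(ct) != 3L || nrow(ct) < 3L)
        stop(sprintf("structure '%s': every contour needs an n x 3 matrix with >= 3 vertices", nm),
             call. = FALSE)
    }
  }
  structure(list(structures = structures), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>\n")
  for (nm in names(x$structures))
    cat(sprintf("  %s: %d contour(s)\n", nm, length(x$structures[[nm]])))
  invisible(x)
}

# ---- DICOM CT series ----

#' Write a volume as a DICOM CT series
#'
#' One explicit-VR little-endian file per axial slice, signed 16-bit pixel
#' data with the given rescale slope/intercept. Intended for synthetic
#' fixtures; values are rounded to the stored-integer grid, so integer HU
#' round-trip exactly.
#'
#' @param image a [volume_image()] in HU.
#' @param dir output directory (created if needed).
#' @param slope,intercept rescale parameters, defaults 1 and -1024.
#' @return The slice file paths, invisibly.
#' @export
write_ct_series <- function(image, dir, slope = 1, intercept = -1024) {
  stopifnot(inherits(image, "volume_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(image$values)
  series_uid <- new_uid()
  study_uid <- new_uid()
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    stored <- as.integer(round((image$values[, , k] - intercept) / slope))
    if (any(stored < -32768L | stored > 32767L))
      stop("stored values exceed 16-bit range", call. = FALSE)
    sop <- new_uid()
    ipp <- image$origin + c(0, 0, (k - 1) * image$spacing[3])
    ds <- c(
      dcm_element(0x0008, 0x0016, "UI", UID_CT),
      dcm_element(0x0008, 0x0018, "UI", sop),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS", fmt_ds(ipp)),
      dcm_element(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0018, 0x0050, "DS", fmt_ds(image$spacing[3])),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[2]), # rows = y
      dcm_element(0x0028, 0x0011, "US", d[1]), # columns = x
      dcm_element(0x0028, 0x0030, "DS", fmt_ds(image$spacing[c(2, 1)])),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),
      dcm_element(0x0028, 0x1052, "DS", fmt_ds(intercept)),
      dcm_element(0x0028, 0x1053, "DS", fmt_ds(slope)),
      dcm_element(0x7FE0, 0x0010, "OW",
                  writeBin(as.vector(stored), raw(), size = 2L,
                           endian = "little"))
    )
    paths[k] <- file.path(dir, sprintf("ct_%03d.dcm", k))
    write_dicom_file(paths[k], UID_CT, sop, ds)
  }
  invisible(paths)
}

#' Read a DICOM CT series
#'
#' Accepts a directory of `.dcm` files or an explicit file list. Slices are
#' sorted by position along the slice axis, checked for a single series UID
#' and a uniform slice gap, and rescaled to HU.
#'
#' @param path directory or character vector of file paths.
#' @param gap_tol relative tolerance on slice-gap uniformity, default 1e-3.
#' @return A [volume_image()] in HU.
#' @export
read_ct_series <- function(path, gap_tol = 1e-3) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.dcm$", full.names = TRUE) else path
  if (length(files) < 1L) stop("no DICOM files found", call. = FALSE)
  slices <- lapply(files, function(f) {
    ds <- read_dicom_file(f)$data
    list(
      series = el_string(find_el(ds, 0x0020, 0x000E)),
      ipp = el_numbers(find_el(ds, 0x0020, 0x0032)),
      rows = el_us(find_el(ds, 0x0028, 0x0010)),
      cols = el_us(find_el(ds, 0x0028, 0x0011)),
      ps = el_numbers(find_el(ds, 0x0028, 0x0030)),
      slope = el_numbers(find_el(ds, 0x0028, 0x1053)) %||% 1,
      intercept = el_numbers(find_el(ds, 0x0028, 0x1052)) %||% 0,
      signed = (el_us(find_el(ds, 0x0028, 0x0103)) %||% 0) == 1,
      pix = find_el(ds, 0x7FE0, 0x0010)$value
    )
  })
  if (length(unique(vapply(slices, `[[`, "", "series"))) != 1L)
    stop("mixed series UIDs in CT series", call. = FALSE)
  z <- vapply(slices, function(s) s$ipp[3], 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (length(z) > 1L) {
    gaps <- diff(z)
    if (any(gaps <= 0) ||
        (max(gaps) - min(gaps)) > gap_tol * stats::median(gaps))
      stop("non-uniform slice gap: missing or duplicated slices", call. = FALSE)
    dz <- stats::median(gaps)
  } else dz <- 1
  s1 <- slices[[1]]
  nx <- s1$cols; ny <- s1$rows
  vals <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    stored <- readBin(s$pix, "integer", n = nx * ny, size = 2L,
                      signed = s$signed, endian = "little")
    vals[, , k] <- array(stored * s$slope + s$intercept, c(nx, ny))
  }
  volume_image(vals, spacing = c(s1$ps[2], s1$ps[1], dz),
               origin = c(s1$ipp[1], s1$ipp[2], z[1]))
}

# ---- RT-DOSE ----

#' Write a dose grid as a DICOM RT-DOSE file
#'
#' 32-bit unsigned pixel data with an explicit dose-grid scaling; the
#' default scaling (1e-6 Gy) keeps round-trips within 5e-7 Gy.
#'
#' @param dose a [volume_image()] of dose in Gy (non-negative).
#' @param path output file.
#' @param scaling dose-grid scaling (Gy per stored unit), default 1e-6.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(dose, path, scaling = 1e-6) {
  stopifnot(inherits(dose, "volume_image"))
  if (any(dose$values < 0)) stop("dose must be non-negative", call. = FALSE)
  d <- dim(dose$values)
  stored <- round(as.vector(dose$values) / scaling)
  if (any(stored > 2^31 - 1)) stop("dose exceeds stored range at this scaling", call. = FALSE)
  offsets <- (seq_len(d[3]) - 1) * dose$spacing[3]
  sop <- new_uid()
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_RTDOSE),
    dcm_element(0x0008, 0x0018, "UI", sop),
    dcm_element(0x0020, 0x0032, "DS", fmt_ds(dose$origin)),
    dcm_element(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0008, "IS", as.character(d[3])),
    dcm_element(0x0028, 0x0010, "US", d[2]),
    dcm_element(0x0028, 0x0011, "US", d[1]),
    dcm_element(0x0028, 0x0030, "DS", fmt_ds(dose$spacing[c(2, 1)])),
    dcm_element(0x0028, 0x0100, "US", 32L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x3004, 0x0002, "CS", "GY"),
    dcm_element(0x3004, 0x000C, "DS", fmt_ds(offsets)),
    dcm_element(0x3004, 0x000E, "DS", fmt_ds(scaling)),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(as.integer(stored), raw(), size = 4L,
                         endian = "little"))
  )
  write_dicom_file(path, UID_RTDOSE, sop, ds)
}

#' Read a DICOM RT-DOSE file
#'
#' Values are stored units times the mandatory dose-grid scaling, in Gy;
#' geometry comes from the image position and the grid frame offset vector.
#'
#' @param path RT-DOSE file.
#' @return A [volume_image()] of dose in Gy.
#' @export
read_rtdose <- function(path) {
  ds <- read_dicom_file(path)$data
  scaling <- el_numbers(find_el(ds, 0x3004, 0x000E))
  if (is.null(scaling))
    stop("RT-DOSE file has no DoseGridScaling attribute", call. = FALSE)
  nx <- el_us(find_el(ds, 0x0028, 0x0011))
  ny <- el_us(find_el(ds, 0x0028, 0x0010))
  nz <- as.integer(el_string(find_el(ds, 0x0028, 0x0008)))
  ps <- el_numbers(find_el(ds, 0x0028, 0x0030))
  ipp <- el_numbers(find_el(ds, 0x0020, 0x0032))
  offsets <- el_numbers(find_el(ds, 0x3004, 0x000C))
  gaps <- diff(offsets)
  if (length(offsets) != nz || (nz > 1 && any(gaps <= 0)) ||
      (nz > 2 && max(gaps) - min(gaps) > 1e-6))
    stop("non-uniform grid frame offset vector", call. = FALSE)
  dz <- if (nz > 1) gaps[1] else 1
  stored <- readBin(find_el(ds, 0x7FE0, 0x0010)$value, "integer",
                    n = nx * ny * nz, size = 4L, endian = "little")
  volume_image(array(stored * scaling, c(nx, ny, nz)),
               spacing = c(ps[2], ps[1], dz),
               origin = c(ipp[1], ipp[2], ipp[3] + offsets[1]))
}

# ---- RT-STRUCT ----

#' Write a structure set as a DICOM RT-STRUCT file
#'
#' @param structs a [structure_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(structs, path) {
  stopifnot(inherits(structs, "structure_set"))
  nms <- names(structs$structures)
  roi_items <- raw(0)
  contour_items <- raw(0)
  for (i in seq_along(nms)) {
    roi_items <- c(roi_items, dcm_item(c(
      dcm_element(0x3006, 0x0022, "IS", as.character(i)),
      dcm_element(0x3006, 0x0026, "LO", nms[i])
    )))
    cseq <- raw(0)
    for (ct in structs$structures[[nms[i]]]) {
      cseq <- c(cseq, dcm_item(c(
        dcm_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", as.character(nrow(ct))),
        dcm_element(0x3006, 0x0050, "DS", fmt_ds(as.vector(t(ct))))
      )))
    }
    contour_items <- c(contour_items, dcm_item(c(
      dcm_element(0x3006, 0x0040, "SQ", cseq),
      dcm_element(0x3006, 0x0084, "IS", as.character(i))
    )))
  }
  sop <- new_uid()
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    dcm_element(0x0008, 0x0018, "UI", sop),
    dcm_element(0x3006, 0x0002, "SH", "StructureSet"),
    dcm_element(0x3006, 0x0020, "SQ", roi_items),
    dcm_element(0x3006, 0x0039, "SQ", contour_items)
  )
  write_dicom_file(path, UID_RTSTRUCT, sop, ds)
}

#' Read a DICOM RT-STRUCT file
#'
#' @param path RT-STRUCT file.
#' @return A [structure_set()].
#' @export
read_rtstruct <- function(path) {
  ds <- read_dicom_file(path)$data
  roi_seq <- find_el(ds, 0x3006, 0x0020)
  con_seq <- find_el(ds, 0x3006, 0x0039)
  if (is.null(roi_seq) || is.null(con_seq))
    stop("RT-STRUCT file lacks ROI sequences", call. = FALSE)
  names_by_num <- list()
  for (item in roi_seq$items) {
    num <- el_string(find_el(item, 0x3006, 0x0022))
    names_by_num[[num]] <- el_string(find_el(item, 0x3006, 0x0026))
  }
  out <- list()
  for (item in con_seq$items) {
    num <- el_string(find_el(item, 0x3006, 0x0084))
    nm <- names_by_num[[num]] %||% paste0("ROI_", num)
    contours <- list()
    cs <- find_el(item, 0x3006, 0x0040)
    if (!is.null(cs)) {
      for (cit in cs$items) {
        pts <- el_numbers(find_el(cit, 0x3006, 0x0050))
        contours[[length(contours) + 1L]] <- matrix(pts, ncol = 3L, byrow = TRUE)
      }
    }
    out[[nm]] <- contours
  }
  structure_set(out)
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    crossing <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
    crossing[is.na(crossing)] <- FALSE
    inside <- xor(inside, crossing)
    j <- i
  }
  inside
}

#' Rasterize a named structure onto an image grid
#'
#' A voxel belongs to the mask iff its center lies inside the contour
#' polygon of its slice under the even-odd rule; multiple contours on one
#' slice combine by even-odd (XOR), so holes are supported. Slices without
#' contours are empty. Contours are matched to the nearest slice; a contour
#' farther than half a slice from any grid slice is an error.
#'
#' @param structs a [structure_set()].
#' @param name structure name.
#' @param ref a [volume_image()] providing the grid.
#' @return A [binary_mask()] on the reference grid.
#' @export
rasterize_structure <- function(structs, name, ref) {
  stopifnot(inherits(structs, "structure_set"), inherits(ref, "volume_image"))
  if (!name %in% names(structs$structures))
    stop(sprintf("unknown structure '%s'", name), call. = FALSE)
  d <- dim(ref$values)
  mask <- array(FALSE, d)
  cx <- (seq_len(d[1]) - 1) * ref$spacing[1] + ref$origin[1]
  cy <- (seq_len(d[2]) - 1) * ref$spacing[2] + ref$origin[2]
  px <- rep(cx, times = d[2])
  py <- rep(cy, each = d[1])
  for (ct in structs$structures[[name]]) {
    z <- mean(ct[, 3])
    k <- round((z - ref$origin[3]) / ref$spacing[3]) + 1
    if (k < 1 || k > d[3]) next
    if (abs(z - (ref$origin[3] + (k - 1) * ref$spacing[3])) > ref$spacing[3] / 2 + 1e-6)
      stop("contour plane does not match any slice", call. = FALSE)
    inside <- points_in_polygon(px, py, ct[, 1], ct[, 2])
    mask[, , k] <- xor(mask[, , k], array(inside, d[1:2]))
  }
  binary_mask(mask, ref$spacing, ref$origin)
}

# ---- NIfTI / MetaImage ----

lps_to_nifti_xform <- function(spacing, origin) {
  m <- diag(c(-spacing[1], -spacing[2], spacing[3], 1))
  m[1:3, 4] <- c(-origin[1], -origin[2], origin[3])
  m
}

write_nifti_vol <- function(values, spacing, origin, path) {
  img <- RNifti::asNifti(values)
  img <- RNifti::`sform<-`(img, structure(lps_to_nifti_xform(spacing, origin),
                                          code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  spacing <- c(abs(m[1, 1]), abs(m[2, 2]), abs(m[3, 3]))
  origin <- c(-m[1, 4], -m[2, 4], m[3, 4])
  values <- as.array(img)
  attributes(values) <- list(dim = dim(values)) # drop RNifti metadata
  list(values = values, spacing = spacing, origin = origin)
}

write_mha_vol <- function(values, spacing, origin, path, channels = 1L) {
  if (!grepl("\\.mhd$", path)) stop("MetaImage path must end in .mhd", call. = FALSE)
  rawpath <- sub("\\.mhd$", ".raw", path)
  d <- dim(values)
  if (channels == 1L) {
    vec <- as.vector(values)
    dims <- d
  } else {
    dims <- d[1:3]
    vec <- as.vector(aperm(values, c(4, 1, 2, 3))) # interleave channels
  }
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(fmt_ds(origin), collapse = " ")),
           paste("ElementSpacing =", paste(fmt_ds(spacing), collapse = " ")),
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementNumberOfChannels =", channels),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", basename(rawpath)))
  writeLines(hdr, path)
  con <- file(rawpath, "wb")
  on.exit(close(con))
  writeBin(vec, con, size = 8L, endian = "little")
  invisible(path)
}

read_mha_vol <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  if (!identical(kv[["ElementType"]], "MET_DOUBLE"))
    stop("only MET_DOUBLE MetaImage files are supported", call. = FALSE)
  if (identical(kv[["BinaryDataByteOrderMSB"]], "True"))
    stop("big-endian MetaImage files are not supported", call. = FALSE)
  dims <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(kv[["ElementSpacing"]], "\\s+")[[1]])
  origin <- as.numeric(strsplit(kv[["Offset"]], "\\s+")[[1]])
  channels <- as.integer(kv[["ElementNumberOfChannels"]] %||% "1")
  rawpath <- file.path(dirname(path), kv[["ElementDataFile"]])
  n <- prod(dims) * channels
  vec <- readBin(rawpath, "double", n = n, size = 8L, endian = "little")
  values <- if (channels == 1L) array(vec, dims)
  else aperm(array(vec, c(channels, dims)), c(2, 3, 4, 1))
  list(values = values, spacing = spacing, origin = origin)
}

#' Write a volume or displacement field to NIfTI or MetaImage
#'
#' Format is chosen by extension: `.nii` / `.nii.gz` (NIfTI-1 via RNifti)
#' or `.mhd` (MetaImage text header plus `.raw`, 64-bit floats, exactly
#' lossless). Geometry (spacing, LPS origin) round-trips through
#' [read_volume()] / [read_field()].
#'
#' @param x a [volume_image()] or [displacement_field()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_field <- inherits(x, "displacement_field")
  stopifnot(is_field || inherits(x, "volume_image"))
  values <- if (is_field) x$vectors else x$values
  if (grepl("\\.mhd$", path)) {
    write_mha_vol(values, x$spacing, x$origin, path,
                  channels = if (is_field) 3L else 1L)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    write_nifti_vol(values, x$spacing, x$origin, path)
  } else stop("unsupported extension (use .nii, .nii.gz or .mhd)", call. = FALSE)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path `.nii`, `.nii.gz` or `.mhd` path.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  r <- if (grepl("\\.mhd$", path)) read_mha_vol(path) else read_nifti_vol(path)
  if (length(dim(r$values)) != 3L)
    stop("file holds a multi-channel image; use read_field()", call. = FALSE)
  volume_image(r$values, r$spacing, r$origin)
}

#' Read a displacement field written by [write_volume()]
#'
#' @param path `.nii`, `.nii.gz` or `.mhd` path of a 3-component field.
#' @return A [displacement_field()].
#' @export
read_field <- function(path) {
  r <- if (grepl("\\.mhd$", path)) read_mha_vol(path) else read_nifti_vol(path)
  if (length(dim(r$values)) != 4L || dim(r$values)[4] != 3L)
    stop("file does not hold a 3-component field", call. = FALSE)
  displacement_field(r$values, r$spacing, r$origin)
}
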
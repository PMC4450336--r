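#' Dice similarity coefficient
#'
#' Overlap between two masks, `2 |A intersect B| / (|A| + |B|) x 100`, in
#' percent: 100 is a perfect match, 0 complete disjointness. Two empty
#' masks are defined to match perfectly (limit convention); empty against
#' non-empty is 0.
#'
#' @param a,b grid-compatible [binary_mask()]s.
#' @return DSC in percent.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_incompatible(a, b, "masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) return(100)
  200 * sum(a$values & b$values) / (na + nb)
}

#' Fraction of voxels whose displacement is recovered within tolerance
#'
#' Compares a recovered displacement field against a known ground-truth
#' field over a body mask: the fraction of mask voxels whose vector error
#' magnitude is at most `tol_mm`.
#'
#' @param true_field,recovered_field grid-compatible
#'   [displacement_field()]s.
#' @param body_mask a [binary_mask()] on the same grid.
#' @param tol_mm error tolerance in mm, default 2.
#' @return A fraction in `[0, 1]`.
#' @export
shift_recovery <- function(true_field, recovered_field, body_mask, tol_mm = 2) {
  stopifnot(inherits(true_field, "displacement_field"),
            inherits(recovered_field, "displacement_field"),
            inherits(body_mask, "binary_mask"))
  stop_if_incompatible(true_field, recovered_field, "fields")
  stop_if_incompatible(true_field, body_mask, "field and mask")
  sel <- as.vector(body_mask$values)
  if (!any(sel)) stop("body mask is empty", call. = FALSE)
  err <- matrix(true_field$vectors - recovered_field$vectors, ncol = 3L)[sel, , drop = FALSE]
  mean(sqrt(rowSums(err^2)) <= tol_mm)
}

#' Displacement-field summary statistics over a mask
#'
#' @param field a [displacement_field()].
#' @param mask a [binary_mask()] on the same grid; `NULL` means all voxels.
#' @return A list with `mean_magnitude_mm`, `max_magnitude_mm`,
#'   `mean_axis_mm` (length 3) and `n_voxels`.
#' @export
field_stats <- function(field, mask = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  v <- matrix(field$vectors, ncol = 3L)
  if (!is.null(mask)) {
    stop_if_incompatible(field, mask, "field and mask")
    v <- v[as.vector(mask$values), , drop = FALSE]
  }
  if (nrow(v) == 0L) stop("mask selects no voxels", call. = FALSE)
  mag <- sqrt(rowSums(v^2))
  list(mean_magnitude_mm = mean(mag), max_magnitude_mm = max(mag),
       mean_axis_mm = colMeans(v), n_voxels = nrow(v))
}

#' Tabular evaluation report
#'
#' Collects per-case tumor DSC under rigid alignment alone and under
#' deformable registration with and without the intensity-modification
#' procedure, plus displacement statistics, into one data frame; optionally
#' written as a tab-delimited table.
#'
#' @param cases a list of case results; each element a list with fields
#'   `case`, `dsc_rigid`, `dsc_noimp`, `dsc_imp`, and optionally
#'   `mean_disp_mm`, `max_disp_mm`.
#' @param file optional path for a tab-separated copy.
#' @return A data frame, invisibly if `file` is given.
#' @export
evaluation_report <- function(cases, file = NULL) {
  df <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(case = cs$case,
               dsc_rigid = cs$dsc_rigid,
               dsc_noimp = cs$dsc_noimp,
               dsc_imp = cs$dsc_imp,
               mean_disp_mm = cs$mean_disp_mm %||% NA_real_,
               max_disp_mm = cs$max_disp_mm %||% NA_real_)
  }))
  if (!is.null(file)) {
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
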